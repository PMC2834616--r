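mirna_set	n_mirnas	gene_list	ffls	p_printed
SZmiRNAs	29	160 SZGenes	32	NA
SZmiRNAs	29	75 SZGenes	12	NA
SZmiRNAs	29	124 SZGenes	27	NA
SZmiRNAs	29	270 SZGenes	38	NA
Brain miRNAs	105	160 SZGenes	55	0.020
Brain miRNAs	105	75 SZGenes	26	0.204
Brain miRNAs	105	124 SZGenes	49	0.035
Brain miRNAs	105	270 SZGenes	87	0.120
Non-brain miRNAs	94	160 SZGenes	24	1.80e-5
Non-brain miRNAs	94	75 SZGenes	11	9.86e-3
Non-brain miRNAs	94	124 SZGenes	20	4.79e-5
Non-brain miRNAs	94	270 SZGenes	27	2.97e-7
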