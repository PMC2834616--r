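matrix_id	tf_symbol
V$TCF11MAFG_01	NFE2L1
V$TCF11MAFG_01	MAFG
V$NFKB_C	NFKB1
V$NFKB_C	NFKB2
V$RP58_01	ZNF238
V$IK3_01	IKZF1
V$NGFIC_01	EGR1
V$NGFIC_01	EGR2
V$NGFIC_01	EGR3
V$NGFIC_01	EGR4
V$EGR1_01	EGR1
V$EGR1_01	EGR2
V$EGR1_01	EGR3
V$EGR1_01	EGR4
V$MZF1_02	MZF1
V$OCT_C	POU2F1
V$OCT_C	POU2F2
V$CREBP1_Q2	CREB1
V$CREBP1_Q2	ATF2
V$CREB_01	CREB1
V$CREB_01	ATF2
V$CREBP1CJUN_01	CREB1
V$CREBP1CJUN_01	ATF2
V$OLF1_01	EBF1
V$NRSF_01	REST
V$AHRARNT_01	AHR
V$AHRARNT_01	ARNT
V$AHRARNT_02	AHR
V$AHRARNT_02	ARNT
V$TAL1BETAE47_01	TCF3
V$TAL1BETAE47_01	TAL1
V$GCNF_01	NR6A1
V$POU6F1_01	POU6F1
V$PAX4_03	PAX4
V$BACH2_01	BACH2
V$BACH1_01	BACH1
V$CEBP_C	CEBPA
V$FREAC3_01	FOXC1
V$PAX5_02	PAX5
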