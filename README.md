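# fflnet

Combinatorial regulation of disease genes by microRNAs and transcription
factors, analyzed through regulatory-loop discovery. `fflnet` builds a typed
miRNA–TF–gene network from five annotation-style inputs and finds the two
motifs that matter for combinatorial control:

- a **feed-forward loop (FFL)**: a TF regulates both a miRNA and a target
  gene, while the miRNA also represses that gene;
- a **mutual feedback loop**: a TF regulates a miRNA and the miRNA targets
  the gene encoding that TF.

It is written for systems-biology analysts studying disease gene regulation
(the bundled reference tables come from a schizophrenia study) who want the
whole chain — promoter assignment, binding-site filtering, motif
enumeration, enrichment statistics, SNP overlay — as tested, scriptable R
functions rather than a collection of one-off scripts.

## The method

Inputs are tabular: gene annotations (BED), miRNA precursor annotations
(GFF3 with host gene and conservation class), a TFBS hit track (BED-like
with matrix id, consensus and Z score plus a matrix→TF sidecar), miRNA
target pairs (TSV), and SNPs (TSV). The pipeline:

1. **Promoters.** Precursors within 5 kb of each other are chained into
   clusters (assumed co-transcribed). Every gene, precursor or cluster gets
   a 5 kb strand-aware promoter window upstream of its transcription start:
   genic miRNAs use the host gene's promoter, clustered miRNAs the cluster
   promoter, intergenic miRNAs their own.
2. **Binding sites.** TFBS hits are kept when conserved (human/mouse/rat)
   and Z > 2.33, then mapped to every promoter they overlap. Redundant
   matrices — overlapping placement with a shared TF symbol, or identical
   consensus — are merged into **TF groups**, the unit at which regulators
   are counted.
3. **Edges and loops.** Target pairs are expanded from mature/family names
   to precursors (conserved sites only, primate-specific miRNAs exempt),
   and FFLs are enumerated as exact joins of the three edge sets. Feedback
   loops attach to the network only when they share a TF or miRNA with some
   FFL.
4. **Hubs.** A gene is a *core gene* when regulated by ≥ 3 TF groups and
   ≥ 3 miRNAs; a miRNA is a *core miRNA* when it targets ≥ 3 genes and is
   regulated by ≥ 3 TF groups.
5. **Statistics.** Fisher's exact test compares FFL yield between miRNA
   sets via the 2×2 table `[[FFLs_a, n_miRNAs_a], [FFLs_b, n_miRNAs_b]]`;
   a permutation test resamples target pairs and recounts loops against
   the fixed TF edges (p = proportion of replicates ≥ observed); per-miRNA
   target counts are tested against random gene sets with a one-sample
   t-test; 3'UTR lengths with a rank-sum test.
6. **SNP overlay.** SNPs are categorized by overlap with target sites,
   promoter TFBSs, precursor bodies and their 100 bp flanks.

A synthetic-data module (`sim_config()` / `generate_bundle()`) writes
miniature five-file bundles with *planted* loops, decoy binding sites and
truth tables, so every stage can be validated against known ground truth.

## Worked example

Rebuild the network implied by the bundled reference loop table and find
its hubs:

```r
library(fflnet)
library(dplyr)

bundle <- reference_edge_bundle()
groups <- merge_tfbs_groups(bundle$hits_with_owner)
ffls <- find_ffls(group_edges(bundle$tf_gene, groups),
                  group_edges(bundle$tf_mirna, groups),
                  bundle$mirna_gene)
nrow(ffls)
#> [1] 32
net <- merge_network(ffls, groups = groups)
net
#> <ffl_network> 46 nodes (mirna 11, tf 19, gene 16), 77 edges
core <- find_core_nodes(net)
core$core_genes
#> [1] "EGR3" "GRM7"
core$core_mirnas
#> [1] "hsa-miR-195" "hsa-miR-20b" "hsa-miR-9-3"
core$degrees %>% filter(node %in% c("EGR3", "hsa-miR-195"))
#> # A tibble: 2 × 6
#>   node        type  tf_groups_in mirnas_in genes_out mirnas_out
#>   <chr>       <chr>        <int>     <int>     <int>      <int>
#> 1 EGR3        gene             5         4         0          0
#> 2 hsa-miR-195 mirna            4         0         6          0
```

The 32 loops span 16 genes and 11 precursors; five hub nodes emerge. The
gene EGR3 is regulated by 5 TF groups and 4 miRNAs, and hsa-miR-195
represses 6 of the 16 genes — the regulatory backbone of the network.
Enrichment of the loop yield against a non-brain miRNA control set:

```r
tidy(ffl_set_comparison(32, 29, 24, 94))
#> # A tibble: 1 × 6
#>   method             p.value odds.ratio observed  reps  seed
#>   <chr>                <dbl>      <dbl>    <dbl> <int> <int>
#> 1 fisher_two_sided 0.0000180       4.28       NA    NA    NA
```

A full synthetic run, from simulated inputs to outputs on disk:

```r
dir <- tempfile()
generate_bundle(sim_config(planted_ffls = 7, rng_seed = 7), dir)
man <- run_all(dir, file.path(dir, "out"))
man
#> <run_manifest> seed 1
#>   FFLs: 7; feedback loops: 4; core nodes: 0
#>   stages: promoters, edges, loops, merge, core, stats, snp_overlay, export
```

Networks export to SIF/GraphML (`export_network()`) for Cytoscape;
`autoplot()` gives a quick ggplot2 view; `tidy()`/`glance()` turn test
results into tibbles. A thin command-line wrapper lives at
`inst/scripts/fflnet-run.R`.

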