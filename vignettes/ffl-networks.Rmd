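---
title: "miRNA-TF feed-forward loop networks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{miRNA-TF feed-forward loop networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fflnet)
library(dplyr)
```

## The regulatory model

Transcription factors (TFs) act on promoters; microRNAs (miRNAs) act on
3'UTR target sites. When both converge on the same gene, two motifs carry
most of the combinatorial signal. In a *feed-forward loop* (FFL) a TF
regulates a miRNA and a target gene while the miRNA also represses that
gene; in a *mutual feedback loop* the TF drives the miRNA and the miRNA
silences the gene encoding that TF. `fflnet` enumerates both motifs from
edge sets derived from annotation-style evidence and converges them into a
typed network in which hub ("core") regulators can be read off.

The model rests on three assumptions worth keeping in mind:

- **Promoter proximity implies regulation.** A conserved, high-quality
  binding-site hit within a fixed window upstream of a transcription start
  is treated as a regulatory edge. No expression data is used to confirm
  the edge.
- **Co-location implies co-transcription.** Precursors within the cluster
  gap share one promoter, and genic precursors are driven by their host
  gene's promoter. Antisense-hosted precursors do *not* share the host's
  transcription unit and are treated as intergenic (configurable).
- **Predicted target pairs are edges.** Conserved seed matches stand in
  for repression; the per-precursor expansion of mature/family names means
  loop counts are precursor-level.

## Parameters

All thresholds live in `ffl_config()`:

| parameter | default | units | role |
|---|---|---|---|
| `gene_promoter_len` | 5000 | bp | window upstream of a gene TSS |
| `mirna_promoter_len` | 5000 | bp | window upstream of precursor / cluster / host |
| `cluster_max_gap` | 5000 | bp | max inter-precursor gap within a cluster |
| `z_cutoff` | 2.33 | – | strict lower bound on TFBS Z score (kept if `z > 2.33`) |
| `require_tfbs_conserved` | on | – | human/mouse/rat conservation filter |
| `require_site_conserved` | on | – | conserved target sites; class-P (primate-specific) precursors exempt |
| `core_min_tfs` / `core_min_mirnas` / `core_min_targets` | 3 | count | hub thresholds |
| `snp_flank` | 100 | bp | inclusive flank around precursors for SNP overlay |
| `permutation_reps` | 10000 | count | resampling replicates |
| `rng_seed` | 1 | – | seed for every stochastic stage |

The miRNA promoter and cluster-gap values follow the study design the
package implements; the *gene* promoter length is not fixed by that design,
so the same 5 kb convention is used (loop results are robust down to 1 kb,
which remains available via the config). The Z cutoff is applied strictly
(`> 2.33`, the upper 1% of the score distribution), matching the filter the
binding-site track was built with.

## Choices where the design was open

- **TF-group identity is global.** Redundant matrices are merged within a
  promoter (overlapping placement plus a shared TF symbol) and across
  promoters (identical consensus, or the same matrix id). Without the
  global closure a regulator would fragment into per-promoter nodes and
  hub counting would overstate TF multiplicity. The group label is the
  shortest member matrix id, ties broken lexicographically in the C
  locale, so outputs are identical across platforms.
- **Regulators are counted as groups, not symbols.** A single matrix can
  map to four paralogous TF symbols; counting symbols would multiply one
  physical binding event into four regulators. Symbol-level counting
  remains available (`count_tf_groups = FALSE`).
- **Self-regulation.** A gene that encodes a TF of the network appears as
  a gene node, and the TF group's edge into its own gene is stored but
  flagged; self edges are excluded from the group's regulated-gene tally
  (a factor occupying its own promoter is autoregulation, not an
  additional target) while in-degrees always count every edge. Both
  behaviors are configurable.
- **Fisher table construction.** FFL yield between two miRNA sets is
  compared with the two-sided Fisher test on
  `[[FFLs_a, n_miRNAs_a], [FFLs_b, n_miRNAs_b]]`. The per-set miRNA count
  is the natural exposure for loop yield; a one-sided alternative is
  available.
- **Permutation p-value** uses the plain proportion r/N of replicates
  reaching the observed count, with the conservative (r+1)/(N+1) variant
  as an option. The per-replicate recount is exact: every pair's set of
  contributed loop triples is precomputed and a replicate count is the
  size of a union, which the test suite verifies against a literal
  re-enumeration.
- **Cluster precedence.** A genic precursor that also sits in a
  multi-member cluster uses the cluster promoter (the cluster is the
  stronger co-transcription signal); configurable.
- **SNP flank boundary** is inclusive at exactly `snp_flank` bp.
- **Ties and ordering.** Every list output is sorted (gene, miRNA, group)
  so identical inputs produce byte-identical outputs regardless of input
  order.

## Numerical and degenerate-input behavior

Coordinates use one internal convention (0-based half-open); 1-based
sources (GFF, display coordinates, SNP positions) are converted only at
I/O boundaries, which the round-trip tests pin down. Promoter windows that
would cross coordinate 0 are truncated with a warning. Empty edge sets,
zero-loop networks and header-only input files flow through every stage
and yield typed empty results. A zero-variance resampling null (a miRNA
targeting everything or nothing) falls back to an empirical quantile with
a warning rather than reporting a t-test on degenerate data.

## What the synthetic generator emulates — and what it does not

`generate_bundle()` lays genes and precursors out on three synthetic
chromosomes with feature spacing chosen so that no two promoters overlap
except by design (host genes, clusters). Planted loops are constructed to
be unambiguous: each planted FFL has its own matrix and gene, conserved
above-cutoff binding sites in both relevant promoters, and a conserved
target pair; decoy binding sites are split among sub-threshold Z scores,
non-conserved hits and off-promoter placements; decoy target pairs point
at reserved background genes. Truth tables are first-class outputs and the
tests compare pipeline output to them, never to generator internals.

This emulates the *statistical shape* of real inputs (score distributions,
conservation flags, promoter sharing), not their content: there is no
sequence, no motif model, no linkage between Z score and binding affinity,
and decoys are placed to avoid — rather than mimic — the accidental
adjacency that real genomes exhibit. Passing the recovery suite therefore
demonstrates that the machinery is correct and exact, not that the
upstream predictions it consumes are accurate.

## Problem sizes used by the test suite

The bundled reference tables are desk-scale (29 precursors, 32 loops) and
every fixture-based check runs in well under a second. The calibration
suite uses 200 null datasets with 2,000 permutation replicates each, and
the oracle-equivalence suites stay at or below 20 nodes per class where
exhaustive enumeration is the reference; these sizes give stable empirical
rates while keeping the default test run to about half a minute.

## Known limitations

- Promoters are fixed windows off an annotated TSS; alternative promoters
  and CpG/TATA structure are out of scope.
- Edges are evidence-free beyond conservation and score filters: no
  expression integration, no dynamics or logic modeling of the motifs.
- Loop counts are precursor-level; family-level collapsing is a reporting
  choice, not the enumeration unit.
- The permutation null resamples target pairs only; the TF edge set stays
  fixed, so the test asks whether *these* pairs are loop-rich, not whether
  the promoter annotation itself is unusual.
- SNP overlay reports positional overlap; it does not model allele effects
  on binding affinity.
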