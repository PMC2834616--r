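#' Analysis configuration
#'
#' Collects every tunable threshold of the pipeline in one object. Defaults
#' follow the study design the package implements: 5 kb promoters for genes,
#' miRNA precursors, miRNA clusters and host genes; a 5 kb maximum
#' inter-precursor gap for miRNA clustering; a strict Z > 2.33 cutoff with
#' human/mouse/rat conservation for TFBS hits; conserved target sites with a
#' primate-specific exemption; core-node thresholds of 3; 100 bp SNP flanks;
#' and 10,000 permutation replicates.
#'
#' @param gene_promoter_len Promoter length upstream of a gene TSS, in bp.
#' @param mirna_promoter_len Promoter length upstream of a precursor, cluster
#'   or host gene, in bp.
#' @param cluster_max_gap Maximum inter-precursor gap (bp) for two precursors
#'   to join one miRNA cluster.
#' @param cluster_same_strand Require cluster members to share a strand.
#' @param z_cutoff TFBS quality cutoff; hits are kept when `z_score > z_cutoff`
#'   (strict inequality).
#' @param require_tfbs_conserved Keep only TFBS hits conserved across
#'   human/mouse/rat.
#' @param require_site_conserved Keep only conserved miRNA target sites;
#'   precursors of primate-specific conservation class (`"P"`) are exempt.
#' @param antisense_as_intergenic Treat precursors hosted antisense to a gene
#'   as intergenic for promoter assignment (they do not share the host's
#'   transcription unit).
#' @param cluster_promoter_wins A clustered genic precursor uses the cluster
#'   promoter rather than its host gene's.
#' @param core_min_tfs,core_min_mirnas,core_min_targets Core-node (hub)
#'   thresholds: a gene is core when regulated by at least `core_min_tfs` TF
#'   groups and `core_min_mirnas` miRNAs; a miRNA is core when it regulates at
#'   least `core_min_targets` genes and is regulated by at least
#'   `core_min_tfs` TF groups.
#' @param count_tf_groups Count regulators at the merged TF-group level
#'   (`TRUE`, default) rather than per TF symbol.
#' @param exclude_self_edges Exclude self-regulation (a TF group hitting the
#'   promoter of the gene encoding one of its own symbols) from a TF group's
#'   regulated-gene/miRNA tallies.
#' @param snp_flank Flank width (bp, inclusive) around pre-miRNAs for SNP
#'   annotation.
#' @param permutation_reps Number of resampling replicates.
#' @param conservative_p Use the (r+1)/(N+1) permutation p-value instead of
#'   the plain r/N proportion.
#' @param rng_seed Integer seed used by every stochastic stage.
#'
#' @return A list of class `ffl_config`.
#' @export
#' @examples
#' cfg <- ffl_config(gene_promoter_len = 1000)
#' cfg$z_cutoff
ffl_config <- function(gene_promoter_len = 5000,
                       mirna_promoter_len = 5000,
                       cluster_max_gap = 5000,
                       cluster_same_strand = TRUE,
                       z_cutoff = 2.33,
                       require_tfbs_conserved = TRUE,
                       require_site_conserved = TRUE,
                       antisense_as_intergenic = TRUE,
                       cluster_promoter_wins = TRUE,
                       core_min_tfs = 3L,
                       core_min_mirnas = 3L,
                       core_min_targets = 3L,
                       count_tf_groups = TRUE,
                       exclude_self_edges = TRUE,
                       snp_flank = 100L,
                       permutation_reps = 10000L,
                       conservative_p = FALSE,
                       rng_seed = 1L) {
  cfg <- list(
    gene_promoter_len = as.integer(gene_promoter_len),
    mirna_promoter_len = as.integer(mirna_promoter_len),
    cluster_max_gap = as.integer(cluster_max_gap),
    cluster_same_strand = isTRUE(cluster_same_strand),
    z_cutoff = as.numeric(z_cutoff),
    require_tfbs_conserved = isTRUE(require_tfbs_conserved),
    require_site_conserved = isTRUE(require_site_conserved),
    antisense_as_intergenic = isTRUE(antisense_as_intergenic),
    cluster_promoter_wins = isTRUE(cluster_promoter_wins),
    core_min_tfs = as.integer(core_min_tfs),
    core_min_mirnas = as.integer(core_min_mirnas),
    core_min_targets = as.integer(core_min_targets),
    count_tf_groups = isTRUE(count_tf_groups),
    exclude_self_edges = isTRUE(exclude_self_edges),
    snp_flank = as.integer(snp_flank),
    permutation_reps = as.integer(permutation_reps),
    conservative_p = isTRUE(conservative_p),
    rng_seed = as.integer(rng_seed)
  )
  lens <- c("gene_promoter_len", "mirna_promoter_len", "cluster_max_gap",
            "snp_flank")
  for (nm in lens) {
    if (is.na(cfg[[nm]]) || cfg[[nm]] <= 0L) {
      stop("`", nm, "` must be a positive length in bp", call. = FALSE)
    }
  }
  if (is.na(cfg$permutation_reps) || cfg$permutation_reps < 1L) {
    stop("`permutation_reps` must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "ffl_config")
}

#' @export
print.ffl_config <- function(x, ...) {
  cat("<ffl_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

#' Read or write a configuration as YAML
#'
#' @param path File path.
#' @return `read_config()` returns an [ffl_config()] object; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(ffl_config))
  bad <- setdiff(names(vals), known)
  if (length(bad) > 0) {
    stop("unknown config field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  do.call(ffl_config, vals)
}

#' @rdname read_config
#' @param cfg An [ffl_config()] object.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "ffl_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# Coerce a config argument, accepting NULL for defaults.
as_ffl_config <- function(cfg) {
  if (is.null(cfg)) return(ffl_config())
  if (inherits(cfg, "ffl_config")) return(cfg)
  if (is.list(cfg)) return(do.call(ffl_config, cfg))
  stop("`cfg` must be an ffl_config object, a list, or NULL", call. = FALSE)
}
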