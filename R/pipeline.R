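run_stage <- function(name, timings, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(expr, error = function(e) {
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
  })
  timings[[name]] <- round(proc.time()[["elapsed"]] - t0, 3)
  list(result = res, timings = timings)
}

#' Run the full pipeline on an input bundle
#'
#' Executes the stages in order — promoters (clustering and promoter
#' assignment), edges (TFBS filtering and mapping, group merging, edge
#' construction), loops (feed-forward and feedback enumeration), merge
#' (network convergence), core (hub detection), stats (permutation
#' enrichment of the observed FFL count over resampled target pairs),
#' snp_overlay (when a SNP table is present) and export. Any stage error
#' aborts with the failing stage named. A run manifest records the exact
#' configuration, input file digests, stage timings and output paths;
#' deterministic outputs are byte-identical across re-runs with the same
#' inputs and seed.
#'
#' @param input_dir Directory with `genes.bed`, `mirnas.gff3`, `tfbs.tsv`,
#'   `matrix_tf_map.tsv`, `target_pairs.tsv` and optionally `snps.tsv`
#'   (the layout written by [generate_bundle()]).
#' @param out_dir Output directory (created if missing).
#' @param config An [ffl_config()], a path to a YAML config, or `NULL`.
#' @return Invisibly, a list of class `run_manifest` with elements
#'   `config`, `input_digests`, `timings`, `seed`, `outputs` and the main
#'   results (`ffls`, `loops`, `network`, `core`, `enrichment`,
#'   `snp_summary`).
#' @export
run_all <- function(input_dir, out_dir, config = NULL) {
  cfg <- if (is.character(config)) read_config(config) else
    as_ffl_config(config)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- list(genes = file.path(input_dir, "genes.bed"),
                mirnas = file.path(input_dir, "mirnas.gff3"),
                tfbs = file.path(input_dir, "tfbs.tsv"),
                matrix_map = file.path(input_dir, "matrix_tf_map.tsv"),
                pairs = file.path(input_dir, "target_pairs.tsv"),
                snps = file.path(input_dir, "snps.tsv"))
  timings <- list()

  st <- run_stage("promoters", timings, {
    genes <- read_gene_annotation(paths$genes)
    mirnas <- read_mirna_annotation(paths$mirnas)
    clusters <- cluster_mirnas(mirnas, cfg)
    list(genes = genes, mirnas = mirnas, clusters = clusters,
         promoters = dplyr::bind_rows(
           assign_gene_promoters(genes, cfg),
           assign_mirna_promoters(mirnas, genes, clusters, cfg)))
  })
  timings <- st$timings
  ann <- st$result

  st <- run_stage("edges", timings, {
    hits <- read_tfbs_track(paths$tfbs, paths$matrix_map)
    pairs <- read_target_pairs(paths$pairs)
    mapped <- map_tfbs_to_promoters(hits, ann$promoters, cfg)
    groups <- merge_tfbs_groups(mapped)
    tf_edges <- group_edges(build_tf_edges(mapped), groups)
    mg <- build_mirna_gene_edges(pairs, ann$mirnas, cfg)
    list(mapped = mapped, groups = groups, pairs = pairs,
         tf_gene = tf_edges[tf_edges$target_type == "gene", ] %>%
           dplyr::transmute(group_id = .data$group_id, gene = .data$target),
         tf_mirna = tf_edges[tf_edges$target_type == "mirna", ] %>%
           dplyr::transmute(group_id = .data$group_id, mirna = .data$target),
         mirna_gene = mg)
  })
  timings <- st$timings
  ed <- st$result

  st <- run_stage("loops", timings, {
    list(ffls = find_ffls(ed$tf_gene, ed$tf_mirna, ed$mirna_gene),
         loops = find_feedback_loops(ed$tf_mirna, ed$mirna_gene, ed$groups))
  })
  timings <- st$timings
  lp <- st$result

  st <- run_stage("merge", timings,
                  merge_network(lp$ffls, lp$loops, ed$groups))
  timings <- st$timings
  net <- st$result

  st <- run_stage("core", timings, find_core_nodes(net, cfg))
  timings <- st$timings
  core <- st$result

  st <- run_stage("stats", timings, {
    used <- dplyr::distinct(ed$mirna_gene[, c("mirna", "gene")])
    k <- nrow(used)
    universe <- dplyr::distinct(ed$pairs[, c("mirna", "gene")])
    if (k >= 1 && nrow(universe) > k) {
      permutation_ffl_test(nrow(lp$ffls), universe, k, ed$tf_gene,
                           ed$tf_mirna, ann$mirnas, cfg)
    } else NULL
  })
  timings <- st$timings
  enrich <- st$result

  snp_res <- NULL
  if (file.exists(paths$snps)) {
    st <- run_stage("snp_overlay", timings, {
      snps <- read_snps(paths$snps)
      anns <- annotate_snps(snps, ed$mirna_gene, ed$mapped, ann$mirnas, cfg)
      list(annotations = anns, summary = summarize_snp_annotations(anns))
    })
    timings <- st$timings
    snp_res <- st$result
  }

  st <- run_stage("export", timings, {
    out <- list(
      ffls = file.path(out_dir, "ffls.tsv"),
      loops = file.path(out_dir, "feedback_loops.tsv"),
      sif = file.path(out_dir, "network.sif"),
      graphml = file.path(out_dir, "network.graphml"),
      core = file.path(out_dir, "core_nodes.tsv"),
      enrichment = file.path(out_dir, "enrichment.tsv"),
      manifest = file.path(out_dir, "run_manifest.yaml")
    )
    readr::write_tsv(lp$ffls, out$ffls, progress = FALSE)
    readr::write_tsv(lp$loops, out$loops, progress = FALSE)
    export_network(net, out$sif, "sif")
    export_network(net, out$graphml, "graphml")
    deg <- core$degrees
    deg$core <- deg$node %in% c(core$core_genes, core$core_mirnas)
    readr::write_tsv(deg, out$core, progress = FALSE)
    if (!is.null(enrich)) {
      readr::write_tsv(tidy(enrich), out$enrichment, progress = FALSE)
    }
    if (!is.null(snp_res)) {
      out$snp_annotations <- file.path(out_dir, "snp_annotations.tsv")
      out$snp_summary <- file.path(out_dir, "snp_summary.tsv")
      readr::write_tsv(snp_res$annotations, out$snp_annotations,
                       progress = FALSE)
      readr::write_tsv(snp_res$summary, out$snp_summary, progress = FALSE)
    }
    out
  })
  timings <- st$timings
  outputs <- st$result

  manifest <- structure(list(
    config = unclass(cfg),
    input_digests = as.list(tools::md5sum(unlist(paths[file.exists(
      unlist(paths))]))),
    timings = timings,
    seed = cfg$rng_seed,
    outputs = lapply(outputs, identity),
    ffls = lp$ffls, loops = lp$loops, network = net, core = core,
    enrichment = enrich, snp_summary = snp_res$summary
  ), class = "run_manifest")
  yaml::write_yaml(list(config = unclass(cfg),
                        input_digests = manifest$input_digests,
                        timings = timings, seed = cfg$rng_seed,
                        outputs = lapply(outputs, identity)),
                   outputs$manifest)
  invisible(manifest)
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> seed ", x$seed, "\n", sep = "")
  cat("  FFLs: ", nrow(x$ffls), "; feedback loops: ", nrow(x$loops),
      "; core nodes: ",
      length(x$core$core_genes) + length(x$core$core_mirnas), "\n", sep = "")
  cat("  stages: ", paste(names(x$timings), collapse = ", "), "\n", sep = "")
  invisible(x)
}
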