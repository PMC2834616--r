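upstream_interval <- function(start, end, strand, len) {
  if (strand == "+") {
    list(start = start - len, end = start)
  } else {
    list(start = end, end = end + len)
  }
}

#' Cluster miRNA precursors by genomic proximity
#'
#' Single-linkage chaining along each chromosome: two precursors join one
#' cluster when the gap from the end of one to the start of the next is at
#' most `cfg$cluster_max_gap` (5 kb by default). Clustered precursors are
#' assumed co-transcribed and later share one promoter. By default members
#' must also share a strand (`cfg$cluster_same_strand`). Singletons are
#' returned as one-member clusters, so the result is a partition of the
#' input and is independent of input order.
#'
#' @param mirnas Precursor tibble from [read_mirna_annotation()].
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tibble with one row per cluster: `cluster_id`, `chrom`, `start`,
#'   `end`, `strand`, `n_members`, `members` (list column of precursor ids
#'   ordered by coordinate).
#' @export
#' @examples
#' fx <- load_reference_fixtures()
#' clusters <- cluster_mirnas(fx$mirnas)
#' sum(clusters$n_members > 1)
cluster_mirnas <- function(mirnas, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  check_intervals(mirnas, "miRNA annotation")
  key <- if (cfg$cluster_same_strand) {
    paste(mirnas$chrom, mirnas$strand)
  } else mirnas$chrom
  ord <- order(key, mirnas$start, mirnas$end, mirnas$precursor_id)
  m <- mirnas[ord, ]
  k <- key[ord]
  if (nrow(m) == 0) {
    return(tibble(cluster_id = character(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  n_members = integer(), members = list()))
  }
  # chain: new cluster when chromosome/strand changes or the gap to the
  # running maximum end exceeds the threshold
  cl <- integer(nrow(m))
  cl[1] <- 1L
  run_end <- m$end[1]
  for (i in seq_len(nrow(m))[-1]) {
    if (k[i] != k[i - 1] || m$start[i] - run_end > cfg$cluster_max_gap) {
      cl[i] <- cl[i - 1] + 1L
      run_end <- m$end[i]
    } else {
      cl[i] <- cl[i - 1]
      run_end <- max(run_end, m$end[i])
    }
  }
  m$._cl <- cl
  m %>%
    dplyr::group_by(.data$._cl) %>%
    dplyr::summarise(
      cluster_id = paste0("cluster:", dplyr::first(.data$precursor_id)),
      chrom = dplyr::first(.data$chrom),
      start = min(.data$start), end = max(.data$end),
      strand = dplyr::first(.data$strand),
      n_members = dplyr::n(),
      members = list(.data$precursor_id),
      .groups = "drop"
    ) %>%
    dplyr::select(-"._cl") %>%
    dplyr::arrange(.data$chrom, .data$start, .data$cluster_id)
}

#' Assign promoter intervals to miRNA precursors
#'
#' Each precursor receives one fixed-length promoter window
#' (`cfg$mirna_promoter_len`, 5 kb by default) strand-aware upstream of its
#' transcription basis. The basis is, in order of precedence: the miRNA
#' cluster span for precursors in a multi-member cluster (when
#' `cfg$cluster_promoter_wins`), the host gene's TSS for genic (intronic or
#' 3'UTR-hosted) precursors, and the precursor itself otherwise. Precursors
#' hosted antisense to a gene do not share its transcription unit and are
#' treated as intergenic when `cfg$antisense_as_intergenic` is set.
#'
#' @param mirnas Precursor tibble from [read_mirna_annotation()].
#' @param genes Gene tibble from [read_gene_annotation()]; needed to resolve
#'   host-gene promoters. An intronic precursor whose host is absent raises
#'   an unresolved-host error.
#' @param clusters Optional precomputed [cluster_mirnas()] result.
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tibble with one row per precursor: `owner` (precursor id),
#'   `owner_type` (`"mirna"`), `basis` (`host_gene`, `precursor` or
#'   `cluster`), `basis_id`, `chrom`, `start`, `end`, `strand`. Clustered
#'   precursors share one interval. Windows crossing coordinate 0 are
#'   truncated with a warning.
#' @export
assign_mirna_promoters <- function(mirnas, genes = NULL, clusters = NULL,
                                   cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  if (is.null(clusters)) clusters <- cluster_mirnas(mirnas, cfg)
  member_of <- clusters %>%
    dplyr::filter(.data$n_members > 1) %>%
    tidyr::unnest_longer("members", values_to = "precursor_id")
  rows <- purrr::map_dfr(seq_len(nrow(mirnas)), function(i) {
    m <- mirnas[i, ]
    rel <- m$host_relation
    if (cfg$antisense_as_intergenic && rel == "antisense") rel <- "intergenic"
    clu <- member_of[member_of$precursor_id == m$precursor_id, ]
    if (nrow(clu) == 1 && cfg$cluster_promoter_wins) {
      up <- upstream_interval(clu$start, clu$end, clu$strand,
                              cfg$mirna_promoter_len)
      return(tibble(owner = m$precursor_id, owner_type = "mirna",
                    basis = "cluster", basis_id = clu$cluster_id,
                    chrom = clu$chrom, start = up$start, end = up$end,
                    strand = clu$strand))
    }
    if (rel %in% c("intronic", "utr3")) {
      if (is.null(genes) || !m$host_gene %in% genes$symbol) {
        stop("unresolved host gene '", m$host_gene, "' for ", m$precursor_id,
             call. = FALSE)
      }
      g <- genes[genes$symbol == m$host_gene, ][1, ]
      up <- upstream_interval(g$start, g$end, g$strand,
                              cfg$mirna_promoter_len)
      return(tibble(owner = m$precursor_id, owner_type = "mirna",
                    basis = "host_gene", basis_id = g$symbol,
                    chrom = g$chrom, start = up$start, end = up$end,
                    strand = g$strand))
    }
    up <- upstream_interval(m$start, m$end, m$strand, cfg$mirna_promoter_len)
    tibble(owner = m$precursor_id, owner_type = "mirna", basis = "precursor",
           basis_id = m$precursor_id, chrom = m$chrom, start = up$start,
           end = up$end, strand = m$strand)
  })
  truncate_at_zero(rows)
}

#' Assign promoter intervals to genes
#'
#' A window of `cfg$gene_promoter_len` bp ending at the TSS, strand-aware:
#' `[tss - len, tss)` on the plus strand and `[tss, tss + len)` on the minus
#' strand. Windows that would cross coordinate 0 are truncated with a
#' warning.
#'
#' @param genes Gene tibble from [read_gene_annotation()].
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tibble: `owner` (gene symbol), `owner_type` (`"gene"`), `basis`
#'   (`"gene_tss"`), `basis_id`, `chrom`, `start`, `end`, `strand`.
#' @export
assign_gene_promoters <- function(genes, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  up <- purrr::map2(genes$strand, seq_len(nrow(genes)), function(s, i) {
    upstream_interval(genes$start[i], genes$end[i], s, cfg$gene_promoter_len)
  })
  rows <- tibble(
    owner = genes$symbol, owner_type = "gene", basis = "gene_tss",
    basis_id = genes$symbol, chrom = genes$chrom,
    start = vapply(up, `[[`, numeric(1), "start"),
    end = vapply(up, `[[`, numeric(1), "end"),
    strand = genes$strand
  )
  rows$start <- as.integer(rows$start)
  rows$end <- as.integer(rows$end)
  truncate_at_zero(rows)
}

truncate_at_zero <- function(promoters) {
  neg <- promoters$start < 0
  if (any(neg)) {
    warning(sum(neg), " promoter window(s) truncated at coordinate 0",
            call. = FALSE)
    promoters$start[neg] <- 0L
  }
  promoters
}

#' Map TFBS hits onto promoter intervals
#'
#' Applies the quality filters — `z_score > cfg$z_cutoff` (strict) and, when
#' `cfg$require_tfbs_conserved`, the human/mouse/rat conservation flag — and
#' keeps every hit whose interval overlaps a promoter by at least 1 bp. A
#' hit overlapping several promoters yields one row per owner.
#'
#' @param hits TFBS tibble from [read_tfbs_track()].
#' @param promoters Promoter tibble from [assign_gene_promoters()] and/or
#'   [assign_mirna_promoters()] (rows may be concatenated).
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return The filtered hits with added columns `owner`, `owner_type` and
#'   `basis` of the overlapped promoter.
#' @export
map_tfbs_to_promoters <- function(hits, promoters, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  keep <- hits$z_score > cfg$z_cutoff
  if (cfg$require_tfbs_conserved) keep <- keep & hits$conserved
  hits <- hits[keep, , drop = FALSE]
  ov <- overlap_pairs(hits, promoters)
  out <- dplyr::bind_cols(
    hits[ov$query, , drop = FALSE],
    promoters[ov$subject, c("owner", "owner_type", "basis"), drop = FALSE]
  )
  dplyr::arrange(out, .data$owner, .data$matrix_id, .data$start)
}
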