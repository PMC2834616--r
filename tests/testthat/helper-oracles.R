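# Independent brute-force oracles and small builders shared across tests.

# FFL enumeration by literal triple loop over all (group, mirna, gene)
# combinations; stays independent of the join-based implementation.
brute_force_ffls <- function(tf_gene, tf_mirna, mirna_gene) {
  groups <- unique(c(tf_gene$group_id, tf_mirna$group_id))
  mirnas <- unique(c(tf_mirna$mirna, mirna_gene$mirna))
  genes <- unique(c(tf_gene$gene, mirna_gene$gene))
  has <- function(df, a, b) any(df[[1]] == a & df[[2]] == b)
  out <- list()
  for (g in groups) for (m in mirnas) for (t in genes) {
    if (has(tf_gene[, c("group_id", "gene")], g, t) &&
        has(tf_mirna[, c("group_id", "mirna")], g, m) &&
        has(mirna_gene[, c("mirna", "gene")], m, t)) {
      out[[length(out) + 1]] <- tibble::tibble(group_id = g, mirna = m,
                                               gene = t)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(group_id = character(), mirna = character(),
                          gene = character()))
  }
  dplyr::arrange(res, gene, mirna, group_id)
}

# all-pairs interval overlap scan (same-chromosome, >= 1 bp)
brute_force_overlaps <- function(query, subject) {
  out <- list()
  for (i in seq_len(nrow(query))) for (j in seq_len(nrow(subject))) {
    if (query$chrom[i] == subject$chrom[j] &&
        query$start[i] < subject$end[j] &&
        subject$start[j] < query$end[i]) {
      out[[length(out) + 1]] <- tibble::tibble(query = i, subject = j)
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(query = integer(), subject = integer()))
  }
  dplyr::arrange(res, query, subject)
}

random_edge_sets <- function(n_groups, n_mirnas, n_genes, density = 0.3) {
  gs <- sprintf("g%02d", seq_len(n_groups))
  ms <- sprintf("m%02d", seq_len(n_mirnas))
  ts <- sprintf("t%02d", seq_len(n_genes))
  pick <- function(a, b) {
    grid <- expand.grid(a = a, b = b, stringsAsFactors = FALSE)
    grid[stats::runif(nrow(grid)) < density, ]
  }
  tg <- pick(gs, ts); tm <- pick(gs, ms); mg <- pick(ms, ts)
  list(
    tf_gene = tibble::tibble(group_id = tg$a, gene = tg$b),
    tf_mirna = tibble::tibble(group_id = tm$a, mirna = tm$b),
    mirna_gene = tibble::tibble(mirna = mg$a, gene = mg$b)
  )
}

toy_mirnas <- function(...) {
  rows <- list(...)
  dplyr::bind_rows(lapply(rows, function(r) {
    tibble::tibble(
      precursor_id = r$id, family_id = r$family %||% r$id,
      matures = r$matures %||% (r$family %||% r$id),
      chrom = r$chrom %||% "c1", start = r$start, end = r$end,
      strand = r$strand %||% "+",
      host_gene = r$host %||% "INTERGENIC",
      host_relation = r$rel %||%
        (if (is.null(r$host)) "intergenic" else "intronic"),
      conservation_class = r$class %||% "V"
    )
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fixture_mirna <- function(ids) {
  fx <- load_reference_fixtures()
  fx$mirnas[fx$mirnas$precursor_id %in% ids, ]
}
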