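new_ffl_enrichment <- function(method, p_value, ..., table = NULL,
                               odds_ratio = NA_real_, reps = NA_integer_,
                               seed = NA_integer_) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(
    c(list(method = method, p_value = p_value, table = table,
           odds_ratio = odds_ratio, reps = reps, seed = seed), list(...)),
    class = "ffl_enrichment"
  )
}

#' @export
print.ffl_enrichment <- function(x, ...) {
  cat("<ffl_enrichment> method: ", x$method, "\n", sep = "")
  if (!is.null(x$table)) {
    cat("  table:\n")
    print(x$table)
  }
  if (!is.na(x$odds_ratio)) cat("  odds ratio:", format(x$odds_ratio), "\n")
  cat("  p value:  ", format(x$p_value), "\n")
  if (!is.na(x$reps)) cat("  reps:     ", x$reps, " (seed ", x$seed, ")\n",
                          sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an enrichment result
#'
#' @param x An `ffl_enrichment` object.
#' @param ... Unused.
#' @return A one-row tibble with `method`, `p.value`, `odds.ratio`,
#'   `observed`, `reps` and `seed`.
#' @export
tidy.ffl_enrichment <- function(x, ...) {
  tibble(method = x$method, p.value = x$p_value, odds.ratio = x$odds_ratio,
         observed = x$observed %||% NA_real_, reps = x$reps, seed = x$seed)
}

#' @rdname tidy.ffl_enrichment
#' @export
glance.ffl_enrichment <- function(x, ...) tidy(x, ...)

# Evaluate code under a fixed seed without disturbing the caller's RNG.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

#' Compare FFL yield between two miRNA sets
#'
#' Two-sided Fisher's exact test on the 2x2 table
#' `[[ffl_a, n_mirna_a], [ffl_b, n_mirna_b]]`: the number of feed-forward
#' loops obtained from each miRNA set against the size of that set, for the
#' same gene list.
#'
#' @param ffl_a,n_mirna_a FFL count and miRNA count of the first set.
#' @param ffl_b,n_mirna_b FFL count and miRNA count of the second set.
#' @param alternative Passed to [stats::fisher.test()]; default two-sided.
#' @return An `ffl_enrichment` with the table, odds ratio and p-value.
#' @export
#' @examples
#' tidy(ffl_set_comparison(32, 29, 24, 94))
ffl_set_comparison <- function(ffl_a, n_mirna_a, ffl_b, n_mirna_b,
                               alternative = "two.sided") {
  counts <- c(ffl_a, n_mirna_a, ffl_b, n_mirna_b)
  if (any(counts < 0)) stop("counts must be >= 0", call. = FALSE)
  if (all(counts == 0)) {
    stop("all-zero contingency table: test undefined", call. = FALSE)
  }
  tab <- matrix(counts, nrow = 2, byrow = TRUE,
                dimnames = list(set = c("a", "b"),
                                count = c("ffls", "mirnas")))
  ft <- stats::fisher.test(tab, alternative = alternative)
  new_ffl_enrichment("fisher_two_sided", ft$p.value, table = tab,
                     odds_ratio = unname(ft$estimate))
}

# Triple sets contributed by each target pair: pair i yields all FFL
# triples (group, precursor, gene_i) where the group regulates both gene_i
# and a precursor that the pair's miRNA name expands to. Triples are
# integer-coded so per-replicate recounting is a cheap set-size.
pair_triple_sets <- function(pairs, tf_gene, tf_mirna, mirnas = NULL,
                             cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  pairs <- dplyr::distinct(pairs[, c("mirna", "gene")])
  pairs$pair_id <- seq_len(nrow(pairs))
  mg <- if (is.null(mirnas)) {
    dplyr::mutate(pairs, precursor = .data$mirna)
  } else {
    pairs %>%
      dplyr::inner_join(
        dplyr::bind_rows(
          tibble(name = mirnas$precursor_id, precursor = mirnas$precursor_id),
          tibble(name = mirnas$family_id, precursor = mirnas$precursor_id),
          tibble(name = unlist(split_symbols(mirnas$matures)),
                 precursor = rep(mirnas$precursor_id,
                                 lengths(split_symbols(mirnas$matures))))
        ) %>% dplyr::distinct(),
        by = c(mirna = "name"), relationship = "many-to-many"
      )
  }
  triples <- mg %>%
    dplyr::inner_join(dplyr::distinct(tf_gene[, c("group_id", "gene")]),
                      by = "gene", relationship = "many-to-many") %>%
    dplyr::inner_join(
      dplyr::distinct(tf_mirna[, c("group_id", "mirna")]) %>%
        dplyr::rename(precursor = "mirna"),
      by = c("group_id", "precursor")
    ) %>%
    dplyr::distinct(.data$pair_id, .data$group_id, .data$precursor,
                    .data$gene)
  key <- paste(triples$group_id, triples$precursor, triples$gene, sep = "\r")
  code <- match(key, unique(key))
  sets <- split(code, factor(triples$pair_id, levels = pairs$pair_id))
  lapply(sets, unique)
}

#' Permutation test of FFL enrichment over resampled target pairs
#'
#' Implements the resampling null: each replicate draws `k` miRNA target
#' pairs uniformly without replacement from the full prediction table,
#' rebuilds the miRNA-to-gene edge set, recounts feed-forward loops against
#' the fixed TF edges, and the p-value is the proportion of replicates
#' whose count is at least the observed count (with the conservative
#' `(r+1)/(n+1)` variant available via `cfg$conservative_p`). The
#' per-replicate recount is exact: each pair's contribution of FFL triples
#' is precomputed and the replicate count is the size of the union.
#'
#' @param observed Observed FFL count.
#' @param pairs Target-pair tibble (at least `mirna`, `gene`); duplicates
#'   at (mirna, gene) level are collapsed.
#' @param k Number of pairs to draw per replicate; must not exceed the
#'   number of distinct pairs.
#' @param tf_gene,tf_mirna Group-level TF edge tibbles (the fixed promoter
#'   index).
#' @param mirnas Optional precursor tibble; when supplied, pair names are
#'   expanded to precursors per replicate exactly as in
#'   [build_mirna_gene_edges()].
#' @param cfg An [ffl_config()]; supplies `permutation_reps` and `rng_seed`.
#' @return An `ffl_enrichment` with the observed count, the replicate null
#'   counts (`null`), `reps`, `seed` and the permutation p-value.
#' @export
permutation_ffl_test <- function(observed, pairs, k, tf_gene, tf_mirna,
                                 mirnas = NULL, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  sets <- pair_triple_sets(pairs, tf_gene, tf_mirna, mirnas, cfg)
  n <- length(sets)
  if (k > n) {
    stop("k (", k, ") exceeds the number of distinct pairs (", n, ")",
         call. = FALSE)
  }
  sizes <- lengths(sets)
  # when no triple is shared between pairs, the union size is a plain sum
  disjoint <- sum(sizes) == length(unique(unlist(sets)))
  counts <- with_seed(cfg$rng_seed, {
    vapply(seq_len(cfg$permutation_reps), function(r) {
      idx <- sample.int(n, k)
      if (disjoint) sum(sizes[idx])
      else length(unique(unlist(sets[idx], use.names = FALSE)))
    }, numeric(1))
  })
  r <- sum(counts >= observed)
  p <- if (cfg$conservative_p) (r + 1) / (cfg$permutation_reps + 1)
       else r / cfg$permutation_reps
  new_ffl_enrichment("permutation", p, observed = observed, null = counts,
                     reps = cfg$permutation_reps, seed = cfg$rng_seed)
}

#' Per-miRNA target-count test against random gene sets
#'
#' Counts how many genes of a focal set a miRNA targets, builds the null
#' distribution of that count over random gene sets of the same size drawn
#' uniformly without replacement from a gene universe, and tests the
#' observed count against the null draws with a one-sample t-test. The
#' empirical exceedance quantile and the direction (more or fewer targets
#' than random) are reported alongside. A degenerate (zero-variance) null
#' falls back to the empirical quantile with a warning.
#'
#' @param mirna miRNA name as it appears in `pairs$mirna`.
#' @param focal_genes Character vector, the gene set of interest.
#' @param universe Character vector of candidate genes to draw from.
#' @param pairs Target-pair tibble (`mirna`, `gene`).
#' @param cfg An [ffl_config()]; supplies `permutation_reps` and `rng_seed`.
#' @return An `ffl_enrichment` with `observed`, `null`, `empirical_ge`
#'   (proportion of draws at least the observed count) and `direction`.
#' @export
target_count_enrichment <- function(mirna, focal_genes, universe, pairs,
                                    cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  if (length(focal_genes) > length(universe)) {
    stop("focal set larger than universe", call. = FALSE)
  }
  targets <- unique(pairs$gene[pairs$mirna == mirna])
  observed <- sum(focal_genes %in% targets)
  null <- with_seed(cfg$rng_seed, {
    vapply(seq_len(cfg$permutation_reps), function(r) {
      sum(sample(universe, length(focal_genes)) %in% targets)
    }, numeric(1))
  })
  emp_ge <- mean(null >= observed)
  direction <- if (observed > mean(null)) "more"
               else if (observed < mean(null)) "fewer" else "equal"
  if (stats::var(null) == 0) {
    warning("zero-variance null; reporting empirical quantile p-value",
            call. = FALSE)
    p <- if (all(null == observed)) 1 else
      min(1, 2 * min(emp_ge, mean(null <= observed)))
    return(new_ffl_enrichment("permutation", p, observed = observed,
                              null = null, empirical_ge = emp_ge,
                              direction = direction,
                              reps = cfg$permutation_reps,
                              seed = cfg$rng_seed))
  }
  tt <- stats::t.test(null, mu = observed)
  new_ffl_enrichment("t_test", tt$p.value, observed = observed, null = null,
                     empirical_ge = emp_ge, direction = direction,
                     statistic = unname(tt$statistic),
                     reps = cfg$permutation_reps, seed = cfg$rng_seed)
}

#' Compare 3'UTR length distributions
#'
#' Two-sided Wilcoxon rank-sum test between two sets of UTR lengths, used
#' to check that a focal gene list does not differ from background in the
#' sequence space available for target sites.
#'
#' @param lengths_a,lengths_b Numeric vectors of 3'UTR lengths (bp).
#' @return An `ffl_enrichment` with method `wilcoxon`.
#' @export
utr_length_test <- function(lengths_a, lengths_b) {
  if (length(lengths_a) == 0 || length(lengths_b) == 0) {
    stop("both length vectors must be non-empty", call. = FALSE)
  }
  wt <- suppressWarnings(stats::wilcox.test(lengths_a, lengths_b))
  new_ffl_enrichment("wilcoxon", wt$p.value,
                     statistic = unname(wt$statistic),
                     observed = stats::median(lengths_a) -
                       stats::median(lengths_b))
}
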