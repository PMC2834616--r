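test_that("Fisher comparison reproduces known p-values on the count table", {
  r <- ffl_set_comparison(32, 29, 24, 94)
  expect_equal(signif(r$p_value, 3), 1.80e-5)
  r2 <- ffl_set_comparison(32, 29, 55, 105)
  expect_equal(signif(r2$p_value, 2), 0.020)
  r3 <- ffl_set_comparison(5, 10, 5, 10)
  expect_equal(r3$p_value, 1)
})

test_that("Fisher p is row-swap invariant and the odds ratio inverts", {
  a <- ffl_set_comparison(12, 29, 11, 94)
  b <- ffl_set_comparison(11, 94, 12, 29)
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$odds_ratio * b$odds_ratio, 1, tolerance = 1e-6)
  expect_error(ffl_set_comparison(0, 0, 0, 0), "all-zero")
  expect_error(ffl_set_comparison(-1, 2, 3, 4), ">= 0")
})

test_that("tidy and glance return one-row summaries", {
  r <- ffl_set_comparison(32, 29, 24, 94)
  td <- tidy(r)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 1)
  expect_equal(td$method, "fisher_two_sided")
  expect_equal(glance(r)$p.value, r$p_value)
})

# a small planted scenario: 6 focal pairs each completing one FFL, decoy
# pairs completing none
planted_perm_setup <- function(n_decoys = 40) {
  tg <- tibble::tibble(group_id = sprintf("g%d", 1:6),
                       gene = sprintf("T%d", 1:6))
  tm <- tibble::tibble(group_id = sprintf("g%d", 1:6),
                       mirna = sprintf("m%d", 1:6))
  focal <- tibble::tibble(mirna = sprintf("m%d", 1:6),
                          gene = sprintf("T%d", 1:6))
  decoys <- tibble::tibble(mirna = sprintf("m%d", rep(1:6, length.out = n_decoys)),
                           gene = sprintf("D%d", seq_len(n_decoys)))
  list(tg = tg, tm = tm, focal = focal,
       universe = dplyr::bind_rows(focal, decoys))
}

test_that("permutation test recovers planted enrichment and trivial nulls", {
  s <- planted_perm_setup()
  cfg <- ffl_config(permutation_reps = 1000, rng_seed = 5)
  r <- permutation_ffl_test(6, s$universe, k = 6, s$tg, s$tm, cfg = cfg)
  expect_lte(r$p_value, 0.01)
  expect_equal(r$observed, 6)
  # observed zero can never be exceeded
  r0 <- permutation_ffl_test(0, s$universe, k = 6, s$tg, s$tm, cfg = cfg)
  expect_equal(r0$p_value, 1)
  # p sits on the replicate grid
  expect_equal(r$p_value * cfg$permutation_reps,
               round(r$p_value * cfg$permutation_reps))
  expect_error(
    permutation_ffl_test(1, s$focal, k = 100, s$tg, s$tm, cfg = cfg),
    "exceeds"
  )
})

test_that("per-pair triple precomputation equals a literal re-enumeration", {
  # overlapping triple sets: a family name and one of its precursors name
  # the same (precursor, gene) edges
  mirnas <- fixture_mirna(c("hsa-miR-9-1", "hsa-miR-9-2", "hsa-miR-9-3"))
  tg <- tibble::tibble(group_id = c("gA", "gB"), gene = c("T1", "T1"))
  tm <- tibble::tibble(group_id = c("gA", "gA", "gB"),
                       mirna = c("hsa-miR-9-1", "hsa-miR-9-2",
                                 "hsa-miR-9-1"))
  pairs <- tibble::tibble(mirna = c("hsa-miR-9", "hsa-miR-9-1", "hsa-miR-9-2"),
                          gene = "T1")
  sets <- fflnet:::pair_triple_sets(pairs, tg, tm, mirnas)
  idx_sets <- unlist(lapply(1:3, function(k) utils::combn(3, k, simplify = FALSE)),
                     recursive = FALSE)
  for (idx in idx_sets) {
    fast <- length(unique(unlist(sets[idx])))
    chosen <- pairs[idx, ]
    edges <- build_mirna_gene_edges(
      dplyr::mutate(chosen, chrom = NA_character_, start = NA_integer_,
                    end = NA_integer_, site_conserved = TRUE),
      mirnas
    )
    expect_equal(fast, nrow(find_ffls(tg, tm, edges)))
  }
})

test_that("identical seeds give identical resampling results", {
  s <- planted_perm_setup()
  cfg <- ffl_config(permutation_reps = 200, rng_seed = 42)
  r1 <- permutation_ffl_test(3, s$universe, k = 6, s$tg, s$tm, cfg = cfg)
  r2 <- permutation_ffl_test(3, s$universe, k = 6, s$tg, s$tm, cfg = cfg)
  expect_identical(r1$null, r2$null)
  cfg2 <- ffl_config(permutation_reps = 200, rng_seed = 43)
  r3 <- permutation_ffl_test(3, s$universe, k = 6, s$tg, s$tm, cfg = cfg2)
  expect_false(identical(r1$null, r3$null))
})

test_that("conservative permutation p-value never reaches zero", {
  s <- planted_perm_setup()
  cfg <- ffl_config(permutation_reps = 200, rng_seed = 1,
                    conservative_p = TRUE)
  r <- permutation_ffl_test(6, s$universe, k = 6, s$tg, s$tm, cfg = cfg)
  expect_gt(r$p_value, 0)
  expect_equal(r$p_value * 201, round(r$p_value * 201))
})

test_that("target-count test flags planted enrichment with direction", {
  set.seed(2)
  universe <- sprintf("U%03d", 1:400)
  focal <- sprintf("U%03d", 1:40)
  targets <- c(sample(focal, 12), sample(setdiff(universe, focal), 8))
  pairs <- tibble::tibble(mirna = "mirX", gene = targets)
  cfg <- ffl_config(permutation_reps = 2000, rng_seed = 7)
  r <- target_count_enrichment("mirX", focal, universe, pairs, cfg)
  expect_lt(r$p_value, 0.001)
  expect_equal(r$direction, "more")
  expect_equal(r$observed, 12)
})

test_that("degenerate nulls fall back to the empirical quantile", {
  universe <- sprintf("U%d", 1:20)
  pairs_all <- tibble::tibble(mirna = "mirX", gene = universe)
  cfg <- ffl_config(permutation_reps = 100, rng_seed = 1)
  expect_warning(
    r <- target_count_enrichment("mirX", universe[1:5], universe, pairs_all,
                                 cfg),
    "zero-variance"
  )
  expect_equal(r$observed, 5)
  expect_equal(r$p_value, 1)

  none <- tibble::tibble(mirna = "mirY", gene = character(0))
  expect_warning(
    r0 <- target_count_enrichment("mirY", universe[1:5], universe, none,
                                  cfg),
    "zero-variance"
  )
  expect_equal(r0$observed, 0)
  expect_equal(r0$p_value, 1)
})

test_that("UTR length comparison behaves on known shifts and edge cases", {
  x <- c(100, 200, 300)
  expect_equal(utr_length_test(x, x)$p_value, 1)
  set.seed(3)
  a <- stats::rlnorm(50, meanlog = 6.5, sdlog = 0.5)
  r <- utr_length_test(a, a + 1000)
  expect_lt(r$p_value, 0.01)
  expect_equal(r$method, "wilcoxon")
  expect_equal(utr_length_test(5, 9)$p_value, 1)
  expect_error(utr_length_test(numeric(0), 1), "non-empty")
})
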