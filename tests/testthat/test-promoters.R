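test_that("adjacent precursors within the gap threshold form one cluster", {
  pair <- fixture_mirna(c("hsa-miR-29c", "hsa-miR-29b-2"))
  cl <- cluster_mirnas(pair)
  expect_equal(nrow(cl), 1)
  expect_equal(cl$n_members, 2)
  expect_equal(cl$members[[1]], c("hsa-miR-29c", "hsa-miR-29b-2"))
  # inter-precursor gap: start of the next minus end of the previous
  gap <- pair$start[pair$precursor_id == "hsa-miR-29b-2"] -
    pair$end[pair$precursor_id == "hsa-miR-29c"]
  expect_equal(gap, 503)
  expect_lte(gap, ffl_config()$cluster_max_gap)
})

test_that("an isolated precursor stays a singleton cluster", {
  cl <- cluster_mirnas(fixture_mirna("hsa-miR-195"))
  expect_equal(cl$n_members, 1)
})

test_that("the bundled precursor set clusters into four multi-member groups", {
  # exhaustive pairwise gap check over the 29 intervals gives exactly these
  # four pairs at <= 5 kb (miR-30b/miR-30d sit 4268 bp apart)
  cl <- cluster_mirnas(load_reference_fixtures()$mirnas)
  multi <- cl[cl$n_members > 1, ]
  expect_equal(nrow(multi), 4)
  expect_equal(sum(multi$n_members), 8)
  sets <- lapply(multi$members, sort)
  expect_true(list(sort(c("hsa-miR-29c", "hsa-miR-29b-2"))) %in% sets)
  expect_true(list(sort(c("hsa-miR-29a", "hsa-miR-29b-1"))) %in% sets)
  expect_true(list(sort(c("hsa-miR-92a-2", "hsa-miR-20b"))) %in% sets)
  expect_true(list(sort(c("hsa-miR-30b", "hsa-miR-30d"))) %in% sets)
})

test_that("clustering is independent of input order", {
  mirnas <- load_reference_fixtures()$mirnas
  ref <- cluster_mirnas(mirnas)
  for (seed in 1:3) {
    set.seed(seed)
    shuffled <- mirnas[sample.int(nrow(mirnas)), ]
    expect_equal(cluster_mirnas(shuffled), ref)
  }
})

test_that("intergenic promoter is strand-aware upstream of the precursor", {
  m195 <- fixture_mirna("hsa-miR-195")
  p <- assign_mirna_promoters(m195)
  # minus strand: upstream is coordinate-increasing from the precursor end;
  # 1-based display 6861745-6866744
  expect_equal(p$basis, "precursor")
  expect_equal(p$start, 6861744)
  expect_equal(p$end, 6866744)
  expect_equal(p$end - p$start, ffl_config()$mirna_promoter_len)
  # never overlaps the precursor body
  expect_true(p$start >= m195$end || p$end <= m195$start)
})

test_that("genic precursors use the host gene promoter, antisense do not", {
  genes <- tibble::tibble(symbol = "WDR82", chrom = "3", start = 52260000L,
                          end = 52290000L, strand = "+", tss = 52260000L)
  let7g <- fixture_mirna("hsa-let-7g")
  p <- assign_mirna_promoters(let7g, genes)
  expect_equal(p$basis, "host_gene")
  expect_equal(c(p$start, p$end), c(52255000L, 52260000L))

  expect_error(assign_mirna_promoters(let7g, genes[0, ]),
               "unresolved host")

  # antisense host does not share the transcription unit: precursor basis,
  # and the (absent) host gene is not looked up
  m29a <- fixture_mirna("hsa-miR-29a")
  p29 <- assign_mirna_promoters(m29a, genes)
  expect_equal(p29$basis, "precursor")
})

test_that("clustered precursors share one promoter upstream of the span", {
  pair <- fixture_mirna(c("hsa-miR-29c", "hsa-miR-29b-2"))
  p <- assign_mirna_promoters(pair)
  expect_equal(p$basis, c("cluster", "cluster"))
  expect_equal(p$start[1], p$start[2])
  expect_equal(p$end[1], p$end[2])
  # minus-strand cluster: window starts at the span end
  expect_equal(p$start[1], max(pair$end))
})

test_that("gene promoters follow the TSS strand-aware with configurable length", {
  genes <- tibble::tibble(
    symbol = c("PLUS", "MINUS"), chrom = "1",
    start = c(100000L, 100000L), end = c(110000L, 120000L),
    strand = c("+", "-"), tss = c(100000L, 120000L)
  )
  p <- assign_gene_promoters(genes)
  expect_equal(c(p$start[1], p$end[1]), c(95000L, 100000L))
  expect_equal(c(p$start[2], p$end[2]), c(120000L, 125000L))
  p1k <- assign_gene_promoters(genes, ffl_config(gene_promoter_len = 1000))
  expect_equal(p1k$end - p1k$start, c(1000L, 1000L))

  near0 <- tibble::tibble(symbol = "EDGE", chrom = "1", start = 1000L,
                          end = 5000L, strand = "+", tss = 1000L)
  expect_warning(pt <- assign_gene_promoters(near0), "truncated")
  expect_equal(pt$start, 0L)
})

test_that("TFBS mapping applies the strict Z cutoff and conservation filter", {
  prom <- tibble::tibble(owner = "G1", owner_type = "gene",
                         basis = "gene_tss", basis_id = "G1", chrom = "1",
                         start = 1000L, end = 6000L, strand = "+")
  hit <- function(z, conserved = TRUE, start = 2000L) {
    tibble::tibble(matrix_id = "V$X_01", consensus = "ACGT", chrom = "1",
                   start = start, end = start + 20L, strand = "+",
                   z_score = z, conserved = conserved, tf_symbols = "X")
  }
  expect_equal(nrow(map_tfbs_to_promoters(hit(2.32), prom)), 0)
  expect_equal(nrow(map_tfbs_to_promoters(hit(2.33), prom)), 0)  # strict >
  expect_equal(nrow(map_tfbs_to_promoters(hit(2.34), prom)), 1)
  expect_equal(nrow(map_tfbs_to_promoters(hit(3, conserved = FALSE), prom)),
               0)
  cfg_nc <- ffl_config(require_tfbs_conserved = FALSE)
  expect_equal(nrow(map_tfbs_to_promoters(hit(3, conserved = FALSE), prom,
                                          cfg_nc)), 1)
  # outside the promoter
  expect_equal(nrow(map_tfbs_to_promoters(hit(3, start = 7000L), prom)), 0)
})

test_that("a hit spanning two promoters is reported once per owner", {
  proms <- tibble::tibble(
    owner = c("G1", "G2"), owner_type = "gene", basis = "gene_tss",
    basis_id = c("G1", "G2"), chrom = "1",
    start = c(1000L, 2010L), end = c(2020L, 7000L), strand = "+"
  )
  hit <- tibble::tibble(matrix_id = "V$X_01", consensus = "ACGT",
                        chrom = "1", start = 2000L, end = 2030L,
                        strand = "+", z_score = 3, conserved = TRUE,
                        tf_symbols = "X")
  mapped <- map_tfbs_to_promoters(hit, proms)
  expect_equal(nrow(mapped), 2)
  expect_setequal(mapped$owner, c("G1", "G2"))
})

test_that("raising the Z cutoff never increases retained records", {
  set.seed(11)
  prom <- tibble::tibble(owner = sprintf("G%d", 1:5), owner_type = "gene",
                         basis = "gene_tss", basis_id = sprintf("G%d", 1:5),
                         chrom = "1", start = seq(0L, 40000L, 10000L),
                         end = seq(5000L, 45000L, 10000L), strand = "+")
  hits <- tibble::tibble(
    matrix_id = sprintf("V$M%d", 1:60), consensus = "ACGT", chrom = "1",
    start = sample.int(45000L, 60), strand = "+",
    z_score = stats::rnorm(60, 2.3, 0.5), conserved = TRUE,
    tf_symbols = "X"
  )
  hits$end <- hits$start + 20L
  counts <- vapply(seq(1.5, 3.5, by = 0.25), function(zc) {
    nrow(map_tfbs_to_promoters(hits, prom, ffl_config(z_cutoff = zc)))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("indexed overlap matches the all-pairs scan on small inputs", {
  for (seed in 1:5) {
    set.seed(seed)
    q <- tibble::tibble(chrom = sample(c("a", "b"), 30, TRUE),
                        start = sample.int(2000L, 30), strand = "+")
    q$end <- q$start + sample.int(300L, 30)
    s <- tibble::tibble(chrom = sample(c("a", "b"), 20, TRUE),
                        start = sample.int(2000L, 20), strand = "+")
    s$end <- s$start + sample.int(300L, 20)
    expect_equal(fflnet:::overlap_pairs(q, s), brute_force_overlaps(q, s))
  }
})
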