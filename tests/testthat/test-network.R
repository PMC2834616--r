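owner_hit <- function(matrix_id, owner, start, symbols, consensus = NULL,
                      owner_type = "gene") {
  tibble::tibble(matrix_id = matrix_id, consensus = consensus %||% matrix_id,
                 chrom = "1", start = start, end = start + 20L, strand = "+",
                 z_score = 3, conserved = TRUE, tf_symbols = symbols,
                 owner = owner, owner_type = owner_type, basis = "gene_tss")
}

test_that("matrix merging follows overlap+symbol and shared-consensus rules", {
  # three CREB-family matrices overlapping in one promoter, shared symbols
  creb <- dplyr::bind_rows(
    owner_hit("V$CREB_01", "NR4A2", 100L, "ATF2,CREB1"),
    owner_hit("V$CREBP1CJUN_01", "NR4A2", 105L, "ATF2,CREB1"),
    owner_hit("V$CREBP1_Q2", "NR4A2", 110L, "ATF2,CREB1")
  )
  g <- merge_tfbs_groups(creb)
  expect_equal(nrow(g$groups), 1)
  expect_equal(g$groups$group_id, "V$CREB_01")

  # identical consensus merges without overlap
  egr <- dplyr::bind_rows(
    owner_hit("V$EGR1_01", "YWHAH", 100L, "EGR1,EGR2,EGR3,EGR4",
              consensus = "TGCGTRGGYGK"),
    owner_hit("V$NGFIC_01", "GRM7", 900L, "EGR1,EGR2,EGR3,EGR4",
              consensus = "TGCGTRGGYGK")
  )
  g2 <- merge_tfbs_groups(egr)
  expect_equal(nrow(g2$groups), 1)
  expect_equal(g2$groups$group_id, "V$EGR1_01")

  # non-overlapping, disjoint symbols, different consensus: two groups
  apart <- dplyr::bind_rows(
    owner_hit("V$A_01", "G1", 100L, "A"),
    owner_hit("V$B_01", "G1", 900L, "B")
  )
  expect_equal(nrow(merge_tfbs_groups(apart)$groups), 2)

  # overlap without a shared symbol does not merge
  overlap_nosym <- dplyr::bind_rows(
    owner_hit("V$A_01", "G1", 100L, "A"),
    owner_hit("V$B_01", "G1", 105L, "B")
  )
  expect_equal(nrow(merge_tfbs_groups(overlap_nosym)$groups), 2)
})

test_that("miRNA-gene edges expand names to precursors with the conservation rule", {
  mirnas <- fixture_mirna(c("hsa-miR-9-1", "hsa-miR-9-2", "hsa-miR-9-3",
                            "hsa-miR-198", "hsa-miR-195"))
  pairs <- tibble::tibble(
    mirna = c("hsa-miR-9", "hsa-miR-195", "hsa-miR-198"),
    gene = c("DRD2", "BDNF", "FSTL1"),
    chrom = NA_character_, start = NA_integer_, end = NA_integer_,
    site_conserved = c(TRUE, FALSE, FALSE)
  )
  edges <- build_mirna_gene_edges(pairs, mirnas)
  # family expands to all three precursors
  expect_setequal(edges$mirna[edges$gene == "DRD2"],
                  c("hsa-miR-9-1", "hsa-miR-9-2", "hsa-miR-9-3"))
  # non-conserved site of a mammal-class miRNA is dropped
  expect_false("BDNF" %in% edges$gene)
  # primate-specific precursor is exempt from the conservation requirement
  expect_true("FSTL1" %in% edges$gene)

  expect_error(
    build_mirna_gene_edges(dplyr::mutate(pairs, mirna = "hsa-miR-999"),
                           mirnas),
    "no known precursor"
  )
})

test_that("FFL enumeration joins the three edge sets exactly", {
  tg <- tibble::tibble(group_id = "g", gene = "G")
  tm <- tibble::tibble(group_id = "g", mirna = "m")
  mg <- tibble::tibble(mirna = "m", gene = "G")
  expect_equal(nrow(find_ffls(tg, tm, mg)), 1)
  expect_equal(nrow(find_ffls(tg, tm, mg[0, ])), 0)
  expect_equal(nrow(find_ffls(tg[0, ], tm, mg)), 0)
})

test_that("FFL enumeration equals the brute-force triple loop", {
  for (seed in 1:8) {
    set.seed(seed)
    e <- random_edge_sets(n_groups = sample(2:6, 1),
                          n_mirnas = sample(2:6, 1),
                          n_genes = sample(2:8, 1))
    expect_equal(find_ffls(e$tf_gene, e$tf_mirna, e$mirna_gene),
                 brute_force_ffls(e$tf_gene, e$tf_mirna, e$mirna_gene))
  }
})

test_that("enumeration output is deterministic under input permutation", {
  set.seed(99)
  e <- random_edge_sets(5, 5, 6, density = 0.4)
  ref <- find_ffls(e$tf_gene, e$tf_mirna, e$mirna_gene)
  perm <- find_ffls(e$tf_gene[sample.int(nrow(e$tf_gene)), ],
                    e$tf_mirna[sample.int(nrow(e$tf_mirna)), ],
                    e$mirna_gene[sample.int(nrow(e$mirna_gene)), ])
  expect_identical(ref, perm)
})

test_that("the reconstructed fixture bundle yields the published loop set", {
  b <- reference_edge_bundle()
  groups <- merge_tfbs_groups(b$hits_with_owner)
  ffls <- find_ffls(group_edges(b$tf_gene, groups),
                    group_edges(b$tf_mirna, groups), b$mirna_gene)
  expect_equal(nrow(ffls), 32)
  expect_equal(dplyr::n_distinct(ffls$gene), 16)
  expect_equal(dplyr::n_distinct(ffls$mirna), 11)
  # merging never increases the loop count; unmerged is at least as large
  raw <- find_ffls(dplyr::rename(b$tf_gene, group_id = "matrix_id"),
                   dplyr::rename(b$tf_mirna, group_id = "matrix_id"),
                   b$mirna_gene)
  expect_gte(nrow(raw), nrow(ffls))
})

test_that("feedback loops require the miRNA to target a group symbol", {
  hits <- owner_hit("V$X_01", "m1", 100L, "TFX", owner_type = "mirna")
  groups <- merge_tfbs_groups(hits)
  tm <- tibble::tibble(group_id = "V$X_01", mirna = "m1")
  hit_back <- tibble::tibble(mirna = "m1", gene = "TFX")
  miss <- tibble::tibble(mirna = "m1", gene = "OTHER")
  expect_equal(nrow(find_feedback_loops(tm, hit_back, groups)), 1)
  expect_equal(nrow(find_feedback_loops(tm, miss, groups)), 0)
})

test_that("network convergence keeps only loops anchored to the FFLs", {
  ffls <- tibble::tibble(group_id = "gA", mirna = "m1", gene = "T1")
  disjoint <- tibble::tibble(group_id = "gB", mirna = "m9",
                             tf_genes_targeted = "X")
  net <- merge_network(ffls, disjoint)
  expect_equal(nrow(net$nodes), 3)

  sharing <- tibble::tibble(group_id = "gB", mirna = "m1",
                            tf_genes_targeted = "X")
  net2 <- merge_network(ffls, sharing)
  expect_gte(nrow(net2$nodes), 4)
  expect_true("gB" %in% net2$nodes$id)
  expect_true(any(net2$edges$kind == "mirna_tf"))
})

test_that("a single-loop network has no core nodes", {
  net <- merge_network(tibble::tibble(group_id = "g", mirna = "m",
                                      gene = "G"))
  core <- find_core_nodes(net)
  expect_equal(length(core$core_genes) + length(core$core_mirnas), 0)
})

test_that("subnetwork extraction takes the node and its direct neighbors", {
  ffls <- tibble::tibble(group_id = c("g1", "g2", "g3"),
                         mirna = c("m1", "m2", "m3"),
                         gene = c("HUB", "HUB", "HUB"))
  net <- merge_network(ffls)
  sub <- extract_subnetwork(net, "HUB")
  expect_setequal(sub$nodes$id, c("HUB", "g1", "g2", "g3", "m1", "m2", "m3"))
  expect_error(extract_subnetwork(net, "NOPE"), "unknown node")

  iso <- fflnet:::new_ffl_network(
    tibble::tibble(id = c("HUB", "ALONE"), type = c("gene", "mirna"),
                   symbols = ""),
    net$edges[0, ]
  )
  expect_equal(nrow(extract_subnetwork(iso, "ALONE")$nodes), 1)
})

test_that("network exports round-trip through SIF and GraphML", {
  b <- reference_edge_bundle()
  groups <- merge_tfbs_groups(b$hits_with_owner)
  ffls <- find_ffls(group_edges(b$tf_gene, groups),
                    group_edges(b$tf_mirna, groups), b$mirna_gene)
  net <- merge_network(ffls, groups = groups)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_equal(length(readLines(sif)), nrow(net$edges))
  back <- import_network(sif, "sif")
  expect_equal(back$nodes[, c("id", "type")], net$nodes[, c("id", "type")])
  expect_equal(back$edges[, c("from", "to", "kind")],
               net$edges[, c("from", "to", "kind")])
  expect_equal(sum(back$nodes$type == "gene"), 16)

  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back2 <- import_network(gml, "graphml")
  expect_equal(back2$nodes, net$nodes)
  expect_equal(back2$edges, net$edges)

  one <- merge_network(tibble::tibble(group_id = "g", mirna = "m",
                                      gene = "G"))
  sif1 <- withr::local_tempfile(fileext = ".sif")
  export_network(one, sif1, "sif")
  expect_equal(length(readLines(sif1)), 3)
})

test_that("self-regulation is flagged and excluded from TF out-degree only", {
  # the EGR group binds the promoter of its own gene in the fixture network
  b <- reference_edge_bundle()
  groups <- merge_tfbs_groups(b$hits_with_owner)
  ffls <- find_ffls(group_edges(b$tf_gene, groups),
                    group_edges(b$tf_mirna, groups), b$mirna_gene)
  net <- merge_network(ffls, groups = groups)
  self <- net$edges[net$edges$self_edge, ]
  expect_equal(nrow(self), 1)
  expect_equal(self$from, "V$EGR1_01")
  expect_equal(self$to, "EGR3")
  deg <- node_degrees(net)
  egr <- deg[deg$node == "V$EGR1_01", ]
  expect_equal(egr$genes_out, 3)   # EGR3 itself excluded
  expect_equal(egr$mirnas_out, 3)
  # with the policy off the self target is counted again
  deg_all <- node_degrees(net, ffl_config(exclude_self_edges = FALSE))
  expect_equal(deg_all$genes_out[deg_all$node == "V$EGR1_01"], 4)
  # in-degree of the gene still counts the self group
  expect_equal(deg$tf_groups_in[deg$node == "EGR3"], 5)
})
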