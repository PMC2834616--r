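#' Simulation configuration
#'
#' Parameters of the synthetic input generator. Defaults emulate a small
#' regulatory locus set in the style of the study inputs: a few dozen genes,
#' a dozen miRNA precursors of which a quarter are genic and a fifth
#' clustered, a matrix catalog, a handful of planted feed-forward and
#' feedback loops, and decoy binding sites split among sub-threshold Z
#' scores, non-conserved hits and placements outside any promoter.
#'
#' @param n_genes Number of genes (>= planted loops + feedback + hosts + 4).
#' @param n_mirnas Number of precursors.
#' @param frac_genic Fraction of precursors hosted in a gene intron.
#' @param frac_clustered Fraction of precursors laid out in 2-member
#'   clusters (rounded down to an even count).
#' @param n_matrices Matrix catalog size (>= planted_ffls + planted_feedback).
#' @param planted_ffls Number of planted feed-forward loops.
#' @param planted_feedback Number of planted miRNA-TF mutual loops.
#' @param decoy_tfbs_rate Decoy TFBS hits per feature (genes + miRNAs).
#' @param z_decoy_mean,z_decoy_sd Normal distribution of decoy Z scores;
#'   planted hits draw uniformly from (2.5, 4.0) and always pass the 2.33
#'   cutoff.
#' @param nonconserved_fraction Fraction of decoy target pairs flagged
#'   non-conserved.
#' @param n_decoy_pairs Number of decoy target pairs (to genes outside any
#'   planted loop).
#' @param n_snps SNPs planted per annotation category (plus as many
#'   background SNPs overlapping nothing).
#' @param rng_seed Integer seed; identical seeds give byte-identical
#'   bundles.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 40, n_mirnas = 12, frac_genic = 0.25,
                       frac_clustered = 0.2, n_matrices = 15,
                       planted_ffls = 7, planted_feedback = 4,
                       decoy_tfbs_rate = 1, z_decoy_mean = 1.5,
                       z_decoy_sd = 0.5, nonconserved_fraction = 0.3,
                       n_decoy_pairs = 10, n_snps = 2, rng_seed = 1L) {
  sim <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              frac_genic = frac_genic, frac_clustered = frac_clustered,
              n_matrices = as.integer(n_matrices),
              planted_ffls = as.integer(planted_ffls),
              planted_feedback = as.integer(planted_feedback),
              decoy_tfbs_rate = decoy_tfbs_rate,
              z_decoy_mean = z_decoy_mean, z_decoy_sd = z_decoy_sd,
              nonconserved_fraction = nonconserved_fraction,
              n_decoy_pairs = as.integer(n_decoy_pairs),
              n_snps = as.integer(n_snps), rng_seed = as.integer(rng_seed))
  fr <- c(sim$frac_genic, sim$frac_clustered, sim$nonconserved_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]",
                                 call. = FALSE)
  structure(sim, class = "sim_config")
}

check_feasible <- function(sim) {
  if (sim$planted_ffls + sim$planted_feedback > sim$n_matrices) {
    stop("infeasible: need n_matrices >= planted_ffls + planted_feedback",
         call. = FALSE)
  }
  n_hosts <- floor(sim$frac_genic * sim$n_mirnas)
  need_genes <- sim$planted_ffls + sim$planted_feedback + n_hosts + 4
  if (need_genes > sim$n_genes) {
    stop("infeasible: need n_genes >= planted_ffls + planted_feedback + ",
         "hosts + 4 (", need_genes, ")", call. = FALSE)
  }
  if (sim$planted_ffls + sim$planted_feedback > 0 && sim$n_mirnas < 1) {
    stop("infeasible: planted loops require at least one miRNA",
         call. = FALSE)
  }
  invisible(sim)
}

#' Generate a synthetic input bundle with planted loop structure
#'
#' Writes the five pipeline inputs (gene BED, miRNA GFF3, TFBS track with
#' matrix sidecar, target-pair TSV, SNP TSV) plus ground-truth tables to a
#' directory. Every planted feed-forward loop uses its own matrix, gene and
#' a (possibly reused) precursor: the matrix receives a conserved,
#' above-cutoff binding site in both the gene's and the precursor's
#' promoter, and a conserved target pair links the precursor to the gene.
#' Feedback loops plant a matrix whose TF symbol is encoded by a reserved
#' gene that the precursor targets. Decoy binding sites are split among
#' sub-threshold Z scores, non-conserved hits and off-promoter placements;
#' decoy target pairs point at reserved background genes, so planted
#' structure is recovered exactly by construction. Features are spaced so
#' that no two promoters overlap except by design (hosts, clusters).
#'
#' @param sim A [sim_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the file paths, the truth tables
#'   (`truth_ffls`, `truth_feedback`, `truth_snps`) and the generated
#'   tibbles.
#' @export
generate_bundle <- function(sim = sim_config(), dir) {
  stopifnot(inherits(sim, "sim_config"))
  check_feasible(sim)
  out <- with_seed(sim$rng_seed, build_bundle_tables(sim))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    genes = file.path(dir, "genes.bed"),
    mirnas = file.path(dir, "mirnas.gff3"),
    tfbs = file.path(dir, "tfbs.tsv"),
    matrix_map = file.path(dir, "matrix_tf_map.tsv"),
    pairs = file.path(dir, "target_pairs.tsv"),
    snps = file.path(dir, "snps.tsv"),
    truth_ffls = file.path(dir, "truth_ffls.tsv"),
    truth_feedback = file.path(dir, "truth_feedback.tsv"),
    truth_snps = file.path(dir, "truth_snps.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  write_gene_annotation(out$genes, paths$genes)
  write_mirna_annotation(out$mirnas, paths$mirnas)
  write_tfbs_track(out$tfbs, paths$tfbs)
  readr::write_tsv(out$matrix_map, paths$matrix_map, progress = FALSE)
  write_target_pairs(out$pairs, paths$pairs)
  write_snps(out$snps, paths$snps)
  readr::write_tsv(out$truth_ffls, paths$truth_ffls, progress = FALSE)
  readr::write_tsv(out$truth_feedback, paths$truth_feedback,
                   progress = FALSE)
  readr::write_tsv(out$truth_snps, paths$truth_snps, progress = FALSE)
  yaml::write_yaml(list(sim = unclass(sim),
                        files = lapply(paths, basename)), paths$manifest)
  invisible(c(list(paths = paths), out))
}

build_bundle_tables <- function(sim) {
  cfg <- ffl_config()
  step <- 60000L
  chrom_of <- function(i) paste0("sim", (i %% 3L) + 1L)
  # genes: 10 kb bodies, alternating strand, spaced so promoters never touch
  genes <- purrr::map_dfr(seq_len(sim$n_genes), function(i) {
    s <- 100000L + (i %/% 3L) * step
    strand <- if (i %% 2L == 0L) "+" else "-"
    tibble(symbol = sprintf("GENE%02d", i), chrom = chrom_of(i),
           start = s, end = s + 10000L, strand = strand,
           tss = if (strand == "+") s else s + 10000L)
  })
  n_host <- floor(sim$frac_genic * sim$n_mirnas)
  n_clu <- 2L * (floor(sim$frac_clustered * sim$n_mirnas) %/% 2L)
  # gene roles: FFL targets, feedback TF genes, hosts, decoy-pair targets
  i_ffl <- seq_len(sim$planted_ffls)
  i_fb <- sim$planted_ffls + seq_len(sim$planted_feedback)
  i_host <- sim$planted_ffls + sim$planted_feedback + seq_len(n_host)
  i_bg <- setdiff(seq_len(sim$n_genes), c(i_ffl, i_fb, i_host))
  mirna_base <- 3000000L
  mirnas <- purrr::map_dfr(seq_len(sim$n_mirnas), function(j) {
    id <- sprintf("sim-mir-%02d", j)
    if (j <= n_host) {
      g <- genes[i_host[j], ]
      s <- g$start + 4000L   # intronic placement
      return(tibble(precursor_id = id, family_id = id, matures = id,
                    chrom = g$chrom, start = s, end = s + 90L,
                    strand = g$strand, host_gene = g$symbol,
                    host_relation = "intronic", conservation_class = "V"))
    }
    if (j <= n_host + n_clu) {
      # lay clustered precursors out pairwise, 2 kb apart
      pair <- (j - n_host - 1L) %/% 2L
      off <- ((j - n_host - 1L) %% 2L) * 2000L
      s <- mirna_base + pair * step + off
      return(tibble(precursor_id = id, family_id = id, matures = id,
                    chrom = "sim1", start = s, end = s + 90L, strand = "+",
                    host_gene = "INTERGENIC", host_relation = "intergenic",
                    conservation_class = "V"))
    }
    s <- mirna_base + 1000L * step + j * step
    tibble(precursor_id = id, family_id = id, matures = id,
           chrom = chrom_of(j), start = s, end = s + 90L, strand = "+",
           host_gene = "INTERGENIC", host_relation = "intergenic",
           conservation_class = "V")
  })
  gene_prom <- assign_gene_promoters(genes, cfg)
  mirna_prom <- assign_mirna_promoters(mirnas, genes, cfg = cfg)
  matrices <- sprintf("SIM$MAT_%02d", seq_len(sim$n_matrices))
  consensus <- sprintf("ACGT%02dNNNN", seq_len(sim$n_matrices))
  # planted FFLs: matrix i -> gene i and mirna (i mod n), pair mirna -> gene
  ffl_mirna <- mirnas$precursor_id[(i_ffl - 1L) %% sim$n_mirnas + 1L]
  plant_hit <- function(matrix_id, cons, prom, z, conserved = TRUE) {
    center <- (prom$start + prom$end) %/% 2L
    tibble(matrix_id = matrix_id, consensus = cons, chrom = prom$chrom,
           start = center, end = center + 20L, strand = "+",
           z_score = z, conserved = conserved)
  }
  tfbs <- list(tibble(matrix_id = character(), consensus = character(),
                      chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      z_score = numeric(), conserved = logical()))
  map_rows <- list()
  truth_ffls <- tibble(group_id = character(), mirna = character(),
                       gene = character())
  pairs <- list(tibble(mirna = character(), gene = character(),
                       chrom = character(), start = integer(),
                       end = integer(), site_conserved = logical()))
  for (i in i_ffl) {
    m <- matrices[i]
    g <- genes$symbol[i]
    mir <- ffl_mirna[i - min(i_ffl) + 1L]
    gp <- gene_prom[gene_prom$owner == g, ][1, ]
    mp <- mirna_prom[mirna_prom$owner == mir, ][1, ]
    z1 <- stats::runif(1, 2.5, 4.0)
    z2 <- stats::runif(1, 2.5, 4.0)
    tfbs[[length(tfbs) + 1]] <- dplyr::bind_rows(
      plant_hit(m, consensus[i], gp, z1),
      plant_hit(m, consensus[i], mp, z2)
    )
    map_rows[[length(map_rows) + 1]] <-
      tibble(matrix_id = m, tf_symbol = sprintf("SIMTF%02d", i))
    truth_ffls <- dplyr::bind_rows(
      truth_ffls, tibble(group_id = m, mirna = mir, gene = g))
    site0 <- genes$end[genes$symbol == g] + 500L  # 3'UTR-like downstream
    pairs[[length(pairs) + 1]] <- tibble(
      mirna = mir, gene = g, chrom = genes$chrom[genes$symbol == g],
      start = site0, end = site0 + 7L, site_conserved = TRUE)
  }
  # planted feedback loops: matrix encodes the TF of a reserved gene
  truth_feedback <- tibble(group_id = character(), mirna = character(),
                           tf_genes_targeted = character())
  for (q in seq_len(sim$planted_feedback)) {
    i <- sim$planted_ffls + q
    m <- matrices[i]
    tf_gene_sym <- genes$symbol[i_fb[q]]
    mir <- mirnas$precursor_id[(i - 1L) %% sim$n_mirnas + 1L]
    mp <- mirna_prom[mirna_prom$owner == mir, ][1, ]
    tfbs[[length(tfbs) + 1]] <-
      plant_hit(m, consensus[i], mp, stats::runif(1, 2.5, 4.0))
    map_rows[[length(map_rows) + 1]] <-
      tibble(matrix_id = m, tf_symbol = tf_gene_sym)
    site0 <- genes$end[genes$symbol == tf_gene_sym] + 500L
    pairs[[length(pairs) + 1]] <- tibble(
      mirna = mir, gene = tf_gene_sym,
      chrom = genes$chrom[genes$symbol == tf_gene_sym],
      start = site0, end = site0 + 7L, site_conserved = TRUE)
    truth_feedback <- dplyr::bind_rows(
      truth_feedback,
      tibble(group_id = m, mirna = mir, tf_genes_targeted = tf_gene_sym))
  }
  # spare matrices get symbols but no planted placement
  spare <- setdiff(seq_len(sim$n_matrices),
                   seq_len(sim$planted_ffls + sim$planted_feedback))
  for (i in spare) {
    map_rows[[length(map_rows) + 1]] <-
      tibble(matrix_id = matrices[i], tf_symbol = sprintf("SIMTF%02d", i))
  }
  # decoys: sub-threshold z in promoters / non-conserved in promoters /
  # well-placed but outside any promoter
  n_decoy <- round(sim$decoy_tfbs_rate * (sim$n_genes + sim$n_mirnas))
  if (n_decoy > 0) {
    mode <- rep_len(c("lowz", "noncons", "offprom"), n_decoy)
    all_prom <- dplyr::bind_rows(gene_prom, mirna_prom)
    for (d in seq_len(n_decoy)) {
      i <- sample.int(sim$n_matrices, 1)
      z <- stats::rnorm(1, sim$z_decoy_mean, sim$z_decoy_sd)
      if (mode[d] == "offprom") {
        row <- tibble(matrix_id = matrices[i], consensus = consensus[i],
                      chrom = "sim1",
                      start = 10000000L + d * 1000L,
                      end = 10000000L + d * 1000L + 20L, strand = "+",
                      z_score = z, conserved = TRUE)
      } else {
        p <- all_prom[sample.int(nrow(all_prom), 1), ]
        off <- sample.int(1000L, 1)
        row <- tibble(matrix_id = matrices[i], consensus = consensus[i],
                      chrom = p$chrom, start = p$start + off,
                      end = p$start + off + 20L, strand = "+",
                      z_score = if (mode[d] == "lowz") min(z, 2.33) else
                        stats::runif(1, 2.5, 4.0),
                      conserved = mode[d] != "noncons")
      }
      tfbs[[length(tfbs) + 1]] <- row
    }
  }
  # decoy target pairs to reserved background genes
  if (sim$n_decoy_pairs > 0) {
    dg <- genes$symbol[i_bg]
    dm <- mirnas$precursor_id
    decoy_pairs <- purrr::map_dfr(seq_len(sim$n_decoy_pairs), function(d) {
      g <- dg[sample.int(length(dg), 1)]
      site0 <- genes$end[genes$symbol == g] + 600L + d * 10L
      tibble(mirna = dm[sample.int(length(dm), 1)], gene = g,
             chrom = genes$chrom[genes$symbol == g],
             start = site0, end = site0 + 7L,
             site_conserved = stats::runif(1) >= sim$nonconserved_fraction)
    })
    pairs[[length(pairs) + 1]] <- decoy_pairs
  }
  tfbs <- dplyr::bind_rows(tfbs)
  pairs <- dplyr::distinct(dplyr::bind_rows(pairs))
  matrix_map <- dplyr::distinct(dplyr::bind_rows(map_rows))
  # SNPs per category plus background SNPs hitting nothing
  snps <- list()
  truth_snps <- list()
  add_snp <- function(rsid, chrom, pos0, category, element) {
    snps[[length(snps) + 1]] <<- tibble(rsid = rsid, chrom = chrom,
                                        position = pos0, alleles = "A/G")
    if (!is.na(category)) {
      truth_snps[[length(truth_snps) + 1]] <<- tibble(
        rsid = rsid, category = category, element = element)
    }
  }
  loose_mirnas <- mirnas[mirnas$host_gene == "INTERGENIC" &
                           !mirnas$precursor_id %in%
                           mirnas$precursor_id[seq_len(n_host + n_clu)], ,
                         drop = FALSE]
  if (sim$n_snps > 0 && sim$planted_ffls > 0 && nrow(loose_mirnas) > 0) {
    for (s in seq_len(sim$n_snps)) {
      i <- i_ffl[(s - 1L) %% length(i_ffl) + 1L]
      g <- genes$symbol[i]
      mir <- ffl_mirna[i]
      site <- pairs[pairs$gene == g & pairs$mirna == mir, ][1, ]
      add_snp(sprintf("rs_site_%02d", s), site$chrom, site$start + 2L,
              "target_site", g)
      hit_g <- tfbs[tfbs$matrix_id == matrices[i], ][1, ]
      add_snp(sprintf("rs_tfbsg_%02d", s), hit_g$chrom, hit_g$start + 3L,
              "tfbs_gene_promoter", g)
      # the miRNA-promoter category is only unambiguous for an intergenic,
      # unclustered owner: pick such an FFL for this SNP when one exists
      i_loose <- i_ffl[ffl_mirna %in% loose_mirnas$precursor_id]
      if (length(i_loose) > 0) {
        il <- i_loose[(s - 1L) %% length(i_loose) + 1L]
        hit_m <- tfbs[tfbs$matrix_id == matrices[il], ][2, ]
        add_snp(sprintf("rs_tfbsm_%02d", s), hit_m$chrom, hit_m$start + 3L,
                "tfbs_mirna_promoter", ffl_mirna[il])
      }
      lm <- loose_mirnas[(s - 1L) %% nrow(loose_mirnas) + 1L, ]
      add_snp(sprintf("rs_body_%02d", s), lm$chrom,
              (lm$start + lm$end) %/% 2L, "pre_mirna", lm$precursor_id)
      d <- sample.int(ffl_config()$snp_flank, 1)
      add_snp(sprintf("rs_flank_%02d", s), lm$chrom, lm$end + d - 1L,
              "pre_mirna_flank", lm$precursor_id)
      add_snp(sprintf("rs_bg_%02d", s), "sim2", 20000000L + s * 5000L,
              NA_character_, NA_character_)
    }
  }
  snps <- if (length(snps) > 0) dplyr::bind_rows(snps) else
    tibble(rsid = character(), chrom = character(), position = integer(),
           alleles = character())
  truth_snps <- if (length(truth_snps) > 0) dplyr::bind_rows(truth_snps) else
    tibble(rsid = character(), category = character(), element = character())
  list(genes = genes, mirnas = mirnas, tfbs = tfbs, matrix_map = matrix_map,
       pairs = pairs, snps = snps,
       truth_ffls = dplyr::arrange(dplyr::distinct(truth_ffls),
                                   .data$gene, .data$mirna, .data$group_id),
       truth_feedback = truth_feedback, truth_snps = truth_snps)
}
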