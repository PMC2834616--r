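#' @importFrom dplyr %>%
NULL

split_symbols <- function(x) strsplit(x, ",", fixed = TRUE)

join_symbols <- function(x) vapply(x, paste, character(1), collapse = ",")

parse_flag <- function(x, what, line_offset = 0L) {
  out <- rep(NA, length(x))
  out[tolower(x) %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[tolower(x) %in% c("false", "f", "0", "no", "n")] <- FALSE
  if (anyNA(out)) {
    stop("cannot parse ", what, " flag at line ",
         which(is.na(out))[1] + line_offset, call. = FALSE)
  }
  as.logical(out)
}

conservation_codes <- c("V", "M", "P", "A")
host_relations <- c("intronic", "utr3", "antisense", "intergenic")

#' Read miRNA precursor annotations (GFF3 dialect)
#'
#' Parses a GFF3-like file with 1-based inclusive coordinates. The attribute
#' column must carry `ID` (precursor name) and `conservation` (one of `V`
#' vertebrate, `M` mammal, `P` primate, `A` conserved down to Drosophila);
#' `family`, `matures`, `host_gene` and `host_relation` are optional with
#' sensible defaults. Coordinates are converted to the package-internal
#' 0-based half-open convention.
#'
#' @param path Path to the GFF3-like file.
#' @return A tibble with one row per precursor: `precursor_id`, `family_id`,
#'   `matures` (comma-separated mature names), `chrom`, `start`, `end`
#'   (0-based half-open), `strand`, `host_gene` (`"INTERGENIC"` when none),
#'   `host_relation`, `conservation_class`.
#' @export
#' @examples
#' gff <- system.file("extdata", "sz_mirna_annotation.gff3", package = "fflnet")
#' mirnas <- read_mirna_annotation(gff)
#' nrow(mirnas)
read_mirna_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  empty <- tibble(
    precursor_id = character(), family_id = character(), matures = character(),
    chrom = character(), start = integer(), end = integer(),
    strand = character(), host_gene = character(), host_relation = character(),
    conservation_class = character()
  )
  if (length(keep) == 0) return(empty)
  rows <- purrr::map_dfr(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 9) {
      stop("malformed GFF record at line ", i, ": expected 9 fields",
           call. = FALSE)
    }
    start1 <- suppressWarnings(as.integer(f[4]))
    end1 <- suppressWarnings(as.integer(f[5]))
    if (is.na(start1) || is.na(end1) || start1 > end1 || start1 < 1) {
      stop("malformed coordinates at line ", i, call. = FALSE)
    }
    if (!f[7] %in% c("+", "-")) {
      stop("malformed strand at line ", i, call. = FALSE)
    }
    kv <- strsplit(strsplit(f[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    att <- stats::setNames(
      vapply(kv, function(p) if (length(p) >= 2) p[2] else "", character(1)),
      vapply(kv, `[[`, character(1), 1)
    )
    if (is.na(att["ID"]) || att[["ID"]] == "") {
      stop("missing ID attribute at line ", i, call. = FALSE)
    }
    cons <- if (!is.na(att["conservation"])) att[["conservation"]] else NA
    if (is.na(cons) || !cons %in% conservation_codes) {
      stop("unknown conservation code at line ", i, call. = FALSE)
    }
    host <- if (!is.na(att["host_gene"]) && att[["host_gene"]] != "") {
      att[["host_gene"]]
    } else "INTERGENIC"
    rel <- if (!is.na(att["host_relation"]) && att[["host_relation"]] != "") {
      att[["host_relation"]]
    } else if (identical(host, "INTERGENIC")) "intergenic" else "intronic"
    if (!rel %in% host_relations) {
      stop("unknown host_relation at line ", i, call. = FALSE)
    }
    if (identical(rel, "intergenic") && !identical(host, "INTERGENIC")) {
      stop("intergenic record must have host_gene INTERGENIC (line ", i, ")",
           call. = FALSE)
    }
    fam <- if (!is.na(att["family"]) && att[["family"]] != "") {
      att[["family"]]
    } else att[["ID"]]
    mat <- if (!is.na(att["matures"]) && att[["matures"]] != "") {
      att[["matures"]]
    } else fam
    cc <- coords_from_1based(start1, end1)
    tibble(
      precursor_id = att[["ID"]], family_id = fam, matures = mat,
      chrom = f[1], start = cc$start, end = cc$end, strand = f[7],
      host_gene = host, host_relation = rel, conservation_class = cons
    )
  })
  check_intervals(rows, "miRNA annotation")
  rows
}

#' Write miRNA precursor annotations (GFF3 dialect)
#'
#' Inverse of [read_mirna_annotation()]; coordinates are emitted 1-based
#' inclusive so a source file round-trips exactly.
#'
#' @param mirnas Tibble as returned by [read_mirna_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mirna_annotation <- function(mirnas, path) {
  cc <- coords_to_1based(mirnas$start, mirnas$end)
  att <- sprintf(
    "ID=%s;family=%s;matures=%s;host_gene=%s;host_relation=%s;conservation=%s",
    mirnas$precursor_id, mirnas$family_id, mirnas$matures, mirnas$host_gene,
    mirnas$host_relation, mirnas$conservation_class
  )
  lines <- c("##gff-version 3",
             sprintf("%s\tfflnet\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\t%s",
                     mirnas$chrom, cc$start, cc$end, mirnas$strand, att))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotations (BED dialect)
#'
#' BED6: chrom, start (0-based), end, symbol, score (ignored), strand. The
#' transcription start site is derived from the strand: interval start on
#' `+`, interval end on `-`.
#'
#' @param path Path to a BED6 file.
#' @return Tibble: `symbol`, `chrom`, `start`, `end`, `strand`, `tss`.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|track|$)", lines))
  empty <- tibble(symbol = character(), chrom = character(), start = integer(),
                  end = integer(), strand = character(), tss = integer())
  if (length(keep) == 0) return(empty)
  rows <- purrr::map_dfr(keep, function(i) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6) stop("malformed BED record at line ", i, call. = FALSE)
    s <- suppressWarnings(as.integer(f[2]))
    e <- suppressWarnings(as.integer(f[3]))
    if (is.na(s) || is.na(e) || s >= e || s < 0) {
      stop("malformed coordinates at line ", i, call. = FALSE)
    }
    if (!f[6] %in% c("+", "-")) stop("malformed strand at line ", i,
                                     call. = FALSE)
    tibble(symbol = f[4], chrom = f[1], start = s, end = e, strand = f[6],
           tss = if (f[6] == "+") s else e)
  })
  check_intervals(rows, "gene annotation")
  rows
}

#' Write gene annotations (BED dialect)
#' @param genes Tibble as returned by [read_gene_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_annotation <- function(genes, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", genes$chrom, genes$start,
                     genes$end, genes$symbol, genes$strand), path)
  invisible(path)
}

#' Read the matrix-to-TF sidecar table
#'
#' Two tab-separated columns, `matrix_id` and `tf_symbol`, one row per
#' (matrix, symbol) pair. Position-weight matrices map to one or more TF
#' gene symbols; the catalog is supplied alongside the TFBS track.
#'
#' @param path Path to the TSV.
#' @return Tibble with columns `matrix_id`, `tf_symbol`.
#' @export
read_matrix_map <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("matrix_id", "tf_symbol") %in% names(df))) {
    stop("matrix map needs columns matrix_id and tf_symbol", call. = FALSE)
  }
  dplyr::distinct(as_tibble(df[, c("matrix_id", "tf_symbol")]))
}

#' Read a TFBS hit track (BED dialect with a header)
#'
#' Tab-separated with header columns `chrom`, `start` (0-based half-open),
#' `end`, `matrix_id`, `z_score`, `strand`, `consensus`, `conserved`. TF
#' symbols are resolved through the sidecar matrix map; no quality filtering
#' happens at read time.
#'
#' @param path Path to the track file.
#' @param matrix_map Tibble from [read_matrix_map()], or a path to one.
#' @return Tibble: `matrix_id`, `consensus`, `chrom`, `start`, `end`,
#'   `strand`, `z_score`, `conserved`, `tf_symbols` (comma-separated).
#' @export
read_tfbs_track <- function(path, matrix_map) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(matrix_map)) matrix_map <- read_matrix_map(matrix_map)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("chrom", "start", "end", "matrix_id", "z_score", "strand")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("TFBS track is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble(matrix_id = character(), consensus = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), z_score = numeric(),
                  conserved = logical(), tf_symbols = character()))
  }
  z <- suppressWarnings(as.numeric(df$z_score))
  if (anyNA(z) || any(!is.finite(z))) {
    stop("non-numeric Z score at line ", which(!is.finite(z))[1] + 1L,
         call. = FALSE)
  }
  s <- suppressWarnings(as.integer(df$start))
  e <- suppressWarnings(as.integer(df$end))
  if (anyNA(s) || anyNA(e)) {
    stop("malformed coordinates at line ",
         which(is.na(s) | is.na(e))[1] + 1L, call. = FALSE)
  }
  cons <- if ("conserved" %in% names(df)) {
    parse_flag(df$conserved, "conserved", 1L)
  } else rep(TRUE, nrow(df))
  syms <- matrix_map %>%
    dplyr::group_by(.data$matrix_id) %>%
    dplyr::summarise(tf_symbols = paste(sort(.data$tf_symbol), collapse = ","),
                     .groups = "drop")
  out <- tibble(
    matrix_id = df$matrix_id,
    consensus = if ("consensus" %in% names(df)) df$consensus else "",
    chrom = df$chrom, start = s, end = e, strand = df$strand,
    z_score = z, conserved = cons
  ) %>%
    dplyr::left_join(syms, by = "matrix_id")
  if (anyNA(out$tf_symbols)) {
    stop("no TF symbol mapping for matrix ",
         out$matrix_id[is.na(out$tf_symbols)][1], call. = FALSE)
  }
  check_intervals(out, "TFBS track")
  out
}

#' Write a TFBS hit track (BED dialect with a header)
#' @param hits Tibble as returned by [read_tfbs_track()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tfbs_track <- function(hits, path) {
  readr::write_tsv(
    tibble(chrom = hits$chrom, start = hits$start, end = hits$end,
           matrix_id = hits$matrix_id, z_score = hits$z_score,
           strand = hits$strand, consensus = hits$consensus,
           conserved = hits$conserved),
    path, progress = FALSE
  )
  invisible(path)
}

#' Read miRNA target pairs (TSV)
#'
#' Columns `mirna`, `gene`, `site_conserved`, and optionally `chrom`,
#' `site_start`, `site_end` (1-based inclusive genomic coordinates of the
#' 3'UTR seed match). Duplicate (mirna, gene, site) rows are removed with a
#' warning stating how many were dropped.
#'
#' @param path Path to the TSV.
#' @return Tibble: `mirna`, `gene`, `chrom`, `start`, `end` (internal
#'   convention; `NA` for pair-only tables), `site_conserved`.
#' @export
read_target_pairs <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  if (!all(c("mirna", "gene") %in% names(df))) {
    stop("target pairs need columns mirna and gene", call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble(mirna = character(), gene = character(), chrom = character(),
                  start = integer(), end = integer(),
                  site_conserved = logical()))
  }
  has_site <- all(c("chrom", "site_start", "site_end") %in% names(df))
  if (has_site) {
    s1 <- suppressWarnings(as.integer(df$site_start))
    e1 <- suppressWarnings(as.integer(df$site_end))
    cc <- coords_from_1based(s1, e1)
    chrom <- df$chrom
  } else {
    cc <- list(start = rep(NA_integer_, nrow(df)),
               end = rep(NA_integer_, nrow(df)))
    chrom <- rep(NA_character_, nrow(df))
  }
  consv <- if ("site_conserved" %in% names(df)) {
    parse_flag(df$site_conserved, "site_conserved", 1L)
  } else rep(TRUE, nrow(df))
  out <- tibble(mirna = df$mirna, gene = df$gene, chrom = chrom,
                start = cc$start, end = cc$end, site_conserved = consv)
  ded <- dplyr::distinct(out)
  if (nrow(ded) < nrow(out)) {
    warning(nrow(out) - nrow(ded), " duplicate target pair(s) removed",
            call. = FALSE)
  }
  ded
}

#' Write miRNA target pairs (TSV)
#' @param pairs Tibble as returned by [read_target_pairs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_pairs <- function(pairs, path) {
  out <- tibble(mirna = pairs$mirna, gene = pairs$gene,
                site_conserved = pairs$site_conserved)
  if (any(!is.na(pairs$start))) {
    cc <- coords_to_1based(pairs$start, pairs$end)
    out$chrom <- pairs$chrom
    out$site_start <- cc$start
    out$site_end <- cc$end
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read SNP records (TSV)
#'
#' Columns `rsid`, `chrom`, `position` (1-based single base), `alleles`.
#'
#' @param path Path to the TSV.
#' @return Tibble: `rsid`, `chrom`, `position` (internal 0-based), `alleles`.
#' @export
read_snps <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  need <- c("rsid", "chrom", "position", "alleles")
  if (!all(need %in% names(df))) {
    stop("SNP table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) {
    return(tibble(rsid = character(), chrom = character(),
                  position = integer(), alleles = character()))
  }
  p <- suppressWarnings(as.integer(df$position))
  if (anyNA(p) || any(p < 1)) {
    stop("malformed SNP position at line ",
         which(is.na(p) | p < 1)[1] + 1L, call. = FALSE)
  }
  tibble(rsid = df$rsid, chrom = df$chrom, position = p - 1L,
         alleles = df$alleles)
}

#' Write SNP records (TSV)
#' @param snps Tibble as returned by [read_snps()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snps <- function(snps, path) {
  readr::write_tsv(
    tibble(rsid = snps$rsid, chrom = snps$chrom,
           position = snps$position + 1L, alleles = snps$alleles),
    path, progress = FALSE
  )
  invisible(path)
}
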