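#' @importFrom rlang .data
#' @importFrom tibble tibble as_tibble
NULL

# Genomic intervals live in tibble columns chrom / start / end / strand and
# use ONE convention everywhere inside the package: 0-based half-open
# [start, end). 1-based inclusive sources (GFF, display coordinates) and
# 0-based half-open sources (BED) are converted at the I/O boundary only.

# 1-based inclusive -> internal.
coords_from_1based <- function(start1, end1) {
  list(start = as.integer(start1) - 1L, end = as.integer(end1))
}

# internal -> 1-based inclusive.
coords_to_1based <- function(start0, end0) {
  list(start = as.integer(start0) + 1L, end = as.integer(end0))
}

check_intervals <- function(df, what = "interval") {
  bad <- which(!(df$start < df$end))
  if (length(bad) > 0) {
    stop(what, ": start must be < end (row ", bad[1], ")", call. = FALSE)
  }
  bad <- which(!df$strand %in% c("+", "-"))
  if (length(bad) > 0) {
    stop(what, ": strand must be '+' or '-' (row ", bad[1], ")", call. = FALSE)
  }
  invisible(df)
}

# All (i, j) index pairs where query row i overlaps subject row j by >= 1 bp
# on the same chromosome (strand is ignored: binding sites and promoters
# interact regardless of the reading strand). Uses IRanges internally.
overlap_pairs <- function(query, subject) {
  if (nrow(query) == 0 || nrow(subject) == 0) {
    return(tibble(query = integer(), subject = integer()))
  }
  hits <- purrr::map_dfr(intersect(unique(query$chrom), unique(subject$chrom)),
    function(chr) {
      qi <- which(query$chrom == chr)
      si <- which(subject$chrom == chr)
      qr <- IRanges::IRanges(start = query$start[qi] + 1L, end = query$end[qi])
      sr <- IRanges::IRanges(start = subject$start[si] + 1L,
                             end = subject$end[si])
      ov <- IRanges::findOverlaps(qr, sr, minoverlap = 1L)
      tibble(query = qi[S4Vectors::queryHits(ov)],
             subject = si[S4Vectors::subjectHits(ov)])
    })
  dplyr::arrange(hits, .data$query, .data$subject)
}

# Does a single base (internal 0-based position pos, i.e. [pos, pos + 1))
# fall inside [start, end)?
point_in <- function(pos, start, end) pos >= start & pos < end
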