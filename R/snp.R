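#' Annotate SNPs on regulatory elements
#'
#' Categorizes each SNP by single-base overlap with the regulatory features
#' of the network: miRNA target sites (`target_site`), TFBS hits mapped to
#' gene promoters (`tfbs_gene_promoter`) or miRNA promoters
#' (`tfbs_mirna_promoter`), precursor bodies (`pre_mirna`), and the flanking
#' windows of `cfg$snp_flank` bp on each side of a precursor
#' (`pre_mirna_flank`, boundary inclusive). A SNP may carry several
#' categories; for one precursor the body and flank categories are mutually
#' exclusive. For flank hits the distance in bp from the SNP to the nearest
#' precursor boundary is reported (1 = immediately adjacent).
#'
#' @param snps SNP tibble from [read_snps()].
#' @param target_sites Target pairs with site coordinates (rows without
#'   coordinates are ignored).
#' @param mapped_hits Promoter-mapped TFBS hits from
#'   [map_tfbs_to_promoters()]; may be `NULL`.
#' @param mirnas Precursor tibble; may be `NULL`.
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tidy tibble, one row per (SNP, category, element): `rsid`,
#'   `category`, `element`, `distance` (`NA` except for flanks). SNPs
#'   overlapping nothing are absent; see [summarize_snp_annotations()].
#' @export
annotate_snps <- function(snps, target_sites = NULL, mapped_hits = NULL,
                          mirnas = NULL, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  snp_iv <- tibble(chrom = snps$chrom, start = snps$position,
                   end = snps$position + 1L, strand = "+")
  out <- list()
  hit_rows <- function(features, category, element) {
    if (is.null(features) || nrow(features) == 0) return(NULL)
    ov <- overlap_pairs(snp_iv, features)
    if (nrow(ov) == 0) return(NULL)
    tibble(rsid = snps$rsid[ov$query], category = category,
           element = element[ov$subject], distance = NA_integer_)
  }
  if (!is.null(target_sites)) {
    ts <- target_sites[!is.na(target_sites$start), , drop = FALSE]
    out$site <- hit_rows(
      tibble(chrom = ts$chrom, start = ts$start, end = ts$end, strand = "+"),
      "target_site", paste(ts$mirna, ts$gene, sep = ":")
    )
  }
  if (!is.null(mapped_hits) && nrow(mapped_hits) > 0) {
    gh <- mapped_hits[mapped_hits$owner_type == "gene", , drop = FALSE]
    mh <- mapped_hits[mapped_hits$owner_type == "mirna", , drop = FALSE]
    out$tfbs_g <- hit_rows(gh, "tfbs_gene_promoter",
                           paste(gh$matrix_id, gh$owner, sep = ":"))
    out$tfbs_m <- hit_rows(mh, "tfbs_mirna_promoter",
                           paste(mh$matrix_id, mh$owner, sep = ":"))
  }
  if (!is.null(mirnas) && nrow(mirnas) > 0) {
    out$body <- hit_rows(mirnas, "pre_mirna", mirnas$precursor_id)
    flank <- tibble(chrom = mirnas$chrom,
                    start = pmax(0L, mirnas$start - cfg$snp_flank),
                    end = mirnas$end + cfg$snp_flank, strand = "+")
    ov <- overlap_pairs(snp_iv, flank)
    if (nrow(ov) > 0) {
      pos <- snps$position[ov$query]
      st <- mirnas$start[ov$subject]
      en <- mirnas$end[ov$subject]
      inside <- point_in(pos, st, en)
      ov <- ov[!inside, , drop = FALSE]
      pos <- pos[!inside]
      if (nrow(ov) > 0) {
        dist <- ifelse(pos < mirnas$start[ov$subject],
                       mirnas$start[ov$subject] - pos,
                       pos - mirnas$end[ov$subject] + 1L)
        out$flank <- tibble(rsid = snps$rsid[ov$query],
                            category = "pre_mirna_flank",
                            element = mirnas$precursor_id[ov$subject],
                            distance = as.integer(dist))
      }
    }
  }
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(rsid = character(), category = character(),
                  element = character(), distance = integer()))
  }
  res %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$rsid, .data$category, .data$element)
}

#' Summarize SNP annotations per category
#'
#' @param annotations Tibble from [annotate_snps()].
#' @return Tibble with one row per category: `category`, `n_snps` (distinct
#'   SNPs) and `n_elements` (distinct owner features; for TFBS categories
#'   the owner is the promoter's gene or miRNA, not the matrix). Categories
#'   with no hits appear with zero counts.
#' @export
summarize_snp_annotations <- function(annotations) {
  cats <- c("target_site", "tfbs_gene_promoter", "tfbs_mirna_promoter",
            "pre_mirna", "pre_mirna_flank")
  owner_of <- function(category, element) {
    # element is "matrix:owner" or "mirna:gene" or a precursor id; the
    # owner feature is the last :-separated component
    ifelse(category %in% c("tfbs_gene_promoter", "tfbs_mirna_promoter",
                           "target_site"),
           sub("^.*:", "", element), element)
  }
  counted <- annotations %>%
    dplyr::mutate(owner = owner_of(.data$category, .data$element)) %>%
    dplyr::group_by(.data$category) %>%
    dplyr::summarise(n_snps = dplyr::n_distinct(.data$rsid),
                     n_elements = dplyr::n_distinct(.data$owner),
                     .groups = "drop")
  tibble(category = cats) %>%
    dplyr::left_join(counted, by = "category") %>%
    tidyr::replace_na(list(n_snps = 0L, n_elements = 0L))
}
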