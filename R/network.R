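#' Merge redundant TFBS matrices into regulator groups
#'
#' Different position-weight matrices often describe the same physical
#' regulator. Within one promoter, two matrix placements are merged when
#' their intervals overlap and they share at least one TF symbol; matrices
#' with an identical consensus string are merged wherever they occur.
#' Merging is the transitive closure of these links (matrix identity links
#' placements of the same matrix across promoters), so every matrix belongs
#' to exactly one group, the unit at which regulators are counted.
#'
#' @param mapped_hits Promoter-mapped hits from [map_tfbs_to_promoters()].
#' @return An object of class `tf_groups`: a list with `map` (tibble
#'   `matrix_id`, `group_id`) and `groups` (tibble `group_id`, `matrix_ids`,
#'   `tf_symbols`, both comma-separated). The group id is the shortest
#'   member matrix id (ties broken lexicographically).
#' @export
merge_tfbs_groups <- function(mapped_hits) {
  ids <- sort(unique(mapped_hits$matrix_id))
  if (length(ids) == 0) {
    out <- list(map = tibble(matrix_id = character(), group_id = character()),
                groups = tibble(group_id = character(),
                                matrix_ids = character(),
                                tf_symbols = character()))
    return(structure(out, class = "tf_groups"))
  }
  links <- list()
  # (b) identical consensus, anywhere
  by_cons <- split(mapped_hits$matrix_id,
                   mapped_hits$consensus)[nzchar(names(split(
                     mapped_hits$matrix_id, mapped_hits$consensus)))]
  for (grp in by_cons) {
    u <- unique(grp)
    if (length(u) > 1) {
      links[[length(links) + 1]] <- tibble(a = u[-length(u)], b = u[-1])
    }
  }
  # (a) overlapping placement within one promoter with a shared TF symbol
  for (own in unique(mapped_hits$owner)) {
    h <- mapped_hits[mapped_hits$owner == own, , drop = FALSE]
    if (nrow(h) < 2) next
    ov <- overlap_pairs(h, h)
    ov <- ov[ov$query < ov$subject, , drop = FALSE]
    if (nrow(ov) == 0) next
    sy <- split_symbols(h$tf_symbols)
    share <- vapply(seq_len(nrow(ov)), function(i) {
      length(intersect(sy[[ov$query[i]]], sy[[ov$subject[i]]])) > 0
    }, logical(1))
    if (any(share)) {
      links[[length(links) + 1]] <- tibble(
        a = h$matrix_id[ov$query[share]], b = h$matrix_id[ov$subject[share]])
    }
  }
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(ids)
  if (length(links) > 0) {
    ed <- dplyr::bind_rows(links)
    ed <- ed[ed$a != ed$b, , drop = FALSE]
    g <- igraph::add_edges(g, rbind(ed$a, ed$b))
  }
  comp <- igraph::components(g)$membership
  map <- tibble(matrix_id = names(comp), group_id = NA_character_) %>%
    dplyr::mutate(comp = unname(comp)) %>%
    dplyr::group_by(.data$comp) %>%
    # deterministic, locale-independent label: shortest member id, ties
    # broken by C-collation order
    dplyr::mutate(group_id = .data$matrix_id[
      order(nchar(.data$matrix_id),
            xtfrm(factor(.data$matrix_id,
                         levels = sort(unique(.data$matrix_id),
                                       method = "radix"))))[1]]) %>%
    dplyr::ungroup() %>%
    dplyr::select("matrix_id", "group_id") %>%
    dplyr::arrange(.data$matrix_id)
  sym_map <- mapped_hits %>%
    dplyr::distinct(.data$matrix_id, .data$tf_symbols) %>%
    dplyr::mutate(sym = split_symbols(.data$tf_symbols))
  groups <- map %>%
    dplyr::left_join(sym_map[, c("matrix_id", "sym")], by = "matrix_id") %>%
    dplyr::group_by(.data$group_id) %>%
    dplyr::summarise(
      matrix_ids = paste(sort(unique(.data$matrix_id)), collapse = ","),
      tf_symbols = paste(sort(unique(unlist(.data$sym))), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$group_id)
  structure(list(map = map, groups = groups), class = "tf_groups")
}

#' @export
print.tf_groups <- function(x, ...) {
  cat("<tf_groups> ", nrow(x$groups), " group(s) over ", nrow(x$map),
      " matrix id(s)\n", sep = "")
  print(x$groups, ...)
  invisible(x)
}

group_symbol_list <- function(groups) {
  stats::setNames(split_symbols(groups$groups$tf_symbols),
                  groups$groups$group_id)
}

#' Lift matrix-level regulator edges to TF-group level
#'
#' @param edges Tibble with a `matrix_id` column plus target columns.
#' @param groups A `tf_groups` object from [merge_tfbs_groups()].
#' @return The edges with `matrix_id` replaced by `group_id`, deduplicated.
#' @export
group_edges <- function(edges, groups) {
  edges %>%
    dplyr::inner_join(groups$map, by = "matrix_id") %>%
    dplyr::select(-"matrix_id") %>%
    dplyr::relocate("group_id") %>%
    dplyr::distinct() %>%
    dplyr::arrange(dplyr::across(dplyr::everything()))
}

#' Build TF-to-target edges from promoter-mapped TFBS hits
#'
#' @param mapped_hits Output of [map_tfbs_to_promoters()].
#' @return Tibble `matrix_id`, `target`, `target_type` (`"gene"` or
#'   `"mirna"`), one row per distinct (matrix, target).
#' @export
build_tf_edges <- function(mapped_hits) {
  mapped_hits %>%
    dplyr::transmute(matrix_id = .data$matrix_id, target = .data$owner,
                     target_type = .data$owner_type) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$matrix_id, .data$target)
}

#' Build miRNA-to-gene edges from target pairs
#'
#' Target-prediction tables name mature miRNAs or families; regulatory loops
#' are enumerated per precursor. Each pair is expanded to one edge per
#' precursor whose `family_id`, mature name or precursor id matches the
#' pair's `mirna`. When `cfg$require_site_conserved` is set, pairs with a
#' non-conserved seed site are dropped — except for precursors of
#' conservation class `"P"` (primate-specific), whose sites cannot be
#' conserved in mammals by definition.
#'
#' @param pairs Target pairs from [read_target_pairs()].
#' @param mirnas Precursor tibble from [read_mirna_annotation()].
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tibble `mirna` (precursor id), `gene`, plus the site columns
#'   `chrom`, `start`, `end`, `site_conserved`.
#' @export
build_mirna_gene_edges <- function(pairs, mirnas, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  if (nrow(pairs) == 0) {
    return(tibble(mirna = character(), gene = character(), chrom = character(),
                  start = integer(), end = integer(),
                  site_conserved = logical()))
  }
  expand <- mirnas %>%
    dplyr::transmute(precursor_id = .data$precursor_id,
                     conservation_class = .data$conservation_class,
                     name = purrr::map2(.data$family_id, .data$matures,
                                        function(f, m) {
                                          unique(c(f, split_symbols(m)[[1]]))
                                        }),
                     self = .data$precursor_id) %>%
    tidyr::unnest_longer("name") %>%
    dplyr::bind_rows(
      mirnas %>% dplyr::transmute(precursor_id = .data$precursor_id,
                                  conservation_class = .data$conservation_class,
                                  name = .data$precursor_id,
                                  self = .data$precursor_id)
    ) %>%
    dplyr::distinct(.data$precursor_id, .data$conservation_class, .data$name)
  unknown <- setdiff(unique(pairs$mirna), expand$name)
  if (length(unknown) > 0) {
    stop("target pair names no known precursor, mature or family: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- pairs %>%
    dplyr::inner_join(expand, by = c(mirna = "name"),
                      relationship = "many-to-many")
  if (cfg$require_site_conserved) {
    out <- out[out$site_conserved | out$conservation_class == "P", ,
               drop = FALSE]
  }
  out %>%
    dplyr::transmute(mirna = .data$precursor_id, gene = .data$gene,
                     chrom = .data$chrom, start = .data$start,
                     end = .data$end, site_conserved = .data$site_conserved) %>%
    dplyr::distinct() %>%
    dplyr::arrange(.data$mirna, .data$gene, .data$start)
}

#' Enumerate feed-forward loops
#'
#' A feed-forward loop (FFL) is a triple (TF group g, miRNA precursor m,
#' gene t) such that g regulates t, g regulates m, and m represses t. The
#' enumeration is an exact join over the three edge sets, deduplicated and
#' returned in a deterministic order (gene, miRNA, group).
#'
#' @param tf_gene Tibble `group_id`, `gene`.
#' @param tf_mirna Tibble `group_id`, `mirna`.
#' @param mirna_gene Tibble `mirna`, `gene` (extra columns ignored).
#' @return Tibble `group_id`, `mirna`, `gene`, one row per FFL.
#' @export
#' @examples
#' find_ffls(
#'   tf_gene = tibble::tibble(group_id = "g", gene = "G"),
#'   tf_mirna = tibble::tibble(group_id = "g", mirna = "m"),
#'   mirna_gene = tibble::tibble(mirna = "m", gene = "G")
#' )
find_ffls <- function(tf_gene, tf_mirna, mirna_gene) {
  tg <- dplyr::distinct(tf_gene[, c("group_id", "gene")])
  tm <- dplyr::distinct(tf_mirna[, c("group_id", "mirna")])
  mg <- dplyr::distinct(mirna_gene[, c("mirna", "gene")])
  tg %>%
    dplyr::inner_join(tm, by = "group_id", relationship = "many-to-many") %>%
    dplyr::inner_join(mg, by = c("mirna", "gene")) %>%
    dplyr::distinct(.data$group_id, .data$mirna, .data$gene) %>%
    dplyr::arrange(.data$gene, .data$mirna, .data$group_id) %>%
    dplyr::relocate("group_id", "mirna", "gene")
}

#' Find miRNA-TF mutual feedback loops
#'
#' A composite feedback loop is a pair (TF group g, miRNA precursor m) where
#' g has a binding site in m's promoter and m targets the gene encoding one
#' of g's TF symbols. Unlike FFL enumeration, the miRNA target edges here
#' may point at any gene, including TF-encoding genes outside the
#' disease-gene list.
#'
#' @param tf_mirna Tibble `group_id`, `mirna`.
#' @param mirna_gene_all Tibble `mirna`, `gene` over all targets.
#' @param groups A `tf_groups` object giving each group's symbols.
#' @return Tibble `group_id`, `mirna`, `tf_genes_targeted` (comma-separated
#'   symbols of the group that the miRNA targets), one row per loop.
#' @export
find_feedback_loops <- function(tf_mirna, mirna_gene_all, groups) {
  syms <- group_symbol_list(groups)
  tm <- dplyr::distinct(tf_mirna[, c("group_id", "mirna")])
  mg <- dplyr::distinct(mirna_gene_all[, c("mirna", "gene")])
  tm %>%
    dplyr::inner_join(mg, by = "mirna", relationship = "many-to-many") %>%
    dplyr::filter(purrr::map2_lgl(.data$group_id, .data$gene,
                                  function(g, t) t %in% (syms[[g]] %||% character()))) %>%
    dplyr::group_by(.data$group_id, .data$mirna) %>%
    dplyr::summarise(
      tf_genes_targeted = paste(sort(unique(.data$gene)), collapse = ","),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$mirna, .data$group_id)
}

#' Reconstruct matrix-level edge sets from the bundled FFL table
#'
#' Expands the 32 published loops into the regulator structure they imply:
#' for each loop row (gene t, precursor m, matrices M), every matrix in M
#' has a binding site in t's promoter and in m's promoter, and m represses
#' t. Placements are laid out on a synthetic chromosome so that matrices
#' co-listed in one row overlap (and merge) while matrices from different
#' rows do not; per-matrix TF symbols come from the sidecar catalog and the
#' consensus string from the row. Feeding the result through
#' [merge_tfbs_groups()] and [find_ffls()] reproduces the published loop
#' set.
#'
#' @param fixtures Fixture bundle from [load_reference_fixtures()]; reloaded
#'   when `NULL`.
#' @return A list with `hits_with_owner` (synthetic promoter-mapped hits),
#'   and matrix-level `tf_gene`, `tf_mirna`, `mirna_gene` edge tibbles.
#' @export
reference_edge_bundle <- function(fixtures = NULL) {
  if (is.null(fixtures)) fixtures <- load_reference_fixtures()
  tab <- fixtures$ffl_table
  sym <- fixtures$matrix_tf %>%
    dplyr::group_by(.data$matrix_id) %>%
    dplyr::summarise(tf_symbols = paste(sort(.data$tf_symbol), collapse = ","),
                     .groups = "drop")
  owners <- sort(unique(c(tab$gene, tab$mirna)))
  slot <- stats::setNames(seq_along(owners), owners)
  rows <- purrr::map_dfr(seq_len(nrow(tab)), function(i) {
    mats <- split_symbols(tab$matrices[i])[[1]]
    purrr::map_dfr(c(tab$gene[i], tab$mirna[i]), function(own) {
      # one 20 bp placement slot per (owner, loop row); co-listed matrices
      # share it so the overlap+symbol / shared-consensus merge rules fire
      base <- slot[[own]] * 100000L + tab$no[i] * 100L
      tibble(matrix_id = mats, consensus = tab$consensus[i],
             chrom = "fx1", start = base, end = base + 20L, strand = "+",
             z_score = 3.0, conserved = TRUE,
             owner = own,
             owner_type = if (own == tab$gene[i]) "gene" else "mirna",
             basis = if (own == tab$gene[i]) "gene_tss" else "precursor")
    })
  })
  hits <- dplyr::left_join(rows, sym, by = "matrix_id")
  if (anyNA(hits$tf_symbols)) {
    stop("matrix missing from sidecar catalog: ",
         hits$matrix_id[is.na(hits$tf_symbols)][1], call. = FALSE)
  }
  expand <- tab %>%
    dplyr::mutate(matrix_id = split_symbols(.data$matrices)) %>%
    tidyr::unnest_longer("matrix_id")
  list(
    hits_with_owner = hits,
    tf_gene = dplyr::distinct(expand[, c("matrix_id", "gene")]),
    tf_mirna = dplyr::distinct(expand[, c("matrix_id", "mirna")]),
    mirna_gene = dplyr::distinct(tab[, c("mirna", "gene")])
  )
}
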