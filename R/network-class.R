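node_types <- c("mirna", "tf", "gene")

new_ffl_network <- function(nodes, edges) {
  nodes <- dplyr::arrange(dplyr::distinct(nodes), .data$type, .data$id)
  edges <- dplyr::arrange(dplyr::distinct(edges),
                          .data$kind, .data$from, .data$to)
  bad <- setdiff(nodes$type, node_types)
  if (length(bad) > 0) stop("unknown node type: ", bad[1], call. = FALSE)
  dangling <- setdiff(unique(c(edges$from, edges$to)), nodes$id)
  if (length(dangling) > 0) {
    stop("edge refers to unknown node: ", dangling[1], call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges), class = "ffl_network")
}

#' @export
print.ffl_network <- function(x, ...) {
  tally <- table(factor(x$nodes$type, levels = node_types))
  cat("<ffl_network> ", nrow(x$nodes), " nodes (",
      paste(sprintf("%s %d", names(tally), tally), collapse = ", "),
      "), ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Converge feed-forward and feedback loops into a regulatory network
#'
#' Builds a typed graph from the FFL set: each loop contributes a TF-group
#' node, a miRNA node, a gene node and the three directed edges `tf_gene`,
#' `tf_mirna` and `mirna_gene`. Mutual feedback loops are then attached,
#' but only those sharing at least one TF-group or miRNA node with some
#' FFL; an attached loop contributes its `tf_mirna` edge and a `mirna_tf`
#' edge back to the group node. Edges are deduplicated. A `tf_gene` edge
#' whose target gene encodes one of the group's own symbols is flagged as a
#' self edge.
#'
#' @param ffls FFL tibble from [find_ffls()].
#' @param loops Optional feedback-loop tibble from [find_feedback_loops()].
#' @param groups Optional `tf_groups` object; supplies group symbols for
#'   node metadata and self-edge flags.
#' @return An `ffl_network`: list with `nodes` (`id`, `type`, `symbols`)
#'   and `edges` (`from`, `to`, `kind`, `self_edge`).
#' @export
merge_network <- function(ffls, loops = NULL, groups = NULL) {
  syms <- if (is.null(groups)) list() else group_symbol_list(groups)
  sym_of <- function(g) paste(syms[[g]] %||% character(), collapse = ",")
  edges <- dplyr::bind_rows(
    tibble(from = ffls$group_id, to = ffls$gene, kind = "tf_gene"),
    tibble(from = ffls$group_id, to = ffls$mirna, kind = "tf_mirna"),
    tibble(from = ffls$mirna, to = ffls$gene, kind = "mirna_gene")
  )
  nodes <- dplyr::bind_rows(
    tibble(id = unique(ffls$group_id), type = "tf"),
    tibble(id = unique(ffls$mirna), type = "mirna"),
    tibble(id = unique(ffls$gene), type = "gene")
  )
  if (!is.null(loops) && nrow(loops) > 0) {
    keep <- loops$group_id %in% ffls$group_id | loops$mirna %in% ffls$mirna
    lp <- loops[keep, , drop = FALSE]
    if (nrow(lp) > 0) {
      edges <- dplyr::bind_rows(
        edges,
        tibble(from = lp$group_id, to = lp$mirna, kind = "tf_mirna"),
        tibble(from = lp$mirna, to = lp$group_id, kind = "mirna_tf")
      )
      nodes <- dplyr::bind_rows(
        nodes,
        tibble(id = unique(lp$group_id), type = "tf"),
        tibble(id = unique(lp$mirna), type = "mirna")
      )
    }
  }
  nodes <- dplyr::distinct(nodes)
  dup <- nodes$id[duplicated(nodes$id)]
  if (length(dup) > 0) {
    stop("node typed inconsistently: ", dup[1], call. = FALSE)
  }
  nodes$symbols <- ifelse(nodes$type == "tf",
                          vapply(nodes$id, sym_of, character(1)), "")
  edges <- dplyr::distinct(edges)
  self <- edges$kind == "tf_gene" &
    purrr::map2_lgl(edges$from, edges$to,
                    function(g, t) t %in% (syms[[g]] %||% character()))
  edges$self_edge <- self
  new_ffl_network(nodes, edges)
}

#' Per-node degree summary of a regulatory network
#'
#' Counts distinct regulator and target partners per node. For TF groups
#' the regulated-gene tally excludes self edges (a group hitting the
#' promoter of a gene encoding one of its own symbols) when
#' `cfg$exclude_self_edges` is set; in-degrees always count every edge.
#'
#' @param net An `ffl_network`.
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return Tibble: `node`, `type`, `tf_groups_in`, `mirnas_in`, `genes_out`,
#'   `mirnas_out`.
#' @export
node_degrees <- function(net, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  if (nrow(net$nodes) == 0) {
    return(tibble(node = character(), type = character(),
                  tf_groups_in = integer(), mirnas_in = integer(),
                  genes_out = integer(), mirnas_out = integer()))
  }
  e <- net$edges
  count_in <- function(kind, id) {
    sub <- e[e$kind == kind & e$to == id, , drop = FALSE]
    length(unique(sub$from))
  }
  count_out <- function(kind, id, drop_self = FALSE) {
    sub <- e[e$kind == kind & e$from == id, , drop = FALSE]
    if (drop_self) sub <- sub[!sub$self_edge, , drop = FALSE]
    length(unique(sub$to))
  }
  purrr::map_dfr(seq_len(nrow(net$nodes)), function(i) {
    id <- net$nodes$id[i]
    type <- net$nodes$type[i]
    tibble(
      node = id, type = type,
      tf_groups_in = switch(type,
        gene = count_in("tf_gene", id),
        mirna = count_in("tf_mirna", id), 0L),
      mirnas_in = switch(type,
        gene = count_in("mirna_gene", id),
        tf = count_in("mirna_tf", id), 0L),
      genes_out = switch(type,
        tf = count_out("tf_gene", id, cfg$exclude_self_edges),
        mirna = count_out("mirna_gene", id), 0L),
      mirnas_out = if (type == "tf") count_out("tf_mirna", id) else 0L
    )
  })
}

#' Detect core (hub) nodes
#'
#' A gene is core when it is regulated by at least `cfg$core_min_tfs` TF
#' groups and at least `cfg$core_min_mirnas` miRNAs. A miRNA is core when
#' it regulates at least `cfg$core_min_targets` genes and is itself
#' regulated by at least `cfg$core_min_tfs` TF groups. Regulator
#' multiplicity is counted at the merged TF-group level.
#'
#' @param net An `ffl_network`.
#' @param cfg An [ffl_config()]; `NULL` for defaults.
#' @return A list with `core_genes`, `core_mirnas` (character vectors,
#'   sorted) and `degrees` (the [node_degrees()] table).
#' @export
find_core_nodes <- function(net, cfg = NULL) {
  cfg <- as_ffl_config(cfg)
  deg <- node_degrees(net, cfg)
  genes <- deg$node[deg$type == "gene" &
                      deg$tf_groups_in >= cfg$core_min_tfs &
                      deg$mirnas_in >= cfg$core_min_mirnas]
  mirnas <- deg$node[deg$type == "mirna" &
                       deg$genes_out >= cfg$core_min_targets &
                       deg$tf_groups_in >= cfg$core_min_tfs]
  list(core_genes = sort(genes), core_mirnas = sort(mirnas), degrees = deg)
}

#' Extract the neighborhood subnetwork of a node
#'
#' Induced subgraph on the node and its direct neighbors (either edge
#' direction), retaining every edge among the retained nodes.
#'
#' @param net An `ffl_network`.
#' @param node_id Node identifier.
#' @return An `ffl_network`.
#' @export
extract_subnetwork <- function(net, node_id) {
  if (!node_id %in% net$nodes$id) {
    stop("unknown node: ", node_id, call. = FALSE)
  }
  e <- net$edges
  nb <- unique(c(node_id, e$to[e$from == node_id], e$from[e$to == node_id]))
  keep_e <- e$from %in% nb & e$to %in% nb
  new_ffl_network(net$nodes[net$nodes$id %in% nb, , drop = FALSE],
                  e[keep_e, , drop = FALSE])
}

#' Convert a regulatory network to an igraph object
#'
#' @param net An `ffl_network`.
#' @return A directed `igraph` graph with vertex attributes `type` and
#'   `symbols` and edge attributes `kind` and `self_edge`.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "ffl_network"))
  igraph::graph_from_data_frame(
    d = net$edges, directed = TRUE,
    vertices = as.data.frame(net$nodes)
  )
}

#' Export a regulatory network to SIF or GraphML
#'
#' SIF writes one `source<TAB>relation<TAB>target` line per edge using the
#' relation labels `tf_gene`, `tf_mirna`, `mirna_gene`, `mirna_tf` (nodes
#' without edges are not representable in SIF). GraphML carries the node
#' `type`/`symbols` and edge `kind`/`self_edge` attributes, so an
#' export/import round trip reproduces the node and edge sets.
#'
#' @param net An `ffl_network`.
#' @param path Output path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  bad <- setdiff(net$nodes$type, node_types)
  if (length(bad) > 0) stop("unknown node type: ", bad[1], call. = FALSE)
  if (format == "sif") {
    writeLines(sprintf("%s\t%s\t%s", net$edges$from, net$edges$kind,
                       net$edges$to), path)
  } else {
    igraph::write_graph(as_igraph(net), path, format = "graphml")
  }
  invisible(path)
}

#' Import a regulatory network from SIF or GraphML
#'
#' @param path File written by [export_network()].
#' @param format `"sif"` or `"graphml"`.
#' @return An `ffl_network`. For SIF, node types are inferred from the
#'   relation labels and self-edge flags are recomputed as unavailable
#'   (`FALSE`).
#' @export
import_network <- function(path, format = c("sif", "graphml")) {
  format <- match.arg(format)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    nodes <- tibble(id = igraph::V(g)$name, type = igraph::V(g)$type,
                    symbols = igraph::V(g)$symbols %||%
                      rep("", igraph::gorder(g)))
    el <- igraph::as_edgelist(g)
    edges <- tibble(from = el[, 1], to = el[, 2],
                    kind = igraph::E(g)$kind,
                    self_edge = as.logical(igraph::E(g)$self_edge))
    return(new_ffl_network(nodes, edges))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) != 3)) stop("malformed SIF line", call. = FALSE)
  edges <- tibble(from = vapply(f, `[[`, character(1), 1),
                  kind = vapply(f, `[[`, character(1), 2),
                  to = vapply(f, `[[`, character(1), 3),
                  self_edge = FALSE)
  type_from <- c(tf_gene = "tf", tf_mirna = "tf", mirna_gene = "mirna",
                 mirna_tf = "mirna")
  type_to <- c(tf_gene = "gene", tf_mirna = "mirna", mirna_gene = "gene",
               mirna_tf = "tf")
  bad <- setdiff(edges$kind, names(type_from))
  if (length(bad) > 0) stop("unknown relation label: ", bad[1], call. = FALSE)
  nodes <- dplyr::distinct(dplyr::bind_rows(
    tibble(id = edges$from, type = unname(type_from[edges$kind])),
    tibble(id = edges$to, type = unname(type_to[edges$kind]))
  ))
  nodes$symbols <- ""
  new_ffl_network(nodes, edges[, c("from", "to", "kind", "self_edge")])
}
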