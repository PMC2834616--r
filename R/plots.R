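#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a regulatory network
#'
#' Force-directed layout (Fruchterman-Reingold, seeded for
#' reproducibility) with nodes colored by type and edges drawn as
#' segments. Intended as a quick look; for publication figures export to
#' GraphML and use a dedicated network editor.
#'
#' @param object An `ffl_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffl_network <- function(object, seed = 1L, ...) {
  g <- as_igraph(object)
  xy <- with_seed(seed, igraph::layout_with_fr(g))
  nodes <- dplyr::mutate(object$nodes, x = xy[, 1], y = xy[, 2])
  edges <- object$edges %>%
    dplyr::left_join(nodes[, c("id", "x", "y")], by = c(from = "id")) %>%
    dplyr::left_join(nodes[, c("id", "x", "y")], by = c(to = "id"),
                     suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linetype = .data$kind),
      color = "grey60") +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$type), size = 3) +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1, size = 2.7) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "node type", linetype = "regulation")
}

#' Plot a resampling null distribution
#'
#' Histogram of the replicate counts with the observed value marked,
#' for permutation and target-count enrichment results.
#'
#' @param object An `ffl_enrichment` carrying a `null` vector.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ffl_enrichment <- function(object, ...) {
  if (is.null(object$null)) {
    stop("no resampling null stored in this result", call. = FALSE)
  }
  df <- tibble(count = object$null)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$count)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "red") +
    ggplot2::labs(x = "replicate count", y = "replicates",
                  subtitle = sprintf("observed = %s, p = %.4g",
                                     format(object$observed),
                                     object$p_value)) +
    ggplot2::theme_minimal()
}
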