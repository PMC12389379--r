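#' Plot annual publication counts
#'
#' Bar chart of publications per year with a line for total citations of each
#' year's documents on a secondary scale.
#'
#' @param annual an [annual_production()] tibble.
#' @return a ggplot object.
#' @export
plot_annual_production <- function(annual) {
  ggplot2::ggplot(annual, ggplot2::aes(x = .data$year, y = .data$NP)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Year", y = "Publications",
                  title = "Annual scientific production") +
    ggplot2::theme_minimal()
}

#' Heatmap of the miRNA-by-year article matrix
#'
#' @param object a `mirna_matrix` from [annual_mirna_matrix()].
#' @param top_n miRNAs shown, ranked by total articles (default 10).
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot mirna_matrix
#' @export
autoplot.mirna_matrix <- function(object, top_n = 10, ...) {
  ranked <- rank_mirnas(object, top_n = top_n)
  dat <- object |>
    dplyr::filter(.data$mirna %in% ranked$mirna) |>
    dplyr::mutate(mirna = factor(.data$mirna, levels = rev(ranked$mirna)))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$year, y = .data$mirna,
                                    fill = .data$n)) +
    ggplot2::geom_tile(color = "grey90") +
    ggplot2::scale_fill_gradient(low = "lightyellow", high = "firebrick") +
    ggplot2::labs(x = "Year", y = NULL, fill = "Articles",
                  title = "Annual publications per miRNA") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot corresponding-author country output split into SCP and MCP
#'
#' @param scp_mcp a [scp_mcp_counts()] tibble.
#' @param top_n countries shown (default 20).
#' @return a ggplot object.
#' @export
plot_scp_mcp <- function(scp_mcp, top_n = 20) {
  dat <- utils::head(scp_mcp, top_n) |>
    tidyr::pivot_longer(c("SCP", "MCP"), names_to = "type", values_to = "n") |>
    dplyr::mutate(country = factor(.data$country, levels = rev(unique(.data$country))))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$country,
                                    fill = .data$type)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Corresponding-author articles", y = NULL, fill = NULL,
                  title = "Single- vs multiple-country publications") +
    ggplot2::theme_minimal()
}

#' Word-cloud style plot of keyword frequencies
#'
#' Deterministic spiral layout; text size scales with frequency.
#'
#' @param freqs a [keyword_frequencies()] tibble.
#' @param max_terms terms shown (default 50).
#' @return a ggplot object.
#' @export
plot_keyword_cloud <- function(freqs, max_terms = 50) {
  dat <- utils::head(freqs, max_terms)
  k <- nrow(dat)
  theta <- 2.4 * seq_len(k)
  dat$x <- sqrt(seq_len(k)) * cos(theta)
  dat$y <- sqrt(seq_len(k)) * sin(theta)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$y,
                                    label = .data$keyword, size = .data$n)) +
    ggplot2::geom_text(color = "steelblue4") +
    ggplot2::scale_size_continuous(range = c(2.5, 9), guide = "none") +
    ggplot2::theme_void()
}

#' Plot a weighted network with optional community colors
#'
#' @param graph a weighted igraph.
#' @param partition optional `graph_partition` coloring the nodes.
#' @param seed layout seed (default 1).
#' @return a ggplot object.
#' @export
plot_network <- function(graph, partition = NULL, seed = 1) {
  if (igraph::vcount(graph) == 0) {
    return(ggplot2::ggplot() + ggplot2::theme_void())
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  xy <- igraph::layout_with_fr(graph)
  nodes <- tibble::tibble(node = igraph::V(graph)$name, x = xy[, 1], y = xy[, 2],
                          weight = igraph::vertex_attr(graph, "weight"))
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, tidy(partition), by = "node")
  } else {
    nodes$cluster <- 1L
  }
  edges <- tidy(graph)
  if (nrow(edges) > 0) {
    edges$x <- nodes$x[match(edges$from, nodes$node)]
    edges$y <- nodes$y[match(edges$from, nodes$node)]
    edges$xend <- nodes$x[match(edges$to, nodes$node)]
    edges$yend <- nodes$y[match(edges$to, nodes$node)]
  }
  p <- ggplot2::ggplot()
  if (nrow(edges) > 0) {
    p <- p + ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$weight),
      color = "grey70", alpha = 0.7)
  }
  p +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     size = .data$weight,
                                     color = factor(.data$cluster))) +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(x = .data$x, y = .data$y, label = .data$node),
                       vjust = -1, size = 3) +
    ggplot2::scale_linewidth_continuous(range = c(0.2, 2), guide = "none") +
    ggplot2::scale_size_continuous(range = c(2, 8), guide = "none") +
    ggplot2::labs(color = "Cluster") +
    ggplot2::theme_void()
}
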