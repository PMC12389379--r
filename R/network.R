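# Weighted undirected graphs are igraph objects with a vertex attribute
# `weight` (occurrence count) and edge attribute `weight` (co-occurrence
# count, or association strength after normalization). The raw total link
# weight m is kept as the graph attribute `total_link_weight`.

build_weighted_graph <- function(node_weights, edge_tbl) {
  g <- igraph::make_empty_graph(n = length(node_weights), directed = FALSE)
  if (length(node_weights) > 0) {
    g <- igraph::set_vertex_attr(g, "name", value = names(node_weights))
    g <- igraph::set_vertex_attr(g, "weight", value = unname(node_weights))
  }
  if (nrow(edge_tbl) > 0) {
    g <- igraph::add_edges(g, rbind(edge_tbl$from, edge_tbl$to),
                           weight = edge_tbl$weight)
  }
  igraph::graph_attr(g, "total_link_weight") <- sum(edge_tbl$weight)
  g
}

# unordered pair counting over per-record entity sets
count_pairs <- function(sets, per_pair_weight = NULL) {
  rows <- purrr::imap_dfr(sets, function(s, i) {
    s <- sort(unique(s))
    if (length(s) < 2) return(NULL)
    pr <- utils::combn(s, 2)
    w <- if (is.null(per_pair_weight)) 1 else per_pair_weight(length(s))
    tibble::tibble(from = pr[1, ], to = pr[2, ], weight = w)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(from = character(0), to = character(0), weight = numeric(0)))
  }
  rows |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(weight = sum(.data$weight), .groups = "drop")
}

#' Country collaboration network
#'
#' Nodes are countries weighted by the number of articles with at least one
#' author from the country; an edge between two countries is weighted by the
#' number of articles with at least one author from each (full counting).
#'
#' @param corpus a corpus tibble.
#' @param country_table alias map from [country_alias_table()].
#' @return an undirected igraph with vertex attribute `weight` and edge
#'   attribute `weight`; `total_link_weight` graph attribute holds the sum of
#'   edge weights.
#' @export
collaboration_network <- function(corpus, country_table = country_alias_table()) {
  sets <- purrr::map(corpus$authors, function(a) {
    cc <- parse_affiliation_country(a$affiliation, country_table)
    unique(cc[!is.na(cc)])
  })
  node_w <- table(unlist(sets))
  node_weights <- stats::setNames(as.integer(node_w), names(node_w))
  build_weighted_graph(node_weights, count_pairs(sets))
}

#' Keyword co-occurrence network
#'
#' Nodes are normalized author keywords occurring in at least `min_occurrence`
#' articles. Under full counting each article adds 1 to every kept-keyword
#' pair it contains; under fractional counting an article with `k` kept
#' keywords adds `1/(k - 1)` per pair, so each keyword distributes exactly
#' unit weight across its pairs.
#'
#' @param corpus a corpus tibble.
#' @param thesaurus optional [thesaurus()] applied before counting.
#' @param min_occurrence minimum article-level keyword occurrence (default 5).
#' @param counting `"fractional"` (default for keyword maps) or `"full"`.
#' @return an undirected igraph (see [collaboration_network()]).
#' @export
cooccurrence_network <- function(corpus, thesaurus = NULL, min_occurrence = 5,
                                 counting = c("fractional", "full")) {
  counting <- match.arg(counting)
  sets <- purrr::map(corpus$author_keywords, function(kw) {
    kw <- normalize_keyword(kw, thesaurus)
    unique(kw[!is.na(kw)])
  })
  occ <- table(unlist(sets))
  keep <- names(occ)[occ >= min_occurrence]
  sets <- purrr::map(sets, intersect, keep)
  node_weights <- stats::setNames(as.integer(occ[keep]), keep)
  edge_tbl <- count_pairs(sets, per_pair_weight = if (counting == "fractional") {
    function(k) 1 / (k - 1)
  } else {
    NULL
  })
  build_weighted_graph(node_weights[sort(names(node_weights))], edge_tbl)
}

#' Association-strength normalization of edge weights
#'
#' Replaces each co-occurrence weight by the association strength
#' `s_ij = 2 m c_ij / (w_i w_j)`, comparing observed to expected
#' co-occurrence under independence; `m` is the total link weight. Node
#' weights are preserved and the raw co-occurrence is kept in the edge
#' attribute `cooccurrence`.
#'
#' @param graph an igraph from [collaboration_network()] or
#'   [cooccurrence_network()].
#' @return the graph with normalized edge `weight`.
#' @export
normalize_association <- function(graph) {
  if (igraph::ecount(graph) == 0) return(graph)
  ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  w <- igraph::vertex_attr(graph, "weight")
  if (any(w[unique(as.vector(ends))] == 0)) {
    stop("zero node weight on an edge endpoint", call. = FALSE)
  }
  cij <- igraph::edge_attr(graph, "weight")
  m <- igraph::graph_attr(graph, "total_link_weight") %||% sum(cij)
  graph <- igraph::set_edge_attr(graph, "cooccurrence", value = cij)
  igraph::set_edge_attr(graph, "weight",
                        value = 2 * m * cij / (w[ends[, 1]] * w[ends[, 2]]))
}

new_partition <- function(nodes, cluster, method, residual = rep(FALSE, length(nodes)),
                          quality = NA_real_) {
  structure(
    list(assignment = tibble::tibble(node = nodes, cluster = as.integer(cluster),
                                     residual = residual),
         method = method, quality = quality),
    class = "graph_partition"
  )
}

#' @export
print.graph_partition <- function(x, ...) {
  cat("<graph_partition> method=", x$method, ", ",
      length(unique(x$assignment$cluster)), " cluster(s), ",
      nrow(x$assignment), " node(s)\n", sep = "")
  print(dplyr::count(x$assignment, .data$cluster))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a community partition into a node-cluster tibble
#'
#' @param x a `graph_partition`.
#' @param ... unused.
#' @return tibble `node`, `cluster`, `residual`.
#' @method tidy graph_partition
#' @export
tidy.graph_partition <- function(x, ...) x$assignment

#' One-row summary of a community partition
#'
#' @param x a `graph_partition`.
#' @param ... unused.
#' @return tibble `method`, `n_nodes`, `n_clusters`, `quality`.
#' @method glance graph_partition
#' @export
glance.graph_partition <- function(x, ...) {
  tibble::tibble(method = x$method, n_nodes = nrow(x$assignment),
                 n_clusters = length(unique(x$assignment$cluster)),
                 quality = x$quality)
}

#' Walktrap community detection
#'
#' Random-walk agglomerative community detection: short random walks define
#' node distances, clusters merge hierarchically, and the dendrogram is cut at
#' maximum modularity. Deterministic given the graph and walk length;
#' disconnected components are handled independently.
#'
#' @param graph a weighted igraph.
#' @param walk_length random-walk length (default 4).
#' @return a `graph_partition`.
#' @export
walktrap_communities <- function(graph, walk_length = 4) {
  cl <- igraph::cluster_walktrap(graph, weights = igraph::E(graph)$weight,
                                 steps = walk_length)
  new_partition(igraph::V(graph)$name, igraph::membership(cl),
                method = "walktrap", quality = igraph::modularity(cl))
}

# quality of a partition under the resolution objective:
# sum over same-cluster pairs of (s_ij - gamma * w_i w_j / (2m))
resolution_quality <- function(S, Egamma, membership) {
  B <- S - Egamma
  diag(B) <- 0
  q <- 0
  for (cl in unique(membership)) {
    idx <- which(membership == cl)
    if (length(idx) > 1) q <- q + sum(B[idx, idx]) / 2
  }
  q
}

# Louvain-style optimization of B = S - gamma*E (diagonal zero): local moving
# until stable, then aggregate clusters into supernodes and recurse.
local_move_aggregate <- function(B) {
  n <- nrow(B)
  if (n <= 1) return(rep(1L, n))
  groups <- seq_len(n)
  moved <- TRUE
  while (moved) {
    moved <- FALSE
    for (i in sample.int(n)) {
      own <- groups[i]
      link <- tapply(B[i, -i], groups[-i], sum)
      # moving to an empty cluster (staying alone) has gain 0
      gain_own <- if (as.character(own) %in% names(link)) link[[as.character(own)]] else 0
      gain_best <- max(link)
      if (gain_best > gain_own + 1e-12 && gain_best > 1e-12) {
        groups[i] <- as.integer(names(link)[which.max(link)])
        moved <- TRUE
      } else if (gain_own < -1e-12) {
        groups[i] <- max(groups) + 1L
        moved <- TRUE
      }
    }
  }
  groups <- match(groups, unique(groups))
  k <- length(unique(groups))
  if (k == n) return(groups)
  agg <- rowsum(t(rowsum(B, groups)), groups)
  diag(agg) <- 0
  inner <- local_move_aggregate(agg)
  match(inner[groups], unique(inner[groups]))
}

#' Resolution-parameterized clustering of a normalized network
#'
#' Maximizes `sum over same-cluster pairs of (s_ij - gamma * expected_ij)`
#' where `expected_ij = w_i w_j / (2m)` is the configuration-model
#' expectation, by Louvain-style local moving with random restarts under a
#' fixed seed. Clusters smaller than `min_cluster_size` are merged into the
#' neighbor cluster with the largest connecting weight; clusters with no
#' connection are flagged residual instead.
#'
#' @param graph a weighted igraph, typically association-normalized with
#'   [normalize_association()].
#' @param resolution resolution parameter gamma (default 0.5); larger values
#'   give more, smaller clusters.
#' @param min_cluster_size smallest reportable cluster (default 10).
#' @param n_restarts random restarts (default 10).
#' @param seed RNG seed for the restarts (default 20240925).
#' @return a `graph_partition`.
#' @export
resolution_clustering <- function(graph, resolution = 0.5, min_cluster_size = 10,
                                  n_restarts = 10, seed = 20240925) {
  nodes <- igraph::V(graph)$name
  n <- length(nodes)
  if (n == 0) return(new_partition(character(0), integer(0), "resolution"))
  S <- matrix(0, n, n, dimnames = list(nodes, nodes))
  C <- S
  if (igraph::ecount(graph) > 0) {
    ends <- igraph::ends(graph, igraph::E(graph), names = FALSE)
    s <- igraph::edge_attr(graph, "weight")
    craw <- igraph::edge_attr(graph, "cooccurrence") %||% s
    S[ends] <- s; S[ends[, c(2, 1), drop = FALSE]] <- s
    C[ends] <- craw; C[ends[, c(2, 1), drop = FALSE]] <- craw
  }
  w <- igraph::vertex_attr(graph, "weight")
  m <- igraph::graph_attr(graph, "total_link_weight") %||% (sum(C) / 2)
  Egamma <- if (m > 0) resolution * outer(w, w) / (2 * m) else matrix(0, n, n)
  diag(Egamma) <- 0

  best <- NULL
  best_q <- -Inf
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  B <- S - Egamma
  diag(B) <- 0
  for (r in seq_len(n_restarts)) {
    membership <- local_move_aggregate(B)
    q <- resolution_quality(S, Egamma, membership)
    if (q > best_q) {
      best_q <- q
      best <- membership
    }
  }

  # merge undersized clusters into the neighbor with max connecting raw weight
  residual <- rep(FALSE, n)
  repeat {
    sizes <- table(best)
    small <- names(sizes)[sizes < min_cluster_size & !purrr::map_lgl(
      names(sizes), function(cl) any(residual[best == as.integer(cl)]))]
    if (length(small) == 0 || length(sizes) == 1) break
    cl <- as.integer(small[which.min(sizes[small])])
    idx <- which(best == cl)
    others <- setdiff(unique(best), cl)
    conn <- purrr::map_dbl(others, function(o) sum(C[idx, best == o, drop = FALSE]))
    if (all(conn == 0)) {
      residual[idx] <- TRUE
    } else {
      best[idx] <- others[which.max(conn)]
    }
  }
  best <- match(best, unique(best))
  new_partition(nodes, best, method = "resolution", residual = residual,
                quality = resolution_quality(S, Egamma, best))
}

#' Prune a network for reporting
#'
#' Keeps the top `max_nodes` nodes by node weight (ties broken
#' lexicographically by name), drops edges to removed nodes, then iteratively
#' removes nodes with fewer than `min_edges_per_node` remaining edges
#' (isolated nodes included).
#'
#' @param graph a weighted igraph.
#' @param max_nodes maximum nodes kept (default 30).
#' @param min_edges_per_node minimum degree (default 1).
#' @return the pruned igraph.
#' @export
prune_network <- function(graph, max_nodes = 30, min_edges_per_node = 1) {
  if (igraph::vcount(graph) == 0) return(graph)
  nm <- igraph::V(graph)$name
  w <- igraph::vertex_attr(graph, "weight")
  keep <- nm[order(-w, nm)][seq_len(min(max_nodes, length(nm)))]
  g <- igraph::induced_subgraph(graph, keep)
  repeat {
    low <- igraph::V(g)[igraph::degree(g) < min_edges_per_node]
    if (length(low) == 0) break
    g <- igraph::delete_vertices(g, low)
  }
  g
}

#' Tidy the edges of a weighted graph
#'
#' @param x an igraph.
#' @param ... unused.
#' @return tibble `from`, `to`, `weight` (plus `cooccurrence` when present).
#' @method tidy igraph
#' @export
tidy.igraph <- function(x, ...) {
  if (igraph::ecount(x) == 0) {
    return(tibble::tibble(from = character(0), to = character(0), weight = numeric(0)))
  }
  ends <- igraph::ends(x, igraph::E(x))
  out <- tibble::tibble(from = ends[, 1], to = ends[, 2],
                        weight = igraph::edge_attr(x, "weight"))
  co <- igraph::edge_attr(x, "cooccurrence")
  if (!is.null(co)) out$cooccurrence <- co
  out
}
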