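make_kw_corpus <- function(keyword_sets) {
  purrr::imap_dfr(keyword_sets, function(kw, i) {
    record_row(paste0("r", i), 2020, keywords = kw)
  })
}

test_that("collaboration network counts articles per country and pair", {
  corpus <- dplyr::bind_rows(
    record_row("a", 2020, authors = tibble::tibble(
      name = c("X", "Y"),
      affiliation = c("Dept, City, China", "Dept, City, USA"))),
    record_row("b", 2020, authors = tibble::tibble(
      name = "Z", affiliation = "Dept, City, China"))
  )
  g <- collaboration_network(corpus)
  w <- igraph::vertex_attr(g, "weight")
  names(w) <- igraph::V(g)$name
  expect_equal(w[["China"]], 2L)
  expect_equal(w[["United States"]], 1L)
  e <- tidy(g)
  expect_equal(nrow(e), 1)
  expect_equal(e$weight, 1)

  # no multi-country article -> edgeless graph
  g0 <- collaboration_network(corpus[2, ])
  expect_equal(igraph::ecount(g0), 0)
})

test_that("planted collaboration incidence yields exact edge weights", {
  set.seed(17)
  countries <- unique(country_alias_table())
  sets <- purrr::map(1:120, function(i) sample(countries, sample(1:4, 1)))
  corpus <- purrr::imap_dfr(sets, function(cc, i) {
    record_row(paste0("r", i), 2020, authors = tibble::tibble(
      name = paste0("A", seq_along(cc)),
      affiliation = paste0("Dept, City, ", cc)))
  })
  g <- collaboration_network(corpus)
  e <- tidy(g)
  # brute-force pair counting
  for (k in seq_len(nrow(e))) {
    expected <- sum(purrr::map_lgl(sets, function(s) {
      all(c(e$from[k], e$to[k]) %in% s)
    }))
    expect_equal(e$weight[k], expected)
  }
  expect_equal(sum(e$weight),
               sum(purrr::map_int(sets, function(s) choose(length(s), 2))))
})

test_that("keyword co-occurrence applies the threshold and both counting schemes", {
  sets <- c(replicate(5, c("proliferation", "metastasis", "invasion"),
                      simplify = FALSE),
            list(c("proliferation", "rare-term")))
  g_full <- cooccurrence_network(make_kw_corpus(sets), min_occurrence = 5,
                                 counting = "full")
  expect_setequal(igraph::V(g_full)$name,
                  c("proliferation", "metastasis", "invasion"))
  e <- tidy(g_full)
  expect_equal(nrow(e), 3)
  expect_true(all(e$weight == 5))

  g_frac <- cooccurrence_network(make_kw_corpus(sets), min_occurrence = 5,
                                 counting = "fractional")
  expect_true(all(tidy(g_frac)$weight == 5 / 2))  # 1/(k-1) with k = 3, 5 articles
})

test_that("fractional counting distributes exactly unit weight per keyword per article", {
  set.seed(23)
  vocab <- paste0("kw", 1:12)
  sets <- purrr::map(1:80, function(i) sample(vocab, sample(2:6, 1)))
  g <- cooccurrence_network(make_kw_corpus(sets), min_occurrence = 1,
                            counting = "fractional")
  e <- tidy(g)
  # per-article contribution of each keyword sums to 1, so each keyword's
  # total incident weight equals the number of multi-keyword articles it is in
  for (kw in vocab) {
    incident <- sum(e$weight[e$from == kw | e$to == kw])
    expected <- sum(purrr::map_lgl(sets, function(s) kw %in% s && length(s) > 1))
    expect_equal(incident, expected)
  }
})

test_that("threshold on a Zipf keyword corpus equals the brute-force filter", {
  gen <- generate_corpus(synth_config(n_records = 300, seed = 12))
  thes <- thesaurus(exclusion_set = "colorectal cancer")
  g <- cooccurrence_network(gen$corpus, thes, min_occurrence = 5)
  freq <- table(unlist(purrr::map(gen$corpus$author_keywords, function(k) {
    unique(normalize_keyword(k, thes) |> stats::na.omit())
  })))
  expect_setequal(igraph::V(g)$name, names(freq)[freq >= 5])
})

test_that("association strength follows the 2m c/(w w) formula", {
  g1 <- igraph::make_graph(c("x", "y"), directed = FALSE)
  igraph::V(g1)$weight <- 1
  igraph::E(g1)$weight <- 1
  g1 <- igraph::set_graph_attr(g1, "total_link_weight", 1)
  expect_equal(tidy(normalize_association(g1))$weight, 2)

  # uniform complete graph: all normalized weights equal
  g2 <- igraph::make_full_graph(4)
  igraph::V(g2)$name <- letters[1:4]
  igraph::V(g2)$weight <- 3
  igraph::E(g2)$weight <- 1
  g2 <- igraph::set_graph_attr(g2, "total_link_weight", 6)
  expect_equal(length(unique(tidy(normalize_association(g2))$weight)), 1)

  # random graph: recompute independently edge by edge
  pg <- planted_block_graph(2, 8, seed = 99)
  gn <- normalize_association(pg$graph)
  e <- tidy(gn)
  w <- stats::setNames(igraph::vertex_attr(gn, "weight"), igraph::V(gn)$name)
  m <- igraph::graph_attr(gn, "total_link_weight")
  expect_equal(e$weight, 2 * m * e$cooccurrence / (w[e$from] * w[e$to]),
               ignore_attr = TRUE)
  # support is preserved
  expect_true(all(e$weight > 0))
  expect_equal(igraph::ecount(gn), igraph::ecount(pg$graph))

  gz <- igraph::make_graph(c("x", "y"), directed = FALSE)
  igraph::V(gz)$weight <- c(0, 1)
  igraph::E(gz)$weight <- 1
  expect_error(normalize_association(gz), "zero node weight")
})

test_that("walktrap recovers planted blocks and degenerate structures", {
  pg <- planted_block_graph(3, 10, seed = 42)
  part <- walktrap_communities(pg$graph)
  expect_gte(ari(tidy(part)$cluster, pg$blocks), 0.9)
  # partition covers all nodes exactly once
  expect_equal(sort(tidy(part)$node), sort(igraph::V(pg$graph)$name))

  # two disjoint triangles -> exactly the two components
  tg <- igraph::make_graph(c("a","b","b","c","c","a","d","e","e","f","f","d"),
                           directed = FALSE)
  igraph::V(tg)$weight <- 2
  igraph::E(tg)$weight <- 1
  p2 <- walktrap_communities(tg)
  expect_equal(glance(p2)$n_clusters, 2)
  comp <- tidy(p2)
  expect_equal(length(unique(comp$cluster[comp$node %in% c("a","b","c")])), 1)

  # complete graph -> one community
  kg <- igraph::make_full_graph(6)
  igraph::V(kg)$name <- letters[1:6]
  igraph::V(kg)$weight <- 5
  igraph::E(kg)$weight <- 1
  expect_equal(glance(walktrap_communities(kg))$n_clusters, 1)
})

test_that("resolution clustering recovers planted blocks and obeys the merge rule", {
  pg <- planted_block_graph(2, 12, p_in = 0.8, p_out = 0.05, seed = 1)
  gn <- normalize_association(pg$graph)
  part <- resolution_clustering(gn, resolution = 0.5, min_cluster_size = 10, seed = 3)
  expect_gte(ari(tidy(part)$cluster, pg$blocks), 0.9)
  expect_equal(glance(part)$n_clusters, 2)

  # three blocks at resolution 1
  pg3 <- planted_block_graph(3, 10, seed = 42)
  gn3 <- normalize_association(pg3$graph)
  part3 <- resolution_clustering(gn3, resolution = 1, min_cluster_size = 5, seed = 3)
  expect_gte(ari(tidy(part3)$cluster, pg3$blocks), 0.9)

  # resolution 0 on a connected graph: a single cluster
  p0 <- resolution_clustering(gn, resolution = 0, min_cluster_size = 1, seed = 3)
  expect_equal(glance(p0)$n_clusters, 1)

  # min_cluster_size larger than any block: everything merged into one cluster
  pall <- resolution_clustering(gn, resolution = 0.5, min_cluster_size = 30, seed = 3)
  expect_equal(glance(pall)$n_clusters, 1)

  # seed-reproducible
  pa <- resolution_clustering(gn3, resolution = 1, min_cluster_size = 5, seed = 5)
  pb <- resolution_clustering(gn3, resolution = 1, min_cluster_size = 5, seed = 5)
  expect_identical(tidy(pa), tidy(pb))
})

test_that("pruning keeps top-weight nodes and removes low-degree nodes", {
  pg <- planted_block_graph(3, 12, seed = 7)   # 36 nodes
  pruned <- prune_network(pg$graph, max_nodes = 30)
  expect_lte(igraph::vcount(pruned), 30)
  expect_true(all(igraph::degree(pruned) >= 1))
  # the kept nodes are among the 30 heaviest
  nm <- igraph::V(pg$graph)$name
  w <- igraph::vertex_attr(pg$graph, "weight")
  top30 <- nm[order(-w, nm)][1:30]
  expect_true(all(igraph::V(pruned)$name %in% top30))

  # star pruned to 2 nodes: hub plus one leaf
  star <- igraph::make_star(5, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:4))
  igraph::V(star)$weight <- c(10, 4, 3, 2, 1)
  igraph::E(star)$weight <- 1
  ps <- prune_network(star, max_nodes = 2)
  expect_setequal(igraph::V(ps)$name, c("hub", "leaf1"))

  # already-compliant graph is unchanged
  ok <- planted_block_graph(1, 8, p_in = 0.9, seed = 3)$graph
  expect_equal(igraph::vcount(prune_network(ok, max_nodes = 30)),
               igraph::vcount(ok))
})
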