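# fixtures are built in code at test time

bundled_catalog <- function() {
  load_mirna_catalog(system.file(
    "extdata", paste0("synthetic_mirbase_aliases_r", 20:22, ".txt"),
    package = "mirbiblio"))
}

# minimal corpus row constructor
record_row <- function(id, year, title = "", abstract = "",
                       keywords = character(0),
                       authors = tibble::tibble(name = "Smith J.",
                                                affiliation = "Dept, City, China"),
                       corr = NA_character_, gcs = 0L,
                       refs = character(0), doc_type = "Article",
                       language = "English", doi = NA_character_) {
  tibble::tibble(
    record_id = id, title = title, abstract = abstract,
    author_keywords = list(keywords), authors = list(authors),
    correspondence_address = corr, year = as.integer(year),
    source_title = "Test Journal", global_citations = as.integer(gcs),
    references = list(refs), doc_type = doc_type, language = language,
    doi = doi, incomplete = FALSE
  )
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  s <- function(x) sum(choose(x, 2))
  si <- s(rowSums(tab)); sj <- s(colSums(tab)); sij <- s(as.vector(tab))
  n2 <- choose(sum(tab), 2)
  (sij - si * sj / n2) / ((si + sj) / 2 - si * sj / n2)
}

# seeded planted-block graph with weights, as produced by the network builders
planted_block_graph <- function(n_blocks, block_size, p_in = 0.8, p_out = 0.05,
                                seed = 42) {
  set.seed(seed)
  n <- n_blocks * block_size
  blocks <- rep(seq_len(n_blocks), each = block_size)
  from <- c(); to <- c()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      p <- if (blocks[i] == blocks[j]) p_in else p_out
      if (stats::runif(1) < p) { from <- c(from, i); to <- c(to, j) }
    }
  }
  g <- igraph::make_graph(rbind(as.character(from), as.character(to)),
                          directed = FALSE)
  igraph::V(g)$weight <- igraph::degree(g)
  igraph::E(g)$weight <- 1
  g <- igraph::set_graph_attr(g, "total_link_weight", igraph::ecount(g))
  list(graph = g, blocks = blocks[as.integer(igraph::V(g)$name)])
}

# the published top-10 global-citation table: total citations, year, and the
# printed per-year rate at reference year 2025
top_cited_table <- tibble::tibble(
  tc   = c(1669, 465, 445, 299, 271, 261, 206, 192, 186, 180),
  year = c(2008, 2020, 2017, 2011, 2008, 2014, 2017, 2016, 2009, 2013),
  tcy  = c(92.72, 77.5, 49.44, 19.93, 15.06, 21.75, 22.89, 19.2, 10.94, 13.85)
)
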