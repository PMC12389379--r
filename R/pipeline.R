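#' Run the full bibliometric pipeline
#'
#' Orchestrates every analysis stage over a screened corpus: annual production
#' and growth rate, the miRNA-by-year matrix and rankings, citation scores and
#' top-document tables by GCS and LCS, country appearance and SCP/MCP tables,
#' the pruned and clustered collaboration and keyword co-occurrence networks,
#' and the keyword frequency table. Every stage failure aborts with the stage
#' name; outputs are stamped with a configuration fingerprint and the seed.
#'
#' @param corpus a (screened) corpus tibble.
#' @param catalog a [load_mirna_catalog()] object.
#' @param thes optional [thesaurus()] for keyword normalization.
#' @param country_table alias map from [country_alias_table()].
#' @param ref_year reference year for TC/Y.
#' @param top_n rows kept in ranking tables (default 10).
#' @param min_occurrence keyword occurrence threshold (default 5).
#' @param match_threshold reference-matching title similarity (default 0.9).
#' @param resolution resolution parameter for keyword clustering (default
#'   0.5).
#' @param min_cluster_size minimum keyword cluster size (default 10).
#' @param max_nodes maximum nodes in pruned networks (default 30).
#' @param counting keyword co-occurrence counting scheme.
#' @param walk_length walktrap random-walk length (default 4).
#' @param seed seed for the resolution clustering restarts.
#' @param out_dir when non-`NULL`, tables are written there as TSV/JSON.
#' @return a `mirbiblio_report`: named list of result tables and graphs with
#'   the run configuration in the `config` element.
#' @export
run_report <- function(corpus, catalog, thes = NULL,
                       country_table = country_alias_table(),
                       ref_year = 2025, top_n = 10, min_occurrence = 5,
                       match_threshold = 0.9, resolution = 0.5,
                       min_cluster_size = 10, max_nodes = 30,
                       counting = c("fractional", "full"), walk_length = 4,
                       seed = 20240925, out_dir = NULL) {
  counting <- match.arg(counting)
  config <- list(ref_year = ref_year, top_n = top_n,
                 min_occurrence = min_occurrence,
                 match_threshold = match_threshold, resolution = resolution,
                 min_cluster_size = min_cluster_size, max_nodes = max_nodes,
                 counting = counting, walk_length = walk_length, seed = seed,
                 n_records = nrow(corpus))
  config$fingerprint <- config_fingerprint(config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  annual <- stage("annual_production", annual_production(corpus))
  growth <- stage("growth_rate", {
    nz <- annual[annual$NP > 0, ]
    if (nrow(nz) >= 2) cagr(annual, min(nz$year), max(nz$year)) else NULL
  })
  matrix <- stage("mirna_matrix", annual_mirna_matrix(corpus, catalog))
  ranking <- stage("mirna_ranking", rank_mirnas(matrix, top_n = top_n))
  scores <- stage("citation_scores", citation_scores(corpus, ref_year,
                                                     match_threshold))
  top_gcs <- stage("top_gcs", top_documents(scores, "GCS", top_n))
  top_lcs <- stage("top_lcs", top_documents(scores, "LCS", top_n))
  appearances <- stage("appearances", author_appearance_counts(corpus, country_table))
  scp_mcp <- stage("scp_mcp", scp_mcp_counts(corpus, country_table))
  collab <- stage("collaboration_network", {
    g <- collaboration_network(corpus, country_table)
    prune_network(normalize_association(g), max_nodes = max_nodes)
  })
  collab_clusters <- stage("collaboration_clusters", {
    if (igraph::vcount(collab) > 0) walktrap_communities(collab, walk_length) else NULL
  })
  kw_freq <- stage("keyword_frequencies", keyword_frequencies(corpus, thes, 100))
  kw_net <- stage("keyword_network", {
    g <- cooccurrence_network(corpus, thes, min_occurrence, counting)
    prune_network(normalize_association(g), max_nodes = max_nodes)
  })
  kw_clusters <- stage("keyword_clusters", {
    if (igraph::vcount(kw_net) > 0) {
      resolution_clustering(kw_net, resolution, min_cluster_size, seed = seed)
    } else NULL
  })

  report <- structure(
    list(config = config, summary = corpus_summary(corpus), annual = annual,
         growth = growth, mirna_matrix = matrix, mirna_ranking = ranking,
         citation_scores = scores, top_gcs = top_gcs, top_lcs = top_lcs,
         appearances = appearances, scp_mcp = scp_mcp,
         collaboration_network = collab,
         collaboration_clusters = collab_clusters,
         keyword_frequencies = kw_freq, keyword_network = kw_net,
         keyword_clusters = kw_clusters),
    class = "mirbiblio_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# order-independent fingerprint of the run configuration (polynomial rolling
# hash over the serialized key=value pairs)
config_fingerprint <- function(config) {
  config$fingerprint <- NULL
  txt <- paste(sort(paste0(names(config), "=",
                           purrr::map_chr(config, function(x) paste(format(x), collapse = ",")))),
               collapse = ";")
  h <- 5381
  for (b in utf8ToInt(txt)) h <- (h * 33 + b) %% 2^31
  sprintf("%08x", as.integer(h))
}

#' @export
print.mirbiblio_report <- function(x, ...) {
  cat("<mirbiblio_report> ", x$config$n_records, " records; config ",
      x$config$fingerprint, " (seed ", x$config$seed, ")\n", sep = "")
  cat("  tables:", paste(setdiff(names(x), "config"), collapse = ", "), "\n")
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- c(fingerprint = report$config$fingerprint,
             seed = report$config$seed)
  tsv <- function(x, name) {
    if (!is.null(x)) {
      readr::write_tsv(x, file.path(out_dir, paste0(name, ".tsv")))
    }
  }
  tsv(report$annual, "annual_production")
  tsv(report$growth, "growth_rate")
  tsv(mirna_matrix_table(report$mirna_matrix), "mirna_matrix")
  tsv(report$mirna_ranking, "mirna_ranking")
  tsv(report$citation_scores, "citation_scores")
  tsv(report$top_gcs, "top_documents_gcs")
  tsv(report$top_lcs, "top_documents_lcs")
  tsv(report$appearances, "country_appearances")
  tsv(report$scp_mcp, "country_scp_mcp")
  tsv(report$keyword_frequencies, "keyword_frequencies")
  for (nm in c("collaboration_clusters", "keyword_clusters")) {
    if (!is.null(report[[nm]])) tsv(tidy(report[[nm]]), nm)
  }
  for (nm in c("collaboration_network", "keyword_network")) {
    g <- report[[nm]]
    if (!is.null(g) && igraph::vcount(g) > 0) {
      nodes <- tibble::tibble(node = igraph::V(g)$name,
                              weight = igraph::vertex_attr(g, "weight"))
      jsonlite::write_json(list(stamp = as.list(stamp), nodes = nodes,
                                edges = tidy(g)),
                           file.path(out_dir, paste0(nm, ".json")),
                           auto_unbox = TRUE, digits = NA)
    }
  }
  jsonlite::write_json(c(as.list(report$config)),
                       file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
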