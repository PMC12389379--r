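# Default study-like shape: publication counts per year spanning a
# limited-activity phase (2008-2010), a growth phase (2011-2020) and a
# declining phase (2021-2024).
.default_year_counts <- c(
  "2008" = 2, "2009" = 1, "2010" = 0, "2011" = 5, "2012" = 7, "2013" = 10,
  "2014" = 21, "2015" = 31, "2016" = 44, "2017" = 62, "2018" = 96,
  "2019" = 87, "2020" = 125, "2021" = 115, "2022" = 89, "2023" = 71,
  "2024" = 62
)

# mixture heavily skewed toward one leading country
.default_country_mixture <- c(
  "China" = 0.857, "Iran" = 0.030, "Japan" = 0.025, "Italy" = 0.020,
  "United States" = 0.020, "Germany" = 0.015, "United Kingdom" = 0.010,
  "France" = 0.008, "Australia" = 0.008, "Canada" = 0.007
)

.default_mirna_pool <- c(
  "miR-21", "miR-34a", "miR-195-5p", "miR-181a-5p", "miR-200c", "miR-934",
  "miR-342", "miR-138-5p", "miR-196a", "miR-129", "miR-133b", "miR-19a",
  "miR-27a-3p", "miR-29b", "miR-135b", "miR-203", "miR-148a", "miR-363-3p",
  "miR-519d-3p", "miR-338-3p", "let-7a", "miR-17", "miR-155", "miR-143",
  "miR-145", "miR-106a", "miR-221", "miR-222", "miR-31", "miR-92a"
)

# keyword vocabulary with head weights proportional to word-cloud scale
# frequencies, split into two planted co-occurrence blocks (tumor progression
# vs therapy response)
.default_keyword_vocab <- tibble::tibble(
  keyword = c("proliferation", "metastasis", "invasion", "migration",
              "apoptosis", "epithelial-mesenchymal transition",
              "wnt/b-catenin", "cell cycle", "tp53", "pten",
              "chemoresistance", "oxaliplatin", "5-fluorouracil", "autophagy",
              "exosomes", "angiogenesis", "glycolysis", "ferroptosis",
              "cerna", "methylation"),
  weight = c(117, 79, 77, 64, 51, 27, 19, 12, 10, 10,
             45, 32, 28, 12, 27, 13, 11, 8, 8, 10),
  block = rep(c("progression", "therapy"), each = 10)
)

#' Configuration for the synthetic corpus generator
#'
#' The defaults emulate the statistical structure of a single-topic citation
#' corpus: yearly output in three growth phases, a country mixture dominated
#' by one country (85.7 percent), Zipf-distributed miRNA mentions with noisy
#' token variants, planted keyword co-occurrence blocks, backward-in-time
#' within-corpus citations, and occasionally missing correspondence addresses
#' (rate 41/828).
#'
#' @param n_records corpus size (default 828).
#' @param year_counts named integer vector of per-year publication counts used
#'   as apportionment weights (largest-remainder, so per-year counts are
#'   deterministic given `n_records`).
#' @param country_mixture named probability vector over countries (must sum to
#'   1).
#' @param collab_prob probability that a record has a co-author from a country
#'   other than the corresponding country (default 0.03).
#' @param missing_correspondence_rate share of records without a
#'   correspondence address (default 41/828).
#' @param mirna_pool canonical miRNA ids to plant; defaults to a 30-id pool
#'   covered by the bundled catalog.
#' @param mirna_zipf Zipf exponent for mention frequencies (default 1.1).
#' @param mention_noise list: `case_variant`, `spacing_variant` (rates of
#'   grammar-valid surface variants) and `invalid_rate` (rate of records
#'   carrying a catalog-invalid distractor id).
#' @param keyword_vocab tibble `keyword`, `weight`, `block`.
#' @param keywords_per_record range of planted keywords per record.
#' @param citation_density expected within-corpus references per record
#'   (default 2).
#' @param gcs_inflation Poisson mean of extra out-of-corpus citations added on
#'   top of the in-corpus in-degree, so GCS >= LCS by construction (default 3).
#' @param seed integer seed; fully determines the output.
#' @return a `synth_config` object.
#' @export
synth_config <- function(n_records = 828,
                         year_counts = .default_year_counts,
                         country_mixture = .default_country_mixture,
                         collab_prob = 0.03,
                         missing_correspondence_rate = 41 / 828,
                         mirna_pool = .default_mirna_pool,
                         mirna_zipf = 1.1,
                         mention_noise = list(case_variant = 0.2,
                                              spacing_variant = 0.1,
                                              invalid_rate = 0.1),
                         keyword_vocab = .default_keyword_vocab,
                         keywords_per_record = c(2, 5),
                         citation_density = 2,
                         gcs_inflation = 3,
                         seed = 20240925) {
  stopifnot(n_records >= 1,
            abs(sum(country_mixture) - 1) < 1e-8,
            all(country_mixture >= 0, country_mixture <= 1),
            missing_correspondence_rate >= 0, missing_correspondence_rate <= 1,
            collab_prob >= 0, collab_prob <= 1)
  if (citation_density > n_records / 10) {
    stop("infeasible config: citation_density ", citation_density,
         " is too high for ", n_records,
         " records (backward-in-time citations would be exhausted)",
         call. = FALSE)
  }
  structure(
    list(n_records = as.integer(n_records), year_counts = year_counts,
         country_mixture = country_mixture, collab_prob = collab_prob,
         missing_correspondence_rate = missing_correspondence_rate,
         mirna_pool = mirna_pool, mirna_zipf = mirna_zipf,
         mention_noise = mention_noise, keyword_vocab = keyword_vocab,
         keywords_per_record = keywords_per_record,
         citation_density = citation_density, gcs_inflation = gcs_inflation,
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

# largest-remainder apportionment of n among weights (deterministic)
apportion <- function(n, weights) {
  if (sum(weights) == 0) weights[] <- 1
  quota <- n * weights / sum(weights)
  base <- floor(quota)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(quota - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

render_mirna_token <- function(canonical, noise) {
  u <- stats::runif(length(canonical))
  out <- canonical
  case_hit <- u < noise$case_variant
  out[case_hit] <- toupper(canonical[case_hit])
  space_hit <- !case_hit & u < noise$case_variant + noise$spacing_variant &
    startsWith(canonical, "miR-")
  out[space_hit] <- sub("^miR-", "microRNA ", canonical[space_hit])
  out
}

#' Generate a seeded synthetic corpus with known ground truth
#'
#' Produces a Scopus-shaped corpus whose per-year counts, per-country author
#' appearances and corresponding countries, within-corpus citation graph,
#' per-record miRNA mentions and keyword incidences are all recorded as ground
#' truth, so every pipeline stage can be validated exactly. Titles and
#' abstracts embed the planted miRNA tokens (with grammar-valid case/spacing
#' variants and catalog-invalid distractors at the configured noise rates);
#' reference strings of citing records carry the DOI of the cited in-corpus
#' record. Global citation counts equal the in-corpus in-degree plus a Poisson
#' number of out-of-corpus citations, so GCS >= LCS holds by construction.
#'
#' @param config a [synth_config()].
#' @return list with elements `corpus` (a corpus tibble) and `truth` (list:
#'   `per_year`, `appearances`, `corresponding`, `citations`, `mentions`,
#'   `keywords`).
#' @export
generate_corpus <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)
  n <- config$n_records

  # years: deterministic apportionment, records ordered by year
  yrs <- as.integer(names(config$year_counts))
  per_year <- apportion(n, config$year_counts)
  year <- rep(yrs, per_year)

  doi <- sprintf("10.99999/synth.%05d", seq_len(n))
  record_id <- doi

  # countries
  countries <- names(config$country_mixture)
  record_country <- sample(countries, n, replace = TRUE,
                           prob = config$country_mixture)
  missing_corr <- stats::runif(n) < config$missing_correspondence_rate
  is_mcp <- stats::runif(n) < config$collab_prob
  foreign <- purrr::map_chr(record_country, function(cc) {
    if (length(countries) == 1) cc else sample(setdiff(countries, cc), 1)
  })

  n_auth <- sample(3:8, n, replace = TRUE)

  # miRNA mentions: Zipf-weighted pool draws
  pool <- config$mirna_pool
  zipf_w <- (seq_along(pool))^(-config$mirna_zipf)
  n_mirna <- pmin(1 + stats::rpois(n, 0.8), 3)
  mirnas <- purrr::map(n_mirna, function(k) {
    sample(pool, k, replace = FALSE, prob = zipf_w)
  })
  has_invalid <- stats::runif(n) < config$mention_noise$invalid_rate

  # keywords: block-structured draws
  vocab <- config$keyword_vocab
  blocks <- split(vocab, vocab$block)
  block_w <- purrr::map_dbl(blocks, function(b) sum(b$weight))
  kw_lo <- config$keywords_per_record[1]
  kw_hi <- config$keywords_per_record[2]
  keywords <- purrr::map(seq_len(n), function(i) {
    b <- sample(names(blocks), 1, prob = block_w)
    k <- sample(kw_lo:kw_hi, 1)
    main <- blocks[[b]]
    k_main <- min(k, nrow(main))
    kws <- sample(main$keyword, k_main, prob = main$weight)
    if (k > k_main || stats::runif(1) < 0.15) {
      other <- vocab[vocab$block != b, ]
      kws <- c(kws, sample(other$keyword, 1, prob = other$weight))
    }
    unique(kws)
  })

  # citations: backward in time, weighted toward recent predecessors
  cite_targets <- purrr::map(seq_len(n), function(i) {
    cand <- which(year < year[i])
    if (length(cand) == 0) return(integer(0))
    k <- min(stats::rpois(1, config$citation_density), length(cand))
    if (k == 0) return(integer(0))
    w <- 1 / (year[i] - year[cand])
    sort(sample(cand, k, prob = w))
  })
  in_degree <- tabulate(unlist(cite_targets), nbins = n)
  gcs <- in_degree + stats::rpois(n, config$gcs_inflation)

  journals <- c("Journal of Synthetic Oncology", "Synthetic Cancer Letters",
                "Annals of Simulated Biomarkers", "In Silico Tumor Biology",
                "Synthetic Molecular Medicine", "Journal of Generated Data")
  journal <- sample(journals, n, replace = TRUE)

  titles <- character(n)
  abstracts <- character(n)
  author_lists <- vector("list", n)
  corr_addr <- rep(NA_character_, n)
  references <- vector("list", n)
  kw_lists <- vector("list", n)

  for (i in seq_len(n)) {
    toks <- render_mirna_token(mirnas[[i]], config$mention_noise)
    titles[i] <- paste0("Synthetic study ", i, ": ", toks[1], " modulates ",
                        keywords[[i]][1], " in colorectal cancer")
    invalid_txt <- if (has_invalid[i]) {
      " A distractor identifier miR-99999 and the gene PDCD4 also appear."
    } else ""
    abstracts[i] <- paste0(
      "We report that ", paste(toks, collapse = " and "),
      " regulate ", paste(keywords[[i]], collapse = ", "),
      " in colorectal cancer models.", invalid_txt)

    surnames <- sprintf("Surname%05d%s", i, LETTERS[seq_len(n_auth[i])])
    auth_country <- rep(record_country[i], n_auth[i])
    if (is_mcp[i]) auth_country[n_auth[i]] <- foreign[i]
    affil <- sprintf("Department of Oncology, University %d, City %d, %s",
                     i, i, auth_country)
    author_lists[[i]] <- tibble::tibble(
      name = paste0(surnames, " A."), affiliation = affil)
    if (!missing_corr[i]) {
      corr_addr[i] <- sprintf("%s A.; Department of Oncology, University %d, City %d, %s",
                              surnames[1], i, i, record_country[i])
    }
    kw_lists[[i]] <- c(keywords[[i]], "colorectal cancer", mirnas[[i]][1])

    out_refs <- sprintf("External%04d B., Unrelated work %d, Outside Journal, %d",
                        i, seq_len(2), pmax(1990, year[i] - 10))
    in_refs <- purrr::map_chr(cite_targets[[i]], function(j) {
      sprintf("Surname%05dA A., Synthetic study %d, %s, %d, doi:%s",
              j, j, journal[j], year[j], doi[j])
    })
    references[[i]] <- c(in_refs, out_refs)
  }

  corpus <- tibble::tibble(
    record_id = record_id,
    title = titles,
    abstract = abstracts,
    author_keywords = kw_lists,
    authors = author_lists,
    correspondence_address = corr_addr,
    year = year,
    source_title = journal,
    global_citations = as.integer(gcs),
    references = references,
    doc_type = "Article",
    language = "English",
    doi = doi,
    incomplete = FALSE
  )
  attr(corpus, "provenance") <- paste0("generate_corpus:seed=", config$seed)

  truth <- list(
    per_year = tibble::tibble(year = yrs, NP = per_year),
    appearances = tibble::tibble(
      country = unlist(purrr::map(seq_len(n), function(i) {
        c(rep(record_country[i], n_auth[i] - is_mcp[i]),
          if (is_mcp[i]) foreign[i])
      }))) |>
      dplyr::count(.data$country, name = "appearances") |>
      dplyr::arrange(dplyr::desc(.data$appearances), .data$country),
    corresponding = tibble::tibble(
      record_id = record_id,
      country = ifelse(missing_corr, NA_character_, record_country),
      mcp = is_mcp
    ),
    citations = tibble::tibble(
      citing = rep(record_id, purrr::map_int(cite_targets, length)),
      cited = record_id[unlist(cite_targets)]
    ),
    mentions = tibble::tibble(
      record_id = rep(record_id, purrr::map_int(mirnas, length)),
      mirna = unlist(mirnas),
      year = rep(year, purrr::map_int(mirnas, length))
    ),
    keywords = tibble::tibble(
      record_id = rep(record_id, purrr::map_int(keywords, length)),
      keyword = unlist(keywords)
    )
  )
  list(corpus = corpus, truth = truth)
}
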