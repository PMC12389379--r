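#' Annual publication and citation statistics
#'
#' One row per year across the full corpus span (zero years included): `NP`
#' (publications), `pct` (share of total publications, 1 decimal), `TC` (total
#' citations accrued by that year's documents) and `TC_per_NP` (`NA` when
#' `NP = 0`).
#'
#' @param corpus a corpus tibble.
#' @return tibble `year`, `NP`, `pct`, `TC`, `TC_per_NP`.
#' @export
annual_production <- function(corpus) {
  dat <- corpus |> dplyr::filter(!is.na(.data$year))
  if (nrow(dat) == 0) {
    return(tibble::tibble(year = integer(0), NP = integer(0), pct = numeric(0),
                          TC = integer(0), TC_per_NP = numeric(0)))
  }
  total <- nrow(dat)
  dat |>
    dplyr::group_by(.data$year) |>
    dplyr::summarise(NP = dplyr::n(), TC = sum(.data$global_citations),
                     .groups = "drop") |>
    tidyr::complete(year = tidyr::full_seq(.data$year, 1),
                    fill = list(NP = 0L, TC = 0L)) |>
    dplyr::mutate(
      pct = round_half_up(100 * .data$NP / total, 1),
      TC_per_NP = ifelse(.data$NP > 0, .data$TC / .data$NP, NA_real_)
    ) |>
    dplyr::select("year", "NP", "pct", "TC", "TC_per_NP")
}

#' Annualized geometric growth rate of publications
#'
#' Compound annual growth rate between the endpoint years:
#' `((NP_last / NP_first)^(1 / (last_year - first_year)) - 1) * 100`.
#' Intermediate years (including zero years) do not enter the formula.
#'
#' @param np_by_year tibble with columns `year` and `NP` (e.g. from
#'   [annual_production()]).
#' @param first_year,last_year endpoint years; default the range of
#'   `np_by_year`.
#' @return one-row tibble `first_year`, `last_year`, `NP_first`, `NP_last`,
#'   `rate_pct`.
#' @export
#' @examples
#' cagr(tibble::tibble(year = c(2008, 2024), NP = c(2, 62)))
cagr <- function(np_by_year, first_year = NULL, last_year = NULL) {
  first_year <- first_year %||% min(np_by_year$year)
  last_year <- last_year %||% max(np_by_year$year)
  stopifnot(last_year > first_year)
  np_first <- np_by_year$NP[match(first_year, np_by_year$year)]
  np_last <- np_by_year$NP[match(last_year, np_by_year$year)]
  if (is.na(np_first) || np_first == 0) {
    stop("growth rate undefined: no publications in the first year", call. = FALSE)
  }
  tibble::tibble(
    first_year = first_year, last_year = last_year,
    NP_first = np_first, NP_last = np_last,
    rate_pct = ((np_last / np_first)^(1 / (last_year - first_year)) - 1) * 100
  )
}

#' Average citations per year (TC/Y)
#'
#' Citation-years are counted inclusively: a document published in the
#' reference year has one citation year, so `TC / (ref_year - pub_year + 1)`.
#'
#' @param tc total citations (vectorized).
#' @param pub_year publication year.
#' @param ref_year reference (analysis) year; must be `>= pub_year`.
#' @return numeric vector of citation rates.
#' @export
#' @examples
#' tc_per_year(1669, 2008, 2025)  # 92.72...
tc_per_year <- function(tc, pub_year, ref_year) {
  stopifnot(all(ref_year >= pub_year))
  tc / (ref_year - pub_year + 1)
}

# one reference string -> matched record_id or NA.
# DOI substring match takes precedence; otherwise first-author surname + year
# must agree and normalized-title similarity must reach the threshold.
match_reference <- function(ref, index, threshold) {
  doi <- stringr::str_extract(tolower(ref), "10\\.[0-9]{4,9}/[^\\s;,]+")
  if (!is.na(doi)) {
    doi <- sub("[.)\\]]+$", "", doi)
    hit <- match(doi, index$doi)
    return(if (is.na(hit)) NA_character_ else index$record_id[hit])
  }
  year <- suppressWarnings(as.integer(stringr::str_extract(ref, "\\b(19|20)[0-9]{2}\\b")))
  if (is.na(year)) return(NA_character_)
  surname <- tolower(stringr::str_extract(ref, "^[^,(]+"))
  surname <- trimws(sub("\\s+[A-Za-z].{0,3}$", "", surname))
  if (is.na(surname) || !nzchar(surname)) return(NA_character_)
  cand <- which(index$year == year & index$surname == sub("\\s.*$", "", surname))
  if (length(cand) == 0) return(NA_character_)
  ref_norm <- normalize_title(ref)
  sims <- purrr::map_dbl(cand, function(i) {
    tt <- index$norm_title[i]
    if (!nzchar(tt)) return(0)
    # similarity of the candidate title against its best-matching window of
    # the free-text reference string
    d <- utils::adist(tt, ref_norm, partial = TRUE)[1, 1]
    1 - d / nchar(tt)
  })
  if (max(sims) >= threshold) index$record_id[cand[which.max(sims)]] else NA_character_
}

#' Local citation scores (LCS)
#'
#' The local citation score of a document is the number of other corpus
#' records whose reference lists cite it. A reference matches a record by DOI
#' substring when the reference contains a DOI, otherwise by first-author
#' surname and year agreement plus normalized-title similarity at or above
#' `match_threshold`. Self-citations of a record to itself are excluded;
#' references citing out-of-corpus work are silently ignored.
#'
#' @param corpus a corpus tibble carrying `references`.
#' @param match_threshold title-similarity threshold in `[0, 1]` (default
#'   0.90).
#' @return tibble `record_id`, `LCS`.
#' @export
local_citation_scores <- function(corpus, match_threshold = 0.9) {
  index <- tibble::tibble(
    record_id = corpus$record_id,
    doi = corpus$doi,
    year = corpus$year,
    surname = tolower(sub("[ ,].*$", "", purrr::map_chr(corpus$authors, function(a) {
      if (nrow(a) > 0 && nzchar(a$name[1])) a$name[1] else ""
    }))),
    norm_title = normalize_title(corpus$title)
  )
  lcs <- stats::setNames(integer(nrow(corpus)), corpus$record_id)
  for (i in seq_len(nrow(corpus))) {
    refs <- corpus$references[[i]]
    if (length(refs) == 0) next
    cited <- unique(purrr::map_chr(refs, match_reference, index = index,
                                   threshold = match_threshold))
    cited <- setdiff(cited[!is.na(cited)], corpus$record_id[i])
    lcs[cited] <- lcs[cited] + 1L
  }
  tibble::tibble(record_id = corpus$record_id, LCS = unname(lcs))
}

#' Per-document citation scores
#'
#' Combines the global citation score (GCS, the database "Cited by" count),
#' the local citation score (LCS, citations from within the corpus) and the
#' per-year citation rate TC/Y.
#'
#' @inheritParams local_citation_scores
#' @param ref_year reference year for TC/Y (inclusive citation-years).
#' @return tibble `record_id`, `year`, `GCS`, `LCS`, `tc_per_year`.
#' @export
citation_scores <- function(corpus, ref_year, match_threshold = 0.9) {
  lcs <- local_citation_scores(corpus, match_threshold)
  tibble::tibble(
    record_id = corpus$record_id,
    year = corpus$year,
    GCS = corpus$global_citations,
    LCS = lcs$LCS,
    tc_per_year = ifelse(is.na(corpus$year), NA_real_,
                         tc_per_year(corpus$global_citations,
                                     ifelse(is.na(corpus$year), ref_year, corpus$year),
                                     ref_year))
  )
}

#' Top documents by a citation score
#'
#' @param scores a [citation_scores()] tibble (or any tibble with the key
#'   column plus `year` and `record_id`).
#' @param key ranking key.
#' @param n rows to keep; larger than the corpus returns everything.
#' @return `scores` sorted descending by `key`, ties broken by earlier year
#'   then `record_id`, truncated to `n` rows.
#' @export
top_documents <- function(scores, key = c("GCS", "LCS", "tc_per_year"), n = 10) {
  key <- match.arg(key)
  scores |>
    dplyr::arrange(dplyr::desc(.data[[key]]), .data$year, .data$record_id) |>
    utils::head(n)
}
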