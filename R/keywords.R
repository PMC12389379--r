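#' Build a keyword thesaurus with exclusions
#'
#' The synonym map is one-step (preferred terms never map onward); exclusion
#' is checked after normalization, so query terms and their synonyms are
#' removed regardless of spelling.
#'
#' @param synonym_map named character vector, variant -> preferred term (both
#'   sides compared in normalized form).
#' @param exclusion_set character vector of terms removed before counting.
#' @return a `thesaurus` object.
#' @export
thesaurus <- function(synonym_map = character(0), exclusion_set = character(0)) {
  names(synonym_map) <- normalize_keyword_text(names(synonym_map) %||% character(0))
  synonym_map[] <- normalize_keyword_text(synonym_map)
  chained <- intersect(unname(synonym_map), names(synonym_map))
  chained <- chained[synonym_map[chained] != chained]
  if (length(chained) > 0) {
    stop("thesaurus is not one-step: preferred term(s) map onward: ",
         paste(chained, collapse = ", "), call. = FALSE)
  }
  structure(list(synonym_map = synonym_map,
                 exclusion_set = normalize_keyword_text(exclusion_set)),
            class = "thesaurus")
}

#' Read a thesaurus from a two-column TSV plus an exclusion list
#'
#' @param synonyms_path TSV with columns `variant`, `preferred`; `NULL` for
#'   none.
#' @param exclusions_path plain-text file, one excluded term per line; `NULL`
#'   for none.
#' @return a [thesaurus()] object.
#' @export
read_thesaurus <- function(synonyms_path = NULL, exclusions_path = NULL) {
  map <- character(0)
  if (!is.null(synonyms_path)) {
    tab <- readr::read_tsv(synonyms_path, col_types = "cc", progress = FALSE)
    map <- stats::setNames(tab$preferred, tab$variant)
  }
  excl <- if (!is.null(exclusions_path)) {
    x <- readr::read_lines(exclusions_path)
    x[nzchar(trimws(x))]
  } else character(0)
  thesaurus(map, excl)
}

# lowercase, trim, collapse whitespace, fold unicode dash variants to hyphen
normalize_keyword_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[‐‑‒–—―]", "-", x)
  trimws(gsub("\\s+", " ", x))
}

#' Normalize a raw keyword through the thesaurus
#'
#' Lowercases, trims, collapses internal whitespace, folds dash variants to a
#' plain hyphen, maps through the synonym map, then tests the exclusion set.
#' Idempotent: normalizing an already-normalized term is a no-op.
#'
#' @param raw character vector of raw keywords.
#' @param thes a [thesaurus()] or `NULL` (no mapping, no exclusion).
#' @return character vector of preferred terms, `NA` where excluded.
#' @export
normalize_keyword <- function(raw, thes = NULL) {
  term <- normalize_keyword_text(raw)
  if (!is.null(thes)) {
    stopifnot(inherits(thes, "thesaurus"))
    hit <- match(term, names(thes$synonym_map))
    term[!is.na(hit)] <- thes$synonym_map[hit[!is.na(hit)]]
    term[term %in% thes$exclusion_set] <- NA_character_
  }
  term[!is.na(term) & !nzchar(term)] <- NA_character_
  term
}

#' Author-keyword frequency table
#'
#' Article-level counting: a keyword counts once per article however often it
#' repeats in the record's keyword list. Descending frequency, ties broken
#' lexicographically, truncated to the top `top_n` terms (the word-cloud
#' data).
#'
#' @param corpus a corpus tibble.
#' @param thes a [thesaurus()] or `NULL`.
#' @param top_n rows to keep (default 100).
#' @return tibble `keyword`, `n`.
#' @export
keyword_frequencies <- function(corpus, thes = NULL, top_n = 100) {
  kw <- unlist(purrr::map(corpus$author_keywords, function(k) {
    k <- normalize_keyword(k, thes)
    unique(k[!is.na(k)])
  }))
  if (length(kw) == 0) return(tibble::tibble(keyword = character(0), n = integer(0)))
  tibble::tibble(keyword = kw) |>
    dplyr::count(.data$keyword) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$keyword) |>
    utils::head(top_n)
}
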