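#' Load a country alias table
#'
#' Two-column TSV (`alias`, `country`) resolving affiliation-string country
#' spellings to canonical names (e.g. "PR China" -> "China", "USA" ->
#' "United States"). Canonical names resolve to themselves. The bundled table
#' ships with the package and is editable.
#'
#' @param path TSV path; default the bundled table.
#' @return named character vector, lowercased alias -> canonical country.
#' @export
country_alias_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "country_aliases.tsv", package = "mirbiblio")
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE)
  map <- stats::setNames(tab$country, tolower(tab$alias))
  # canonical names always self-resolve
  self <- stats::setNames(unique(tab$country), tolower(unique(tab$country)))
  c(map, self[!names(self) %in% names(map)])
}

#' Resolve the country of an affiliation string
#'
#' The candidate is the last comma-separated token of the affiliation, trimmed
#' of whitespace and trailing punctuation, resolved case-insensitively through
#' the alias table. Unresolved affiliations return `NA`, never a guess.
#'
#' @param affiliation character vector of affiliation strings.
#' @param country_table alias map from [country_alias_table()].
#' @return character vector of canonical country names (`NA` if unresolved).
#' @export
#' @examples
#' tab <- c(italy = "Italy", "pr china" = "China")
#' parse_affiliation_country("Institute of Gastroenterology, Bari, Italy", tab)
parse_affiliation_country <- function(affiliation, country_table) {
  cand <- purrr::map_chr(affiliation, function(a) {
    if (is.na(a) || !nzchar(a)) return(NA_character_)
    parts <- strsplit(a, ",", fixed = TRUE)[[1]]
    tolower(trimws(gsub("[.;]+$", "", parts[length(parts)])))
  })
  unname(country_table[cand])
}

#' Country appearance counts across all co-authors
#'
#' Attributes each article to all co-authors' countries: every
#' (author, affiliation) pair whose country resolves contributes one
#' appearance (an author with affiliations in two countries contributes one
#' appearance per affiliation).
#'
#' @param corpus a corpus tibble.
#' @param country_table alias map from [country_alias_table()].
#' @return tibble `country`, `appearances`, `share` (percent of all resolved
#'   appearances, 2 decimals), descending by appearances.
#' @export
author_appearance_counts <- function(corpus, country_table = country_alias_table()) {
  countries <- unlist(purrr::map(corpus$authors, function(a) {
    parse_affiliation_country(a$affiliation, country_table)
  }))
  countries <- countries[!is.na(countries)]
  tibble::tibble(country = countries) |>
    dplyr::count(.data$country, name = "appearances") |>
    dplyr::mutate(share = round_half_up(100 * .data$appearances / sum(.data$appearances), 2)) |>
    dplyr::arrange(dplyr::desc(.data$appearances), .data$country)
}

#' Corresponding-author country per record
#'
#' Parsed from the correspondence address only; records with a missing or
#' unresolved address get `NA` (there is no fallback to the first author) and
#' are excluded from SCP/MCP accounting, with the reason reported.
#'
#' @inheritParams author_appearance_counts
#' @return tibble `record_id`, `country`, `reason` (`"ok"`,
#'   `"missing_address"` or `"unresolved_country"`).
#' @export
corresponding_country <- function(corpus, country_table = country_alias_table()) {
  country <- parse_affiliation_country(corpus$correspondence_address, country_table)
  tibble::tibble(
    record_id = corpus$record_id,
    country = country,
    reason = dplyr::case_when(
      is.na(corpus$correspondence_address) ~ "missing_address",
      is.na(country) ~ "unresolved_country",
      TRUE ~ "ok"
    )
  )
}

#' Single- and multiple-country publication counts per country
#'
#' Each record with a resolved corresponding country is attributed to that
#' country only: it counts as a multiple-country publication (MCP) when at
#' least one co-author's resolved country differs from the corresponding
#' country, else as a single-country publication (SCP).
#'
#' @inheritParams author_appearance_counts
#' @param pct_digits decimal places for `MCP_pct` and `corr_share` (default 1).
#' @return tibble `country`, `corr_articles`, `corr_share` (percent of all
#'   corpus records), `SCP`, `MCP`, `MCP_pct` (percent of that country's
#'   corresponding articles), descending by `corr_articles`. Number of records
#'   excluded for missing/unresolved correspondence is attached as the
#'   `n_excluded` attribute.
#' @export
scp_mcp_counts <- function(corpus, country_table = country_alias_table(),
                           pct_digits = 1) {
  corr <- corresponding_country(corpus, country_table)
  per_record <- purrr::map2_dfr(seq_len(nrow(corpus)), corr$country, function(i, cc) {
    if (is.na(cc)) return(NULL)
    author_countries <- parse_affiliation_country(corpus$authors[[i]]$affiliation,
                                                  country_table)
    author_countries <- author_countries[!is.na(author_countries)]
    tibble::tibble(country = cc, mcp = any(author_countries != cc))
  })
  n_total <- nrow(corpus)
  out <- if (nrow(per_record) == 0) {
    tibble::tibble(country = character(0), corr_articles = integer(0),
                   corr_share = numeric(0), SCP = integer(0), MCP = integer(0),
                   MCP_pct = numeric(0))
  } else {
    per_record |>
      dplyr::group_by(.data$country) |>
      dplyr::summarise(corr_articles = dplyr::n(), MCP = sum(.data$mcp),
                       .groups = "drop") |>
      dplyr::mutate(
        SCP = .data$corr_articles - .data$MCP,
        corr_share = round_half_up(100 * .data$corr_articles / n_total, pct_digits),
        MCP_pct = round_half_up(100 * .data$MCP / .data$corr_articles, pct_digits)
      ) |>
      dplyr::select("country", "corr_articles", "corr_share", "SCP", "MCP", "MCP_pct") |>
      dplyr::arrange(dplyr::desc(.data$corr_articles), .data$country)
  }
  attr(out, "n_excluded") <- sum(corr$reason != "ok")
  out
}
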