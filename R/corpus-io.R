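#' Read a Scopus-style CSV export into a tidy corpus
#'
#' Parses a comma-delimited, double-quoted, UTF-8 (optionally BOM-prefixed)
#' bibliographic export of the kind Scopus produces. Each data row becomes one
#' record; missing optional columns become empty fields, never errors.
#'
#' Record identity is the lowercased DOI when present, otherwise a stable key
#' built from the first author's surname, the year and the normalized title.
#' Rows whose year cannot be parsed are kept and flagged `incomplete` so that
#' completeness statistics remain computable.
#'
#' @param path path to the CSV file.
#' @param dialect list of format options; supported: `affiliation_sep`
#'   (default `"; "`), `keyword_sep` (default `"; "`), `reference_sep`
#'   (default `"; "`).
#' @return A corpus: a tibble with one row per record and columns `record_id`,
#'   `title`, `abstract`, `author_keywords` (list of character),
#'   `authors` (list of tibbles with `name`, `affiliation` — one row per
#'   author-affiliation pair), `correspondence_address` (`NA` when absent),
#'   `year`, `source_title`, `global_citations`, `references` (list of
#'   character), `doc_type`, `language`, `doi`, `incomplete`. The source path
#'   is recorded in the `provenance` attribute.
#' @export
read_scopus_csv <- function(path, dialect = list()) {
  stopifnot(file.exists(path))
  sep_aff <- dialect$affiliation_sep %||% "; "
  sep_kw  <- dialect$keyword_sep %||% "; "
  sep_ref <- dialect$reference_sep %||% "; "

  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, show_col_types = FALSE)
  mandatory <- c("Title", "Year", "Cited by")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("Scopus export is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  col <- function(nm) if (nm %in% names(raw)) raw[[nm]] else rep(NA_character_, nrow(raw))

  year <- suppressWarnings(as.integer(col("Year")))
  gcs  <- suppressWarnings(as.integer(col("Cited by")))
  gcs[is.na(gcs)] <- 0L

  split_field <- function(x, sep) {
    purrr::map(x, function(s) {
      if (is.na(s) || !nzchar(trimws(s))) character(0)
      else trimws(strsplit(s, sep, fixed = TRUE)[[1]])
    })
  }

  author_names <- split_field(col("Authors"), "; ")
  with_aff     <- split_field(col("Authors with affiliations"), sep_aff)
  flat_aff     <- split_field(col("Affiliations"), sep_aff)

  authors <- purrr::pmap(list(author_names, with_aff, flat_aff), parse_authors)

  corr <- col("Correspondence Address")
  corr[!is.na(corr) & !nzchar(trimws(corr))] <- NA_character_

  doi <- tolower(trimws(col("DOI")))
  doi[!is.na(doi) & !nzchar(doi)] <- NA_character_

  first_author <- purrr::map_chr(author_names, function(a) if (length(a)) a[[1]] else NA_character_)
  rid <- ifelse(!is.na(doi), doi,
                fallback_record_id(first_author, year, col("Title")))
  rid <- make_ids_unique(rid)

  out <- tibble::tibble(
    record_id = rid,
    title = ifelse(is.na(col("Title")), "", col("Title")),
    abstract = ifelse(is.na(col("Abstract")), "", col("Abstract")),
    author_keywords = split_field(col("Author Keywords"), sep_kw),
    authors = authors,
    correspondence_address = corr,
    year = year,
    source_title = ifelse(is.na(col("Source title")), "", col("Source title")),
    global_citations = gcs,
    references = split_field(col("References"), sep_ref),
    doc_type = ifelse(is.na(col("Document Type")), "", col("Document Type")),
    language = ifelse(is.na(col("Language")), "", col("Language")),
    doi = doi,
    incomplete = is.na(year) | purrr::map_int(authors, nrow) == 0L
  )
  attr(out, "provenance") <- paste0("read_scopus_csv:", path)
  out
}

# "Surname A., Dept, City, Country" entries -> tibble(name, affiliation);
# falls back to bare author names (empty affiliation) or record-level
# affiliations attributed to no named author.
parse_authors <- function(names_vec, with_aff_vec, flat_aff_vec) {
  if (length(with_aff_vec) > 0) {
    name <- sub(",.*$", "", with_aff_vec)
    affiliation <- trimws(sub("^[^,]*,\\s*", "", with_aff_vec))
    affiliation[affiliation == with_aff_vec] <- ""
    return(tibble::tibble(name = trimws(name), affiliation = affiliation))
  }
  if (length(names_vec) > 0) {
    return(tibble::tibble(name = names_vec, affiliation = rep("", length(names_vec))))
  }
  if (length(flat_aff_vec) > 0) {
    return(tibble::tibble(name = rep("", length(flat_aff_vec)), affiliation = flat_aff_vec))
  }
  tibble::tibble(name = character(0), affiliation = character(0))
}

make_ids_unique <- function(ids) {
  dup <- duplicated(ids)
  if (any(dup)) {
    ids <- stats::ave(ids, ids, FUN = function(x) {
      if (length(x) == 1) x else paste0(x, c("", paste0("#", seq_len(length(x) - 1))))
    })
  }
  ids
}

#' Write a corpus back to a Scopus-style CSV
#'
#' Emits the column set accepted by [read_scopus_csv()], so write -> read is
#' an identity on the corpus fields.
#'
#' @param corpus a corpus tibble as returned by [read_scopus_csv()] or
#'   [generate_corpus()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_scopus_csv <- function(corpus, path) {
  join <- function(lst) purrr::map_chr(lst, paste, collapse = "; ")
  out <- tibble::tibble(
    "Authors" = purrr::map_chr(corpus$authors, function(a) {
      paste(unique(a$name[nzchar(a$name)]), collapse = "; ")
    }),
    "Authors with affiliations" = purrr::map_chr(corpus$authors, function(a) {
      keep <- nzchar(a$affiliation)
      paste(ifelse(keep, paste(a$name, a$affiliation, sep = ", "), a$name),
            collapse = "; ")
    }),
    "Title" = corpus$title,
    "Year" = corpus$year,
    "Source title" = corpus$source_title,
    "Cited by" = corpus$global_citations,
    "DOI" = ifelse(is.na(corpus$doi), "", corpus$doi),
    "Author Keywords" = join(corpus$author_keywords),
    "Abstract" = corpus$abstract,
    "Affiliations" = purrr::map_chr(corpus$authors, function(a) {
      paste(unique(a$affiliation[nzchar(a$affiliation)]), collapse = "; ")
    }),
    "Correspondence Address" = ifelse(is.na(corpus$correspondence_address), "",
                                      corpus$correspondence_address),
    "References" = join(corpus$references),
    "Document Type" = corpus$doc_type,
    "Language" = corpus$language
  )
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Build a screening list
#'
#' The manual relevance screen is consumed as an explicit keep list (record
#' ids / DOIs), never re-derived; automatic rule flags additionally restrict
#' by document type and language.
#'
#' @param keep_ids character vector of record ids (or DOIs) to keep; `NULL`
#'   keeps everything not removed by rule flags.
#' @param exclude_doc_types document types to drop (e.g. `c("Review")`).
#' @param keep_language when non-`NULL`, only records in this language pass.
#' @return a `screening_list` object.
#' @export
screening_list <- function(keep_ids = NULL, exclude_doc_types = character(),
                           keep_language = NULL) {
  structure(list(keep_ids = keep_ids, exclude_doc_types = exclude_doc_types,
                 keep_language = keep_language),
            class = "screening_list")
}

#' Apply a relevance screen to a corpus
#'
#' Keeps exactly the records whose id is in the keep list and which pass the
#' rule flags. Order-preserving and deterministic. The per-reason removal
#' counts are attached as the `removal_report` attribute (also retrievable
#' with [screening_report()]).
#'
#' @param corpus a corpus tibble.
#' @param screen a [screening_list()].
#' @return the screened corpus tibble.
#' @export
apply_screening <- function(corpus, screen) {
  stopifnot(inherits(screen, "screening_list"))
  reason <- rep(NA_character_, nrow(corpus))
  if (!is.null(screen$keep_ids)) {
    unknown <- setdiff(screen$keep_ids, corpus$record_id)
    if (length(unknown) > 0) {
      warning(length(unknown), " keep-list id(s) not present in the corpus",
              call. = FALSE)
    }
    reason[!(corpus$record_id %in% screen$keep_ids)] <- "not_in_keep_list"
  }
  if (length(screen$exclude_doc_types) > 0) {
    hit <- is.na(reason) & corpus$doc_type %in% screen$exclude_doc_types
    reason[hit] <- "doc_type"
  }
  if (!is.null(screen$keep_language)) {
    hit <- is.na(reason) & corpus$language != screen$keep_language
    reason[hit] <- "language"
  }
  out <- corpus[is.na(reason), , drop = FALSE]
  if (nrow(out) == 0) warning("screening removed every record", call. = FALSE)
  report <- tibble::tibble(reason = reason[!is.na(reason)]) |>
    dplyr::count(.data$reason, name = "n_removed")
  attr(out, "provenance") <- paste0(attr(corpus, "provenance") %||% "",
                                    " | screened")
  attr(out, "removal_report") <- report
  out
}

#' Retrieve the removal report of a screened corpus
#'
#' @param corpus a corpus returned by [apply_screening()].
#' @return tibble with columns `reason`, `n_removed`.
#' @export
screening_report <- function(corpus) {
  attr(corpus, "removal_report") %||%
    tibble::tibble(reason = character(0), n_removed = integer(0))
}

#' Summarize corpus completeness
#'
#' @param corpus a corpus tibble.
#' @param digits decimal places for the completeness percentages.
#' @return one-row tibble: `n_records`, `pct_abstract`, `pct_correspondence`,
#'   `pct_references`, `missing_correspondence` (integer-precision label such
#'   as `"5%"`), and a `per_year` list-column holding the records-per-year
#'   tibble.
#' @export
corpus_summary <- function(corpus, digits = 1) {
  n <- nrow(corpus)
  pct <- function(k) if (n == 0) 0 else round_half_up(100 * k / n, digits)
  per_year <- if (n == 0) {
    tibble::tibble(year = integer(0), n = integer(0))
  } else {
    corpus |>
      dplyr::filter(!is.na(.data$year)) |>
      dplyr::count(.data$year)
  }
  n_missing_corr <- sum(is.na(corpus$correspondence_address))
  tibble::tibble(
    n_records = n,
    pct_abstract = pct(sum(nzchar(corpus$abstract))),
    pct_correspondence = pct(n - n_missing_corr),
    pct_references = pct(sum(purrr::map_int(corpus$references, length) > 0)),
    missing_correspondence = if (n == 0) "0%" else format_percent(n_missing_corr, n, 0),
    per_year = list(per_year)
  )
}
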