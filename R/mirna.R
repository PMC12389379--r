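# miRNA token grammar, case-insensitive:
#   optional species prefix ([a-z]{3}-), stem miR/mir/miRNA/microRNA/MIR with
#   optional hyphen-or-space separator, number, optional letter suffix,
#   optional paralog "-N", optional arm "-5p"/"-3p"; plus the let-7 family
#   (let-7 + optional letter + optional paralog + optional arm).
# The (?!p) lookahead keeps the greedy paralog group from swallowing the
# leading digit of an arm suffix ("miR-21-5p" must not parse paralog "-5").
.mirna_pattern <- paste0(
  "(?i)(?<![a-z0-9])",
  "(?:[a-z]{3}-)?",
  "(?:",
  "(?:micro-?rna|mirna|mir)[- ]?[0-9]+[a-z]?(?:-[0-9]+(?!p))?(?:-[35]p)?",
  "|",
  "let-7[a-z]?(?:-[0-9]+(?!p))?(?:-[35]p)?",
  ")",
  "(?![a-z0-9])"
)

.mirna_parse_pattern <- paste0(
  "^(?:([a-z]{3})-)?",
  "(?:(?:micro-?rna|mirna|mir)[- ]?([0-9]+)([a-z]?)(-[0-9]+)?(-[35]p)?",
  "|(let)-7([a-z]?)(-[0-9]+)?(-[35]p)?)$"
)

#' Extract raw miRNA tokens from free text
#'
#' Scans text for mentions matching the miRNA nomenclature grammar (species
#' prefix, miR/let-7 stem variants, number, letter suffix, paralog, arm).
#' Matching is case-insensitive; spans are non-overlapping, leftmost-longest.
#'
#' @param text a single character string (empty allowed).
#' @return tibble with columns `token`, `start`, `end` (1-based, inclusive).
#' @export
#' @examples
#' extract_mirna_tokens("MicroRNA-21 (miR-21) downregulates Pdcd4")
extract_mirna_tokens <- function(text) {
  if (length(text) != 1 || is.na(text) || !nzchar(text)) {
    return(tibble::tibble(token = character(0), start = integer(0), end = integer(0)))
  }
  m <- gregexpr(.mirna_pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(tibble::tibble(token = character(0), start = integer(0), end = integer(0)))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  tibble::tibble(
    token = substring(text, start, start + len - 1L),
    start = start,
    end = start + len - 1L
  )
}

#' Canonicalize a raw miRNA token
#'
#' Strips any species prefix, folds the stem variants (mir, miRNA, microRNA,
#' MIR, with hyphen or space separator) to `miR`, lowercases the letter
#' suffix, and preserves paralog and arm suffixes. let-7 family members fold
#' to `let-7` form.
#'
#' @param raw character vector of tokens that match the extraction grammar.
#' @return character vector of canonical ids, e.g. `"MIR-34A"` -> `"miR-34a"`,
#'   `"hsa-miR-195-5p"` -> `"miR-195-5p"`, `"microRNA 21"` -> `"miR-21"`.
#' @export
canonicalize_mirna <- function(raw) {
  purrr::map_chr(raw, function(tok) {
    m <- regmatches(tolower(tok), regexec(.mirna_parse_pattern, tolower(tok), perl = TRUE))[[1]]
    if (length(m) == 0) {
      stop("not a miRNA token (grammar mismatch): ", tok, call. = FALSE)
    }
    if (m[7] == "let") {
      paste0("let-7", m[8], m[9], m[10])
    } else {
      paste0("miR-", m[3], m[4], m[5], m[6])
    }
  })
}

#' Load a multi-release miRNA nomenclature catalog
#'
#' Reads one or more alias tables in the miRBase `aliases.txt` format
#' (accession TAB semicolon-separated names, the last name being current).
#' Releases are unioned: a name valid in any release validates. For renamed
#' entries, every non-current name maps to the current name in the alias map.
#'
#' @param paths character vector of alias-table files, one per release.
#' @param releases optional labels, default basenames of `paths`.
#' @return a `mirna_catalog` object: list with `releases` (tibble of label and
#'   name count), `names` (lowercased union of valid names), `alias_map`
#'   (named character, lowercased alias -> current name).
#' @export
load_mirna_catalog <- function(paths, releases = basename(paths)) {
  stopifnot(length(paths) == length(releases), all(file.exists(paths)))
  per_release <- purrr::map2(paths, releases, function(p, lab) {
    lines <- readr::read_lines(p)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(purrr::map_int(parts, length) < 2)
    if (length(bad) > 0) {
      warning("skipping ", length(bad), " malformed line(s) in ", lab,
              " (lines ", paste(utils::head(bad, 5), collapse = ", "), ")",
              call. = FALSE)
      parts <- parts[-bad]
    }
    acc <- purrr::map_chr(parts, 1)
    names_per_acc <- purrr::map(parts, function(x) {
      nm <- strsplit(x[[2]], ";", fixed = TRUE)[[1]]
      tolower(trimws(nm[nzchar(trimws(nm))]))
    })
    list(label = lab, accessions = acc, names_per_acc = names_per_acc)
  })

  all_names <- unique(unlist(purrr::map(per_release, function(r) unlist(r$names_per_acc))))

  # alias map: for each accession, prefer the newest release's current name
  alias_map <- character(0)
  for (r in per_release) {
    for (i in seq_along(r$accessions)) {
      nm <- r$names_per_acc[[i]]
      if (length(nm) >= 1) {
        current <- nm[length(nm)]
        old <- setdiff(nm, current)
        if (length(old) > 0) alias_map[old] <- current
      }
    }
  }

  structure(
    list(
      releases = tibble::tibble(
        release = purrr::map_chr(per_release, "label"),
        n_names = purrr::map_int(per_release, function(r) length(unique(unlist(r$names_per_acc))))
      ),
      names = all_names,
      alias_map = alias_map
    ),
    class = "mirna_catalog"
  )
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat("<mirna_catalog> ", length(x$names), " names across ",
      nrow(x$releases), " release(s); ", length(x$alias_map), " aliases\n", sep = "")
  print(x$releases)
  invisible(x)
}

#' Validate a canonical miRNA id against the catalog
#'
#' A canonical id validates when its species-prefixed form (tried with mature
#' and precursor casing, compared case-insensitively) appears in the release
#' union or resolves through the alias map.
#'
#' @param canonical_id character vector of canonical ids (see
#'   [canonicalize_mirna()]).
#' @param catalog a [load_mirna_catalog()] object.
#' @param species_prefix species code prepended before lookup (default
#'   `"hsa"`).
#' @return logical vector.
#' @export
validate_mirna <- function(canonical_id, catalog, species_prefix = "hsa") {
  stopifnot(inherits(catalog, "mirna_catalog"))
  probe <- tolower(paste0(species_prefix, "-", canonical_id))
  probe %in% catalog$names | probe %in% names(catalog$alias_map)
}

#' Extract, canonicalize and validate miRNA mentions across a corpus
#'
#' Runs the token grammar over title, author keywords and abstract of every
#' record.
#'
#' @param corpus a corpus tibble.
#' @param catalog a [load_mirna_catalog()] object.
#' @param species_prefix species code for validation (default `"hsa"`).
#' @param fields which record fields to scan.
#' @return tibble with columns `record_id`, `raw_token`, `canonical_id`,
#'   `field_of_origin`, `valid`.
#' @export
extract_mirna_mentions <- function(corpus, catalog, species_prefix = "hsa",
                                   fields = c("title", "keywords", "abstract")) {
  texts <- list(
    title = corpus$title,
    keywords = purrr::map_chr(corpus$author_keywords, paste, collapse = "; "),
    abstract = corpus$abstract
  )[fields]
  mentions <- purrr::map_dfr(names(texts), function(f) {
    purrr::map2_dfr(corpus$record_id, texts[[f]], function(id, txt) {
      tok <- extract_mirna_tokens(txt)
      if (nrow(tok) == 0) return(NULL)
      tibble::tibble(record_id = id, raw_token = tok$token, field_of_origin = f)
    })
  })
  if (nrow(mentions) == 0) {
    return(tibble::tibble(record_id = character(0), raw_token = character(0),
                          canonical_id = character(0), field_of_origin = character(0),
                          valid = logical(0)))
  }
  mentions$canonical_id <- canonicalize_mirna(mentions$raw_token)
  mentions$valid <- validate_mirna(mentions$canonical_id, catalog, species_prefix)
  mentions[, c("record_id", "raw_token", "canonical_id", "field_of_origin", "valid")]
}

#' Annual miRNA-by-year article counts
#'
#' Article-level counting: a record contributes at most 1 to a
#' (miRNA, year) cell no matter how many fields or repeated tokens mention the
#' miRNA. Only catalog-valid mentions are counted; records without a parseable
#' year are skipped.
#'
#' @inheritParams extract_mirna_mentions
#' @param window_end final year of the analysis window used for the
#'   mean-since-first-publication metric; defaults to the corpus maximum year.
#' @return a `mirna_matrix`: tibble with columns `mirna`, `year`, `n`
#'   (articles), carrying the window end as the `window_end` attribute.
#' @export
annual_mirna_matrix <- function(corpus, catalog, species_prefix = "hsa",
                                window_end = NULL) {
  mentions <- extract_mirna_mentions(corpus, catalog, species_prefix)
  years <- corpus$year[match(mentions$record_id, corpus$record_id)]
  keep <- mentions$valid & !is.na(years)
  counts <- tibble::tibble(
    mirna = mentions$canonical_id[keep],
    year = years[keep],
    record_id = mentions$record_id[keep]
  ) |>
    dplyr::distinct(.data$mirna, .data$year, .data$record_id) |>
    dplyr::count(.data$mirna, .data$year) |>
    dplyr::arrange(.data$mirna, .data$year)
  if (is.null(window_end)) {
    window_end <- if (all(is.na(corpus$year))) NA_integer_ else max(corpus$year, na.rm = TRUE)
  }
  attr(counts, "window_end") <- as.integer(window_end)
  class(counts) <- c("mirna_matrix", class(counts))
  counts
}

#' Rank miRNAs by cumulative count or mean since first publication
#'
#' Two ranking metrics: `total`, the cumulative article count across all
#' years, and `mean_since_first`, the total divided by the inclusive span
#' from the first year the miRNA appears to the window end
#' (`window_end - first_year + 1`). Ties break by earlier first year, then
#' lexicographic id.
#'
#' @param matrix a [annual_mirna_matrix()] result.
#' @param top_n rows to keep (default 10; `Inf` keeps all).
#' @param metric ranking metric.
#' @param window_end override of the matrix's window end.
#' @return tibble `mirna`, `first_year`, `total`, `mean_since_first`, `rank`.
#' @export
rank_mirnas <- function(matrix, top_n = 10,
                        metric = c("total", "mean_since_first"),
                        window_end = NULL) {
  metric <- match.arg(metric)
  window_end <- window_end %||% attr(matrix, "window_end")
  if (nrow(matrix) == 0) {
    return(tibble::tibble(mirna = character(0), first_year = integer(0),
                          total = integer(0), mean_since_first = numeric(0),
                          rank = integer(0)))
  }
  ranked <- matrix |>
    dplyr::group_by(.data$mirna) |>
    dplyr::summarise(first_year = min(.data$year), total = sum(.data$n),
                     .groups = "drop") |>
    dplyr::mutate(mean_since_first = .data$total / (window_end - .data$first_year + 1)) |>
    dplyr::arrange(dplyr::desc(.data[[metric]]), .data$first_year, .data$mirna) |>
    dplyr::mutate(rank = dplyr::row_number())
  utils::head(ranked, top_n)
}

#' Wide miRNA-by-year table with Total and Mean columns
#'
#' Pivot of the annual matrix into the reporting layout: one row per miRNA,
#' one column per year, plus `Total` and `Mean` (mean articles per year since
#' first appearance, inclusive span).
#'
#' @inheritParams rank_mirnas
#' @return wide tibble ordered by descending `Total`.
#' @export
mirna_matrix_table <- function(matrix, top_n = Inf, window_end = NULL) {
  ranked <- rank_mirnas(matrix, top_n = top_n, metric = "total",
                        window_end = window_end)
  wide <- matrix |>
    dplyr::filter(.data$mirna %in% ranked$mirna) |>
    tidyr::pivot_wider(names_from = "year", values_from = "n", values_fill = 0,
                       names_sort = TRUE)
  ranked |>
    dplyr::select("mirna", "Total" = "total", "Mean" = "mean_since_first") |>
    dplyr::left_join(wide, by = "mirna") |>
    dplyr::relocate("Total", "Mean", .after = dplyr::last_col())
}
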