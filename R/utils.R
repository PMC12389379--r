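#' Round half away from zero
#'
#' Displayed percentages and rates round half-up (2.5 -> 3), matching how
#' bibliometric reports print their tables, rather than R's banker's rounding.
#' Applied at formatting time only; internal arithmetic stays unrounded.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(2.5)   # 3
#' round_half_up(15.05, 1)
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a proportion as a percentage string
#'
#' @param num numerator.
#' @param den denominator.
#' @param digits decimal places (0 prints e.g. "5%").
#' @return character vector like "15.1%".
#' @export
format_percent <- function(num, den, digits = 1) {
  pct <- round_half_up(100 * num / den, digits)
  paste0(formatC(pct, format = "f", digits = digits), "%")
}

# lowercased alphanumeric token normalization used for titles and keys
normalize_title <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

# stable record key when no DOI is present: sanitized
# (first-author-surname, year, normalized-title) triple
fallback_record_id <- function(first_author, year, title) {
  surname <- tolower(sub("[ ,].*$", "", ifelse(is.na(first_author) | first_author == "",
                                               "anon", first_author)))
  tt <- gsub(" ", "-", normalize_title(ifelse(is.na(title), "", title)))
  paste0("rec:", surname, ":", ifelse(is.na(year), "na", year), ":", tt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
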