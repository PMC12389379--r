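test_that("token extraction finds stem variants, prefixes, arms and let-7", {
  hits <- extract_mirna_tokens(
    "MicroRNA-21 (miR-21) post-transcriptionally downregulates tumor suppressor Pdcd4")
  expect_equal(hits$token, c("MicroRNA-21", "miR-21"))

  expect_equal(nrow(extract_mirna_tokens("")), 0)
  expect_equal(extract_mirna_tokens("hsa-miR-195-5p and LET-7A and MIR 34A")$token,
               c("hsa-miR-195-5p", "LET-7A", "MIR 34A"))
  # spans are non-overlapping and leftmost-longest
  h <- extract_mirna_tokens("miR-21-5p")
  expect_equal(h$token, "miR-21-5p")
  expect_equal(h$end - h$start + 1, nchar("miR-21-5p"))
  # grammar-invalid distractors are not matched
  expect_equal(nrow(extract_mirna_tokens("PDCD4, KRAS and SIRT1 but no identifier")), 0)
})

test_that("planted tokens are recovered with full recall and no span overlap", {
  set.seed(31)
  pool <- c("miR-21", "miR-34a", "miR-195-5p", "let-7a", "miR-181a-5p")
  for (i in 1:200) {
    planted <- sample(pool, sample(1:3, 1))
    txt <- paste0("Study of ", paste(planted, collapse = " versus "),
                  " in tumor tissue")
    hits <- extract_mirna_tokens(txt)
    expect_equal(sort(unique(hits$token)), sort(unique(planted)))
    if (nrow(hits) > 1) {
      expect_true(all(hits$start[-1] > hits$end[-nrow(hits)]))
    }
  }
})

test_that("canonicalization folds stems, prefixes and case; errors on misuse", {
  expect_equal(canonicalize_mirna("hsa-miR-195-5p"), "miR-195-5p")
  expect_equal(canonicalize_mirna("microRNA 21"), "miR-21")
  expect_equal(canonicalize_mirna("MIR-34A"), "miR-34a")
  expect_equal(canonicalize_mirna("mmu-let-7a-3p"), "let-7a-3p")
  expect_error(canonicalize_mirna("PDCD4"), "grammar")
})

test_that("canonicalization is idempotent over rendered variants", {
  set.seed(7)
  numbers <- sample(1:600, 120)
  letters_opt <- c("", letters[1:6])
  arms <- c("", "-5p", "-3p")
  stems <- c("miR-", "mir-", "MIR-", "microRNA ", "miRNA-", "hsa-miR-")
  for (i in seq_along(numbers)) {
    canon <- paste0("miR-", numbers[i], sample(letters_opt, 1), sample(arms, 1))
    variant <- sub("^miR-", sample(stems, 1), canon)
    expect_equal(canonicalize_mirna(variant), canon)
    expect_equal(canonicalize_mirna(canonicalize_mirna(variant)), canon)
  }
})

test_that("catalog loading unions releases and resolves renames", {
  dir <- withr::local_tempdir()
  f1 <- file.path(dir, "r1.txt"); f2 <- file.path(dir, "r2.txt")
  writeLines(c("MI001\thsa-mir-21", "MIMAT01\thsa-miR-21"), f1)
  writeLines(c("MI001\thsa-mir-21", "MIMAT01\thsa-miR-21;hsa-miR-21-5p",
               "MIMAT02\thsa-miR-21-3p"), f2)
  cat <- load_mirna_catalog(c(f1, f2), releases = c("r1", "r2"))
  expect_setequal(cat$names, c("hsa-mir-21", "hsa-mir-21-5p", "hsa-mir-21-3p"))
  expect_equal(unname(cat$alias_map["hsa-mir-21"]), "hsa-mir-21-5p")
  # loading the same file twice is an idempotent union
  cat2 <- load_mirna_catalog(c(f2, f2), releases = c("a", "b"))
  expect_setequal(cat2$names, cat$names)
  # malformed lines are skipped with a warning
  f3 <- file.path(dir, "bad.txt")
  writeLines(c("MI001\thsa-mir-21", "no-tab-here"), f3)
  expect_warning(load_mirna_catalog(f3), "malformed")
})

test_that("validation accepts catalog names and rejects unknown ids", {
  cat <- bundled_catalog()
  expect_true(validate_mirna("miR-21", cat))
  expect_true(validate_mirna("miR-195-5p", cat))
  expect_true(validate_mirna("let-7a", cat))
  expect_false(validate_mirna("miR-99999", cat))
  # every catalog name round-trips through canonicalize with no false negative
  hsa <- cat$names[grepl("^hsa-", cat$names)]
  canon <- canonicalize_mirna(hsa)
  expect_true(all(validate_mirna(canon, cat)))
})

test_that("the annual matrix counts articles, not mentions, and skips invalid ids", {
  cat <- bundled_catalog()
  corpus <- dplyr::bind_rows(
    record_row("a", 2020, title = "miR-21 in tumors",
               abstract = "We study miR-21 and MIR-21 again",
               keywords = c("miR-21")),
    record_row("b", 2020, title = "Only miR-99999 here",
               abstract = "miR-99999 is not a real identifier")
  )
  m <- annual_mirna_matrix(corpus, cat)
  expect_equal(nrow(m), 1)
  expect_equal(m$mirna, "miR-21")
  expect_equal(m$n, 1)  # title + abstract + keyword mentions collapse to one article
})

test_that("annual matrix recovers the planted incidence exactly", {
  gen <- generate_corpus(synth_config(n_records = 300, seed = 5))
  m <- annual_mirna_matrix(gen$corpus, bundled_catalog())
  truth <- gen$truth$mentions |> dplyr::count(.data$mirna, .data$year)
  joined <- dplyr::full_join(m, truth, by = c("mirna", "year"))
  expect_true(all(!is.na(joined$n.x) & !is.na(joined$n.y)))
  expect_equal(joined$n.x, joined$n.y)
  # order invariance
  shuffled <- gen$corpus[sample(nrow(gen$corpus)), ]
  m2 <- annual_mirna_matrix(shuffled, bundled_catalog(),
                            window_end = attr(m, "window_end"))
  expect_equal(dplyr::arrange(tibble::as_tibble(m), mirna, year),
               dplyr::arrange(tibble::as_tibble(m2), mirna, year))
})

test_that("ranking uses inclusive spans and the documented tie-breaks", {
  m <- tibble::tibble(
    mirna = c("miR-21", "miR-21", "miR-34a", "miR-1"),
    year = c(2008L, 2024L, 2015L, 2015L),
    n = c(6L, 7L, 4L, 4L)
  )
  attr(m, "window_end") <- 2024L
  class(m) <- c("mirna_matrix", class(m))
  r <- rank_mirnas(m, metric = "total")
  # 13 articles first seen 2008 with window end 2024: inclusive span of 17 years
  expect_equal(r$total[1], 13)
  expect_equal(r$mean_since_first[1], 13 / 17)
  # tie between miR-34a and miR-1 breaks lexicographically (same first year)
  expect_equal(r$mirna, c("miR-21", "miR-1", "miR-34a"))

  single <- m[3, ]
  attr(single, "window_end") <- 2024L
  class(single) <- c("mirna_matrix", class(single))
  expect_equal(rank_mirnas(single, metric = "total")$rank, 1)
  expect_equal(rank_mirnas(single, metric = "mean_since_first")$rank, 1)
})

test_that("ranking agrees with a brute-force sort on random matrices", {
  set.seed(13)
  for (rep in 1:3) {
    m <- tibble::tibble(
      mirna = paste0("miR-", sample(1:50)),
      year = sample(2008:2024, 50, replace = TRUE),
      n = sample(1:9, 50, replace = TRUE)
    ) |> dplyr::arrange(mirna, year)
    attr(m, "window_end") <- 2024L
    class(m) <- c("mirna_matrix", class(m))
    r <- rank_mirnas(m, top_n = Inf, metric = "mean_since_first")
    brute <- stats::aggregate(n ~ mirna, data = as.data.frame(m), FUN = sum)
    brute$first <- stats::aggregate(year ~ mirna, data = as.data.frame(m), FUN = min)$year
    brute$mean <- brute$n / (2024 - brute$first + 1)
    brute <- brute[order(-brute$mean, brute$first, brute$mirna), ]
    expect_equal(r$mirna, brute$mirna)
    expect_equal(r$mean_since_first, brute$mean)
  }
})
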