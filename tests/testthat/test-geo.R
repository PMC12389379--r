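test_that("affiliation country parsing takes the last comma token through aliases", {
  tab <- country_alias_table()
  expect_equal(parse_affiliation_country(
    "National Institute of Gastroenterology, Castellana Grotte, Italy", tab), "Italy")
  expect_equal(parse_affiliation_country("Lab, Beijing, PR China", tab), "China")
  expect_equal(parse_affiliation_country("Dept, Boston, USA", tab), "United States")
  expect_true(is.na(parse_affiliation_country("Dept, Atlantis", tab)))
  expect_true(is.na(parse_affiliation_country(NA_character_, tab)))
})

test_that("planted affiliations resolve completely", {
  gen <- generate_corpus(synth_config(n_records = 100, seed = 2))
  affs <- unlist(purrr::map(gen$corpus$authors, "affiliation"))
  resolved <- parse_affiliation_country(affs, country_alias_table())
  expect_true(all(!is.na(resolved)))
})

test_that("appearance counts and shares match the planted mixture and an oracle", {
  gen <- generate_corpus(synth_config(n_records = 250, seed = 4))
  app <- author_appearance_counts(gen$corpus)
  truth <- gen$truth$appearances
  expect_equal(app$appearances[match(truth$country, app$country)], truth$appearances)
  expect_equal(sum(app$appearances), sum(truth$appearances))
  expect_equal(app$share,
               round_half_up(100 * app$appearances / sum(app$appearances), 2))
  # author order within records is irrelevant
  shuf <- gen$corpus
  shuf$authors <- purrr::map(shuf$authors, function(a) a[sample(nrow(a)), ])
  expect_equal(author_appearance_counts(shuf), app)
})

test_that("published appearance-share arithmetic reproduces", {
  # 4976 of 5670 appearances and 118 of 5670
  expect_equal(round_half_up(100 * 4976 / 5670, 2), 87.76)
  counts <- c(China = 4976, Iran = 118, Other = 5670 - 4976 - 118)
  corpus <- purrr::map_dfr(names(counts), function(cc) {
    record_row(paste0("r", cc), 2020, authors = tibble::tibble(
      name = paste0(cc, seq_len(counts[[cc]])),
      affiliation = paste0("Dept, City, ", cc)))
  })
  tab <- c(country_alias_table(), other = "Other")
  app <- author_appearance_counts(corpus, tab)
  expect_equal(app$share[app$country == "China"], 87.76)
  expect_equal(app$share[app$country == "Iran"], 2.08)

  one <- author_appearance_counts(record_row("x", 2020))
  expect_equal(one$share, 100.00)
})

test_that("corresponding country comes only from the correspondence address", {
  corpus <- dplyr::bind_rows(
    record_row("a", 2020, corr = "Rossi M.; Institute, Bari, Italy"),
    record_row("b", 2020, corr = NA_character_),
    record_row("c", 2020, corr = "Lee K.; Somewhere, Nowhereland")
  )
  cc <- corresponding_country(corpus)
  expect_equal(cc$country, c("Italy", NA, NA))
  expect_equal(cc$reason, c("ok", "missing_address", "unresolved_country"))
})

test_that("SCP/MCP counts satisfy their invariants and detect planted collaboration", {
  gen <- generate_corpus(synth_config(n_records = 400, seed = 6))
  sm <- scp_mcp_counts(gen$corpus)
  expect_true(all(sm$SCP + sm$MCP == sm$corr_articles))
  truth <- gen$truth$corresponding |> dplyr::filter(!is.na(.data$country))
  expect_equal(sum(sm$corr_articles), nrow(truth))
  expect_equal(attr(sm, "n_excluded"), sum(is.na(gen$truth$corresponding$country)))
  brute <- truth |> dplyr::count(.data$country)
  expect_equal(sm$corr_articles[match(brute$country, sm$country)], brute$n)
  brute_mcp <- truth |> dplyr::filter(.data$mcp) |> dplyr::count(.data$country)
  expect_equal(sm$MCP[match(brute_mcp$country, sm$country)], brute_mcp$n)

  # no collaboration -> no MCP anywhere
  gen0 <- generate_corpus(synth_config(n_records = 150, collab_prob = 0, seed = 8))
  expect_true(all(scp_mcp_counts(gen0$corpus)$MCP == 0))

  # single-author records are always SCP
  solo <- record_row("s", 2020, corr = "A; Dept, City, Japan",
                     authors = tibble::tibble(name = "A", affiliation = "Dept, City, Japan"))
  sm1 <- scp_mcp_counts(solo)
  expect_equal(sm1$SCP, 1L)
  expect_equal(sm1$MCP, 0L)
})

test_that("published corresponding-share and MCP arithmetic reproduces", {
  expect_equal(round_half_up(100 * 710 / 828, 1), 85.7)
  expect_equal(format_percent(21, 710, 0), "3%")
  expect_equal(format_percent(41, 828, 0), "5%")

  # a corpus planted with those totals reproduces them through the pipeline
  corpus <- purrr::map_dfr(1:828, function(i) {
    if (i <= 41) return(record_row(paste0("r", i), 2020, corr = NA_character_))
    cc <- if (i <= 41 + 710) "China" else "Iran"
    mcp <- i > 41 && i <= 41 + 21  # 21 of the 710 Chinese records are MCP
    record_row(paste0("r", i), 2020,
               corr = paste0("A; Dept, City, ", cc),
               authors = tibble::tibble(
                 name = c("A", "B"),
                 affiliation = paste0("Dept, City, ", c(cc, if (mcp) "United States" else cc))))
  })
  sm <- scp_mcp_counts(corpus)
  china <- sm[sm$country == "China", ]
  expect_equal(china$corr_articles, 710L)
  expect_equal(china$corr_share, 85.7)
  expect_equal(china$MCP, 21L)
  expect_equal(format_percent(china$MCP, china$corr_articles, 0), "3%")
  expect_equal(attr(sm, "n_excluded"), 41L)
})
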