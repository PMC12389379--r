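# mirbiblio

Bibliometric mining of microRNA literature corpora in R.

Research fields built around a molecular entity — here, microRNAs in
colorectal cancer — are routinely surveyed with bibliometric methods: how fast
is the literature growing, which papers anchor the field, which countries
produce and lead the work, and which concepts co-occur. Generic bibliometric
suites handle the citation side but cannot resolve trends at the level of the
molecule, because miRNA identifiers appear in titles and abstracts under many
surface forms (`miR-21`, `hsa-miR-21-5p`, `microRNA 21`, `MIR-34A`) and many of
those strings are outdated or invalid nomenclature.

`mirbiblio` is a tidyverse-native toolkit for exactly this combination:

* **Corpus handling** — parse Scopus-style CSV exports into a tidy corpus
  (one row per record, list-columns for authors and keywords), apply a manual
  relevance screen plus document-type/language rules, and report completeness.
* **miRNA named-entity recognition** — extract tokens with a nomenclature
  grammar (species prefix, stem variants, number, letter suffix, paralog, arm,
  plus the let-7 family), canonicalize them, and validate against a
  multi-release miRBase-style alias catalog. Counting is article-level: a
  record contributes at most once per miRNA per year.
* **Citation indicators** — annual production `NP` and shares; compound annual
  growth rate `((NP_last/NP_first)^(1/(y_last − y_first)) − 1) · 100`; global
  citation scores (GCS, the database "Cited by" count); local citation scores
  (LCS, citations received from *within* the corpus, matched by DOI or by
  first-author/year/title similarity); citations per year
  `TC/Y = TC / (y_ref − y_pub + 1)` with inclusive citation-years.
* **Geography** — author appearance counts per country from affiliation
  strings, corresponding-author attribution, and single- vs multiple-country
  publications (SCP/MCP).
* **Networks** — country collaboration and keyword co-occurrence graphs with
  full or fractional counting, association-strength normalization
  `s_ij = 2m·c_ij/(w_i·w_j)`, Walktrap communities, a resolution-parameterized
  clustering of the normalized weights with minimum-cluster-size merging, and
  reporting-oriented pruning.
* **Synthetic corpora** — a seeded generator that emulates the statistical
  structure of a real single-topic corpus (three growth phases, one dominant
  country, Zipf-distributed mentions and keywords, backward-in-time citations)
  with full ground truth, so every stage is testable without any download.

## Worked example

```r
library(mirbiblio)

gen    <- generate_corpus(synth_config(n_records = 400, seed = 2024))
write_scopus_csv(gen$corpus, "example.csv")
corpus <- read_scopus_csv("example.csv")

catalog <- load_mirna_catalog(system.file(
  "extdata", paste0("synthetic_mirbase_aliases_r", 20:22, ".txt"),
  package = "mirbiblio"))

annual <- annual_production(corpus)
cagr(annual, 2008, 2024)
#> # A tibble: 1 × 5
#>   first_year last_year NP_first NP_last rate_pct
#> 1       2008      2024        1      30     23.7

rank_mirnas(annual_mirna_matrix(corpus, catalog), top_n = 5)
#> # A tibble: 5 × 5
#>   mirna       first_year total mean_since_first  rank
#> 1 miR-21            2008   174            10.2      1
#> 2 miR-34a           2011    97             6.93     2
#> 3 miR-195-5p        2014    52             4.73     3
#> 4 miR-181a-5p       2013    46             3.83     4
#> 5 miR-934           2014    33             3        5

head(scp_mcp_counts(corpus), 3)
#> # A tibble: 3 × 6
#>   country corr_articles corr_share   SCP   MCP MCP_pct
#> 1 China             326       81.5   315    11     3.4
#> 2 Iran               14        3.5    14     0     0
#> 3 Japan              13        3.3    12     1     7.7
```

The growth rate of 23.7 % per year says the synthetic corpus grew from 1 to 30
papers per year over 16 years; the miRNA ranking reports, per identifier, the
number of distinct articles mentioning it (`total`) and that total averaged
over the inclusive span since its first appearance (`mean_since_first`); the
country table splits each country's corresponding-author articles into
purely national (SCP) and internationally co-authored (MCP) work — here 3.4 %
of China-led articles involve a foreign co-author.

For the full pipeline in one call (annual stats, miRNA matrix, top documents
by GCS and LCS, country tables, clustered networks, keyword table), see
`run_report()`; `plot_annual_production()`, `autoplot()` on the miRNA matrix,
`plot_scp_mcp()`, `plot_keyword_cloud()` and `plot_network()` draw the
standard figures, and `tidy()`/`glance()` work on graphs and partitions.

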