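---
title: "Methods: bibliometric mining of miRNA literature corpora"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bibliometric mining of miRNA literature corpora}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirbiblio)
```

This vignette documents the models and procedures behind `mirbiblio`, the
conventions it adopts where the field leaves choices open, and what its test
suite does and does not establish about real bibliographic data.

## The corpus model

A corpus is a tibble with one row per bibliographic record: title, abstract,
author keywords (list-column), authors with their affiliation strings
(list-column of tibbles, one row per author–affiliation pair), correspondence
address, year, source title, the database citation count, raw reference
strings, document type and language. Records keep their input order, and
record identity is the lowercased DOI when present. When a DOI is missing we
derive a stable key from the first author's surname, the year and the
normalized title; reference matching and screening both need a key that
survives a write/read round trip, and this triple is the most stable
DOI-free signature a Scopus-style export offers. Rows with an unparseable
year are kept and flagged `incomplete` rather than dropped, so completeness
statistics (e.g. the share of records lacking a correspondence address)
remain computable over the full corpus.

The manual relevance screen is consumed as an explicit keep list and never
re-derived: which articles are on-topic is a human judgment, and the package's
job is only to apply it reproducibly and account for every removal
(`apply_screening()` reports removals per reason, and kept + removed always
equals the input size).

## miRNA extraction and validation

Tokens are matched case-insensitively by a nomenclature grammar: an optional
three-letter species prefix, a stem in {miR, mir, miRNA, microRNA, MIR} with
an optional hyphen or single-space separator, a number, an optional letter
suffix, an optional paralog `-N`, and an optional arm `-5p`/`-3p`; the let-7
family has its own production. Spans are non-overlapping and
leftmost-longest. Canonicalization strips the species prefix, folds the stem
to `miR` (or `let-7`) and lowercases the letter suffix, so `MIR-34A` and
`microRNA 34a` are the same identifier. Validation prepends the configured
species prefix (default `hsa`, appropriate for a human-disease corpus) and
looks the name up case-insensitively in the union of the catalog releases and
their alias maps. The union rule means a name valid in any loaded release
passes; releases renumber and rename entries over time and a literature
corpus spans those transitions, so requiring membership in every release
would reject historically correct usage.

Two conventions matter for the annual matrix:

* **Article-level counting.** A record contributes at most 1 to a
  (miRNA, year) cell regardless of how many fields or repeated tokens mention
  the identifier. The quantity of interest is "articles addressing this
  miRNA per year", not token frequency.
* **Arm-level identity.** `miR-195` and `miR-195-5p` are distinct entries;
  arm-resolved identifiers carry biological meaning and are ranked
  separately.

Rankings use two metrics: the cumulative article total, and that total
divided by the *inclusive* span from the identifier's first year of
appearance to the analysis window end (`window_end − first_year + 1`). The
inclusive span is a declared convention — a miRNA first seen in the window's
final year has denominator 1, not 0. Ties break by earlier first year, then
lexicographically.

The bundled alias tables under `inst/extdata/` are synthetic subsets in the
miRBase `aliases.txt` format (accession TAB semicolon-separated names, last
name current), sized for examples and tests; production use should load the
real release files through the same `load_mirna_catalog()` interface.

## Citation indicators

* **Annual production** covers every year in the corpus span, including zero
  years; shares are percentages of the corpus total at one decimal.
* **Growth rate** is the compound annual growth rate between the endpoint
  years, `((NP_last/NP_first)^(1/(y_last − y_first)) − 1)·100`. Intermediate
  years do not enter the formula, and a zero first-year count is an error
  rather than an infinite rate. Note that the ratio of total citations to
  publications (`TC_per_NP`) is reported as the plain quotient `TC/NP`;
  published tables sometimes print slightly different values for this column
  (an undocumented divisor), and we do not imitate numbers we cannot derive.
* **Citations per year** uses inclusive citation-years,
  `TC/(y_ref − y_pub + 1)`: a paper published in the reference year has one
  citation-year. This convention reproduces published per-year rates for
  top-cited-document tables when the reference year is set to the analysis
  year (2025 by default in `run_report()`), and the reference year is always
  an explicit argument.
* **Local citation scores** count, for each document, how many other corpus
  records cite it. A reference string containing a DOI matches by DOI alone;
  otherwise the first-author surname and year must agree and the normalized
  title similarity must reach the threshold (default 0.90). Similarity is a
  normalized edit-distance measure: the candidate title (lowercased
  alphanumeric tokens) is aligned against its best-matching window of the
  reference string, and similarity is 1 minus the edit distance over the
  title length. Free-text references vary too much for exact matching, and
  0.90 tolerates roughly one typo per ten characters while rejecting
  different titles; the threshold is exposed as an argument and exercised on
  synthetic noise in the tests. Self-citations of a record to itself are
  excluded, and references to out-of-corpus work are silently ignored —
  that is what makes the score *local*.

## Country attribution

Affiliation strings resolve to countries by their last comma-separated token
through an editable alias table (`"PR China"` → China, `"USA"` → United
States). Unresolved strings stay unresolved; guessing would silently corrupt
the tables, whereas exclusion is visible and counted.

Two complementary views are computed. *Appearance counting* attributes each
article to all co-authors' countries: every author–affiliation pair with a
resolved country contributes one appearance, so an author with affiliations
in two countries contributes one appearance to each. *Corresponding-author
attribution* assigns each article to exactly one country — that of the
correspondence address; records missing the field are excluded with the
reason logged rather than falling back to the first author, since the two
attributions answer different questions. An article is a multiple-country
publication (MCP) when at least one co-author's resolved country differs from
the corresponding country, else a single-country publication (SCP);
SCP + MCP equals the country's corresponding-article total by construction,
and the suite asserts it on every generated corpus. Percentage precision is a
formatting option (country tables default to one decimal; headline shares of
large counts are conventionally printed at integer precision).

## Networks and clustering

Both network builders produce undirected igraph objects with occurrence
node weights and co-occurrence edge weights. The collaboration network uses
full counting (an article with authors from countries A and B adds 1 to the
A–B edge). The keyword network defaults to fractional counting: an article
with `k` kept keywords adds `1/(k − 1)` per pair, so each keyword distributes
exactly unit weight per article — the unit-distribution identity is a tested
invariant. Keywords below the occurrence threshold (default 5 articles) are
dropped before pair counting.

Edge weights are normalized by association strength,
`s_ij = 2m·c_ij/(w_i·w_j)` with `m` the total link weight — the ratio of the
observed co-occurrence to its expectation if occurrences were independent.
Normalization preserves edge support, and a zero-weight endpoint is an error
because the expectation is then undefined.

Two community detectors are provided:

* `walktrap_communities()` delegates to igraph's Walktrap implementation
  (random-walk distances, agglomerative merging, modularity cut). It is
  deterministic given the graph and walk length (default 4), and disconnected
  components can never merge.
* `resolution_clustering()` maximizes
  `Σ_{i<j, same cluster} (s_ij − γ·w_i w_j/(2m))` — a resolution-parameterized
  modularity variant on the association-normalized weights, with the
  configuration-model expectation. The optimizer is Louvain-style local
  moving with aggregation, restarted (default 10 times) under a fixed seed
  (default 20240925) with the best objective kept, so results are
  reproducible. Clusters below `min_cluster_size` are merged into the
  neighbor cluster with the largest connecting raw weight; a small cluster
  with no connection at all is flagged residual instead of being merged
  arbitrarily.

The resolution default of 0.5 follows common practice for keyword maps:
γ below 1 favors coarser, reader-oriented thematic clusters. On planted
two-block graphs the default recovers the blocks exactly; on finer planted
structure a higher γ (e.g. 1) is needed, which is the parameter's intended
behavior, and the optimizer is verified in the tests to reach objective
values at least as good as the planted partition. `prune_network()` applies
the reporting limits (top 30 nodes by weight, ties lexicographic; iterative
removal below minimum degree, so no isolated nodes survive).

## Keyword normalization

Keywords are lowercased, trimmed, whitespace-collapsed, and Unicode dash
variants are folded to a plain hyphen before thesaurus lookup, so
"Wnt/β-catenin" spellings converge. The synonym map is one-step (a preferred
term never maps onward — enforced at construction), which makes
normalization idempotent; the exclusion set is tested after mapping, so a
query term is removed under any of its spellings. Frequencies are
article-level, ties lexicographic, truncated to the top 100 by default (the
word-cloud convention).

## The synthetic generator

`generate_corpus()` exists so that every stage has exact ground truth without
downloading anything. Its defaults are fixed once to the study-like shape of
a single-topic oncology corpus and are not tuning knobs:

* 828 records over 2008–2024 with per-year counts apportioned (largest
  remainder, hence deterministic) to the three-phase profile: near-zero
  output 2008–2010, growth to a 2020 peak of 125, then decline;
* a country mixture dominated by one country at 0.857, a 3 % probability of
  a foreign co-author, and a 41/828 missing-correspondence rate;
* a 30-identifier miRNA pool drawn Zipf(1.1), rendered with case and spacing
  variants (20 % / 10 %) and catalog-invalid distractor ids in 10 % of
  records;
* keyword draws from two planted co-occurrence blocks (tumor-progression and
  therapy-response vocabularies) with head weights proportional to typical
  word-cloud frequencies;
* within-corpus citations drawn backward in time only, preferentially to
  recent predecessors, at an expected 2 per record, with the database
  citation count set to in-corpus in-degree plus Poisson(3) external
  citations — so LCS ≤ GCS holds by construction.

The generator emulates the *statistical* structure (growth phases, skewed
geography, Zipf vocabularies, citation asymmetry, missing fields). It does
not emulate real titles and author names, indexer inconsistencies beyond the
modeled token noise, multi-affiliation authors, or reference strings in
heterogeneous citation styles. Tests passing on synthetic corpora therefore
establish the correctness of the arithmetic and the matching rules under
clean and mildly noisy conditions; they do not certify recall on arbitrarily
messy real exports, which is why every matching threshold is exposed as a
parameter.

## Problem sizes and numerical choices

The test suite and acceptance script run generated corpora of 300–1385
records, planted block graphs of 24–36 nodes, and one full 828-record
pipeline pass — sizes chosen so the whole suite completes in about a minute
while leaving every counting identity exact. Displayed percentages round
half-away-from-zero at formatting time only (`round_half_up()`); internal
values stay unrounded. Degenerate inputs are defined rather than accidental:
empty corpora give empty tables, a zero-publication first year makes the
growth rate an error, records without a parseable year are skipped by the
annual matrix, and empty graphs pass through pruning and plotting unchanged.

## Orchestration

`run_report()` chains all stages over a corpus and catalog, stamps outputs
with a configuration fingerprint and seed, aborts with the stage name on
failure, and optionally writes all tables (TSV), networks (node-link JSON)
and the run configuration to a directory. The package is library-first: the
exported functions, this vignette and `scripts/acceptance.R` are the
interface, and each stage's thresholds are arguments with the defaults
documented above.

## Known limitations

* Reference matching assumes the first comma- or parenthesis-delimited token
  of a reference string is the first author; heavily reformatted references
  fall back to unmatched (undercounting LCS, never overcounting).
* Country resolution depends on the alias table; affiliations whose last
  token is not a country (e.g. ending with a postal code) are excluded, not
  inferred.
* Multi-release catalogs are unioned; the package does not track per-release
  validity windows or flag identifiers as deprecated.
* The resolution objective uses the configuration-model expectation on
  association-normalized weights; other published variants normalize inside
  the expectation differently, so cluster granularity at equal γ is not
  comparable across tools.
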