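# assertnet

Assertion networks for *in silico* biomarker discovery.

`assertnet` is for bioinformaticians and text-mining researchers who want to
turn biomedical text and structured tables into a queryable knowledge store
and derive candidate disease biomarkers from it. It implements, end to end
and fully offline:

* **Concept vocabularies** — preferred labels with flat synonym sets and
  closed concept types (disease, pathological observation, anatomical
  structure, protein/mRNA, gene mutation, biological process), with shallow
  surface normalization (case folding, Greek-letter spelling, hyphen ↔
  space) and dictionary-based longest-match term recognition.
* **Assertion extraction** — within-sentence subject–verb–object triples
  (e.g. `BACE1 —IS INVOLVED IN→ Amyloid Fibril Formation`) via a relation
  lexicon grouped into classes (expression, upregulation, pathology link,
  disease link, pathway membership), typed extraction patterns with token
  gap bounds, direction canonicalization and negation-cue suppression;
  curation decision files and ISO-2859-style acceptance sampling with an
  exact Clopper–Pearson interval on curator accuracy.
* **Structured-source ingestion** — declarative column mappings that turn
  gene–disease or expression tables into accepted assertions with row-level
  provenance and an itemized skip report.
* **The intelligence network** — a provenance-merged triple store with
  typed queries, summary statistics, and a deterministic (byte-identical)
  TSV + JSONL serialization.
* **Candidate derivation** — the three-stage filter chain
  *expressed in relevant brain regions* → *upregulated in disease* →
  *linked to pathological hallmarks*, with per-step audit counts and a
  novelty assessment against tagged biomarker-claim sources.
* **A seeded synthetic-corpus generator** — plants a known truth set in
  template sentences (synonym-varied, with distractor and negated
  sentences) and structured tables, and scores extraction output against
  the gold annotations (precision / recall / F1).
* **Validation statistics** — one-way ANOVA from raw data or from printed
  per-group (n, mean, SD) summaries, Spearman rank correlation with
  tie-aware ranks (exact permutation p for n ≤ 8, t approximation above),
  and a Monte-Carlo Lilliefors Kolmogorov–Smirnov normality check.

Everything is tibble-in / tibble-out with broom-style `tidy()` / `glance()`
methods and `autoplot()` displays; a thin command-line dispatcher ships at
`inst/cli/assertnet.R`.

## Worked example

Extract an assertion from a sentence, derive candidates from the shipped
golden network, and run the summary-statistics ANOVA:

```r
library(assertnet)

v  <- ad_vocabulary()          # 83 disease/pathology/region concepts + 25 proteins
lx <- ad_relation_lexicon()
m  <- compile_matcher(v)

extract_proto_assertions(m, lx, default_patterns(),
                         "pmid-1", "pubmed", 0L,
                         "BACE-1 is involved in amyloid formation.") |>
  dplyr::select(subject_id, relation, object_id, status)
#> # A tibble: 1 × 4
#>   subject_id relation       object_id                status
#> 1 bace1      IS INVOLVED IN amyloid-fibril-formation PROTO
```

Note the normalization at work: surface `"BACE-1"` resolves to the `BACE1`
concept and `"amyloid formation"` to the preferred pathology concept.

```r
g  <- ad_golden_network()      # 60 proteins, 102 assertions
ct <- derive_candidates(g$net, g$config)
ct
#> Candidate derivation
#>   expressed_in_regions     40
#>   upregulated_in_disease   30
#>   pathology_associated     25
#> Final candidates: 25
```

The filter chain retains 40 proteins with region-expression evidence, 30 of
those with upregulation evidence in the disease, and 25 with pathology
links — the candidate set, 18 of which are flagged novel (no tagged
biomarker-claim assertion; e.g. `PLAUR` and `CHAT` are novel, `CLU` is not).

```r
glance(anova_from_summary(plaur_group_summaries()))
#> # A tibble: 1 × 5
#>   statistic df_between df_within  p.value method
#> 1      30.0          2       237 2.36e-12 group summaries
```

The PLAUR plasma group summaries (controls 1.63 ± 0.9 n = 82, MCI
0.98 ± 0.7 n = 80, AD 0.85 ± 0.3 n = 78, arbitrary loading-corrected
intensity units) give F(2, 237) ≈ 30, p ≪ 0.001: plasma PLAUR differs
strongly across diagnostic groups.

See `vignettes/assertion-networks.Rmd` for the model, the design choices
and a full generate → extract → merge → derive run.

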