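---
title: "Assertion networks for in silico biomarker discovery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assertion networks for in silico biomarker discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(assertnet)
library(dplyr)
```

## The model

`assertnet` implements a literature-mining route to candidate disease
biomarkers. The central data structure is an *intelligence network*: a
deduplicated store of **assertions** — subject–verb–object triples such as

    BACE1 —IS INVOLVED IN→ Amyloid Fibril Formation
    CHAT  —IS EXPRESSED IN→ Hippocampus
    PLAUR —IS INCREASED IN→ Alzheimer's Disease

built over curated concept vocabularies. Every concept has one preferred
label, a closed concept type (disease, pathological observation, anatomical
structure, protein/mRNA, gene mutation, biological process) and an explicit
synonym set; every relation verb belongs to exactly one relation class
(pathology link, expression, upregulation, disease link, pathway
membership). Semantic consistency comes from normalization, not inference:
any surface string that matches a synonym resolves to the preferred concept,
and any verb phrase in the relation lexicon resolves to a canonical
preferred relation.

Candidate biomarkers are then derived by a three-stage filter over the
network, with per-step audit counts:

1. proteins with at least one **expression** assertion into a configured set
   of brain regions;
2. of those, proteins with at least one **upregulation** assertion into the
   disease (or a sub-type);
3. of those, proteins with at least one **pathology-link** assertion onto a
   configured set of pathological hallmarks.

The surviving set is assessed for **novelty**: a candidate with no
disease-link assertion whose provenance source is tagged as a published
biomarker claim is flagged novel. The chain is monotone by construction
(each step filters the previous step's set), and output ordering is
deterministic, so the result is insensitive to assertion insertion order.

## Surface normalization and term matching

Normalization is deliberately shallow: case folding, Greek letters mapped to
their spelled-out names (β → beta), hyphens/underscores and all punctuation
treated as token separators, whitespace collapsed. This is exactly what is
needed to make `"BACE-1"` and `"BACE1"`-with-synonym-`"BACE-1"` meet at one
key while avoiding stemming, which can falsely merge distinct terms when
synonym lists are already exhaustive by design. There is no ontology
reasoning; synonym sets are flat.

Mention scanning is dictionary-based longest match: all candidate synonym
spans over the token sequence are resolved greedily, longest span first,
ties broken by earliest start, so `"early onset familial Alzheimer's
disease"` yields the specific sub-type concept and not the nested
`"Alzheimer's Disease"`. A surface that maps to several concepts yields a
multi-concept mention; disambiguation is deferred to the type constraints of
the extraction patterns and, beyond that, to curation. The test suite checks
the scanner against a brute-force enumerate-then-select oracle on generated
sentences.

## Extraction, negation and curation

Extraction is strictly within-sentence. Sentences are segmented at
terminator runs followed by whitespace and a capital letter or digit — a
simple rule that occasionally splits after abbreviations, which is accepted:
cross-sentence assertions are out of scope, and precision is preferred over
recall at this stage. For each relation phrase found in a sentence, every
mention pair (one before, one after) within the pattern's token-gap bound
(default 10 tokens per gap) forms a proto-assertion, provided the concept
types are admissible both for the pattern and for the relation class under
the network map. Inverse surface forms (`"hippocampus expresses X"`, `"has
upregulated"`) are canonicalized on storage, protein-first, so downstream
queries are single-sided.

A small negation-cue set (`not`, `no`, `never`, `failed to`, `absence of`,
`lack of`) suppresses any relation occurrence preceded by a cue in the same
sentence. The automated stage should not assert negated statements; the
cost is abstention on sentences a curator would resolve.

Curation is file-driven: a decision table routes each proto-assertion to
accepted/rejected, with contradictory duplicate decisions an error and
decisions that match nothing a warning. Quality control emulates an
acceptance-sampling inspection: a single-sampling plan (default n = 125,
acceptance number c = 3 — a declared, simplified plan, since the full
standard's switching rules add nothing testable here) draws without
replacement under a mandatory seed, reports point accuracy with an exact
Clopper–Pearson 95% interval, and passes when errors ≤ c. A census (sample
size ≥ population) reports the oracle's exact accuracy.

## Structured sources

Tabular sources (gene–disease tables, expression tables) are ingested
through declarative mapping specs naming the subject/object columns and
types, the emitted relation, and optional constant row filters. Rows whose
surfaces do not normalize to concepts of the declared type are counted and
itemized, never silently dropped; emitted + skipped always equals the row
count. Row-level provenance uses 1-based data-row numbers. Relevance
filtering inside a source is expressed with the constant-filter mechanism
rather than hard-coded.

## The synthetic corpus generator

Because the original corpora (2006-era literature and database snapshots)
cannot be reconstructed, the generator plants a known truth set and
realizes each triple in template sentences (≈6 frames, sentence-cased so
documents segment back into the emitted sentences), with synonym-varied
surfaces and both directions of invertible relations. Noise comes from two
dials: `distractor_rate` (vocabulary terms with a non-lexicon verb) and
`negation_rate` (a cue inserted before an otherwise intact relation
phrase). A `table_share` fraction of the truth is emitted as structured
rows with ready mapping specs instead of text. Generation is fully seeded
and byte-reproducible.

What this emulates is the *mechanics* of assertion-bearing prose: synonym
variation, nested terms, negation, irrelevant co-mentions. What it does not
emulate is real Medline style — long coordinated clauses, anaphora,
hedging, cross-sentence assertions. Perfect precision/recall on clean
synthetic corpora therefore demonstrates that the pipeline is lossless on
in-scope constructions, not that it would achieve such figures on real
abstracts; the original workflow interposed manual curation precisely
because it would not.

## Validation statistics

The validation pattern for assayed candidates is reproduced as three
operations:

* `anova_oneway()` — standard one-way decomposition via `stats::lm/anova`,
  with explicit handling of degenerate inputs (all observations equal gives
  F = 0, p = 1; zero within-group variance with non-zero between-group
  variance is a typed error rather than an infinite F).
* `anova_from_summary()` — the same test from printed per-group (n, mean,
  SD): between-SS from group means about the weighted grand mean, within-SS
  as Σ(nᵢ−1)sᵢ². The suite verifies exact agreement (1e-10 relative) with
  the raw-data route on random tables. On the shipped PLAUR plasma group
  summaries (82/80/78 subjects) this gives F(2, 237) ≈ 30.0, p < 0.001.
* `spearman_cor()` — Pearson correlation of midranks (average ranks on
  ties). The two-sided p-value is an exact permutation enumeration for
  n ≤ 8 (the full n! scan is cheap there and exact under ties) and the t
  approximation t = ρ√((n−2)/(1−ρ²)) above, which is standard practice at
  the validation study's group sizes (~80). The enumeration bound sits at 8
  rather than 10 because full enumeration at n = 9–10 costs 10⁵–10⁶× more
  for no practical gain.

Normality is checked with a Kolmogorov–Smirnov statistic against a normal
fitted by sample mean/SD, with the p-value from seeded Monte-Carlo
simulation under the fitted null (the Lilliefors correction). A
re-implemented Shapiro–Wilk would add nothing — the original analysis used
normality tests only as a preliminary gate — so the package ships the
KS/Monte-Carlo gate only, and the tests cross-check the statistic against
an independent reference implementation.

## The golden derivation fixture

The shipped fixture network pads the 25 candidate proteins with 35 clearly
synthetic ones (`SYNP26`…), assigns expression assertions to 40 proteins,
upregulation to 30 and pathology links to exactly the 25 candidates, so the
filter chain audits 40 → 30 → 25 and ends at the candidate set. Seven
candidates carry biomarker-claim assertions tagged with a claims source, so
novelty assessment flags the remaining 18 (including PLAUR and CHAT) as
novel. Assignment is deterministic (round-robin), so the fixture needs no
seed; a shuffle seed exists only to demonstrate insertion-order
independence.

## Numerical and design choices

* **Determinism.** All ordering uses C-locale radix sorting; exports sort
  rows (and provenance within rows) before writing, so equal networks give
  byte-identical bundles.
* **Evidence threshold.** Each filter requires ≥ 1 supporting assertion
  (existence, not weight); a configurable minimum is exposed.
* **Novelty abstention.** With no tagged biomarker-claim sources, novelty
  is `NA`, never `TRUE`: silent false novelty is worse than abstention.
* **Problem sizes.** The shipped test suite and acceptance script use
  200-document corpora (1000 sentences), a 102-assertion golden network and
  500-replicate QC calibration — sizes chosen so the full pipeline
  (generate → extract → merge → derive) is exercised end-to-end in about a
  minute on one CPU while leaving every rate estimate with narrow enough
  Monte-Carlo error to be meaningful.
* **QC calibration.** The Clopper–Pearson interval is conservative, so
  coverage of a true 0.97 accuracy across seeded runs sits above the
  nominal 95% (observed ≈ 97%); the suite asserts ≥ 93%.

## Known limitations

* No machine-learned NER or relation classification, no coreference, no
  cross-sentence assertions — by design.
* The extractor is recall-oriented within its patterns but blind to syntax:
  `"X is expressed in A, not B"` still yields X→B's suppression only when a
  cue precedes the relation; post-relation negation survives to curation.
* The relation lexicon and pattern set are a declared approximation of the
  original platform's undisclosed noun-phrase patterns.
* Scale: the 2006 network's headline counts (thousands of proteins, tens of
  thousands of assertions) depended on proprietary-era database snapshots
  and are not reproducible from this package's fixtures; the fixtures
  reproduce the *shape* of the workflow, not its scale.

## A worked run

```{r pipeline}
g <- ad_golden_network()
truth <- g$truth[, c("subject_id", "relation", "object_id")]

cfg <- generator_config(n_docs = 60, sentences_per_doc = 5,
                        distractor_rate = 0.2, negation_rate = 0.1,
                        seed = 42)
corpus <- generate_corpus(truth, g$vocab, g$lexicon, cfg)

protos <- extract_corpus(corpus$documents, compile_matcher(g$vocab),
                         g$lexicon)
score_extraction(corpus$gold, protos)

net <- merge_assertions(intelligence_network(g$vocab), accept_all(protos))
candidates <- derive_candidates(net, derivation_config(
  net, g$config$region_ids, g$config$disease_ids, g$config$pathology_ids,
  biomarker_sources = "telemakus"))
glance(candidates)
```

```{r anova}
glance(anova_from_summary(plaur_group_summaries()))
```
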