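# Shipped Alzheimer's disease fixtures: the sample concept vocabularies
# (disease sub-types, pathological observations, brain regions), the
# 25-protein candidate set with aliases, the relation lexicon, and a golden
# network engineered so the derivation chain runs 40 -> 30 -> 25.

extdata <- function(name) {
  system.file("extdata", name, package = "assertnet", mustWork = TRUE)
}

#' Alzheimer's disease concept vocabulary (diseases, pathology, regions)
#'
#' 13 disease sub-type, 44 pathological-observation and 26 brain-region
#' concepts with curated synonyms.
#'
#' @return An `in_vocabulary`.
#' @export
ad_concept_vocabulary <- function() {
  load_vocabulary(extdata("ad_vocabulary.tsv"))
}

#' The 25 candidate biomarker proteins with common aliases
#'
#' @return An `in_vocabulary` of `PROTEIN_OR_MRNA` concepts.
#' @export
ad_protein_vocabulary <- function() {
  load_vocabulary(extdata("ad_proteins.tsv"))
}

#' Synthetic padding proteins for scale fixtures
#'
#' Clearly synthetic protein concepts (`SYNP26`, `SYNP27`, ...) used to pad
#' networks beyond the 25 shipped candidates.
#'
#' @param n Number of synthetic proteins.
#' @param from First index in the label (default 26, so labels continue the
#'   candidate numbering).
#' @return An `in_vocabulary`.
#' @export
synthetic_protein_vocabulary <- function(n = 35L, from = 26L) {
  ids <- sprintf("synp%02d", seq(from, length.out = n))
  vocabulary(tibble(
    concept_id = ids, type = "PROTEIN_OR_MRNA",
    preferred_label = toupper(ids),
    synonym = sprintf("synthetic protein %02d", seq(from, length.out = n))
  ))
}

#' Combined fixture vocabulary (concepts + 25 proteins [+ synthetic padding])
#'
#' @param synthetic_proteins Number of synthetic padding proteins to append
#'   (default 0).
#' @return An `in_vocabulary`.
#' @export
ad_vocabulary <- function(synthetic_proteins = 0L) {
  if (synthetic_proteins > 0L) {
    combine_vocabularies(ad_concept_vocabulary(), ad_protein_vocabulary(),
                         synthetic_protein_vocabulary(synthetic_proteins))
  } else {
    combine_vocabularies(ad_concept_vocabulary(), ad_protein_vocabulary())
  }
}

#' Relation lexicon fixture
#'
#' Canonical verb phrases for pathology links, expression, upregulation,
#' disease links and pathway membership, with synonymous surface forms.
#'
#' @return An `in_relation_lexicon`.
#' @export
ad_relation_lexicon <- function() {
  load_relations(extdata("ad_relations.tsv"))
}

# deterministic assignment helpers for the golden network
cycle <- function(x, i) x[((i - 1L) %% length(x)) + 1L]

#' Golden derivation fixture: a network engineered to filter 40 -> 30 -> 25
#'
#' Builds a network over the fixture vocabulary padded to 60 proteins.
#' Forty proteins (the 25 candidates plus 15 synthetic ones) carry
#' region-expression assertions; of these, 30 (25 + 5) carry upregulation
#' assertions in Alzheimer's disease; of these, exactly the 25 candidate
#' proteins carry pathology-link assertions, so the filter chain ends at the
#' candidate set. Seven proteins previously described as biomarkers carry
#' tagged disease-link claims (source `"telemakus"`), so novelty assessment
#' flags the remainder (including PLAUR and CHAT) as novel. Assertion
#' assignment is deterministic (round-robin over regions, diseases and
#' pathologies).
#'
#' @param shuffle_seed Optional integer: when given, assertion insertion
#'   order is permuted with this seed before merging (the resulting network
#'   is identical — useful for order-independence checks).
#' @return A list with `net` (`intelligence_network`), `vocab`, `lexicon`,
#'   `config` (ready `in_derivation_config`), and `truth` (the assertion
#'   tibble the network was built from).
#' @export
ad_golden_network <- function(shuffle_seed = NULL) {
  vocab <- ad_vocabulary(synthetic_proteins = 35L)
  lexicon <- ad_relation_lexicon()
  con <- vocab$concepts
  proteins_real <- sort(con$concept_id[con$type == "PROTEIN_OR_MRNA" &
                                         !grepl("^synp", con$concept_id)],
                        method = "radix")
  proteins_syn <- sort(con$concept_id[grepl("^synp", con$concept_id)],
                       method = "radix")
  stopifnot(length(proteins_real) == 25L, length(proteins_syn) == 35L)
  regions <- sort(con$concept_id[con$type == "ANATOMICAL_STRUCTURE"],
                  method = "radix")
  pathologies <- sort(con$concept_id[con$type == "PATHOLOGICAL_OBSERVATION"],
                      method = "radix")
  ad <- "alzheimer-s-disease"

  expressed <- c(proteins_real, proteins_syn[1:15])      # 40
  upregulated <- c(proteins_real, proteins_syn[1:5])     # 30
  pathology_linked <- proteins_real                      # 25
  known_biomarkers <- c("clu", "ttr", "apoe", "crp", "c1qb", "bche", "bace1")

  mk <- function(subject, class, relation, object, source, doc) {
    tibble(doc_id = doc, source = source, sentence_index = 0L,
           subject_id = subject, relation_class = class, relation = relation,
           object_id = object, subject_surface = subject,
           object_surface = object, inverted = FALSE,
           pattern_id = "fixture", status = "ACCEPTED",
           snippet = paste(subject, relation, object))
  }
  rows <- list()
  for (i in seq_along(expressed)) {
    rows <- c(rows, list(mk(expressed[i], "EXPRESSION", "IS EXPRESSED IN",
                            cycle(regions, i), "pubmed",
                            sprintf("pmid-e%03d", i))))
  }
  for (i in seq_along(upregulated)) {
    rel <- cycle(c("IS INCREASED IN", "IS HIGHER IN", "IS UPREGULATED IN"), i)
    rows <- c(rows, list(mk(upregulated[i], "UPREGULATION", rel, ad, "geo",
                            sprintf("gse-u%03d", i))))
  }
  for (i in seq_along(pathology_linked)) {
    rel <- cycle(c("IS INVOLVED IN", "LEADS TO", "RESULTS IN"), i)
    rows <- c(rows, list(mk(pathology_linked[i], "PATHOLOGY_LINK", rel,
                            cycle(pathologies, i), "pubmed",
                            sprintf("pmid-p%03d", i))))
  }
  for (i in seq_along(known_biomarkers)) {
    rows <- c(rows, list(mk(known_biomarkers[i], "DISEASE_LINK",
                            "IS ASSOCIATED WITH", ad, "telemakus",
                            sprintf("tk-%03d", i))))
  }
  assertions <- bind_rows(rows)
  if (!is.null(shuffle_seed)) {
    assertions <- withr::with_seed(
      as.integer(shuffle_seed),
      assertions[sample.int(nrow(assertions)), ])
  }
  net <- merge_assertions(intelligence_network(vocab), assertions)
  config <- derivation_config(
    net,
    region_ids = regions,
    disease_ids = sort(con$concept_id[con$type == "DISEASE"],
                       method = "radix"),
    pathology_ids = pathologies,
    biomarker_sources = "telemakus"
  )
  list(net = net, vocab = vocab, lexicon = lexicon, config = config,
       truth = assertions)
}

#' Printed PLAUR plasma group summaries from the validation study
#'
#' Integrated-intensity summaries (arbitrary units, loading-corrected) for
#' the three diagnostic groups: controls n = 82, mean 1.63 (SD 0.9); mild
#' cognitive impairment n = 80, mean 0.98 (SD 0.7); Alzheimer's disease
#' n = 78, mean 0.85 (SD 0.3).
#'
#' @return A tibble `label`, `n`, `mean`, `sd` for [anova_from_summary()].
#' @export
plaur_group_summaries <- function() {
  tibble(label = c("Control", "MCI", "AD"),
         n = c(82L, 80L, 78L),
         mean = c(1.63, 0.98, 0.85),
         sd = c(0.9, 0.7, 0.3))
}

#' Printed ChAt plasma group summaries from the validation study
#'
#' @return A tibble `label`, `n`, `mean`, `sd` for [anova_from_summary()].
#' @export
chat_group_summaries <- function() {
  tibble(label = c("Control", "MCI", "AD"),
         n = c(82L, 80L, 78L),
         mean = c(0.78, 0.75, 0.71),
         sd = c(0.3, 0.3, 0.3))
}
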