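# Synthetic-corpus generation, gold annotation and extraction scoring.

small_truth <- function() {
  g <- ad_golden_network()
  list(g = g, truth = g$truth[, c("subject_id", "relation", "object_id")])
}

test_that("generation is byte-identical under one config and seed", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 25, sentences_per_doc = 5,
                          distractor_rate = 0.2, negation_rate = 0.1,
                          seed = 13)
  a <- generate_corpus(s$truth, s$g$vocab, s$g$lexicon, cfg)
  b <- generate_corpus(s$truth, s$g$vocab, s$g$lexicon, cfg)
  expect_identical(a$documents, b$documents)
  expect_identical(a$gold, b$gold)
})

test_that("zero documents yield an empty corpus and gold", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 0, seed = 1)
  out <- generate_corpus(s$truth, s$g$vocab, s$g$lexicon, cfg)
  expect_equal(nrow(out$documents), 0L)
  expect_equal(nrow(out$gold), 0L)
})

test_that("every text truth triple is realized and gold records its sentence", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 25, sentences_per_doc = 5, seed = 3)
  out <- generate_corpus(s$truth, s$g$vocab, s$g$lexicon, cfg)
  key <- function(d) paste(d$subject_id, d$relation, d$object_id)
  expect_setequal(unique(key(out$gold)), unique(key(s$truth)))
  # gold surfaces occur in the recorded sentence
  docs <- out$documents
  idx <- withr::with_seed(1, sample.int(nrow(out$gold), 25))
  for (i in idx) {
    gold <- out$gold[i, ]
    sents <- segment_sentences(docs$text[docs$doc_id == gold$doc_id])
    sent <- sents$sentence[sents$sentence_index == gold$sentence_index]
    expect_true(grepl(tolower(gold$subject_surface), tolower(sent),
                      fixed = TRUE))
    expect_true(grepl(tolower(gold$object_surface), tolower(sent),
                      fixed = TRUE))
  }
})

test_that("unknown concepts or relations in the truth set are typed errors", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 5, seed = 1)
  bad <- s$truth[1, ]; bad$subject_id <- "unobtainium"
  expect_error(generate_corpus(bad, s$g$vocab, s$g$lexicon, cfg),
               "unobtainium", class = "assertnet_error_config")
  bad <- s$truth[1, ]; bad$relation <- "ORBITS"
  expect_error(generate_corpus(bad, s$g$vocab, s$g$lexicon, cfg),
               class = "assertnet_error_config")
})

test_that("table_share diverts truth into ingestible structured tables", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 30, sentences_per_doc = 5,
                          table_share = 0.25, seed = 9)
  out <- generate_corpus(s$truth, s$g$vocab, s$g$lexicon, cfg)
  expect_true(length(out$tables) > 0)
  n_table_rows <- sum(vapply(out$tables, function(t) nrow(t$table),
                             integer(1)))
  expect_equal(n_table_rows, floor(0.25 * nrow(s$truth)))
  # tables ingest back to their triples
  for (t in out$tables) {
    res <- ingest_table(t$table, t$mapping, s$g$vocab)
    expect_equal(nrow(res$skipped), 0L)
    expect_true(all(res$assertions$relation == t$mapping$relation))
  }
})

test_that("scoring arithmetic matches the confusion counts", {
  gold <- tibble::tibble(doc_id = sprintf("d%02d", 1:10), sentence_index = 0L,
                         subject_id = "chat", relation = "IS EXPRESSED IN",
                         object_id = "hippocampus")
  protos <- gold[c(1:9, 1:3), ]   # 9 correct (dups collapse), plus 3 fabricated
  protos$object_id[10:12] <- "thalamus"
  sc <- score_extraction(gold, protos)
  expect_equal(sc$tp, 9L)
  expect_equal(sc$fp, 3L)
  expect_equal(sc$fn, 1L)
  expect_equal(sc$precision, 0.75)
  expect_equal(sc$recall, 0.9)
  expect_equal(sc$f1, 2 * 0.75 * 0.9 / (0.75 + 0.9))
  expect_identical(score_extraction(gold, gold)$f1, 1)
  empty <- score_extraction(gold, protos[0, ])
  expect_true(is.na(empty$precision))
  expect_equal(empty$recall, 0)
})

test_that("negation-only corpora extract nothing (cue rule holds)", {
  s <- small_truth()
  cfg <- generator_config(n_docs = 10, sentences_per_doc = 3,
                          negation_rate = 0.85, seed = 17)
  out <- generate_corpus(s$truth[1:5, ], s$g$vocab, s$g$lexicon, cfg)
  protos <- extract_corpus(out$documents, compile_matcher(s$g$vocab),
                           s$g$lexicon)
  sc <- score_extraction(out$gold, protos)
  expect_true(is.na(sc$precision) || sc$precision == 1)
})
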