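# Sentence segmentation, proto-assertion extraction and curation routing.

fix <- local({
  v <- ad_vocabulary()
  list(v = v, m = compile_matcher(v), lx = ad_relation_lexicon(),
       pats = default_patterns())
})

ex <- function(sentence) {
  extract_proto_assertions(fix$m, fix$lx, fix$pats, "d1", "pubmed", 0L,
                           sentence)
}

test_that("segmentation splits on terminator + capital and keeps offsets", {
  s <- segment_sentences("A. B. is here. Next one.")
  expect_equal(s$sentence, c("A.", "B. is here.", "Next one."))
  expect_equal(nrow(segment_sentences("no terminator at all")), 1L)
  expect_equal(nrow(segment_sentences("   \t ")), 0L)
  # offsets reconstruct the document
  txt <- "First sentence. Second one! Third?  Done."
  seg <- segment_sentences(txt)
  for (i in seq_len(nrow(seg))) {
    expect_equal(substr(txt, seg$start[i] + 1L,
                        seg$start[i] + nchar(seg$sentence[i])),
                 seg$sentence[i])
  }
})

test_that("canonical example sentences extract the expected triples", {
  p <- ex("BACE-1 is involved in amyloid formation.")
  expect_equal(nrow(p), 1L)
  expect_equal(p$subject_id, "bace1")
  expect_equal(p$relation, "IS INVOLVED IN")
  expect_equal(p$object_id, "amyloid-fibril-formation")
  expect_equal(p$status, "PROTO")

  p <- ex("Amyloid deposition is associated with Alzheimer's disease.")
  expect_equal(p$subject_id, "amyloid-deposition")
  expect_equal(p$relation, "IS ASSOCIATED WITH")
  expect_equal(p$object_id, "alzheimer-s-disease")
})

test_that("negation cues before the relation suppress extraction", {
  expect_equal(nrow(ex("BACE1 is not increased in Alzheimer's disease.")), 0L)
  expect_equal(nrow(ex("There is no evidence that BACE1 is increased in Alzheimer's disease.")), 0L)
  expect_equal(nrow(ex("We never observed that CLU is expressed in hippocampus.")), 0L)
  # cue after the relation does not suppress
  p <- ex("CLU is expressed in hippocampus, not thalamus.")
  expect_true(nrow(p) >= 1L)
})

test_that("inverse surface forms are canonicalized protein -> structure", {
  p <- ex("The hippocampus expresses CHAT.")
  expect_equal(p$subject_id, "chat")
  expect_equal(p$relation, "IS EXPRESSED IN")
  expect_equal(p$object_id, "hippocampus")
  expect_true(p$inverted)
})

test_that("token gaps beyond the pattern bound block pairing", {
  pats <- default_patterns(max_gap_tokens = 2L)
  far <- "CLU, a protein of great interest to the field, is expressed in hippocampus."
  p <- extract_proto_assertions(fix$m, fix$lx, pats, "d1", "s", 0L, far)
  expect_equal(nrow(p), 0L)
  p <- extract_proto_assertions(fix$m, fix$lx, fix$pats, "d1", "s", 0L, far)
  expect_equal(nrow(p), 1L)
})

test_that("type-incompatible pairings are rejected", {
  # disease cannot be 'expressed in' a region under the network map
  p <- ex("Alzheimer's disease is expressed in hippocampus.")
  expect_equal(nrow(p), 0L)
})

test_that("provenance snippets contain both mention surfaces", {
  g <- ad_golden_network()
  cfg <- generator_config(n_docs = 10, sentences_per_doc = 4, seed = 21,
                          distractor_rate = 0.2)
  corp <- generate_corpus(g$truth[1:30, c("subject_id", "relation",
                                          "object_id")],
                          g$vocab, g$lexicon, cfg)
  protos <- extract_corpus(corp$documents, compile_matcher(g$vocab),
                           g$lexicon)
  expect_true(nrow(protos) > 0)
  expect_true(all(mapply(grepl, protos$subject_surface, protos$snippet,
                         MoreArgs = list(fixed = TRUE))))
  expect_true(all(mapply(grepl, protos$object_surface, protos$snippet,
                         MoreArgs = list(fixed = TRUE))))
})

test_that("extraction is deterministic across repeated runs", {
  g <- ad_golden_network()
  cfg <- generator_config(n_docs = 8, sentences_per_doc = 4, seed = 5)
  corp <- generate_corpus(g$truth[1:20, c("subject_id", "relation",
                                          "object_id")],
                          g$vocab, g$lexicon, cfg)
  m <- compile_matcher(g$vocab)
  a <- extract_corpus(corp$documents, m, g$lexicon)
  b <- extract_corpus(corp$documents, m, g$lexicon)
  expect_identical(a, b)
})

test_that("curation routes protos into accept/reject/undecided buckets", {
  protos <- dplyr::bind_rows(lapply(1:5, function(i) {
    p <- ex("BACE-1 is involved in amyloid formation.")
    p$doc_id <- paste0("d", i)
    p
  }))
  dec <- tibble::tibble(
    subject_id = "bace1", relation = "IS INVOLVED IN",
    object_id = "amyloid-fibril-formation",
    doc_id = c("d1", "d2", "d3", "d4", "d5"),
    sentence_index = 0L,
    decision = c("accept", "accept", "accept", "reject", "reject"))
  res <- apply_curation(protos, dec[1:5, ])
  expect_equal(nrow(res$accepted), 3L)
  expect_equal(nrow(res$rejected), 2L)
  expect_equal(nrow(res$undecided), 0L)
  expect_true(all(res$accepted$status == "ACCEPTED"))
  expect_true(all(res$rejected$status == "REJECTED"))

  res <- apply_curation(protos, dec[0, ])
  expect_equal(nrow(res$undecided), 5L)

  bad <- dec[c(1, 1), ]
  bad$decision <- c("accept", "reject")
  expect_error(apply_curation(protos, bad), "contradictory",
               class = "assertnet_error_curation")

  orphan <- dec[1, ]
  orphan$doc_id <- "nonexistent"
  expect_warning(apply_curation(protos, orphan), "no proto")
})
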