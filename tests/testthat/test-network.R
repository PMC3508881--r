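# Intelligence-network merge semantics, querying, stats and serialization.

small_net <- function() {
  v <- ad_vocabulary()
  mk <- function(subj, class, rel, obj, src, doc) tibble::tibble(
    doc_id = doc, source = src, sentence_index = 0L, subject_id = subj,
    relation_class = class, relation = rel, object_id = obj,
    subject_surface = subj, object_surface = obj, inverted = FALSE,
    pattern_id = "t", status = "ACCEPTED", snippet = paste(subj, rel, obj))
  a <- dplyr::bind_rows(
    mk("chat", "EXPRESSION", "IS EXPRESSED IN", "hippocampus", "pubmed", "d1"),
    mk("plaur", "UPREGULATION", "IS INCREASED IN", "alzheimer-s-disease",
       "geo", "d2"),
    mk("bace1", "PATHOLOGY_LINK", "IS INVOLVED IN", "amyloid-fibril-formation",
       "pubmed", "d3"))
  list(v = v, a = a, net = merge_assertions(intelligence_network(v), a))
}

test_that("identical triples from different sources merge with provenance union", {
  s <- small_net()
  dup <- s$a[1, ]
  dup$source <- "omim"; dup$doc_id <- "42"
  net <- merge_assertions(s$net, dup)
  expect_equal(nrow(net$assertions), 3L)
  q <- query_assertions(net, subject_type = "PROTEIN_OR_MRNA",
                        relation_class = "EXPRESSION")
  expect_equal(q$n_provenance, 2L)
})

test_that("merge is idempotent, order-independent, and identity on empty input", {
  s <- small_net()
  expect_true(networks_equal(s$net, merge_assertions(s$net, s$a)))
  expect_true(networks_equal(s$net, merge_assertions(s$net, s$a[0, ])))
  perm <- merge_assertions(intelligence_network(s$v), s$a[c(3, 1, 2), ])
  expect_true(networks_equal(s$net, perm))
})

test_that("non-accepted assertions and unknown concepts are rejected", {
  s <- small_net()
  bad <- s$a[1, ]; bad$status <- "PROTO"
  expect_error(merge_assertions(s$net, bad), class = "assertnet_error_status")
  bad <- s$a[1, ]; bad$subject_id <- "martian-protein"
  expect_error(merge_assertions(s$net, bad), "martian-protein",
               class = "assertnet_error_concept")
})

test_that("queries respect every constraint and empty object sets", {
  s <- small_net()
  q <- query_assertions(s$net, subject_type = "PROTEIN_OR_MRNA",
                        relation_class = "EXPRESSION",
                        object_ids = "hippocampus")
  expect_equal(nrow(q), 1L)
  expect_equal(q$subject_id, "chat")
  expect_equal(nrow(query_assertions(s$net)), 3L)
  expect_equal(nrow(query_assertions(s$net, object_ids = character(0))), 0L)
})

test_that("network stats agree with direct enumeration", {
  s <- small_net()
  st <- network_stats(s$net)
  expect_equal(st$n_assertions, nrow(query_assertions(s$net)))
  expect_equal(sum(st$assertions_by_class$n_assertions), st$n_assertions)
  expect_equal(st$concepts_by_type$n_concepts[
    st$concepts_by_type$type == "PROTEIN_OR_MRNA"], 25L)
  empty <- network_stats(intelligence_network(s$v))
  expect_equal(empty$n_assertions, 0L)
  expect_equal(nrow(empty$assertions_by_class), 0L)
})

test_that("export/import round-trips and exports are byte-identical", {
  g <- ad_golden_network()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  export_network(g$net, d1)
  back <- import_network(d1)
  expect_true(networks_equal(g$net, back))
  # byte-identical regardless of insertion order
  g2 <- ad_golden_network(shuffle_seed = 123)
  export_network(g2$net, d2)
  expect_identical(readLines(file.path(d1, "assertions.jsonl")),
                   readLines(file.path(d2, "assertions.jsonl")))
  expect_identical(readLines(file.path(d1, "concepts.tsv")),
                   readLines(file.path(d2, "concepts.tsv")))
})

test_that("truncated bundles fail with a parse error naming the line", {
  g <- ad_golden_network()
  d <- withr::local_tempdir()
  export_network(g$net, d)
  lines <- readLines(file.path(d, "assertions.jsonl"))
  lines[5] <- substr(lines[5], 1, 20)
  writeLines(lines, file.path(d, "assertions.jsonl"))
  expect_error(import_network(d), "line 5", class = "assertnet_error_parse")
})
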