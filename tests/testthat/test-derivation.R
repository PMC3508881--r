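# The filter-chain derivation workflow and novelty assessment.

test_that("the golden fixture derives 40 -> 30 -> 25 ending at the candidate set", {
  g <- ad_golden_network()
  ct <- derive_candidates(g$net, g$config)
  expect_equal(ct$steps$n, c(40L, 30L, 25L))
  real <- g$vocab$concepts[g$vocab$concepts$type == "PROTEIN_OR_MRNA" &
                             !grepl("^synp", g$vocab$concepts$concept_id), ]
  expect_setequal(ct$candidates$symbol, real$preferred_label)
  # monotone chain
  expect_true(all(ct$steps$proteins[[2]] %in% ct$steps$proteins[[1]]))
  expect_true(all(ct$steps$proteins[[3]] %in% ct$steps$proteins[[2]]))
})

test_that("every candidate carries supporting assertion keys for all criteria", {
  g <- ad_golden_network()
  ct <- derive_candidates(g$net, g$config)
  expect_true(all(ct$candidates$n_expression >= 1L))
  expect_true(all(ct$candidates$n_upregulation >= 1L))
  expect_true(all(ct$candidates$n_pathology >= 1L))
  # keys resolve back to network triples
  all_keys <- paste(g$net$assertions$subject_id, g$net$assertions$relation,
                    g$net$assertions$object_id, sep = " | ")
  for (keys in c(ct$candidates$support_expression,
                 ct$candidates$support_upregulation,
                 ct$candidates$support_pathology)) {
    expect_true(all(keys %in% all_keys))
  }
})

test_that("novelty flags proteins without tagged biomarker claims", {
  g <- ad_golden_network()
  ct <- derive_candidates(g$net, g$config)
  cand <- ct$candidates
  expect_true(cand$novel[cand$symbol == "PLAUR"])
  expect_true(cand$novel[cand$symbol == "CHAT"])
  expect_false(cand$novel[cand$symbol == "CLU"])
  expect_equal(cand$n_biomarker_claims[cand$symbol == "CLU"], 1L)
  # untagged config -> indeterminate, not novel
  cfg2 <- derivation_config(g$net, g$config$region_ids, g$config$disease_ids,
                            g$config$pathology_ids,
                            biomarker_sources = NULL)
  nv <- assess_novelty(g$net, cand$protein_id, cfg2)
  expect_true(all(is.na(nv$novel)))
})

test_that("derivation output is identical under permuted assertion insertion", {
  g <- ad_golden_network()
  g2 <- ad_golden_network(shuffle_seed = 77)
  a <- derive_candidates(g$net, g$config)
  b <- derive_candidates(g2$net, g2$config)
  expect_identical(a$steps, b$steps)
  expect_identical(a$candidates, b$candidates)
})

test_that("empty networks derive empty chains", {
  g <- ad_golden_network()
  empty <- intelligence_network(g$vocab)
  ct <- derive_candidates(empty, derivation_config(
    empty, g$config$region_ids, g$config$disease_ids,
    g$config$pathology_ids))
  expect_equal(ct$steps$n, c(0L, 0L, 0L))
  expect_equal(nrow(ct$candidates), 0L)
})

test_that("derive_candidates equals a brute-force triple scan on random networks", {
  g <- ad_golden_network()
  for (seed in 1:10) {
    a <- random_fixture_assertions(g$vocab, n = 20L + (seed * 7L) %% 81L,
                                   seed = seed)
    net <- merge_assertions(intelligence_network(g$vocab), a)
    cfg <- derivation_config(net, g$config$region_ids, g$config$disease_ids,
                             g$config$pathology_ids)
    want <- oracle_derive_sets(net, cfg)
    ct <- derive_candidates(net, cfg)
    expect_equal(ct$steps$proteins[[1]], want$s1)
    expect_equal(ct$steps$proteins[[2]], want$s2)
    expect_equal(ct$steps$proteins[[3]], want$s3)
    expect_equal(ct$candidates$protein_id, want$s3)
  }
})

test_that("config validation rejects unknown ids and empty sets", {
  g <- ad_golden_network()
  expect_error(derivation_config(g$net, character(0), g$config$disease_ids,
                                 g$config$pathology_ids),
               class = "assertnet_error_config")
  expect_error(derivation_config(g$net, c(g$config$region_ids, "atlantis"),
                                 g$config$disease_ids,
                                 g$config$pathology_ids),
               "atlantis", class = "assertnet_error_config")
})
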