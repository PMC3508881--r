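# Independent oracles used across the suite. Each is a deliberately naive
# re-derivation (brute force / closed form) kept separate from the package's
# own code paths.

# enumerate every synonym span in a sentence, then apply greedy
# longest-then-leftmost selection "by hand"
oracle_match <- function(vocab, sentence) {
  toks <- tokenize(sentence)
  n <- nrow(toks)
  keys <- unique(vocab$synonyms$key)
  cands <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      key <- paste(toks$token[i:j], collapse = " ")
      if (key %in% keys) {
        ids <- sort(unique(vocab$synonyms$concept_id[
          vocab$synonyms$key == key]), method = "radix")
        cands[[length(cands) + 1]] <- list(i = i, j = j, ids = ids)
      }
    }
  }
  chosen <- list()
  used <- rep(FALSE, n)
  repeat {
    best <- NULL
    for (c in cands) {
      if (any(used[c$i:c$j])) next
      if (is.null(best) ||
          (c$j - c$i) > (best$j - best$i) ||
          ((c$j - c$i) == (best$j - best$i) && c$i < best$i)) {
        best <- c
      }
    }
    if (is.null(best)) break
    chosen[[length(chosen) + 1]] <- best
    used[best$i:best$j] <- TRUE
  }
  ord <- order(vapply(chosen, `[[`, integer(1), "i"))
  chosen[ord]
}

# one-way ANOVA via explicit sum-of-squares loops
oracle_anova <- function(groups, values) {
  g <- unique(groups)
  grand <- mean(values)
  ssb <- 0; ssw <- 0
  for (gi in g) {
    v <- values[groups == gi]
    ssb <- ssb + length(v) * (mean(v) - grand)^2
    ssw <- ssw + sum((v - mean(v))^2)
  }
  dfb <- length(g) - 1
  dfw <- length(values) - length(g)
  f <- (ssb / dfb) / (ssw / dfw)
  list(F = f, p = stats::pf(f, dfb, dfw, lower.tail = FALSE))
}

# Spearman rho as Pearson correlation of rank() vectors
oracle_spearman_rho <- function(x, y) {
  stats::cor(rank(x), rank(y))
}

# brute-force triple scan implementing the filter chain independently of
# query_assertions / derive_candidates
oracle_derive_sets <- function(net, config) {
  a <- net$assertions
  types <- stats::setNames(net$concepts$type, net$concepts$concept_id)
  is_prot <- function(id) types[[id]] == "PROTEIN_OR_MRNA"
  s1 <- character(0)
  for (i in seq_len(nrow(a))) {
    if (a$relation_class[i] == "EXPRESSION" && is_prot(a$subject_id[i]) &&
        a$object_id[i] %in% config$region_ids) {
      s1 <- union(s1, a$subject_id[i])
    }
  }
  s2 <- character(0)
  for (i in seq_len(nrow(a))) {
    if (a$relation_class[i] == "UPREGULATION" && is_prot(a$subject_id[i]) &&
        a$subject_id[i] %in% s1 && a$object_id[i] %in% config$disease_ids) {
      s2 <- union(s2, a$subject_id[i])
    }
  }
  s3 <- character(0)
  for (i in seq_len(nrow(a))) {
    if (a$relation_class[i] == "PATHOLOGY_LINK" && is_prot(a$subject_id[i]) &&
        a$subject_id[i] %in% s2 && a$object_id[i] %in% config$pathology_ids) {
      s3 <- union(s3, a$subject_id[i])
    }
  }
  list(s1 = sort(s1, method = "radix"), s2 = sort(s2, method = "radix"),
       s3 = sort(s3, method = "radix"))
}

# small random network over the golden fixture's concepts for property tests
random_fixture_assertions <- function(vocab, n, seed) {
  con <- vocab$concepts
  prot <- con$concept_id[con$type == "PROTEIN_OR_MRNA"]
  reg <- con$concept_id[con$type == "ANATOMICAL_STRUCTURE"]
  dis <- con$concept_id[con$type == "DISEASE"]
  pat <- con$concept_id[con$type == "PATHOLOGICAL_OBSERVATION"]
  withr::with_seed(seed, {
    cls <- sample(c("EXPRESSION", "UPREGULATION", "PATHOLOGY_LINK"), n,
                  replace = TRUE)
    rel <- c(EXPRESSION = "IS EXPRESSED IN", UPREGULATION = "IS INCREASED IN",
             PATHOLOGY_LINK = "IS INVOLVED IN")[cls]
    obj <- vapply(cls, function(cl) {
      switch(cl, EXPRESSION = sample(reg, 1), UPREGULATION = sample(dis, 1),
             PATHOLOGY_LINK = sample(pat, 1))
    }, character(1))
    tibble::tibble(
      doc_id = sprintf("r%03d", seq_len(n)), source = "random",
      sentence_index = 0L, subject_id = sample(prot, n, replace = TRUE),
      relation_class = unname(cls), relation = unname(rel),
      object_id = unname(obj), subject_surface = "s", object_surface = "o",
      inverted = FALSE, pattern_id = "fixture", status = "ACCEPTED",
      snippet = "s o")
  })
}
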