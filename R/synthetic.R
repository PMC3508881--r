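# Seeded synthetic-corpus generator: realizes a planted truth set of
# assertions as template sentences (with synonym variation, distractor and
# negated sentences), optionally diverting a share of the truth into
# structured tables, and scores extraction output against the gold records.

TRUTH_FRAMES <- c(
  "{S} {R} {O}.",
  "It is known that {S} {R} {O}.",
  "Recent studies show that {S} {R} {O}.",
  "We report that {S} {R} {O}.",
  "{S} {R} {O}, according to several reports.",
  "{S} {R} {O} in post-mortem tissue."
)

NEGATED_FRAMES <- c(
  "There is no evidence that {S} {R} {O}.",
  "It is not the case that {S} {R} {O}.",
  "We never observed that {S} {R} {O}."
)

DISTRACTOR_FRAMES <- c(
  "{A} was measured alongside {B}.",
  "{A} and {B} were examined in this study.",
  "The relevance of {A} to {B} remains unclear."
)

#' Configuration for the synthetic-corpus generator
#'
#' @param n_docs Number of documents to emit.
#' @param sentences_per_doc Sentences per document (default 5).
#' @param synonym_substitution Sample concept surfaces from the full synonym
#'   set (`TRUE`, default) or always use preferred labels (`FALSE`).
#' @param distractor_rate Fraction of sentence slots carrying distractor
#'   sentences (vocabulary terms with a non-lexicon verb), in `[0, 1]`.
#' @param negation_rate Fraction of sentence slots carrying negated
#'   realizations (a negation cue before the relation), in `[0, 1]`.
#' @param table_share Fraction of the truth set emitted as structured-table
#'   rows instead of text, in `[0, 1]` (default 0).
#' @param seed Integer seed (mandatory); generation is fully reproducible.
#' @return An object of class `in_generator_config`.
#' @export
generator_config <- function(n_docs, sentences_per_doc = 5L,
                             synonym_substitution = TRUE,
                             distractor_rate = 0, negation_rate = 0,
                             table_share = 0, seed) {
  stopifnot(!missing(seed))
  for (r in c(distractor_rate, negation_rate, table_share)) {
    if (r < 0 || r > 1) an_abort("rates must lie in [0, 1]",
                                 "assertnet_error_config")
  }
  if (distractor_rate + negation_rate >= 1) {
    an_abort("distractor_rate + negation_rate must leave room for truth sentences",
             "assertnet_error_config")
  }
  structure(list(n_docs = as.integer(n_docs),
                 sentences_per_doc = as.integer(sentences_per_doc),
                 synonym_substitution = isTRUE(synonym_substitution),
                 distractor_rate = distractor_rate,
                 negation_rate = negation_rate,
                 table_share = table_share,
                 seed = as.integer(seed)),
            class = "in_generator_config")
}

# pick a surface for a concept (synonym-varied or preferred label)
sample_surface <- function(vocab, concept_id, substitute) {
  if (substitute) {
    syn <- vocab$synonyms$synonym[vocab$synonyms$concept_id == concept_id]
    syn[sample.int(length(syn), 1L)]
  } else {
    vocab$concepts$preferred_label[vocab$concepts$concept_id == concept_id]
  }
}

# surface-form candidates (incl. inverse-direction variants) for a canonical
# preferred relation
relation_surfaces <- function(lexicon, relation) {
  rel <- lexicon$relations
  rel[rel$canonical_relation == relation, ]
}

realize_sentence <- function(frame, s_surface, r_surface, o_surface,
                             inverted) {
  if (inverted) { tmp <- s_surface; s_surface <- o_surface; o_surface <- tmp }
  out <- sub("{S}", s_surface, frame, fixed = TRUE)
  out <- sub("{R}", r_surface, out, fixed = TRUE)
  out <- sub("{O}", o_surface, out, fixed = TRUE)
  # sentence case, so documents segment back into the emitted sentences
  paste0(toupper(substr(out, 1L, 1L)), substr(out, 2L, nchar(out)))
}

#' Generate an annotated synthetic corpus realizing a planted truth set
#'
#' Every text-bound truth triple is realized in at least one sentence built
#' from a small template library; additional slots are filled by recycling
#' truth triples, distractor sentences, and negated variants at the
#' configured rates. A `table_share` fraction of the truth is emitted as
#' structured-table rows (grouped by relation and endpoint types, with ready
#' mapping specs) instead of text. Everything is driven by the config seed.
#'
#' @param truth A tibble of canonical triples: columns `subject_id`,
#'   `relation`, `object_id` (preferred relations from `lexicon`).
#' @param vocab An `in_vocabulary` covering every endpoint.
#' @param lexicon An `in_relation_lexicon` covering every relation.
#' @param config An `in_generator_config`.
#' @return A list of class `in_synthetic_corpus`: `documents` (tibble
#'   `doc_id`, `source`, `text`), `gold` (tibble `doc_id`, `sentence_index`,
#'   `subject_id`, `relation`, `object_id`, surfaces used), and `tables`
#'   (list of `list(table =, mapping =)` per relation/type group).
#' @export
generate_corpus <- function(truth, vocab, lexicon, config) {
  stopifnot(inherits(vocab, "in_vocabulary"),
            inherits(lexicon, "in_relation_lexicon"),
            inherits(config, "in_generator_config"))
  truth <- as_tibble(truth)[, c("subject_id", "relation", "object_id")]
  unknown <- setdiff(c(truth$subject_id, truth$object_id),
                     vocab$concepts$concept_id)
  if (length(unknown) > 0) {
    an_abort(sprintf("truth references unknown concept '%s'", unknown[1]),
             "assertnet_error_config")
  }
  known_rel <- unique(lexicon$relations$canonical_relation)
  bad_rel <- setdiff(unique(truth$relation), known_rel)
  if (length(bad_rel) > 0) {
    an_abort(sprintf("truth references unknown relation '%s'", bad_rel[1]),
             "assertnet_error_config")
  }
  types <- vocab$concepts$type
  names(types) <- vocab$concepts$concept_id
  compat <- relation_compat()
  truth$relation_class <- relation_class_of(lexicon, truth$relation)
  for (i in seq_len(nrow(truth))) {
    ok <- any(compat$relation_class == truth$relation_class[i] &
                compat$subject_type == types[[truth$subject_id[i]]] &
                compat$object_type == types[[truth$object_id[i]]])
    if (!ok) {
      an_abort(sprintf("truth triple %d is not type-compatible with the network map",
                       i), "assertnet_error_config")
    }
  }

  empty_docs <- tibble(doc_id = character(), source = character(),
                       text = character())
  empty_gold <- tibble(doc_id = character(), sentence_index = integer(),
                       subject_id = character(), relation = character(),
                       object_id = character(), subject_surface = character(),
                       relation_surface = character(),
                       object_surface = character())
  if (config$n_docs == 0L || nrow(truth) == 0L) {
    return(structure(list(documents = empty_docs, gold = empty_gold,
                          tables = list(), config = config),
                     class = "in_synthetic_corpus"))
  }

  withr::with_seed(config$seed, {
    n_table <- floor(config$table_share * nrow(truth))
    tab_idx <- if (n_table > 0) sample.int(nrow(truth), n_table) else integer(0)
    tab_truth <- truth[tab_idx, ]
    txt_truth <- truth[setdiff(seq_len(nrow(truth)), tab_idx), ]

    n_slots <- config$n_docs * config$sentences_per_doc
    if (nrow(txt_truth) > n_slots) {
      an_abort(sprintf("%d text truth triples but only %d sentence slots",
                       nrow(txt_truth), n_slots),
               "assertnet_error_config")
    }
    # guarantee coverage: one slot per text triple, then fill by rate
    kind <- character(n_slots)
    tri <- integer(n_slots)
    guaranteed <- sample.int(n_slots, nrow(txt_truth))
    kind[guaranteed] <- "truth"
    tri[guaranteed] <- seq_len(nrow(txt_truth))
    free <- setdiff(seq_len(n_slots), guaranteed)
    for (s in free) {
      u <- stats::runif(1)
      kind[s] <- if (u < config$distractor_rate) "distractor"
        else if (u < config$distractor_rate + config$negation_rate) "negated"
        else "truth"
      if (kind[s] != "distractor") {
        tri[s] <- sample.int(nrow(txt_truth), 1L)
      }
    }

    all_ids <- vocab$concepts$concept_id
    gold <- list()
    sentences <- character(n_slots)
    for (s in seq_len(n_slots)) {
      if (kind[s] == "distractor") {
        ab <- sample(all_ids, 2L)
        frame <- DISTRACTOR_FRAMES[sample.int(length(DISTRACTOR_FRAMES), 1L)]
        frame <- sub("{A}", "{S}", frame, fixed = TRUE)
        frame <- sub("{B}", "{O}", frame, fixed = TRUE)
        sentences[s] <- realize_sentence(
          frame,
          sample_surface(vocab, ab[1], config$synonym_substitution), "",
          sample_surface(vocab, ab[2], config$synonym_substitution), FALSE)
        next
      }
      t <- txt_truth[tri[s], ]
      surf <- relation_surfaces(lexicon, t$relation)
      ri <- sample.int(nrow(surf), 1L)
      s_surface <- sample_surface(vocab, t$subject_id,
                                  config$synonym_substitution)
      o_surface <- sample_surface(vocab, t$object_id,
                                  config$synonym_substitution)
      r_surface <- stringr::str_to_lower(surf$surface_form[ri])
      frames <- if (kind[s] == "negated") NEGATED_FRAMES else TRUTH_FRAMES
      sentences[s] <- realize_sentence(
        frames[sample.int(length(frames), 1L)],
        s_surface, r_surface, o_surface, surf$inverted[ri])
      if (kind[s] == "truth") {
        doc_i <- (s - 1L) %/% config$sentences_per_doc + 1L
        gold <- c(gold, list(tibble(
          doc_id = sprintf("doc%05d", doc_i),
          sentence_index = (s - 1L) %% config$sentences_per_doc,
          subject_id = t$subject_id, relation = t$relation,
          object_id = t$object_id, subject_surface = s_surface,
          relation_surface = r_surface, object_surface = o_surface)))
      }
    }

    docs <- tibble(
      doc_id = sprintf("doc%05d", seq_len(config$n_docs)),
      source = "synthetic",
      text = vapply(seq_len(config$n_docs), function(d) {
        paste(sentences[((d - 1L) * config$sentences_per_doc + 1L):
                          (d * config$sentences_per_doc)], collapse = " ")
      }, character(1))
    )

    tables <- list()
    if (nrow(tab_truth) > 0) {
      tab_truth$subject_type <- unname(types[tab_truth$subject_id])
      tab_truth$object_type <- unname(types[tab_truth$object_id])
      grp <- split(tab_truth, paste(tab_truth$relation,
                                    tab_truth$subject_type,
                                    tab_truth$object_type, sep = " / "))
      tables <- lapply(grp, function(g) {
        list(
          table = tibble(
            subject = vapply(g$subject_id, function(id)
              sample_surface(vocab, id, config$synonym_substitution),
              character(1), USE.NAMES = FALSE),
            object = vapply(g$object_id, function(id)
              sample_surface(vocab, id, config$synonym_substitution),
              character(1), USE.NAMES = FALSE)
          ),
          mapping = mapping_spec(
            source_name = paste0("synthetic-table:", g$relation[1]),
            subject_column = "subject", subject_type = g$subject_type[1],
            object_column = "object", object_type = g$object_type[1],
            relation_class = g$relation_class[1], relation = g$relation[1])
        )
      })
    }

    structure(list(documents = docs,
                   gold = bind_rows(gold),
                   tables = tables, config = config),
              class = "in_synthetic_corpus")
  })
}

#' @export
print.in_synthetic_corpus <- function(x, ...) {
  cat(sprintf("<in_synthetic_corpus> %d documents, %d gold records, %d structured tables\n",
              nrow(x$documents), nrow(x$gold), length(x$tables)))
  invisible(x)
}

#' Score extracted proto-assertions against gold annotations
#'
#' Matching is on the triple key at (document, sentence) granularity.
#' Precision is TP / (TP + FP), recall TP / (TP + FN); a zero denominator is
#' reported as `NA` (undefined), not 0.
#'
#' @param gold Gold tibble from [generate_corpus()].
#' @param protos A proto-assertion tibble.
#' @return An object of class `in_score`: `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f1`, and a `confusion` tibble of keyed records with status
#'   TP/FP/FN.
#' @export
score_extraction <- function(gold, protos) {
  gold <- as_tibble(gold)
  protos <- as_tibble(protos)
  key <- function(d) paste(d$doc_id, d$sentence_index, d$subject_id,
                           d$relation, d$object_id, sep = "\u001f")
  gk <- unique(key(gold))
  pk <- unique(key(protos))
  tp <- length(intersect(gk, pk))
  fp <- length(setdiff(pk, gk))
  fn <- length(setdiff(gk, pk))
  precision <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  recall <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  confusion <- bind_rows(
    tibble(key = intersect(gk, pk), status = "TP"),
    tibble(key = setdiff(pk, gk), status = "FP"),
    tibble(key = setdiff(gk, pk), status = "FN")
  )
  confusion <- as_tibble(radix_arrange(confusion, c("status", "key")))
  structure(list(tp = tp, fp = fp, fn = fn, precision = precision,
                 recall = recall, f1 = f1, confusion = confusion),
            class = "in_score")
}

#' @export
print.in_score <- function(x, ...) {
  cat(sprintf("Extraction score: TP %d, FP %d, FN %d; precision %s, recall %s, F1 %s\n",
              x$tp, x$fp, x$fn,
              format(x$precision, digits = 4), format(x$recall, digits = 4),
              format(x$f1, digits = 4)))
  invisible(x)
}
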