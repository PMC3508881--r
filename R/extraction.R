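# Sentence segmentation and within-sentence subject-verb-object extraction,
# followed by curation-decision routing.

#' Split document text into sentences with character offsets
#'
#' A sentence boundary is a run of `.`, `!` or `?` followed by whitespace and
#' an upper-case letter or digit (a deliberately simple rule: abbreviations
#' followed by capitalized words do split). Offsets are 0-based; sentence
#' substrings plus the intervening whitespace reconstruct the document.
#'
#' @param text Document text (single string).
#' @return A tibble with `sentence_index` (0-based), `sentence`, `start`.
#' @export
segment_sentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  empty <- tibble(sentence_index = integer(), sentence = character(),
                  start = integer())
  if (is.na(text) || !nzchar(trimws(text))) return(empty)
  # end position of each terminator run that is followed by ws + capital/digit
  loc <- stringr::str_locate_all(text, "[.!?]+(?=\\s+[\"'(]?[A-Z0-9])")[[1]]
  cut_after <- if (nrow(loc) == 0L) integer(0) else loc[, 2]
  starts <- c(1L, vapply(cut_after, function(p) {
    rest <- stringr::str_sub(text, p + 1L)
    p + as.integer(stringr::str_locate(rest, "\\S")[1, 1])
  }, integer(1)))
  ends <- c(cut_after, nchar(text))
  sent <- stringr::str_sub(text, starts, ends)
  keep <- nzchar(trimws(sent))
  sent <- stringr::str_replace(sent[keep], "\\s+$", "")
  tibble(sentence_index = seq_along(sent) - 1L, sentence = sent,
         start = as.integer(starts[keep] - 1L))
}

#' Construct an extraction pattern
#'
#' A pattern admits a canonicalized (subject, relation, object) triple when
#' the subject concept type is in `subject_types`, the object type is in
#' `object_types`, and each token gap (subject to relation, relation to
#' object, in surface order) is at most `max_gap_tokens`.
#'
#' @param pattern_id Identifier.
#' @param subject_types,object_types Character vectors of concept types.
#' @param max_gap_tokens Positive integer, default 10.
#' @return A one-row patterns tibble.
#' @export
extraction_pattern <- function(pattern_id, subject_types, object_types,
                               max_gap_tokens = 10L) {
  stopifnot(length(subject_types) > 0, length(object_types) > 0,
            max_gap_tokens > 0)
  bad <- setdiff(c(subject_types, object_types), CONCEPT_TYPES)
  if (length(bad) > 0) {
    an_abort(paste0("unknown concept type in pattern: ", bad[1]),
             "assertnet_error_config")
  }
  tibble(pattern_id = pattern_id, subject_types = list(subject_types),
         object_types = list(object_types),
         max_gap_tokens = as.integer(max_gap_tokens))
}

#' Default extraction pattern set
#'
#' Mirrors the network map guiding assertion generation: protein-anatomy
#' (expression), protein-disease, protein-pathology, and
#' pathology/mutation-disease links.
#'
#' @param max_gap_tokens Token gap bound applied to every pattern.
#' @return A patterns tibble (one row per pattern).
#' @export
default_patterns <- function(max_gap_tokens = 10L) {
  bind_rows(
    extraction_pattern("protein-anatomy", "PROTEIN_OR_MRNA",
                       "ANATOMICAL_STRUCTURE", max_gap_tokens),
    extraction_pattern("protein-disease", "PROTEIN_OR_MRNA", "DISEASE",
                       max_gap_tokens),
    extraction_pattern("protein-pathology", "PROTEIN_OR_MRNA",
                       c("PATHOLOGICAL_OBSERVATION", "BIOLOGICAL_PROCESS"),
                       max_gap_tokens),
    extraction_pattern("pathology-disease",
                       c("PATHOLOGICAL_OBSERVATION", "GENE_MUTATION"),
                       "DISEASE", max_gap_tokens),
    extraction_pattern("disease-pathology", "DISEASE",
                       c("PATHOLOGICAL_OBSERVATION", "BIOLOGICAL_PROCESS"),
                       max_gap_tokens)
  )
}

proto_columns <- function() {
  tibble(
    doc_id = character(), source = character(), sentence_index = integer(),
    subject_id = character(), relation_class = character(),
    relation = character(), object_id = character(),
    subject_surface = character(), object_surface = character(),
    inverted = logical(), pattern_id = character(), status = character(),
    snippet = character()
  )
}

# token positions (indices) of negation cues in a token vector
negation_positions <- function(tokens) {
  pos <- which(tokens %in% c("not", "no", "never"))
  for (cue in list(c("failed", "to"), c("absence", "of"), c("lack", "of"))) {
    hit <- which(tokens == cue[1])
    hit <- hit[hit < length(tokens) & tokens[hit + 1L] == cue[2]]
    pos <- c(pos, hit)
  }
  sort(unique(pos))
}

#' Extract proto-assertions from one sentence
#'
#' Finds vocabulary mentions and relation phrases, pairs every mention before
#' a relation with every mention after it within the pattern gap bounds,
#' canonicalizes direction (inverse surface forms such as "expresses" swap
#' subject and object), gates on pattern and relation-class type
#' compatibility, and suppresses relations preceded by a negation cue.
#' Ambiguous mentions expand into one proto-assertion per compatible concept.
#'
#' @param matcher An `in_term_matcher`.
#' @param lexicon An `in_relation_lexicon`.
#' @param patterns A patterns tibble (see [default_patterns()]).
#' @param doc_id,source,sentence_index Provenance fields.
#' @param sentence Sentence text.
#' @return A tibble of proto-assertions (status `"PROTO"`); zero rows when
#'   nothing extractable.
#' @export
extract_proto_assertions <- function(matcher, lexicon, patterns,
                                     doc_id, source, sentence_index,
                                     sentence) {
  stopifnot(nzchar(sentence))
  toks <- tokenize(sentence)
  out <- proto_columns()
  if (nrow(toks) < 3L) return(out)
  mentions <- match_terms(matcher, doc_id, sentence_index, sentence)
  if (nrow(mentions) < 2L) return(out)
  rels <- match_relations(lexicon, toks)
  if (nrow(rels) == 0L) return(out)
  negpos <- negation_positions(toks$token)
  compat <- relation_compat()
  types <- matcher$concepts$type
  names(types) <- matcher$concepts$concept_id

  rows <- list()
  for (r in seq_len(nrow(rels))) {
    if (length(negpos) > 0 && any(negpos < rels$tok_start[r])) next
    left <- which(mentions$tok_end < rels$tok_start[r])
    right <- which(mentions$tok_start > rels$tok_end[r])
    for (li in left) {
      gap1 <- rels$tok_start[r] - mentions$tok_end[li] - 1L
      for (ri in right) {
        gap2 <- mentions$tok_start[ri] - rels$tok_end[r] - 1L
        for (p in seq_len(nrow(patterns))) {
          if (gap1 > patterns$max_gap_tokens[p] ||
              gap2 > patterns$max_gap_tokens[p]) next
          for (lc in mentions$concept_ids[[li]]) {
            for (rc in mentions$concept_ids[[ri]]) {
              if (rels$inverted[r]) {
                subj <- rc; obj <- lc
                subj_surface <- mentions$surface[ri]
                obj_surface <- mentions$surface[li]
              } else {
                subj <- lc; obj <- rc
                subj_surface <- mentions$surface[li]
                obj_surface <- mentions$surface[ri]
              }
              st <- types[[subj]]; ot <- types[[obj]]
              if (!st %in% patterns$subject_types[[p]] ||
                  !ot %in% patterns$object_types[[p]]) next
              ok <- any(compat$relation_class == rels$relation_class[r] &
                          compat$subject_type == st &
                          compat$object_type == ot)
              if (!ok) next
              rows <- c(rows, list(tibble(
                doc_id = doc_id, source = source,
                sentence_index = as.integer(sentence_index),
                subject_id = subj,
                relation_class = rels$relation_class[r],
                relation = rels$canonical_relation[r],
                object_id = obj,
                subject_surface = subj_surface,
                object_surface = obj_surface,
                inverted = rels$inverted[r],
                pattern_id = patterns$pattern_id[p],
                status = "PROTO",
                snippet = sentence
              )))
            }
          }
        }
      }
    }
  }
  if (length(rows) == 0L) return(out)
  distinct(bind_rows(rows), .data$doc_id, .data$sentence_index,
           .data$subject_id, .data$relation, .data$object_id,
           .keep_all = TRUE)
}

#' Extract proto-assertions from a whole corpus
#'
#' @param corpus A tibble with columns `doc_id`, `source`, `text` (one row
#'   per document, as read from a corpus JSONL file).
#' @inheritParams extract_proto_assertions
#' @return A tibble of proto-assertions across all documents, in document /
#'   sentence order.
#' @export
extract_corpus <- function(corpus, matcher, lexicon,
                           patterns = default_patterns()) {
  corpus <- as_tibble(corpus)
  stopifnot(all(c("doc_id", "source", "text") %in% names(corpus)))
  if (anyDuplicated(corpus$doc_id)) {
    an_abort("duplicate doc_id in corpus", "assertnet_error_load")
  }
  res <- purrr::pmap(corpus[, c("doc_id", "source", "text")],
                     function(doc_id, source, text) {
    sents <- segment_sentences(text)
    purrr::pmap(sents[, c("sentence_index", "sentence")],
                function(sentence_index, sentence) {
      extract_proto_assertions(matcher, lexicon, patterns, doc_id, source,
                               sentence_index, sentence)
    }) %>% bind_rows()
  })
  out <- bind_rows(res)
  if (nrow(out) == 0L) proto_columns() else out
}

proto_key <- function(df) {
  paste(df$subject_id, df$relation, df$object_id, df$doc_id,
        df$sentence_index, sep = "\u001f")
}

#' Route proto-assertions through a curation decision table
#'
#' @param protos A proto-assertion tibble.
#' @param decisions A tibble with columns `subject_id`, `relation`,
#'   `object_id`, `doc_id`, `sentence_index`, `decision` (`accept` or
#'   `reject`). Contradictory duplicate decisions for one key are an error;
#'   decisions that match no proto raise a warning.
#' @return A list with tibbles `accepted` (status `ACCEPTED`), `rejected`
#'   (status `REJECTED`) and `undecided` (status unchanged).
#' @export
apply_curation <- function(protos, decisions) {
  protos <- as_tibble(protos)
  decisions <- as_tibble(decisions)
  need <- c("subject_id", "relation", "object_id", "doc_id",
            "sentence_index", "decision")
  miss <- setdiff(need, names(decisions))
  if (length(miss) > 0) {
    an_abort(paste0("decision table lacks column(s): ",
                    paste(miss, collapse = ", ")),
             "assertnet_error_load")
  }
  if (!all(decisions$decision %in% c("accept", "reject"))) {
    an_abort("decision must be 'accept' or 'reject'", "assertnet_error_load")
  }
  dkey <- proto_key(decisions)
  contradict <- unique(dkey[duplicated(dkey)])
  contradict <- contradict[vapply(contradict, function(k) {
    length(unique(decisions$decision[dkey == k])) > 1L
  }, logical(1))]
  if (length(contradict) > 0) {
    an_abort(sprintf("contradictory curation decisions for key '%s'",
                     gsub("\u001f", " / ", contradict[1], fixed = TRUE)),
             "assertnet_error_curation")
  }
  decisions <- decisions[!duplicated(dkey), ]
  dkey <- proto_key(decisions)
  pkey <- proto_key(protos)
  orphan <- setdiff(dkey, pkey)
  if (length(orphan) > 0) {
    warn(sprintf("%d curation decision(s) match no proto-assertion",
                 length(orphan)))
  }
  verdict <- decisions$decision[match(pkey, dkey)]
  accepted <- protos[!is.na(verdict) & verdict == "accept", ]
  rejected <- protos[!is.na(verdict) & verdict == "reject", ]
  undecided <- protos[is.na(verdict), ]
  if (nrow(accepted) > 0) accepted$status <- "ACCEPTED"
  if (nrow(rejected) > 0) rejected$status <- "REJECTED"
  list(accepted = accepted, rejected = rejected, undecided = undecided)
}

#' Accept every proto-assertion (oracle curation)
#'
#' Convenience for pipelines where extraction output is trusted wholesale,
#' e.g. against synthetic corpora with known ground truth.
#'
#' @param protos A proto-assertion tibble.
#' @return The same tibble with status `ACCEPTED`.
#' @export
accept_all <- function(protos) {
  protos <- as_tibble(protos)
  if (nrow(protos) > 0) protos$status <- "ACCEPTED"
  protos
}
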