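# Dictionary matcher: longest-match scanning of tokenized sentences against
# the normalized synonym index of a vocabulary.

#' Compile an immutable term matcher from a vocabulary
#'
#' Builds a hash index from normalized token sequences to concept ids,
#' supporting longest-match scanning. The matcher is a snapshot: later
#' changes to the vocabulary object do not affect it.
#'
#' @param vocab An `in_vocabulary`.
#' @return An object of class `in_term_matcher`.
#' @export
compile_matcher <- function(vocab) {
  stopifnot(inherits(vocab, "in_vocabulary"))
  idx <- new.env(parent = emptyenv(), hash = TRUE)
  keys <- vocab$synonyms$key
  ids <- vocab$synonyms$concept_id
  for (i in seq_along(keys)) {
    idx[[keys[i]]] <- c(idx[[keys[i]]], ids[i])
  }
  for (k in ls(idx)) idx[[k]] <- sort(unique(idx[[k]]), method = "radix")
  max_len <- if (length(keys) == 0L) 0L else
    max(lengths(strsplit(keys, " ", fixed = TRUE)))
  structure(
    list(index = idx, max_len = as.integer(max_len),
         concepts = vocab$concepts),
    class = "in_term_matcher"
  )
}

#' @export
print.in_term_matcher <- function(x, ...) {
  cat(sprintf("<in_term_matcher> %d surface keys, max phrase length %d tokens\n",
              length(ls(x$index)), x$max_len))
  invisible(x)
}

# All candidate dictionary spans over a token table (used by the greedy
# selector); returns token-index spans [tok_start, tok_end] inclusive.
candidate_spans <- function(matcher, toks) {
  n <- nrow(toks)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    max_j <- min(n, i + matcher$max_len - 1L)
    for (j in i:max_j) {
      key <- paste(toks$token[i:j], collapse = " ")
      ids <- matcher$index[[key]]
      if (!is.null(ids)) {
        out[[i]] <- c(out[[i]], list(list(tok_start = i, tok_end = j,
                                          concept_ids = ids)))
      }
    }
  }
  unlist(out, recursive = FALSE)
}

# Greedy longest-then-leftmost selection of non-overlapping spans.
select_spans <- function(cands) {
  if (length(cands) == 0L) return(list())
  len <- vapply(cands, function(c) c$tok_end - c$tok_start + 1L, integer(1))
  start <- vapply(cands, `[[`, integer(1), "tok_start")
  ord <- order(-len, start, method = "radix")
  chosen <- list()
  taken <- integer(0)
  for (k in ord) {
    span <- cands[[k]]$tok_start:cands[[k]]$tok_end
    if (!any(span %in% taken)) {
      chosen <- c(chosen, cands[k])
      taken <- c(taken, span)
    }
  }
  chosen[order(vapply(chosen, `[[`, integer(1), "tok_start"))]
}

#' Find vocabulary term mentions in a sentence
#'
#' Scans the tokenized sentence for dictionary phrases; overlapping candidates
#' are resolved greedily, longest match first, ties broken by earliest start.
#'
#' @param matcher An `in_term_matcher`.
#' @param doc_id,sentence_index Provenance of the sentence.
#' @param sentence Sentence text.
#' @return A tibble of mentions ordered by span start: `doc_id`,
#'   `sentence_index`, `start`, `end` (0-based half-open character offsets),
#'   `surface`, `tok_start`, `tok_end`, and a list-column `concept_ids`.
#' @export
match_terms <- function(matcher, doc_id, sentence_index, sentence) {
  stopifnot(inherits(matcher, "in_term_matcher"))
  empty <- tibble(
    doc_id = character(), sentence_index = integer(),
    start = integer(), end = integer(), surface = character(),
    tok_start = integer(), tok_end = integer(), concept_ids = list()
  )
  toks <- tokenize(sentence)
  if (nrow(toks) == 0L) return(empty)
  sel <- select_spans(candidate_spans(matcher, toks))
  if (length(sel) == 0L) return(empty)
  tibble(
    doc_id = doc_id,
    sentence_index = as.integer(sentence_index),
    start = toks$start[vapply(sel, `[[`, integer(1), "tok_start")],
    end = toks$end[vapply(sel, `[[`, integer(1), "tok_end")],
    surface = NA_character_,
    tok_start = vapply(sel, `[[`, integer(1), "tok_start"),
    tok_end = vapply(sel, `[[`, integer(1), "tok_end"),
    concept_ids = lapply(sel, `[[`, "concept_ids")
  ) %>%
    mutate(surface = stringr::str_sub(sentence, .data$start + 1L, .data$end))
}

# Relation-phrase occurrences in a token table (longest match per start;
# occurrences may overlap each other but each start yields at most one).
match_relations <- function(lexicon, toks) {
  rel <- lexicon$relations
  keys <- new.env(parent = emptyenv(), hash = TRUE)
  for (i in seq_len(nrow(rel))) keys[[rel$key[i]]] <- i
  max_len <- if (nrow(rel) == 0L) 0L else
    max(lengths(strsplit(rel$key, " ", fixed = TRUE)))
  n <- nrow(toks)
  hits <- list()
  for (i in seq_len(n)) {
    for (j in min(n, i + max_len - 1L):i) {   # longest first
      key <- paste(toks$token[i:j], collapse = " ")
      ri <- keys[[key]]
      if (!is.null(ri)) {
        hits <- c(hits, list(tibble(
          tok_start = i, tok_end = j,
          relation_class = rel$relation_class[ri],
          preferred_relation = rel$preferred_relation[ri],
          inverted = rel$inverted[ri],
          canonical_relation = rel$canonical_relation[ri]
        )))
        break
      }
    }
  }
  if (length(hits) == 0L) {
    return(tibble(tok_start = integer(), tok_end = integer(),
                  relation_class = character(), preferred_relation = character(),
                  inverted = logical(), canonical_relation = character()))
  }
  bind_rows(hits)
}
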