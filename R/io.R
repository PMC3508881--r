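# Flat-file interchange: corpus / assertion JSONL, decision TSVs, and the
# compiled lexicon bundle (vocabulary + relation lexicon as one JSON file).

#' Read a corpus from JSONL
#'
#' One JSON object per line with fields `doc_id`, `source`, `text`.
#'
#' @param path JSONL file.
#' @return A corpus tibble.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
    if (is.null(rec) || !all(c("doc_id", "source", "text") %in% names(rec))) {
      an_abort(sprintf("malformed corpus record at line %d of %s", i, path),
               "assertnet_error_parse")
    }
    tibble(doc_id = rec$doc_id, source = rec$source, text = rec$text)
  })
  bind_rows(recs)
}

#' Write a corpus to JSONL
#'
#' @param corpus Corpus tibble (`doc_id`, `source`, `text`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  lines <- purrr::pmap_chr(as_tibble(corpus)[, c("doc_id", "source", "text")],
                           function(doc_id, source, text) {
    jsonlite::toJSON(list(doc_id = doc_id, source = source, text = text),
                     auto_unbox = TRUE)
  })
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write proto/accepted assertions to JSONL
#'
#' One object per assertion with nested provenance, mirroring the network
#' assertion layout.
#'
#' @param assertions A proto-assertion tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_assertions <- function(assertions, path) {
  assertions <- as_tibble(assertions)
  lines <- vapply(seq_len(nrow(assertions)), function(i) {
    a <- assertions[i, ]
    jsonlite::toJSON(list(
      subject_id = a$subject_id, relation_class = a$relation_class,
      relation = a$relation, object_id = a$object_id, status = a$status,
      provenance = list(source = a$source, doc_id = a$doc_id,
                        sentence_index = a$sentence_index,
                        snippet = a$snippet)
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read assertions written by [write_assertions()]
#'
#' @param path JSONL file.
#' @return A proto-assertion tibble (surface/pattern columns absent in the
#'   file are filled with `NA`).
#' @export
read_assertions <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line), error = function(e) NULL)
    if (is.null(rec) ||
        !all(c("subject_id", "relation", "object_id", "status",
               "provenance") %in% names(rec))) {
      an_abort(sprintf("malformed assertion record at line %d of %s", i, path),
               "assertnet_error_parse")
    }
    tibble(
      doc_id = rec$provenance$doc_id, source = rec$provenance$source,
      sentence_index = as.integer(rec$provenance$sentence_index),
      subject_id = rec$subject_id, relation_class = rec$relation_class,
      relation = rec$relation, object_id = rec$object_id,
      subject_surface = NA_character_, object_surface = NA_character_,
      inverted = NA, pattern_id = NA_character_, status = rec$status,
      snippet = rec$provenance$snippet
    )
  })
  out <- bind_rows(recs)
  if (nrow(out) == 0L) proto_columns() else out
}

#' Write a compiled lexicon bundle (vocabulary + relations) to JSON
#'
#' @param vocab An `in_vocabulary`.
#' @param lexicon An `in_relation_lexicon`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(vocab, lexicon, path) {
  stopifnot(inherits(vocab, "in_vocabulary"),
            inherits(lexicon, "in_relation_lexicon"))
  obj <- list(
    concepts = vocab$concepts,
    synonyms = vocab$synonyms[, c("concept_id", "synonym")],
    relations = lexicon$relations[, c("relation_class", "preferred_relation",
                                      "surface_form")]
  )
  writeLines(jsonlite::toJSON(obj, dataframe = "rows", auto_unbox = TRUE,
                              pretty = TRUE),
             path, useBytes = TRUE)
  invisible(path)
}

#' Read a lexicon bundle written by [write_lexicon()]
#'
#' @param path JSON path.
#' @return A list with elements `vocab` and `lexicon`.
#' @export
read_lexicon <- function(path) {
  obj <- tryCatch(jsonlite::fromJSON(path),
                  error = function(e) {
                    an_abort(sprintf("malformed lexicon bundle: %s", path),
                             "assertnet_error_parse")
                  })
  con <- as_tibble(obj$concepts)
  syn <- as_tibble(obj$synonyms)
  tab <- left_join(syn, con, by = "concept_id")
  tab <- tab[, c("concept_id", "type", "preferred_label", "synonym")]
  list(vocab = vocabulary(tab),
       lexicon = relation_lexicon(as_tibble(obj$relations)))
}
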