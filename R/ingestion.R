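# Declarative ingestion of structured tabular sources (gene-disease tables,
# expression tables) into accepted assertions.

#' Declare how a structured table maps onto assertions
#'
#' @param source_name Provenance source tag for all emitted assertions.
#' @param subject_column,object_column Column names holding the subject and
#'   object surface strings (must differ).
#' @param subject_type,object_type Declared concept types; rows whose
#'   surfaces do not normalize to a concept of the declared type are skipped
#'   and reported.
#' @param relation_class,relation Relation class and canonical preferred
#'   relation for every emitted assertion; the pair must be admissible for
#'   the declared types under the network map.
#' @param filters Optional named list of constant `column = value`
#'   constraints; rows failing any constraint are ignored (not reported as
#'   skips).
#' @return An object of class `in_mapping_spec`.
#' @export
mapping_spec <- function(source_name, subject_column, subject_type,
                         object_column, object_type, relation_class,
                         relation, filters = NULL) {
  if (identical(subject_column, object_column)) {
    an_abort("subject_column and object_column must differ",
             "assertnet_error_config")
  }
  if (!subject_type %in% CONCEPT_TYPES || !object_type %in% CONCEPT_TYPES) {
    an_abort("unknown concept type in mapping", "assertnet_error_config")
  }
  if (!relation_class %in% RELATION_CLASSES) {
    an_abort("unknown relation class in mapping", "assertnet_error_config")
  }
  compat <- relation_compat()
  ok <- any(compat$relation_class == relation_class &
              compat$subject_type == subject_type &
              compat$object_type == object_type)
  if (!ok) {
    an_abort(sprintf(
      "relation class %s does not admit %s -> %s under the network map",
      relation_class, subject_type, object_type),
      "assertnet_error_config")
  }
  structure(
    list(source_name = source_name, subject_column = subject_column,
         subject_type = subject_type, object_column = object_column,
         object_type = object_type, relation_class = relation_class,
         relation = relation, filters = filters),
    class = "in_mapping_spec"
  )
}

#' Read a mapping spec from JSON
#'
#' @param path JSON file with the fields of [mapping_spec()].
#' @return An `in_mapping_spec`.
#' @export
read_mapping_spec <- function(path) {
  j <- jsonlite::fromJSON(path)
  mapping_spec(j$source_name, j$subject_column, j$subject_type,
               j$object_column, j$object_type, j$relation_class, j$relation,
               filters = j$filters)
}

#' Convert a structured table into accepted assertions
#'
#' Each data row whose subject and object surfaces both normalize to concepts
#' of the declared types yields one `ACCEPTED` assertion (ambiguous surfaces
#' expand to all type-compatible concept pairs). Rows that fail to normalize
#' are counted and itemized, never silently dropped. Provenance `doc_id` is
#' the 1-based data-row number (header excluded).
#'
#' @param table A data frame or path to a TSV file.
#' @param mapping An `in_mapping_spec`.
#' @param vocab An `in_vocabulary` resolving both columns.
#' @return A list with `assertions` (accepted-assertion tibble) and
#'   `skipped` (tibble of `row`, `column`, `surface`, `reason`).
#' @export
ingest_table <- function(table, mapping, vocab) {
  stopifnot(inherits(mapping, "in_mapping_spec"),
            inherits(vocab, "in_vocabulary"))
  if (is.character(table) && length(table) == 1L) {
    table <- readr::read_tsv(table, col_types = readr::cols(.default = "c"),
                             progress = FALSE)
  }
  table <- as_tibble(table)
  need <- c(mapping$subject_column, mapping$object_column,
            names(mapping$filters))
  miss <- setdiff(need, names(table))
  if (length(miss) > 0) {
    an_abort(paste0("table lacks mapped column(s): ",
                    paste(miss, collapse = ", ")),
             "assertnet_error_load")
  }
  table$.row <- seq_len(nrow(table))
  for (col in names(mapping$filters)) {
    table <- table[!is.na(table[[col]]) &
                     table[[col]] == mapping$filters[[col]], ]
  }
  skipped <- tibble(row = integer(), column = character(),
                    surface = character(), reason = character())
  rows <- list()
  for (i in seq_len(nrow(table))) {
    rn <- table$.row[i]
    s_surface <- table[[mapping$subject_column]][i]
    o_surface <- table[[mapping$object_column]][i]
    s_hit <- normalize_term(vocab, s_surface)
    s_hit <- s_hit[s_hit$type == mapping$subject_type, ]
    o_hit <- normalize_term(vocab, o_surface)
    o_hit <- o_hit[o_hit$type == mapping$object_type, ]
    if (nrow(s_hit) == 0L) {
      skipped <- bind_rows(skipped, tibble(
        row = rn, column = mapping$subject_column, surface = s_surface,
        reason = sprintf("no %s concept for surface", mapping$subject_type)))
      next
    }
    if (nrow(o_hit) == 0L) {
      skipped <- bind_rows(skipped, tibble(
        row = rn, column = mapping$object_column, surface = o_surface,
        reason = sprintf("no %s concept for surface", mapping$object_type)))
      next
    }
    for (s in s_hit$concept_id) {
      for (o in o_hit$concept_id) {
        rows <- c(rows, list(tibble(
          doc_id = as.character(rn), source = mapping$source_name,
          sentence_index = 0L, subject_id = s,
          relation_class = mapping$relation_class,
          relation = mapping$relation, object_id = o,
          subject_surface = s_surface, object_surface = o_surface,
          inverted = FALSE, pattern_id = "structured", status = "ACCEPTED",
          snippet = paste(s_surface, o_surface, sep = " | ")
        )))
      }
    }
  }
  assertions <- if (length(rows) == 0L) {
    acc <- proto_columns(); acc
  } else {
    bind_rows(rows)
  }
  list(assertions = assertions, skipped = skipped)
}
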