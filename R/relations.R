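# Relation lexicon: canonical verb phrases grouped into relation classes,
# with synonymous surface forms and direction canonicalization.

# Which (subject type, object type) pairs each relation class may connect,
# stated for the canonical (stored) direction of the triple.
relation_compat <- function() {
  tibble(
    relation_class = c(
      rep("EXPRESSION", 1L),
      rep("UPREGULATION", 2L),
      rep("PATHOLOGY_LINK", 6L),
      rep("DISEASE_LINK", 3L),
      rep("PATHWAY_MEMBERSHIP", 1L)
    ),
    subject_type = c(
      "PROTEIN_OR_MRNA",
      "PROTEIN_OR_MRNA", "PROTEIN_OR_MRNA",
      "PROTEIN_OR_MRNA", "PROTEIN_OR_MRNA", "DISEASE", "DISEASE",
      "GENE_MUTATION", "GENE_MUTATION",
      "PROTEIN_OR_MRNA", "PATHOLOGICAL_OBSERVATION", "GENE_MUTATION",
      "PROTEIN_OR_MRNA"
    ),
    object_type = c(
      "ANATOMICAL_STRUCTURE",
      "DISEASE", "ANATOMICAL_STRUCTURE",
      "PATHOLOGICAL_OBSERVATION", "BIOLOGICAL_PROCESS",
      "PATHOLOGICAL_OBSERVATION", "BIOLOGICAL_PROCESS",
      "PATHOLOGICAL_OBSERVATION", "BIOLOGICAL_PROCESS",
      "DISEASE", "DISEASE", "DISEASE",
      "BIOLOGICAL_PROCESS"
    )
  )
}

new_relation_lexicon <- function(tbl) {
  structure(list(relations = tbl), class = "in_relation_lexicon")
}

#' Build a relation lexicon from a table of surface forms
#'
#' @param relations Data frame with columns `relation_class`,
#'   `preferred_relation`, `surface_form`. The preferred relation itself is
#'   always added as a surface form. Surface forms must be disjoint across
#'   relation classes. Preferred relations listed in the package's inverse
#'   table (e.g. `EXPRESSES`) are flagged `inverted` and mapped to their
#'   canonical storage relation (e.g. `IS EXPRESSED IN`).
#' @return An `in_relation_lexicon` whose `relations` tibble has one row per
#'   surface form with columns `relation_class`, `preferred_relation`, `surface_form`,
#'   `key`, `inverted`, `canonical_relation`.
#' @export
relation_lexicon <- function(relations) {
  rel <- as_tibble(relations)
  need <- c("relation_class", "preferred_relation", "surface_form")
  miss <- setdiff(need, names(rel))
  if (length(miss) > 0) {
    an_abort(paste0("relation table lacks column(s): ",
                    paste(miss, collapse = ", ")),
             "assertnet_error_load")
  }
  bad <- which(!rel$relation_class %in% RELATION_CLASSES)
  if (length(bad) > 0) {
    an_abort(sprintf("unknown relation class '%s' at row %d",
                     rel$relation_class[bad[1]], bad[1]),
             "assertnet_error_load")
  }
  rel <- bind_rows(
    distinct(rel, .data$relation_class, .data$preferred_relation) %>%
      mutate(surface_form = .data$preferred_relation),
    rel
  )
  rel$key <- normalize_surface(rel$surface_form)
  rel <- distinct(rel, .data$relation_class, .data$preferred_relation,
                  .data$key, .keep_all = TRUE)
  amb <- rel$key[duplicated(rel$key)]
  if (length(amb) > 0) {
    an_abort(sprintf("relation surface '%s' assigned to more than one relation",
                     amb[1]),
             "assertnet_error_load")
  }
  rel$inverted <- rel$preferred_relation %in% names(INVERSE_RELATIONS)
  rel$canonical_relation <- ifelse(
    rel$inverted, unname(INVERSE_RELATIONS[rel$preferred_relation]),
    rel$preferred_relation
  )
  new_relation_lexicon(as_tibble(radix_arrange(
    rel, c("relation_class", "preferred_relation", "key"))))
}

#' Load a relation lexicon from a TSV file
#'
#' Columns: `relation_class`, `preferred_relation`, `surface_form`.
#'
#' @param path Path to a UTF-8 TSV file with a header row.
#' @return An `in_relation_lexicon`.
#' @export
load_relations <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  relation_lexicon(raw)
}

#' @export
print.in_relation_lexicon <- function(x, ...) {
  cat(sprintf("<in_relation_lexicon> %d surface forms, %d preferred relations\n",
              nrow(x$relations),
              nrow(distinct(x$relations, .data$preferred_relation))))
  print(count(x$relations, .data$relation_class))
  invisible(x)
}

#' Resolve a verb phrase to its relation class and preferred relation
#'
#' @param lexicon An `in_relation_lexicon`.
#' @param surface A single verb-phrase string.
#' @return A one-row tibble (`relation_class`, `preferred_relation`,
#'   `inverted`, `canonical_relation`), or a zero-row tibble when the phrase
#'   is not in the lexicon.
#' @export
normalize_relation <- function(lexicon, surface) {
  stopifnot(inherits(lexicon, "in_relation_lexicon"))
  k <- normalize_surface(surface)
  select(filter(lexicon$relations, .data$key == k),
         "relation_class", "preferred_relation", "inverted",
         "canonical_relation")
}

# class of a canonical preferred relation (vectorized)
relation_class_of <- function(lexicon, relation) {
  tbl <- distinct(lexicon$relations, .data$canonical_relation,
                  .data$relation_class)
  tbl$relation_class[match(relation, tbl$canonical_relation)]
}
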