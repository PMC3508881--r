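# Concept vocabularies: load, index, and resolve surface strings to concepts.

new_vocabulary <- function(concepts, synonyms) {
  structure(
    list(concepts = concepts, synonyms = synonyms),
    class = "in_vocabulary"
  )
}

#' Build a vocabulary from a concept table
#'
#' @param concepts A data frame with columns `concept_id`, `type`,
#'   `preferred_label` and `synonym` (one row per synonym; the preferred label
#'   is always added to the synonym closure).
#' @return An object of class `in_vocabulary` with a `concepts` tibble
#'   (`concept_id`, `type`, `preferred_label`) and a `synonyms` tibble
#'   (`concept_id`, `synonym`, `key`), where `key` is the normalized surface.
#' @export
vocabulary <- function(concepts) {
  concepts <- as_tibble(concepts)
  need <- c("concept_id", "type", "preferred_label", "synonym")
  miss <- setdiff(need, names(concepts))
  if (length(miss) > 0) {
    an_abort(paste0("vocabulary table lacks column(s): ",
                    paste(miss, collapse = ", ")),
             "assertnet_error_load")
  }
  bad <- which(!concepts$type %in% CONCEPT_TYPES)
  if (length(bad) > 0) {
    an_abort(sprintf("unknown concept type '%s' at row %d",
                     concepts$type[bad[1]], bad[1]),
             "assertnet_error_load")
  }
  con <- distinct(concepts, .data$concept_id, .data$type, .data$preferred_label)
  dup <- con$concept_id[duplicated(con$concept_id)]
  if (length(dup) > 0) {
    an_abort(sprintf("concept_id '%s' declared with conflicting type or label",
                     dup[1]),
             "assertnet_error_load")
  }
  syn <- bind_rows(
    select(concepts, "concept_id", synonym = "preferred_label"),
    select(concepts, "concept_id", "synonym")
  )
  syn <- filter(syn, !is.na(.data$synonym), .data$synonym != "")
  syn$key <- normalize_surface(syn$synonym)
  syn <- filter(syn, .data$key != "")
  syn <- distinct(syn, .data$concept_id, .data$key, .keep_all = TRUE)
  new_vocabulary(
    as_tibble(radix_arrange(con, "concept_id")),
    as_tibble(radix_arrange(syn, c("concept_id", "key")))
  )
}

#' Load a concept vocabulary from a TSV file
#'
#' The file must have a header with columns `concept_id`, `type`,
#' `preferred_label`, `synonym` (one row per synonym; blank synonym rows are
#' allowed and contribute only the preferred label). When `concept_id` is
#' blank it is derived by slugifying the preferred label.
#'
#' @param path Path to a UTF-8 TSV file.
#' @return An `in_vocabulary` object.
#' @export
load_vocabulary <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (nrow(raw) == 0L) {
    warn("vocabulary file has no data rows; returning an empty vocabulary")
    return(vocabulary(tibble(concept_id = character(), type = character(),
                             preferred_label = character(),
                             synonym = character())))
  }
  if (!"synonym" %in% names(raw)) raw$synonym <- NA_character_
  if (!"concept_id" %in% names(raw) || all(is.na(raw$concept_id))) {
    raw$concept_id <- slugify(raw$preferred_label)
  }
  raw$concept_id <- ifelse(is.na(raw$concept_id) | raw$concept_id == "",
                           slugify(raw$preferred_label), raw$concept_id)
  vocabulary(raw)
}

#' @export
print.in_vocabulary <- function(x, ...) {
  cat(sprintf("<in_vocabulary> %d concepts, %d surface keys\n",
              nrow(x$concepts), nrow(distinct(x$synonyms, .data$key))))
  print(count(x$concepts, .data$type))
  invisible(x)
}

#' Resolve a surface string to the concepts whose synonym closure contains it
#'
#' @param vocab An `in_vocabulary`.
#' @param surface A single surface string.
#' @return A tibble of matching concepts (possibly zero rows) with columns
#'   `concept_id`, `type`, `preferred_label`.
#' @export
normalize_term <- function(vocab, surface) {
  stopifnot(inherits(vocab, "in_vocabulary"))
  k <- normalize_surface(surface)
  ids <- unique(vocab$synonyms$concept_id[vocab$synonyms$key == k])
  filter(vocab$concepts, .data$concept_id %in% ids)
}

#' Combine several vocabularies into one
#'
#' @param ... `in_vocabulary` objects.
#' @return An `in_vocabulary` with the union of concepts and synonyms;
#'   conflicting reuse of a `concept_id` is an error.
#' @export
combine_vocabularies <- function(...) {
  vs <- list(...)
  stopifnot(all(vapply(vs, inherits, logical(1), "in_vocabulary")))
  con <- bind_rows(lapply(vs, `[[`, "concepts"))
  syn <- bind_rows(lapply(vs, function(v) {
    left_join(v$synonyms, v$concepts[, c("concept_id", "preferred_label")],
              by = "concept_id")[, c("concept_id", "synonym", "key")]
  }))
  tab <- distinct(con, .data$concept_id, .data$type, .data$preferred_label)
  dup <- tab$concept_id[duplicated(tab$concept_id)]
  if (length(dup) > 0) {
    an_abort(sprintf("concept_id '%s' conflicts across vocabularies", dup[1]),
             "assertnet_error_load")
  }
  new_vocabulary(
    as_tibble(radix_arrange(tab, "concept_id")),
    as_tibble(radix_arrange(distinct(syn), c("concept_id", "key")))
  )
}
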