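# The intelligence network: a deduplicated, provenance-merged store of
# accepted assertions over a fixed concept table.

provenance_columns <- function() {
  tibble(subject_id = character(), relation = character(),
         object_id = character(), relation_class = character(),
         source = character(), doc_id = character(),
         sentence_index = integer(), snippet = character())
}

canonical_net <- function(concepts, provenance) {
  provenance <- provenance[, c("subject_id", "relation", "object_id",
                               "relation_class", "source", "doc_id",
                               "sentence_index", "snippet")]
  provenance <- as_tibble(radix_arrange(
    distinct(provenance),
    c("subject_id", "relation", "object_id", "source", "doc_id",
      "sentence_index", "snippet")
  ))
  assertions <- distinct(provenance, .data$subject_id, .data$relation,
                         .data$object_id, .data$relation_class)
  structure(
    list(
      concepts = as_tibble(radix_arrange(concepts, "concept_id")),
      assertions = assertions,
      provenance = provenance
    ),
    class = "intelligence_network"
  )
}

#' Create an (initially empty) intelligence network over a concept table
#'
#' @param vocab An `in_vocabulary`, or a concept tibble with columns
#'   `concept_id`, `type`, `preferred_label`.
#' @return An `intelligence_network` with no assertions.
#' @export
intelligence_network <- function(vocab) {
  concepts <- if (inherits(vocab, "in_vocabulary")) vocab$concepts else
    as_tibble(vocab)[, c("concept_id", "type", "preferred_label")]
  canonical_net(concepts, provenance_columns())
}

#' @export
print.intelligence_network <- function(x, ...) {
  cat(sprintf("<intelligence_network> %d concepts, %d assertions, %d provenance records\n",
              nrow(x$concepts), nrow(x$assertions), nrow(x$provenance)))
  invisible(x)
}

#' Merge accepted assertions into a network
#'
#' Identical triples (subject, preferred relation, object) merge into one
#' network assertion whose provenance is the deduplicated union of all
#' contributing records; merging is idempotent and insertion-order
#' independent. Only `ACCEPTED` assertions are admitted and every endpoint
#' must exist in the network's concept table.
#'
#' @param net An `intelligence_network`.
#' @param assertions A tibble with columns `subject_id`, `relation_class`,
#'   `relation`, `object_id`, `status`, `source`, `doc_id`, `sentence_index`,
#'   `snippet` (the accepted-assertion layout produced by extraction,
#'   curation or ingestion).
#' @return The updated network.
#' @export
merge_assertions <- function(net, assertions) {
  stopifnot(inherits(net, "intelligence_network"))
  assertions <- as_tibble(assertions)
  if (nrow(assertions) == 0L) return(net)
  need <- c("subject_id", "relation_class", "relation", "object_id", "status",
            "source", "doc_id", "sentence_index", "snippet")
  miss <- setdiff(need, names(assertions))
  if (length(miss) > 0) {
    an_abort(paste0("assertion table lacks column(s): ",
                    paste(miss, collapse = ", ")),
             "assertnet_error_load")
  }
  if (any(assertions$status != "ACCEPTED")) {
    an_abort("only ACCEPTED assertions may enter the network",
             "assertnet_error_status")
  }
  unknown <- setdiff(c(assertions$subject_id, assertions$object_id),
                     net$concepts$concept_id)
  if (length(unknown) > 0) {
    an_abort(sprintf("unknown concept id '%s' in assertions", unknown[1]),
             "assertnet_error_concept")
  }
  prov <- assertions[, c("subject_id", "relation", "object_id",
                         "relation_class", "source", "doc_id",
                         "sentence_index", "snippet")]
  prov$sentence_index <- as.integer(prov$sentence_index)
  canonical_net(net$concepts, bind_rows(net$provenance, prov))
}

#' Query network assertions by type, relation class and object set
#'
#' @param net An `intelligence_network`.
#' @param subject_type,object_type Optional concept type filters.
#' @param relation_class Optional relation class filter.
#' @param object_ids Optional set of object concept ids (an empty set matches
#'   nothing).
#' @return A tibble of assertions, one row per triple, ordered by triple key,
#'   with subject/object types and provenance counts attached.
#' @export
query_assertions <- function(net, subject_type = NULL, relation_class = NULL,
                             object_ids = NULL, object_type = NULL) {
  stopifnot(inherits(net, "intelligence_network"))
  types <- net$concepts$type
  names(types) <- net$concepts$concept_id
  out <- net$assertions
  out$subject_type <- unname(types[out$subject_id])
  out$object_type <- unname(types[out$object_id])
  nprov <- count(net$provenance, .data$subject_id, .data$relation,
                 .data$object_id, name = "n_provenance")
  out <- left_join(out, nprov,
                   by = c("subject_id", "relation", "object_id"))
  if (!is.null(subject_type)) out <- out[out$subject_type %in% subject_type, ]
  if (!is.null(object_type)) out <- out[out$object_type %in% object_type, ]
  if (!is.null(relation_class)) {
    out <- out[out$relation_class %in% relation_class, ]
  }
  if (!is.null(object_ids)) out <- out[out$object_id %in% object_ids, ]
  as_tibble(radix_arrange(out, c("subject_id", "relation", "object_id")))
}

#' Summary counts for a network
#'
#' @param net An `intelligence_network`.
#' @return An object of class `in_network_stats`: concept counts by type,
#'   assertion counts by relation class, and totals.
#' @export
network_stats <- function(net) {
  stopifnot(inherits(net, "intelligence_network"))
  by_type <- count(net$concepts, type = .data$type, name = "n_concepts")
  by_class <- count(net$assertions, relation_class = .data$relation_class,
                    name = "n_assertions")
  structure(
    list(
      concepts_by_type = as_tibble(radix_arrange(by_type, "type")),
      assertions_by_class = as_tibble(radix_arrange(by_class,
                                                    "relation_class")),
      n_concepts = nrow(net$concepts),
      n_assertions = nrow(net$assertions),
      n_provenance = nrow(net$provenance)
    ),
    class = "in_network_stats"
  )
}

#' @export
print.in_network_stats <- function(x, ...) {
  cat(sprintf("Network: %d concepts, %d assertions, %d provenance records\n",
              x$n_concepts, x$n_assertions, x$n_provenance))
  print(x$concepts_by_type)
  print(x$assertions_by_class)
  invisible(x)
}

#' Export a network to a directory bundle
#'
#' Writes `concepts.tsv` and `assertions.jsonl` (one JSON object per triple
#' with its sorted provenance array) into `path`. Rows are sorted by key
#' before writing, so two exports of equal networks are byte-identical.
#'
#' @param net An `intelligence_network`.
#' @param path Directory to create/overwrite (conventionally `*.inet`).
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path) {
  stopifnot(inherits(net, "intelligence_network"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  con_path <- file.path(path, "concepts.tsv")
  readr::write_tsv(net$concepts, con_path, progress = FALSE)
  lines <- purrr::pmap_chr(net$assertions, function(subject_id, relation,
                                                    object_id,
                                                    relation_class) {
    prov <- net$provenance[net$provenance$subject_id == subject_id &
                             net$provenance$relation == relation &
                             net$provenance$object_id == object_id, ]
    jsonlite::toJSON(list(
      subject_id = subject_id,
      relation_class = relation_class,
      relation = relation,
      object_id = object_id,
      provenance = lapply(seq_len(nrow(prov)), function(i) list(
        source = prov$source[i],
        doc_id = prov$doc_id[i],
        sentence_index = prov$sentence_index[i],
        snippet = prov$snippet[i]
      ))
    ), auto_unbox = TRUE)
  })
  writeLines(lines, file.path(path, "assertions.jsonl"), useBytes = TRUE)
  invisible(path)
}

#' Import a network bundle written by [export_network()]
#'
#' @param path Bundle directory.
#' @return An `intelligence_network`.
#' @export
import_network <- function(path) {
  con_path <- file.path(path, "concepts.tsv")
  jl_path <- file.path(path, "assertions.jsonl")
  if (!file.exists(con_path) || !file.exists(jl_path)) {
    an_abort(sprintf("'%s' is not a network bundle", path),
             "assertnet_error_parse")
  }
  concepts <- readr::read_tsv(con_path,
                              col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  lines <- readLines(jl_path, encoding = "UTF-8")
  prov <- purrr::imap(lines, function(line, i) {
    rec <- tryCatch(jsonlite::fromJSON(line, simplifyDataFrame = TRUE),
                    error = function(e) NULL)
    if (is.null(rec) ||
        !all(c("subject_id", "relation", "object_id", "relation_class",
               "provenance") %in% names(rec))) {
      an_abort(sprintf("malformed assertion record at line %d of %s",
                       i, jl_path),
               "assertnet_error_parse")
    }
    p <- as_tibble(rec$provenance)
    p$subject_id <- rec$subject_id
    p$relation <- rec$relation
    p$object_id <- rec$object_id
    p$relation_class <- rec$relation_class
    p
  })
  prov <- bind_rows(prov)
  if (nrow(prov) == 0L) prov <- provenance_columns() else
    prov$sentence_index <- as.integer(prov$sentence_index)
  canonical_net(concepts, prov)
}

#' Test two networks for equality
#'
#' Equality of the concept table, the triple set, and the provenance multiset
#' (after canonical ordering).
#'
#' @param a,b `intelligence_network` objects.
#' @return `TRUE` or `FALSE`.
#' @export
networks_equal <- function(a, b) {
  isTRUE(all.equal(a$concepts, b$concepts)) &&
    isTRUE(all.equal(a$assertions, b$assertions)) &&
    isTRUE(all.equal(a$provenance, b$provenance))
}
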