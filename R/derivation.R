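# Candidate-biomarker derivation: the three-stage filter chain over the
# network (region expression -> upregulation in disease -> pathology
# association) plus novelty assessment.

#' Configuration for candidate derivation
#'
#' @param net The `intelligence_network` the config will be applied to (used
#'   to validate ids).
#' @param region_ids Anatomical-structure concept ids defining the brain
#'   regions of interest.
#' @param disease_ids Disease concept ids (the disease and its sub-types).
#' @param pathology_ids Pathological-observation / biological-process ids
#'   defining the pathological hallmarks.
#' @param biomarker_sources Optional character vector of provenance source
#'   tags that represent published biomarker claims; used by novelty
#'   assessment. When `NULL`, novelty is reported as indeterminate (`NA`)
#'   rather than silently `TRUE`.
#' @param min_support Minimum number of supporting assertions per criterion
#'   (default 1).
#' @return An object of class `in_derivation_config`.
#' @export
derivation_config <- function(net, region_ids, disease_ids, pathology_ids,
                              biomarker_sources = NULL, min_support = 1L) {
  stopifnot(inherits(net, "intelligence_network"), min_support >= 1)
  for (nm in c("region_ids", "disease_ids", "pathology_ids")) {
    ids <- get(nm)
    if (length(ids) == 0L) {
      an_abort(paste0(nm, " must be non-empty"), "assertnet_error_config")
    }
    unknown <- setdiff(ids, net$concepts$concept_id)
    if (length(unknown) > 0) {
      an_abort(sprintf("%s contains unknown concept id '%s'", nm, unknown[1]),
               "assertnet_error_config")
    }
  }
  structure(
    list(region_ids = region_ids, disease_ids = disease_ids,
         pathology_ids = pathology_ids,
         biomarker_sources = biomarker_sources,
         min_support = as.integer(min_support)),
    class = "in_derivation_config"
  )
}

# ids of proteins with >= min_support assertions of `class` onto `objects`,
# together with the supporting triple keys
protein_support <- function(net, config, class, objects, within = NULL) {
  hits <- query_assertions(net, subject_type = "PROTEIN_OR_MRNA",
                           relation_class = class, object_ids = objects)
  if (!is.null(within)) hits <- hits[hits$subject_id %in% within, ]
  if (nrow(hits) == 0L) {
    return(tibble(protein_id = character(), keys = list()))
  }
  hits$key <- paste(hits$subject_id, hits$relation, hits$object_id,
                    sep = " | ")
  sup <- hits %>%
    group_by(protein_id = .data$subject_id) %>%
    summarise(keys = list(sort(unique(.data$key), method = "radix")),
              .groups = "drop")
  sup[lengths(sup$keys) >= config$min_support, ]
}

#' Proteins expressed in the configured brain regions
#'
#' @param net An `intelligence_network`.
#' @param config An `in_derivation_config`.
#' @return Character vector of protein concept ids (sorted).
#' @export
proteins_in_regions <- function(net, config) {
  sort(protein_support(net, config, "EXPRESSION",
                       config$region_ids)$protein_id, method = "radix")
}

#' Subset of proteins with upregulation evidence in the configured disease
#'
#' @param proteins Character vector of protein ids from the previous step.
#' @inheritParams proteins_in_regions
#' @return Character vector of protein ids (sorted subset of `proteins`).
#' @export
filter_upregulated <- function(net, proteins, config) {
  sort(protein_support(net, config, "UPREGULATION", config$disease_ids,
                       within = proteins)$protein_id, method = "radix")
}

#' Subset of proteins linked to the configured pathological hallmarks
#'
#' @inheritParams filter_upregulated
#' @return Character vector of protein ids (sorted subset of `proteins`).
#' @export
filter_pathology_associated <- function(net, proteins, config) {
  sort(protein_support(net, config, "PATHOLOGY_LINK", config$pathology_ids,
                       within = proteins)$protein_id, method = "radix")
}

#' Count published biomarker claims and flag novel candidates
#'
#' A protein is novel when it has zero disease-link assertions to the
#' configured disease ids whose provenance source is tagged as a
#' biomarker-claim source. With no tagged sources configured, `novel` is
#' `NA` (indeterminate) for every protein.
#'
#' @param proteins Character vector of protein concept ids.
#' @inheritParams proteins_in_regions
#' @return A tibble `protein_id`, `n_biomarker_claims`, `novel`.
#' @export
assess_novelty <- function(net, proteins, config) {
  if (length(proteins) == 0L) {
    return(tibble(protein_id = character(), n_biomarker_claims = integer(),
                  novel = logical()))
  }
  proteins <- sort(proteins, method = "radix")
  if (is.null(config$biomarker_sources)) {
    return(tibble(protein_id = proteins, n_biomarker_claims = NA_integer_,
                  novel = NA))
  }
  hits <- query_assertions(net, subject_type = "PROTEIN_OR_MRNA",
                           relation_class = "DISEASE_LINK",
                           object_ids = config$disease_ids)
  prov <- semi_join(net$provenance, hits,
                    by = c("subject_id", "relation", "object_id"))
  prov <- prov[prov$source %in% config$biomarker_sources &
                 prov$subject_id %in% proteins, ]
  cnt <- count(prov, protein_id = .data$subject_id, name = "n_biomarker_claims")
  out <- tibble(protein_id = proteins) %>%
    left_join(cnt, by = "protein_id") %>%
    mutate(n_biomarker_claims = ifelse(is.na(.data$n_biomarker_claims), 0L,
                                       .data$n_biomarker_claims),
           novel = .data$n_biomarker_claims == 0L)
  out
}

#' Run the full candidate-derivation workflow
#'
#' Chains the three filters (region expression, upregulation in disease,
#' pathology association), records the per-step protein sets and counts,
#' attaches the supporting assertion keys for each criterion, and assesses
#' novelty. Output ordering is deterministic (by protein id), independent of
#' assertion insertion order.
#'
#' @inheritParams proteins_in_regions
#' @return An object of class `candidate_table` with `steps` (tibble of
#'   step name, count, protein id list) and `candidates` (one row per final
#'   candidate).
#' @export
derive_candidates <- function(net, config) {
  stopifnot(inherits(net, "intelligence_network"),
            inherits(config, "in_derivation_config"))
  s1 <- proteins_in_regions(net, config)
  s2 <- filter_upregulated(net, s1, config)
  s3 <- filter_pathology_associated(net, s2, config)
  steps <- tibble(
    step = c("expressed_in_regions", "upregulated_in_disease",
             "pathology_associated"),
    n = c(length(s1), length(s2), length(s3)),
    proteins = list(s1, s2, s3)
  )
  labels <- net$concepts$preferred_label
  names(labels) <- net$concepts$concept_id
  sup_e <- protein_support(net, config, "EXPRESSION", config$region_ids,
                           within = s3)
  sup_u <- protein_support(net, config, "UPREGULATION", config$disease_ids,
                           within = s3)
  sup_p <- protein_support(net, config, "PATHOLOGY_LINK",
                           config$pathology_ids, within = s3)
  novelty <- assess_novelty(net, s3, config)
  candidates <- tibble(protein_id = s3) %>%
    mutate(symbol = unname(labels[.data$protein_id])) %>%
    left_join(rename(sup_e, support_expression = "keys"), by = "protein_id") %>%
    left_join(rename(sup_u, support_upregulation = "keys"), by = "protein_id") %>%
    left_join(rename(sup_p, support_pathology = "keys"), by = "protein_id") %>%
    left_join(novelty, by = "protein_id") %>%
    mutate(
      n_expression = lengths(.data$support_expression),
      n_upregulation = lengths(.data$support_upregulation),
      n_pathology = lengths(.data$support_pathology)
    ) %>%
    select("protein_id", "symbol", "n_expression", "n_upregulation",
           "n_pathology", "n_biomarker_claims", "novel",
           "support_expression", "support_upregulation", "support_pathology")
  structure(list(steps = steps, candidates = candidates, config = config),
            class = "candidate_table")
}

#' @export
print.candidate_table <- function(x, ...) {
  cat("Candidate derivation\n")
  for (i in seq_len(nrow(x$steps))) {
    cat(sprintf("  %-24s %d\n", x$steps$step[i], x$steps$n[i]))
  }
  cat(sprintf("Final candidates: %d\n", nrow(x$candidates)))
  print(select(x$candidates, "protein_id", "symbol", "n_expression",
               "n_upregulation", "n_pathology", "novel"), n = 30)
  invisible(x)
}

#' Write a candidate table to TSV
#'
#' Columns: `protein_id`, `symbol`, `n_expression`, `n_upregulation`,
#' `n_pathology`, `n_biomarker_claims`, `novel`.
#'
#' @param x A `candidate_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_candidates <- function(x, path) {
  stopifnot(inherits(x, "candidate_table"))
  readr::write_tsv(
    select(x$candidates, "protein_id", "symbol", "n_expression",
           "n_upregulation", "n_pathology", "n_biomarker_claims", "novel"),
    path, progress = FALSE)
  invisible(path)
}
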