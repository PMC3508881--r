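#' @keywords internal
"_PACKAGE"

#' @import rlang
#' @importFrom dplyr %>% across arrange bind_rows case_when count distinct
#'   filter group_by left_join anti_join semi_join inner_join mutate n pull
#'   rename row_number select slice summarise ungroup
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang .data abort warn
NULL

# Greek letters that occur in protein / peptide names; mapped before token
# extraction so that "Abeta" and the Greek spelling share one surface key.
GREEK_MAP <- c(
  "α" = "alpha", "β" = "beta", "γ" = "gamma",
  "δ" = "delta", "ß" = "beta"
)

CONCEPT_TYPES <- c(
  "DISEASE", "PATHOLOGICAL_OBSERVATION", "ANATOMICAL_STRUCTURE",
  "PROTEIN_OR_MRNA", "GENE_MUTATION", "BIOLOGICAL_PROCESS"
)

RELATION_CLASSES <- c(
  "PATHOLOGY_LINK", "EXPRESSION", "UPREGULATION",
  "DISEASE_LINK", "PATHWAY_MEMBERSHIP"
)

# Surface relation variants that state the canonical assertion with subject
# and object swapped (e.g. "hippocampus EXPRESSES synaptophysin"); on storage
# the triple is inverted and keyed by the canonical preferred relation.
INVERSE_RELATIONS <- c(
  "EXPRESSES"                 = "IS EXPRESSED IN",
  "HAS CONSTITUENT"           = "IS EXPRESSED IN",
  "IS LOCATION OF"            = "IS EXPRESSED IN",
  "IS SITE OF ALTERATION OF"  = "IS EXPRESSED IN",
  "HAS UPREGULATED"           = "IS UPREGULATED IN"
)

# Negation cues that, when seen before a relation surface in the same
# sentence, suppress automated extraction of that relation.
NEGATION_CUES <- c("not", "no", "never", "failed to", "absence of")

#' Tokenize a string into letter/digit runs with character offsets
#'
#' Hyphens, underscores, apostrophes and all other punctuation act as token
#' separators; Greek letters are rewritten to their spelled-out names inside
#' tokens. Offsets are 0-based half-open into the original string.
#'
#' @param x A single string.
#' @return A tibble with columns `token` (normalized), `start`, `end`.
#' @export
tokenize <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  loc <- stringr::str_locate_all(x, "[\\p{L}\\p{N}]+")[[1]]
  if (nrow(loc) == 0L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  raw <- stringr::str_sub(x, loc[, 1], loc[, 2])
  tok <- stringr::str_replace_all(stringr::str_to_lower(raw), GREEK_MAP)
  tibble(token = tok, start = as.integer(loc[, 1] - 1L), end = as.integer(loc[, 2]))
}

#' Normalize a surface string to its lookup key
#'
#' Case-folds, maps Greek letters to names, treats hyphens/underscores and all
#' punctuation as spaces, and collapses whitespace, so that e.g. "BACE-1" and
#' "BACE 1" share a key.
#'
#' @param x Character vector of surface strings.
#' @return Character vector of normalized keys ("" for strings with no
#'   alphanumeric content).
#' @export
normalize_surface <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return(NA_character_)
    paste(tokenize(s)$token, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

slugify <- function(x) {
  k <- normalize_surface(x)
  stringr::str_replace_all(k, " ", "-")
}

# Locale-stable (C collation) ordering used everywhere determinism matters.
radix_arrange <- function(df, cols) {
  df[do.call(order, c(unname(as.list(df[cols])), list(method = "radix"))), ,
     drop = FALSE]
}

an_abort <- function(msg, class, ...) {
  abort(msg, class = c(class, "assertnet_error"), ...)
}
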