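# broom-style tidiers for the package's result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a one-way ANOVA result
#'
#' @param x An `in_anova`.
#' @param ... Unused.
#' @return A tibble with one row per stratum (`between`, `within`).
#' @method tidy in_anova
#' @export
tidy.in_anova <- function(x, ...) {
  tibble(term = c("between", "within"),
         df = c(x$df_between, x$df_within),
         statistic = c(x$statistic, NA_real_),
         p.value = c(x$p_value, NA_real_))
}

#' @rdname tidy.in_anova
#' @method glance in_anova
#' @export
glance.in_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df_between = x$df_between,
         df_within = x$df_within, p.value = x$p_value, method = x$method)
}

#' Tidy a Spearman correlation result
#'
#' @param x An `in_spearman`.
#' @param ... Unused.
#' @return A one-row tibble (`estimate`, `p.value`, `n`, `method`).
#' @method tidy in_spearman
#' @export
tidy.in_spearman <- function(x, ...) {
  tibble(estimate = x$rho, p.value = x$p_value, n = x$n, method = x$method)
}

#' @rdname tidy.in_spearman
#' @method glance in_spearman
#' @export
glance.in_spearman <- tidy.in_spearman

#' Tidy a normality-check result
#'
#' @param x An `in_normality`.
#' @param ... Unused.
#' @return A one-row tibble (`statistic`, `p.value`, `n`, `n_mc`).
#' @method tidy in_normality
#' @export
tidy.in_normality <- function(x, ...) {
  tibble(statistic = x$statistic, p.value = x$p_value, n = x$n, n_mc = x$n_mc)
}

#' Tidy a candidate table
#'
#' @param x A `candidate_table`.
#' @param ... Unused.
#' @return `tidy()`: the per-candidate tibble (without support-key
#'   list-columns); `glance()`: one row of per-step counts.
#' @method tidy candidate_table
#' @export
tidy.candidate_table <- function(x, ...) {
  select(x$candidates, "protein_id", "symbol", "n_expression",
         "n_upregulation", "n_pathology", "n_biomarker_claims", "novel")
}

#' @rdname tidy.candidate_table
#' @method glance candidate_table
#' @export
glance.candidate_table <- function(x, ...) {
  tibble(n_expressed = x$steps$n[1], n_upregulated = x$steps$n[2],
         n_pathology = x$steps$n[3], n_candidates = nrow(x$candidates),
         n_novel = sum(x$candidates$novel %in% TRUE))
}

#' Tidy a QC acceptance-sampling report
#'
#' @param x An `in_qc_report`.
#' @param ... Unused.
#' @return A one-row tibble.
#' @method tidy in_qc_report
#' @export
tidy.in_qc_report <- function(x, ...) {
  tibble(n = x$n, errors = x$errors, accuracy = x$accuracy,
         ci_lower = x$ci_lower, ci_upper = x$ci_upper, pass = x$pass,
         census = x$census, indeterminate = x$indeterminate)
}

#' Tidy an extraction score
#'
#' @param x An `in_score`.
#' @param ... Unused.
#' @return A one-row tibble of counts and rates.
#' @method tidy in_score
#' @export
tidy.in_score <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, precision = x$precision,
         recall = x$recall, f1 = x$f1)
}

#' Tidy network summary counts
#'
#' @param x An `in_network_stats`.
#' @param ... Unused.
#' @return `tidy()`: long tibble of counts by concept type and relation
#'   class; `glance()`: one row of totals.
#' @method tidy in_network_stats
#' @export
tidy.in_network_stats <- function(x, ...) {
  bind_rows(
    tibble(dimension = "concept_type", level = x$concepts_by_type$type,
           n = x$concepts_by_type$n_concepts),
    tibble(dimension = "relation_class",
           level = x$assertions_by_class$relation_class,
           n = x$assertions_by_class$n_assertions)
  )
}

#' @rdname tidy.in_network_stats
#' @method glance in_network_stats
#' @export
glance.in_network_stats <- function(x, ...) {
  tibble(n_concepts = x$n_concepts, n_assertions = x$n_assertions,
         n_provenance = x$n_provenance)
}
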