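# Acceptance-sampling quality control for curated assertions: a simplified
# single-sampling plan (sample n, accept if errors <= c) with an exact
# binomial confidence interval on accuracy.

#' Declare an acceptance-sampling plan
#'
#' @param sample_size Number of assertions to inspect (default 125).
#' @param acceptance_number Maximum tolerated errors in the sample
#'   (default 3; must be smaller than `sample_size`).
#' @param seed Integer seed for the sampling draw (mandatory).
#' @return An object of class `in_qc_plan`.
#' @export
qc_plan <- function(sample_size = 125L, acceptance_number = 3L, seed) {
  stopifnot(!missing(seed))
  sample_size <- as.integer(sample_size)
  acceptance_number <- as.integer(acceptance_number)
  if (sample_size < 1L || acceptance_number < 0L ||
      acceptance_number >= sample_size) {
    an_abort("need 0 <= acceptance_number < sample_size >= 1",
             "assertnet_error_config")
  }
  structure(list(sample_size = sample_size,
                 acceptance_number = acceptance_number,
                 seed = as.integer(seed)),
            class = "in_qc_plan")
}

#' Inspect a random sample of accepted assertions against a truth oracle
#'
#' Draws `sample_size` assertions without replacement (all of them when the
#' population is smaller — a census), counts errors per the oracle, and
#' reports point accuracy with an exact (Clopper-Pearson) 95% confidence
#' interval. The lot passes when errors do not exceed the acceptance number.
#'
#' @param assertions An accepted-assertion tibble (columns `subject_id`,
#'   `relation`, `object_id`; duplicates allowed — sampling is over rows).
#' @param truth A tibble mapping triples to correctness: columns
#'   `subject_id`, `relation`, `object_id`, `correct` (logical). Every
#'   sampled assertion must be covered.
#' @param plan An `in_qc_plan`.
#' @return An object of class `in_qc_report`: `n`, `errors`, `accuracy`,
#'   `ci_lower`, `ci_upper`, `pass`, `indeterminate`, `census`.
#' @export
qc_sample <- function(assertions, truth, plan) {
  stopifnot(inherits(plan, "in_qc_plan"))
  assertions <- as_tibble(assertions)
  truth <- as_tibble(truth)
  if (nrow(assertions) == 0L) {
    return(structure(list(n = 0L, errors = 0L, accuracy = NA_real_,
                          ci_lower = NA_real_, ci_upper = NA_real_,
                          pass = NA, indeterminate = TRUE, census = TRUE,
                          plan = plan),
                     class = "in_qc_report"))
  }
  n <- min(plan$sample_size, nrow(assertions))
  idx <- withr::with_seed(plan$seed, sample.int(nrow(assertions), n))
  sampled <- assertions[idx, c("subject_id", "relation", "object_id")]
  key <- function(d) paste(d$subject_id, d$relation, d$object_id,
                           sep = "\u001f")
  verdict <- truth$correct[match(key(sampled), key(truth))]
  if (anyNA(verdict)) {
    an_abort("truth oracle does not cover every sampled assertion",
             "assertnet_error_config")
  }
  errors <- sum(!verdict)
  ci <- stats::binom.test(n - errors, n)$conf.int
  structure(list(n = n, errors = as.integer(errors), accuracy = 1 - errors / n,
                 ci_lower = ci[1], ci_upper = ci[2],
                 pass = errors <= plan$acceptance_number,
                 indeterminate = FALSE, census = n == nrow(assertions),
                 plan = plan),
            class = "in_qc_report")
}

#' @export
print.in_qc_report <- function(x, ...) {
  if (x$indeterminate) {
    cat("QC report: no assertions to sample (indeterminate)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "QC report: %d sampled%s, %d error(s); accuracy %.3f [95%% CI %.3f, %.3f]; %s (c = %d)\n",
    x$n, if (x$census) " (census)" else "", x$errors, x$accuracy,
    x$ci_lower, x$ci_upper, if (x$pass) "PASS" else "FAIL",
    x$plan$acceptance_number))
  invisible(x)
}
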