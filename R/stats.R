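# Validation statistics for candidate follow-up: one-way ANOVA (raw or from
# printed group summaries), Spearman rank correlation, and a Monte-Carlo
# Lilliefors normality check.

new_anova <- function(F, df_between, df_within, p_value, method) {
  structure(list(statistic = F, df_between = df_between,
                 df_within = df_within, p_value = p_value, method = method),
            class = "in_anova")
}

#' @export
print.in_anova <- function(x, ...) {
  cat(sprintf("One-way ANOVA (%s): F(%d, %d) = %.4g, p = %.4g\n",
              x$method, x$df_between, x$df_within, x$statistic, x$p_value))
  invisible(x)
}

#' One-way ANOVA on a measurement table
#'
#' @param table A data frame with columns `group` and `value` (extra columns
#'   such as `subject_id` or `covariate` are ignored). At least two groups,
#'   each with at least two observations.
#' @return An `in_anova` object (`statistic`, `df_between`, `df_within`,
#'   `p_value`).
#' @details When every observation is identical the decomposition is
#'   degenerate in a benign way and `F = 0`, `p = 1` is returned; zero
#'   within-group variance with non-zero between-group variance is an error.
#' @export
anova_oneway <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("group", "value") %in% names(table)))
  table <- filter(table, !is.na(.data$value), !is.na(.data$group))
  ns <- count(table, .data$group)
  if (nrow(ns) < 2L) {
    an_abort("ANOVA needs at least two groups", "assertnet_error_stats")
  }
  if (any(ns$n < 2L)) {
    an_abort(sprintf("group '%s' has fewer than 2 observations",
                     ns$group[which(ns$n < 2L)[1]]),
             "assertnet_error_stats")
  }
  k <- nrow(ns); N <- nrow(table)
  if (stats::var(table$value) == 0) {
    return(new_anova(0, k - 1L, N - k, 1, "raw data"))
  }
  fit <- stats::lm(value ~ factor(group), data = table)
  # perfect-fit warnings are redundant: the zero-within case errors below
  tab <- suppressWarnings(stats::anova(fit))
  if (tab[2, "Sum Sq"] <= .Machine$double.eps * sum(tab[, "Sum Sq"])) {
    an_abort("zero within-group variance: F is unbounded",
             "assertnet_error_stats")
  }
  new_anova(unname(tab[1, "F value"]), as.integer(tab[1, "Df"]),
            as.integer(tab[2, "Df"]), unname(tab[1, "Pr(>F)"]), "raw data")
}

#' One-way ANOVA from printed group summaries (n, mean, SD)
#'
#' Reconstructs the sum-of-squares decomposition from per-group summary
#' statistics: between-group SS from the group means about the weighted grand
#' mean, within-group SS as \eqn{\sum (n_i - 1) s_i^2}. Agrees exactly with
#' [anova_oneway()] on any raw table having those summaries.
#'
#' @param groups A data frame with columns `label`, `n`, `mean`, `sd`
#'   (one row per group; `n >= 2` per group).
#' @return An `in_anova` object.
#' @export
anova_from_summary <- function(groups) {
  groups <- as_tibble(groups)
  stopifnot(all(c("n", "mean", "sd") %in% names(groups)))
  if (nrow(groups) < 2L) {
    an_abort("ANOVA needs at least two groups", "assertnet_error_stats")
  }
  if (any(groups$n < 2L)) {
    an_abort("every group needs n >= 2", "assertnet_error_stats")
  }
  if (any(groups$sd < 0)) {
    an_abort("negative SD", "assertnet_error_stats")
  }
  k <- nrow(groups)
  N <- sum(groups$n)
  grand <- sum(groups$n * groups$mean) / N
  ssb <- sum(groups$n * (groups$mean - grand)^2)
  ssw <- sum((groups$n - 1) * groups$sd^2)
  if (ssw == 0 && ssb == 0) {
    return(new_anova(0, k - 1L, N - k, 1, "group summaries"))
  }
  if (ssw == 0) {
    an_abort("zero within-group variance: F is unbounded",
             "assertnet_error_stats")
  }
  f <- (ssb / (k - 1)) / (ssw / (N - k))
  new_anova(f, k - 1L, as.integer(N - k),
            stats::pf(f, k - 1, N - k, lower.tail = FALSE),
            "group summaries")
}

# midranks with average ties (explicit, rather than rank(), so the
# rank-then-Pearson oracle in the tests stays an independent route)
midranks <- function(x) {
  n <- length(x)
  ord <- order(x, method = "radix")
  r <- numeric(n)
  i <- 1L
  xs <- x[ord]
  while (i <= n) {
    j <- i
    while (j < n && xs[j + 1L] == xs[i]) j <- j + 1L
    r[ord[i:j]] <- (i + j) / 2
    i <- j + 1L
  }
  r
}

all_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (i in seq_len(n)) {
    for (p in sub) {
      k <- k + 1L
      out[[k]] <- c(i, ifelse(p >= i, p + 1L, p))
    }
  }
  out
}

#' Spearman rank correlation with tie-aware ranks
#'
#' Rho is the Pearson correlation of midranks (average ranks for ties). The
#' two-sided p-value is exact (full permutation enumeration) for n <= 8 and
#' otherwise uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 3, neither constant.
#' @return An object of class `in_spearman` (`rho`, `p_value`, `n`,
#'   `method`).
#' @export
spearman_cor <- function(x, y) {
  stopifnot(is.numeric(x), is.numeric(y))
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (length(y) != n) an_abort("x and y lengths differ", "assertnet_error_stats")
  if (n < 3L) an_abort("need n >= 3", "assertnet_error_stats")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    an_abort("rho is undefined for a constant vector", "assertnet_error_stats")
  }
  rx <- midranks(x); ry <- midranks(y)
  pearson <- function(a, b) {
    a <- a - mean(a); b <- b - mean(b)
    sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  }
  rho <- pearson(rx, ry)
  if (n <= 8L) {
    perms <- all_permutations(n)
    stat <- vapply(perms, function(p) pearson(rx, ry[p]), numeric(1))
    p <- mean(abs(stat) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      t <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(abs(t), n - 2, lower.tail = FALSE)
    }
    method <- "t approximation"
  }
  structure(list(rho = rho, p_value = p, n = n, method = method),
            class = "in_spearman")
}

#' @export
print.in_spearman <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: rho = %.4f, p = %.4g (n = %d, %s)\n",
              x$rho, x$p_value, x$n, x$method))
  invisible(x)
}

lilliefors_stat <- function(x) {
  n <- length(x)
  z <- sort((x - mean(x)) / stats::sd(x))
  cdf <- stats::pnorm(z)
  max(max(seq_len(n) / n - cdf), max(cdf - (seq_len(n) - 1) / n))
}

#' Kolmogorov-Smirnov normality check with Monte-Carlo p-value
#'
#' Computes the KS distance between the empirical CDF and a normal
#' distribution fitted by the sample mean and SD, and estimates the p-value
#' by seeded Monte-Carlo simulation under the fitted null (the Lilliefors
#' correction for estimated parameters).
#'
#' @param x Numeric vector, n >= 5.
#' @param n_mc Number of Monte-Carlo replicates (default 2000).
#' @param seed Integer seed (mandatory; the simulation is reproducible).
#' @return An object of class `in_normality` (`statistic`, `p_value`, `n`,
#'   `n_mc`).
#' @export
normality_check <- function(x, n_mc = 2000L, seed) {
  stopifnot(is.numeric(x), !missing(seed))
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 5L) an_abort("need n >= 5", "assertnet_error_stats")
  if (stats::sd(x) == 0) {
    an_abort("constant sample: normality check undefined",
             "assertnet_error_stats")
  }
  d <- lilliefors_stat(x)
  exceed <- withr::with_seed(as.integer(seed), {
    sum(vapply(seq_len(n_mc), function(b) {
      lilliefors_stat(stats::rnorm(n)) >= d
    }, logical(1)))
  })
  structure(list(statistic = d, p_value = (exceed + 1) / (n_mc + 1),
                 n = n, n_mc = as.integer(n_mc)),
            class = "in_normality")
}

#' @export
print.in_normality <- function(x, ...) {
  cat(sprintf("Lilliefors KS normality check: D = %.4f, Monte-Carlo p = %.4g (n = %d, %d replicates)\n",
              x$statistic, x$p_value, x$n, x$n_mc))
  invisible(x)
}

#' Summarise a measurement table into per-group (n, mean, SD)
#'
#' @param table A data frame with columns `group`, `value`.
#' @return A tibble `label`, `n`, `mean`, `sd` suitable for
#'   [anova_from_summary()].
#' @export
summarize_groups <- function(table) {
  table <- as_tibble(table)
  stopifnot(all(c("group", "value") %in% names(table)))
  table %>%
    filter(!is.na(.data$value)) %>%
    group_by(label = .data$group) %>%
    summarise(n = n(), mean = mean(.data$value), sd = stats::sd(.data$value),
              .groups = "drop")
}
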