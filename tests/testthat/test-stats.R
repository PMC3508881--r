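# Validation statistics: ANOVA (raw and from summaries), Spearman, and the
# Monte-Carlo Lilliefors normality check.

test_that("raw-data ANOVA matches the sum-of-squares oracle on toy data", {
  tab <- tibble::tibble(group = rep(c("a", "b", "c"), each = 3),
                        value = c(1.2, 0.8, 1.1, 2.3, 2.0, 2.6, 0.4, 0.7, 0.3))
  got <- anova_oneway(tab)
  want <- oracle_anova(tab$group, tab$value)
  expect_equal(got$statistic, want$F, tolerance = 1e-12)
  expect_equal(got$p_value, want$p, tolerance = 1e-12)
  expect_equal(got$df_between, 2L)
  expect_equal(got$df_within, 6L)
})

test_that("ANOVA degenerate cases: all-equal, zero-within, tiny groups", {
  allsame <- tibble::tibble(group = rep(c("a", "b"), each = 3), value = 5)
  got <- anova_oneway(allsame)
  expect_equal(got$statistic, 0)
  expect_equal(got$p_value, 1)
  sep <- tibble::tibble(group = rep(c("a", "b"), each = 3),
                        value = rep(c(1, 2), each = 3))
  expect_error(anova_oneway(sep), class = "assertnet_error_stats")
  expect_error(anova_oneway(tibble::tibble(group = c("a", "a", "b"),
                                           value = c(1, 2, 3))),
               class = "assertnet_error_stats")
  expect_error(anova_from_summary(
    tibble::tibble(label = c("a", "b"), n = c(5, 5), mean = c(1, 2),
                   sd = c(0, 0))),
    class = "assertnet_error_stats")
  same <- anova_from_summary(
    tibble::tibble(label = c("a", "b"), n = c(5, 5), mean = c(2, 2),
                   sd = c(0, 0)))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
})

test_that("summary-based ANOVA equals raw ANOVA on random tables", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      k <- sample(2:5, 1)
      tab <- dplyr::bind_rows(lapply(seq_len(k), function(g) {
        tibble::tibble(group = paste0("g", g),
                       value = stats::rnorm(sample(3:12, 1),
                                            mean = stats::runif(1, -2, 2),
                                            sd = stats::runif(1, 0.5, 2)))
      }))
      raw <- anova_oneway(tab)
      summ <- anova_from_summary(summarize_groups(tab))
      expect_equal(summ$statistic, raw$statistic, tolerance = 1e-10)
      expect_equal(summ$p_value, raw$p_value, tolerance = 1e-10)
      expect_equal(summ$df_within, raw$df_within)
    }
  })
})

test_that("the printed PLAUR group summaries give F near 30 and p < 0.001", {
  a <- anova_from_summary(plaur_group_summaries())
  expect_equal(a$df_between, 2L)
  expect_equal(a$df_within, 237L)
  expect_gt(a$statistic, 25)
  expect_lt(a$statistic, 35)
  expect_lt(a$p_value, 0.001)
  # and the ChAt summaries show no group difference
  expect_gt(anova_from_summary(chat_group_summaries())$p_value, 0.05)
})

test_that("spearman reproduces identity, reversal and the closed-form example", {
  x <- c(3, 7, 1, 9, 5)
  expect_equal(spearman_cor(x, x)$rho, 1)
  expect_equal(spearman_cor(x, -x)$rho, -1)
  s <- spearman_cor(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$rho, 1 - 6 * 4 / (5 * (5^2 - 1)))   # Sum d^2 = 4
  expect_equal(s$rho, 0.8)
})

test_that("spearman equals the rank-Pearson oracle on all permutations of n = 5", {
  x <- c(1, 2, 3, 4, 5)
  perms <- assertnet:::all_permutations(5L)
  expect_length(perms, 120L)
  for (p in perms) {
    expect_equal(spearman_cor(x, as.numeric(p))$rho,
                 oracle_spearman_rho(x, p), tolerance = 1e-12)
  }
})

test_that("spearman handles ties via midranks and is monotone-invariant", {
  withr::with_seed(7, {
    x <- stats::rnorm(30); y <- x + stats::rnorm(30)
    base <- spearman_cor(x, y)
    expect_equal(spearman_cor(exp(x), y)$rho, base$rho)
    expect_equal(spearman_cor(x, y^3 + 5)$rho, base$rho)
    xt <- round(x)   # heavy ties
    expect_equal(spearman_cor(xt, y)$rho, stats::cor(xt, y,
                                                     method = "spearman"),
                 tolerance = 1e-12)
  })
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "assertnet_error_stats")
  expect_error(spearman_cor(1:2, 1:2), class = "assertnet_error_stats")
})

test_that("spearman t-approximation p agrees with cor.test at moderate n", {
  withr::with_seed(11, {
    x <- stats::rnorm(40); y <- x + stats::rnorm(40, sd = 2)
  })
  s <- spearman_cor(x, y)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(s$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("the KS statistic matches the reference implementation", {
  skip_if_not_installed("nortest")
  withr::with_seed(5, x <- stats::rnorm(80))
  got <- normality_check(x, n_mc = 200, seed = 1)
  ref <- nortest::lillie.test(x)
  expect_equal(got$statistic, unname(ref$statistic), tolerance = 1e-12)
})

test_that("normality check calibrates on normal data and rejects bimodal data", {
  ok <- 0L
  for (seed in 1:60) {
    x <- withr::with_seed(1000L + seed, stats::rnorm(200))
    p <- normality_check(x, n_mc = 300, seed = seed)$p_value
    if (p > 0.01) ok <- ok + 1L
  }
  expect_gte(ok / 60, 0.98)
  bimodal <- rep(c(0, 1), 100)
  expect_lt(normality_check(bimodal, n_mc = 300, seed = 2)$p_value, 0.01)
  expect_error(normality_check(c(1, 2, 3), n_mc = 10, seed = 1),
               class = "assertnet_error_stats")
  expect_error(normality_check(rep(2, 10), n_mc = 10, seed = 1),
               class = "assertnet_error_stats")
})

test_that("tidy and glance expose the fitted objects as tibbles", {
  a <- anova_from_summary(plaur_group_summaries())
  expect_named(glance(a), c("statistic", "df_between", "df_within",
                            "p.value", "method"))
  expect_equal(nrow(tidy(a)), 2L)
  s <- spearman_cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9))
  expect_equal(tidy(s)$estimate, s$rho)
})
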