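# ggplot2 displays for derivation funnels, extraction scores and network
# composition.

#' @import ggplot2
NULL

#' Funnel plot of the candidate-derivation filter chain
#'
#' @param object A `candidate_table`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot candidate_table
#' @export
autoplot.candidate_table <- function(object, ...) {
  df <- mutate(object$steps,
               step = factor(.data$step, levels = rev(.data$step)))
  ggplot(df, aes(x = .data$n, y = .data$step)) +
    geom_col(fill = "steelblue") +
    geom_text(aes(label = .data$n), hjust = -0.2, size = 3.5) +
    expand_limits(x = max(df$n) * 1.12) +
    labs(x = "proteins retained", y = NULL,
         title = "Candidate derivation filter chain") +
    theme_minimal()
}

#' Bar chart of extraction precision / recall / F1
#'
#' @param object An `in_score`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot in_score
#' @export
autoplot.in_score <- function(object, ...) {
  df <- tibble(metric = factor(c("precision", "recall", "F1"),
                               levels = c("precision", "recall", "F1")),
               value = c(object$precision, object$recall, object$f1))
  ggplot(df, aes(x = .data$metric, y = .data$value)) +
    geom_col(fill = "darkorange") +
    scale_y_continuous(limits = c(0, 1)) +
    labs(x = NULL, y = NULL, title = "Extraction performance vs gold") +
    theme_minimal()
}

#' Composition plot of a network (concepts by type, assertions by class)
#'
#' @param object An `in_network_stats`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot in_network_stats
#' @export
autoplot.in_network_stats <- function(object, ...) {
  df <- tidy.in_network_stats(object)
  ggplot(df, aes(x = .data$n, y = .data$level)) +
    geom_col(fill = "seagreen") +
    facet_wrap(~.data$dimension, scales = "free_y") +
    labs(x = "count", y = NULL, title = "Network composition") +
    theme_minimal()
}

#' Group means with the fitted ANOVA annotation
#'
#' @param table A measurement tibble (`group`, `value`).
#' @return A ggplot of per-group distributions.
#' @export
plot_group_values <- function(table) {
  table <- as_tibble(table)
  ggplot(table, aes(x = .data$group, y = .data$value)) +
    geom_boxplot(outlier.shape = NA, fill = "grey90") +
    geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    labs(x = NULL, y = "value") +
    theme_minimal()
}
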