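#' Volcano-style plot of a candidate rule set
#'
#' Plots each rule's log2 odds ratio against -log10 p, sized by pattern
#' support, with the candidate z threshold implied by the run's
#' configuration drawn as a reference line on the p scale.
#'
#' @param object A `snprules_rules` object from [discover()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snprules_rules
#' @export
autoplot.snprules_rules <- function(object, ...) {
  df <- tidy(object)
  zmin <- attr(object, "config")$z_min
  p_thr <- pchisq(zmin^2, 1, lower.tail = FALSE) / 2
  ggplot2::ggplot(df, ggplot2::aes(x = log2(.data$odds_ratio),
                                   y = -log10(.data$p_chisq),
                                   size = .data$support)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_hline(yintercept = -log10(p_thr), linetype = "dashed") +
    ggplot2::labs(x = "log2 odds ratio", y = "-log10 p (chi-squared)",
                  size = "support",
                  title = "Candidate association rules") +
    ggplot2::theme_minimal()
}

#' Forest-style plot of replicated rules
#'
#' Odds ratios with 95% Wald intervals for each replicated rule, coloured
#' by its multiple-testing outcome.
#'
#' @param object A `snprules_replication` object from [replicate_rules()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snprules_replication
#' @export
autoplot.snprules_replication <- function(object, ...) {
  df <- tidy(object) %>%
    filter(!.data$untestable) %>%
    mutate(
      outcome = dplyr::case_when(
        .data$significant_bonferroni ~ "Bonferroni",
        .data$significant_fdr ~ "FDR",
        TRUE ~ "not significant"
      ),
      label = paste0(.data$lhs_items, " => ", .data$rhs_features)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$odds_ratio,
                                   y = stats::reorder(.data$label, .data$odds_ratio),
                                   colour = .data$outcome)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ci_low,
                                         xmax = .data$ci_high), height = 0.2) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "odds ratio (95% Wald CI)", y = NULL,
                  colour = "significance") +
    ggplot2::theme_minimal()
}

#' QQ plot of replication chi-squared p-values
#'
#' Compares the observed -log10 p-values of a rule table with their
#' expectation under a uniform null, the standard check that the
#' replication-stage p-value distribution matches the chi-squared
#' reference; the inflation factor lambda is shown in the subtitle.
#'
#' @param rules A tibble with a `p_chisq` column (and optionally `chi2`).
#' @return A ggplot object.
#' @export
plot_rule_qq <- function(rules) {
  p <- rules$p_chisq[!is.na(rules$p_chisq)]
  m <- length(p)
  if (m == 0) abort("no p-values to plot", class = "snprules_value_error")
  df <- tibble(
    expected = -log10(stats::ppoints(m)),
    observed = -log10(sort(p))
  )
  lambda <- median(qchisq(p, 1, lower.tail = FALSE)) / qchisq(0.5, 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "expected -log10 p", y = "observed -log10 p",
                  title = "Replication p-value QQ plot",
                  subtitle = sprintf("inflation factor lambda = %.3f", lambda)) +
    ggplot2::theme_minimal()
}
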