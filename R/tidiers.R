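#' Tidy and summarise rule sets
#'
#' `tidy()` returns the rule table as a plain tibble; `glance()` returns a
#' one-row summary of the run: the counts at each stage and, for
#' replication results, the significance tallies and the genomic-control
#' style inflation factor `lambda` (median observed chi-squared over the
#' chi-squared(1) median).
#'
#' @param x A `snprules_rules` or `snprules_replication` object.
#' @param ... Unused.
#' @return A tibble.
#' @name snprules-tidiers
NULL

#' @rdname snprules-tidiers
#' @method tidy snprules_rules
#' @export
tidy.snprules_rules <- function(x, ...) {
  as_tibble(unclass_rules(x))
}

#' @rdname snprules-tidiers
#' @method glance snprules_rules
#' @export
glance.snprules_rules <- function(x, ...) {
  cnt <- attr(x, "counts")
  tibble(
    n_individuals = cnt$n_individuals,
    n_items = cnt$n_items,
    n_patterns = cnt$n_patterns,
    n_closed = cnt$n_closed,
    n_clusters = cnt$n_clusters,
    n_tests = cnt$n_tests,
    n_candidates = cnt$n_candidates,
    max_z = if (nrow(x) > 0) max(x$z) else NA_real_
  )
}

#' @rdname snprules-tidiers
#' @method tidy snprules_replication
#' @export
tidy.snprules_replication <- function(x, ...) {
  as_tibble(unclass_rules(x))
}

#' @rdname snprules-tidiers
#' @method glance snprules_replication
#' @export
glance.snprules_replication <- function(x, ...) {
  chi <- x$chi2[!is.na(x$chi2)]
  tibble(
    n_rules = nrow(x),
    n_cr = attr(x, "n_cr"),
    alpha = attr(x, "alpha"),
    alpha_adjusted = attr(x, "alpha_adjusted"),
    n_untestable = sum(x$untestable),
    n_nominal = sum(x$p_chisq <= attr(x, "alpha"), na.rm = TRUE),
    n_significant_bonferroni = sum(x$significant_bonferroni),
    n_significant_fdr = sum(x$significant_fdr),
    lambda = if (length(chi) > 0) median(chi) / qchisq(0.5, 1) else NA_real_
  )
}

unclass_rules <- function(x) {
  attr(x, "config") <- NULL
  attr(x, "counts") <- NULL
  attr(x, "alpha") <- NULL
  attr(x, "n_cr") <- NULL
  attr(x, "alpha_adjusted") <- NULL
  class(x) <- class(tibble())
  x
}
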