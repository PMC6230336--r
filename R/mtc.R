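#' Bonferroni-adjusted p-values
#'
#' @param p Numeric vector of raw p-values in \[0, 1\].
#' @param n_tests Number of tests in the family (e.g. the number of
#'   candidate rules carried to replication).
#' @return `pmin(1, p * n_tests)`.
#' @export
bonferroni_adjust <- function(p, n_tests) {
  check_pvalues(p)
  stopifnot(n_tests >= 1)
  pmin(1, p * n_tests)
}

#' Bonferroni-adjusted significance level
#'
#' The test-wide threshold for replication of `n_cr` candidate rules:
#' `alpha / n_cr`.
#'
#' @param n_cr Number of candidate rules.
#' @param alpha Family-wise error rate (default 0.05).
#' @return Adjusted alpha.
#' @export
alpha_adjusted <- function(n_cr, alpha = 0.05) {
  stopifnot(n_cr >= 1, alpha > 0, alpha <= 1)
  alpha / n_cr
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Step-up FDR adjustment: the value at ascending-p rank i is
#' `min(1, min_{j >= i} p_(j) * n_tests / j)`. With `n_tests` larger than
#' the number of supplied p-values, a top-k list is adjusted against the
#' full family, under the assumption that the unsupplied p-values are
#' large enough not to lower the running minimum (they occupy the ranks
#' above k).
#'
#' @param p Numeric vector of raw p-values.
#' @param n_tests Size of the test family; defaults to `length(p)`.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p, n_tests = length(p)) {
  check_pvalues(p)
  if (n_tests < length(p)) {
    abort("n_tests must be at least length(p)", class = "snprules_value_error")
  }
  if (length(p) == 0) return(numeric(0))
  p.adjust(p, method = "BH", n = n_tests)
}

check_pvalues <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]", class = "snprules_value_error")
  }
  invisible(p)
}
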