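#' Contingency table for a rule on aligned data
#'
#' Builds the 2x2 table of genotype-pattern presence against
#' phenotype-cluster presence. The antecedent (`lhs`) is present when all
#' its items are true; the consequent (`rhs`) is present when all its
#' features are true (a conjunction, supporting multi-feature phenotype
#' clusters). Individuals missing any involved item or feature are
#' excluded (complete case over the union of `lhs` and `rhs`).
#'
#' @param items Binary item tibble (`IID` + logical item columns).
#' @param pheno Phenotype tibble (`IID` + logical feature columns).
#' @param lhs Character vector of item IDs (the genotype pattern).
#' @param rhs Character vector of feature names (the phenotype cluster).
#' @return A one-row tibble with counts `a` (pattern and phenotype present),
#'   `b` (pattern present, phenotype absent), `c`, `d`, and `n_effective`.
#' @export
contingency <- function(items, pheno, lhs, rhs) {
  validate_items(items)
  if (length(lhs) < 1 || length(rhs) < 1) {
    abort("lhs and rhs must be non-empty", class = "snprules_value_error")
  }
  missing_lhs <- setdiff(lhs, names(items))
  if (length(missing_lhs) > 0) {
    abort(paste0("unknown item(s): ", paste(missing_lhs, collapse = ", ")),
          class = "snprules_value_error")
  }
  missing_rhs <- setdiff(rhs, names(pheno))
  if (length(missing_rhs) > 0) {
    abort(paste0("unknown feature(s): ", paste(missing_rhs, collapse = ", ")),
          class = "snprules_value_error")
  }
  joined <- inner_join(items[, c("IID", lhs), drop = FALSE],
                       pheno[, c("IID", rhs), drop = FALSE], by = "IID")
  if (nrow(joined) == 0) {
    abort("no overlapping individuals between item and phenotype tables",
          class = "snprules_value_error")
  }
  pat <- conjunction_status(joined, lhs)
  ph <- conjunction_status(joined, rhs)
  ok <- !is.na(pat) & !is.na(ph)
  tibble(
    a = sum(pat[ok] & ph[ok]),
    b = sum(pat[ok] & !ph[ok]),
    c = sum(!pat[ok] & ph[ok]),
    d = sum(!pat[ok] & !ph[ok]),
    n_effective = sum(ok)
  )
}

# all-true conjunction over columns; NA if any involved value is missing
conjunction_status <- function(tbl, cols) {
  m <- as.matrix(tbl[, cols, drop = FALSE])
  rowSums(m) == length(cols)
}

#' Pearson chi-squared test for 2x2 counts
#'
#' One-degree-of-freedom Pearson chi-squared without continuity
#' correction: `chi2 = n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. A table
#' with any zero margin is degenerate: `chi2 = 0`, `p = 1`, flagged.
#'
#' All count arguments are vectorized.
#'
#' @param a,b,c,d Cell counts (pattern x phenotype, see [contingency()]).
#' @return Tibble with `chi2`, `p` and logical `degenerate`.
#' @export
chi2_test <- function(a, b, c, d) {
  n <- a + b + c + d
  r1 <- a + b; r2 <- c + d; c1 <- a + c; c2 <- b + d
  degenerate <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  denom <- as.numeric(r1) * r2 * c1 * c2
  chi2 <- ifelse(degenerate, 0, n * (as.numeric(a) * d - as.numeric(b) * c)^2 / denom)
  tibble(
    chi2 = chi2,
    p = ifelse(degenerate, 1, pchisq(chi2, df = 1, lower.tail = FALSE)),
    degenerate = degenerate
  )
}

#' Signed z-score of a 2x2 association
#'
#' The rule-interestingness measure: the signed square root of the Pearson
#' chi-squared statistic, positive when the pattern and phenotype co-occur
#' more often than expected under independence (`a` above its expectation
#' `(a+b)(a+c)/n`). `z^2` equals the Pearson chi-squared statistic, so the
#' candidate threshold z >= 5 corresponds to chi2 >= 25 with positive
#' association. Degenerate tables score 0. Vectorized.
#'
#' @inheritParams chi2_test
#' @return Numeric vector of signed z-scores.
#' @export
z_score <- function(a, b, c, d) {
  ct <- chi2_test(a, b, c, d)
  n <- a + b + c + d
  expected_a <- ifelse(n == 0, 0, as.numeric(a + b) * (a + c) / n)
  sign(a - expected_a) * sqrt(ct$chi2)
}

#' Odds ratio with Wald confidence interval
#'
#' Raw cross-product odds ratio `ad/(bc)` and the 95% Wald interval on the
#' log scale. With `correction = "haldane"`, 0.5 is added to every cell
#' whenever any cell is zero (Haldane-Anscombe). Without correction, a
#' table with `bc = 0` yields an infinite (flagged) odds ratio and no
#' interval. Vectorized.
#'
#' @inheritParams chi2_test
#' @param correction `"none"` or `"haldane"`.
#' @param conf_level Confidence level of the Wald interval.
#' @return Tibble with `or`, `ci_low`, `ci_high` and logical `or_defined`.
#' @export
odds_ratio <- function(a, b, c, d, correction = c("none", "haldane"),
                       conf_level = 0.95) {
  correction <- match.arg(correction)
  any_zero <- a == 0 | b == 0 | c == 0 | d == 0
  shift <- if (correction == "haldane") ifelse(any_zero, 0.5, 0) else 0
  aa <- a + shift; bb <- b + shift; cc <- c + shift; dd <- d + shift
  defined <- bb * cc > 0
  or <- ifelse(defined, (aa * dd) / (bb * cc), Inf)
  z <- qnorm(1 - (1 - conf_level) / 2)
  se <- ifelse(defined & aa > 0 & dd > 0,
               sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd), NA_real_)
  tibble(
    or = or,
    ci_low = ifelse(is.na(se), NA_real_, exp(log(or) - z * se)),
    ci_high = ifelse(is.na(se), NA_real_, exp(log(or) + z * se)),
    or_defined = defined
  )
}

#' Cochran-Armitage trend test on genotype counts
#'
#' Tests for a linear trend of case proportion in the allele dosage
#' (scores 0/1/2), as in single-SNP case-control trend analyses. The
#' statistic is the signed score-test z (its square is the 1-df trend
#' chi-squared); the sign is positive when the case fraction increases
#' with dosage.
#'
#' @param case_counts Integer vector `(n0, n1, n2)` of cases per dosage.
#' @param control_counts Integer vector `(n0, n1, n2)` of controls.
#' @return One-row tibble with `z`, `chi2`, `p` and logical `degenerate`
#'   (true when the pooled genotype distribution has no variance).
#' @export
trend_test <- function(case_counts, control_counts) {
  stopifnot(length(case_counts) == 3, length(control_counts) == 3,
            all(case_counts >= 0), all(control_counts >= 0))
  if (sum(case_counts) == 0 || sum(control_counts) == 0) {
    abort("both groups must be non-empty", class = "snprules_value_error")
  }
  totals <- case_counts + control_counts
  score <- 0:2
  if (sum(totals > 0) < 2) {
    return(tibble(z = 0, chi2 = 0, p = 1, degenerate = TRUE))
  }
  tt <- suppressWarnings(prop.trend.test(case_counts, totals, score = score))
  chi2 <- unname(tt$statistic)
  # direction: covariance of dosage score with case indicator
  n <- sum(totals)
  direction <- sum(score * case_counts) - sum(case_counts) * sum(score * totals) / n
  tibble(
    z = sign(direction) * sqrt(chi2),
    chi2 = chi2,
    p = tt$p.value,
    degenerate = FALSE
  )
}

#' Case-control test of a genotype pattern
#'
#' Compares carrier status of a genotype pattern between two groups of
#' individuals (e.g. phenotype-defined cases versus controls): builds the
#' 2x2 of pattern presence x group label and returns the full rule
#' statistics.
#'
#' @param items Binary item tibble (`IID` + logical item columns).
#' @param lhs Character vector of item IDs.
#' @param group Logical vector aligned to `items` rows (`TRUE` = case), or
#'   a two-column data frame `IID`/`group` to align by ID.
#' @return One-row tibble with counts `a`..`d` (a = pattern present in a
#'   case), `n_effective`, `z`, `chi2`, `p`, `or`, `ci_low`, `ci_high`,
#'   `degenerate`.
#' @export
pattern_group_test <- function(items, lhs, group) {
  validate_items(items)
  if (is.data.frame(group)) {
    stopifnot(all(c("IID", "group") %in% names(group)))
    group <- group$group[match(items$IID, group$IID)]
  }
  if (length(group) != nrow(items)) {
    abort("group labels must align with item-matrix rows",
          class = "snprules_value_error")
  }
  pat <- conjunction_status(items, lhs)
  ok <- !is.na(pat) & !is.na(group)
  a <- sum(pat[ok] & group[ok])
  b <- sum(pat[ok] & !group[ok])
  c <- sum(!pat[ok] & group[ok])
  d <- sum(!pat[ok] & !group[ok])
  ct <- chi2_test(a, b, c, d)
  orx <- odds_ratio(a, b, c, d)
  tibble(
    a = a, b = b, c = c, d = d, n_effective = sum(ok),
    z = z_score(a, b, c, d), chi2 = ct$chi2, p = ct$p,
    or = orx$or, ci_low = orx$ci_low, ci_high = orx$ci_high,
    degenerate = ct$degenerate
  )
}
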