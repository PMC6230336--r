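#' Permutation test by phenotype re-sampling
#'
#' Scheme (a): estimates the probability of finding an association at
#' least as strong as the observed one when the phenotype rows are
#' randomly re-assigned to individuals. Whole phenotype rows are permuted
#' jointly, preserving the correlation between clinical features; the
#' genotype side is left fixed. Exceedances are permutations whose
#' chi-squared statistic is greater than or equal to the observed one.
#'
#' @param items Binary item tibble (`IID` + logical item columns).
#' @param pheno Phenotype tibble (`IID` + logical feature columns).
#' @param lhs Character vector of item IDs (the rule's genotype pattern).
#' @param rhs Character vector of feature names (the rule's phenotype
#'   cluster).
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param add_one Use the add-one estimator `(n_exceed + 1)/(n_perm + 1)`
#'   instead of the plain `n_exceed / n_perm`.
#' @return One-row tibble with `scheme`, `observed_stat` (chi-squared),
#'   `n_perm`, `n_exceed`, `p_empirical` and `seed`.
#' @export
permute_phenotype <- function(items, pheno, lhs, rhs, n_perm, seed,
                              add_one = FALSE) {
  stopifnot(n_perm >= 1)
  obs <- contingency(items, pheno, lhs, rhs)
  obs_test <- chi2_test(obs$a, obs$b, obs$c, obs$d)
  if (obs_test$degenerate) {
    abort("observed table is degenerate (a zero margin); permutation p undefined",
          class = "snprules_value_error")
  }
  common <- intersect(items$IID, pheno$IID)
  items <- items[match(common, items$IID), , drop = FALSE]
  pheno <- pheno[match(common, pheno$IID), , drop = FALSE]
  pat <- conjunction_status(items, lhs)
  ph <- conjunction_status(pheno, rhs)
  n <- length(common)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      php <- ph[sample.int(n)]
      ok <- !is.na(pat) & !is.na(php)
      po <- pat[ok]; fo <- php[ok]
      a <- sum(po & fo)
      c(a = a, b = sum(po) - a, c = sum(fo) - a,
        d = sum(ok) - sum(po) - sum(fo) + a)
    }, numeric(4))
  })
  chi_perm <- chi2_test(counts[1, ], counts[2, ], counts[3, ], counts[4, ])$chi2
  perm_result("permute_phenotype", obs_test$chi2, n_perm,
              sum(chi_perm >= obs_test$chi2), seed, add_one)
}

#' Permutation test by random genotype patterns
#'
#' Scheme (b): estimates the probability that a randomly chosen genotype
#' pattern of the same length as the rule's antecedent associates with the
#' rule's phenotype cluster at least as strongly as observed. Each draw
#' picks distinct SNPs uniformly and one of the two items of each SNP
#' uniformly (so a draw never contains both items of one SNP).
#'
#' @inheritParams permute_phenotype
#' @param min_support If set, drawn patterns are required to reach this
#'   absolute support (rejection sampling; unconstrained by default).
#' @param max_tries Cap on redraws per accepted pattern when
#'   `min_support` is set.
#' @return One-row tibble as in [permute_phenotype()].
#' @export
random_patterns <- function(items, pheno, lhs, rhs, n_perm, seed,
                            min_support = NULL, add_one = FALSE,
                            max_tries = 1000) {
  stopifnot(n_perm >= 1)
  obs <- contingency(items, pheno, lhs, rhs)
  obs_chi <- chi2_test(obs$a, obs$b, obs$c, obs$d)$chi2
  item_ids <- setdiff(names(items), "IID")
  stems <- item_stem(item_ids)
  stem_items <- split(item_ids, stems)
  k <- length(lhs)
  if (length(stem_items) < k) {
    abort("fewer eligible SNPs than the pattern length",
          class = "snprules_value_error")
  }
  common <- intersect(items$IID, pheno$IID)
  items_al <- items[match(common, items$IID), , drop = FALSE]
  pheno_al <- pheno[match(common, pheno$IID), , drop = FALSE]
  ph <- conjunction_status(pheno_al, rhs)
  n_stem <- length(stem_items)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      for (try in seq_len(max_tries)) {
        chosen <- sample.int(n_stem, k)
        draw <- vapply(stem_items[chosen], function(its) {
          its[sample.int(length(its), 1)]
        }, character(1))
        if (is.null(min_support) ||
            pattern_support(items, draw) >= min_support) break
        if (try == max_tries) {
          abort("could not draw a pattern meeting min_support",
                class = "snprules_value_error")
        }
      }
      pat <- conjunction_status(items_al, draw)
      ok <- !is.na(pat) & !is.na(ph)
      po <- pat[ok]; fo <- ph[ok]
      a <- sum(po & fo)
      c(a = a, b = sum(po) - a, c = sum(fo) - a,
        d = sum(ok) - sum(po) - sum(fo) + a)
    }, numeric(4))
  })
  chi_perm <- chi2_test(counts[1, ], counts[2, ], counts[3, ], counts[4, ])$chi2
  perm_result("random_patterns", obs_chi, n_perm,
              sum(chi_perm >= obs_chi), seed, add_one)
}

perm_result <- function(scheme, observed_stat, n_perm, n_exceed, seed,
                        add_one) {
  tibble(
    scheme = scheme,
    observed_stat = observed_stat,
    n_perm = as.integer(n_perm),
    n_exceed = as.integer(n_exceed),
    p_empirical = if (add_one) (n_exceed + 1) / (n_perm + 1) else n_exceed / n_perm,
    seed = as.integer(seed)
  )
}
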