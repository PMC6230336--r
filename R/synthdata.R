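#' Simulate a genotype-phenotype dataset, optionally with a planted rule
#'
#' Generates data with the statistical structure the rule-mining analysis
#' assumes: SNP dosages drawn under Hardy-Weinberg equilibrium at minor
#' allele frequencies uniform in `maf_range`, and binary clinical features
#' drawn as independent Bernoulli variables at the given prevalences.
#' Defaults emulate a cohort of around 1000 cases typed on ~1581 pruned
#' SNPs with 23 features spanning prevalences from 5% to 80% (here scaled
#' to 100 SNPs; pass `n_snps` to change).
#'
#' A planted rule multiplies the odds of one target feature by
#' `odds_multiplier` for individuals matching a carrier pattern over up to
#' three SNPs, so the planted parameter is directly the odds ratio the
#' pipeline estimates.
#'
#' An optional LD-block mode makes each SNP after the first within a block
#' copy the previous SNP's dosage per individual with probability
#' `ld_copy_prob`, producing high local r2 to exercise [ld_prune()].
#'
#' @param n_individuals Number of individuals.
#' @param n_snps Number of SNPs.
#' @param maf_range Range the per-SNP minor allele frequency is drawn
#'   from, within (0, 0.5].
#' @param feature_prevalences Named or unnamed vector of feature
#'   prevalences in (0, 1); defaults to 23 features evenly spanning
#'   0.05-0.80.
#' @param planted Optional planted rule:
#'   `list(snp_indices =, carrier = , target_feature = , odds_multiplier = )`
#'   with `carrier` a logical vector (TRUE = carrier of >= 1 counted
#'   allele) aligned to `snp_indices`, and `target_feature` a feature
#'   index or name.
#' @param geno_missing_rate,pheno_missing_rate Independent missingness
#'   rates; genotypes default to complete (imputed upstream), features to
#'   5% missing.
#' @param ld_block_size Block length for the LD mode (1 = independent
#'   SNPs, the default: the analysis operates post-pruning).
#' @param ld_copy_prob Per-individual copy probability within LD blocks.
#' @param seed Integer seed; `NULL` uses the current RNG stream.
#' @return `list(genotypes = , phenotypes = , truth = )`: two tibbles
#'   ready for [binarize_dominant()] and [discover()], and a truth record
#'   with the drawn MAFs, realized planted-pattern frequency and realized
#'   feature prevalences.
#' @export
simulate_rule_data <- function(n_individuals = 1000,
                               n_snps = 100,
                               maf_range = c(0.05, 0.5),
                               feature_prevalences = default_prevalences(),
                               planted = NULL,
                               geno_missing_rate = 0,
                               pheno_missing_rate = 0.05,
                               ld_block_size = 1,
                               ld_copy_prob = 0.95,
                               seed = NULL) {
  stopifnot(n_individuals >= 1, n_snps >= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5, maf_range[1] <= maf_range[2],
            all(feature_prevalences > 0), all(feature_prevalences < 1),
            geno_missing_rate >= 0, geno_missing_rate < 1,
            pheno_missing_rate >= 0, pheno_missing_rate < 1,
            ld_block_size >= 1)
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed,
      simulate_rule_data(n_individuals, n_snps, maf_range,
                         feature_prevalences, planted,
                         geno_missing_rate, pheno_missing_rate,
                         ld_block_size, ld_copy_prob, seed = NULL),
      .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
      .rng_sample_kind = "Rejection"
    ))
  }

  n <- n_individuals
  maf <- runif(n_snps, maf_range[1], maf_range[2])
  alleles <- sample(c("A", "C", "G", "T"), n_snps, replace = TRUE)
  snp_cols <- sprintf("snp%04d_%s", seq_len(n_snps), alleles)

  dosage <- matrix(0L, nrow = n, ncol = n_snps)
  for (j in seq_len(n_snps)) {
    in_block <- ld_block_size > 1 && (j - 1) %% ld_block_size != 0
    fresh <- rbinom(n, 2, maf[j])
    if (in_block) {
      copy <- runif(n) < ld_copy_prob
      dosage[, j] <- ifelse(copy, dosage[, j - 1], fresh)
    } else {
      dosage[, j] <- fresh
    }
  }

  feats <- feature_prevalences
  if (is.null(names(feats))) {
    names(feats) <- sprintf("feature%02d", seq_along(feats))
  }

  pattern_match <- rep(TRUE, n)
  if (!is.null(planted)) {
    stopifnot(length(planted$snp_indices) <= 3,
              !anyDuplicated(planted$snp_indices),
              planted$odds_multiplier > 0)
    carrier <- planted$carrier
    if (is.null(carrier)) carrier <- rep(TRUE, length(planted$snp_indices))
    for (k in seq_along(planted$snp_indices)) {
      is_carrier <- dosage[, planted$snp_indices[k]] >= 1L
      pattern_match <- pattern_match & (if (carrier[k]) is_carrier else !is_carrier)
    }
  }

  pheno_vals <- matrix(FALSE, nrow = n, ncol = length(feats))
  target_idx <- NA_integer_
  for (f in seq_along(feats)) {
    pr <- rep(feats[f], n)
    if (!is.null(planted)) {
      tf <- planted$target_feature
      idx <- if (is.character(tf)) match(tf, names(feats)) else as.integer(tf)
      if (f == idx) {
        target_idx <- idx
        odds <- feats[f] / (1 - feats[f]) * planted$odds_multiplier
        pr_carrier <- odds / (1 + odds)
        if (!is.finite(pr_carrier) || pr_carrier >= 1) {
          abort("planted effect implies probability >= 1",
                class = "snprules_value_error")
        }
        pr[pattern_match] <- pr_carrier
      }
    }
    pheno_vals[, f] <- runif(n) < pr
  }

  if (geno_missing_rate > 0) {
    miss <- matrix(runif(n * n_snps) < geno_missing_rate, nrow = n)
    dosage[miss] <- NA_integer_
  }
  if (pheno_missing_rate > 0) {
    miss <- matrix(runif(n * length(feats)) < pheno_missing_rate, nrow = n)
    pheno_vals[miss] <- NA
  }

  iid <- sprintf("ind%05d", seq_len(n))
  geno <- as_tibble(as.data.frame(dosage))
  names(geno) <- snp_cols
  geno <- bind_cols(tibble(IID = iid), geno)
  pheno <- as_tibble(as.data.frame(pheno_vals))
  names(pheno) <- names(feats)
  pheno <- bind_cols(tibble(IID = iid), pheno)

  truth <- list(
    maf = setNames(maf, snp_cols),
    feature_prevalences = setNames(unname(feats), names(feats)),
    realized_prevalences = colMeans(pheno_vals, na.rm = TRUE),
    planted = planted,
    planted_pattern_frequency = if (is.null(planted)) NA_real_ else mean(pattern_match),
    planted_items = if (is.null(planted)) NULL else {
      paste0(snp_cols[planted$snp_indices], "_",
             as.integer(if (is.null(planted$carrier)) {
               rep(TRUE, length(planted$snp_indices))
             } else planted$carrier))
    },
    target_feature = if (is.na(target_idx)) NULL else names(feats)[target_idx]
  )
  list(genotypes = geno, phenotypes = pheno, truth = truth)
}

#' Default clinical-feature prevalences
#'
#' 23 binary features with prevalences evenly spanning 5% to 80%,
#' matching the spread seen in curated bipolar-disorder phenotype panels
#' (rare comorbidities such as eating disorder near 5%, common course
#' features near 80%).
#'
#' @return Named numeric vector of length 23.
#' @export
default_prevalences <- function() {
  setNames(round(seq(0.05, 0.80, length.out = 23), 3),
           sprintf("feature%02d", 1:23))
}

#' Recovery of a planted odds ratio over repeated simulations
#'
#' Validation harness: repeatedly simulates data with a planted rule,
#' rebuilds the rule's 2x2 table and odds ratio, and summarises the
#' estimates and the coverage of the 95% Wald interval.
#'
#' @param n_reps Number of simulation replicates.
#' @param seed Integer seed for the whole experiment.
#' @param ... Arguments passed to [simulate_rule_data()]; must include a
#'   `planted` rule.
#' @return One-row tibble with `n_reps`, `mean_or`, `sd_or`, `coverage`
#'   (fraction of Wald intervals containing the planted odds ratio) and
#'   `mean_pattern_freq`. Per-replicate estimates are attached as
#'   attribute `"estimates"`.
#' @export
estimate_or_recovery <- function(n_reps, seed, ...) {
  args <- list(...)
  if (is.null(args$planted)) {
    abort("estimate_or_recovery requires a planted rule",
          class = "snprules_value_error")
  }
  true_or <- args$planted$odds_multiplier
  est <- withr::with_seed(seed, {
    purrr::map(seq_len(n_reps), function(r) {
      sim <- do.call(simulate_rule_data, c(args, list(seed = NULL)))
      its <- binarize_dominant(sim$genotypes)
      ct <- contingency(its, sim$phenotypes,
                        lhs = sim$truth$planted_items,
                        rhs = sim$truth$target_feature)
      est_or <- odds_ratio(ct$a, ct$b, ct$c, ct$d)
      tibble(rep = r, a = ct$a, b = ct$b, c = ct$c, d = ct$d,
             or = est_or$or, ci_low = est_or$ci_low, ci_high = est_or$ci_high,
             covered = !is.na(est_or$ci_low) &
               est_or$ci_low <= true_or & true_or <= est_or$ci_high,
             pattern_freq = sim$truth$planted_pattern_frequency)
    }) %>% bind_rows()
  }, .rng_kind = "Mersenne-Twister", .rng_normal_kind = "Inversion",
  .rng_sample_kind = "Rejection")
  out <- tibble(
    n_reps = n_reps,
    true_or = true_or,
    mean_or = mean(est$or[is.finite(est$or)]),
    sd_or = stats::sd(est$or[is.finite(est$or)]),
    coverage = mean(est$covered),
    mean_pattern_freq = mean(est$pattern_freq)
  )
  attr(out, "estimates") <- est
  out
}
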