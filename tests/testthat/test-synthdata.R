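test_that("genotypes follow Hardy-Weinberg proportions at the drawn MAF", {
  sim <- simulate_rule_data(n_individuals = 10000, n_snps = 1,
                            maf_range = c(0.3, 0.3), seed = 101)
  d <- sim$genotypes[[2]]
  exp_freq <- c(0.49, 0.42, 0.09)
  for (g in 0:2) {
    se <- sqrt(exp_freq[g + 1] * (1 - exp_freq[g + 1]) / 10000)
    expect_lt(abs(mean(d == g) - exp_freq[g + 1]), 3 * se)
  }
})

test_that("simulation is byte-identical under a fixed seed", {
  s1 <- simulate_rule_data(n_individuals = 50, n_snps = 10, seed = 77)
  s2 <- simulate_rule_data(n_individuals = 50, n_snps = 10, seed = 77)
  expect_identical(s1, s2)
  s3 <- simulate_rule_data(n_individuals = 50, n_snps = 10, seed = 78)
  expect_false(identical(s1$genotypes, s3$genotypes))
})

test_that("planted pattern frequency matches the product of carrier probabilities", {
  maf <- 0.268  # carrier probability ~0.464, three SNPs -> ~10%
  sim <- simulate_rule_data(
    n_individuals = 20000, n_snps = 3, maf_range = c(maf, maf),
    feature_prevalences = c(target = 0.1),
    planted = list(snp_indices = 1:3, carrier = rep(TRUE, 3),
                   target_feature = "target", odds_multiplier = 1),
    pheno_missing_rate = 0, seed = 55
  )
  carrier_p <- 1 - (1 - maf)^2
  expect_equal(sim$truth$planted_pattern_frequency, carrier_p^3,
               tolerance = 0.1)
})

test_that("a unit odds multiplier leaves the target feature independent", {
  sim <- simulate_rule_data(
    n_individuals = 5000, n_snps = 3, maf_range = c(0.268, 0.268),
    feature_prevalences = c(target = 0.1),
    planted = list(snp_indices = 1:3, carrier = rep(TRUE, 3),
                   target_feature = "target", odds_multiplier = 1),
    pheno_missing_rate = 0, seed = 66
  )
  items <- binarize_dominant(sim$genotypes)
  ct <- contingency(items, sim$phenotypes, sim$truth$planted_items, "target")
  expect_gt(chi2_test(ct$a, ct$b, ct$c, ct$d)$p, 1e-3)
})

test_that("an impossible planted effect is rejected", {
  expect_error(
    simulate_rule_data(
      n_individuals = 10, n_snps = 1,
      feature_prevalences = c(t = 0.9),
      planted = list(snp_indices = 1, carrier = TRUE, target_feature = "t",
                     odds_multiplier = Inf),
      seed = 1),
    class = "snprules_value_error")
})

test_that("LD-block mode produces correlated neighbours that pruning removes", {
  sim <- simulate_rule_data(n_individuals = 500, n_snps = 12,
                            maf_range = c(0.3, 0.4),
                            ld_block_size = 4, ld_copy_prob = 0.95, seed = 88)
  dos <- as.matrix(sim$genotypes[, -1])
  r2_adj <- stats::cor(dos[, 1], dos[, 2])^2
  expect_gt(r2_adj, 0.5)
  kept <- ld_prune(sim$genotypes, r2_max = 0.5, window = 12, step = 3)
  expect_lte(length(kept), 6)  # roughly one survivor per block of 4
})

test_that("planted odds ratios are recovered without material bias", {
  rec <- estimate_or_recovery(
    n_reps = 50, seed = 12345,
    n_individuals = 2000, n_snps = 3, maf_range = c(0.268, 0.268),
    feature_prevalences = c(target = 0.1),
    planted = list(snp_indices = 1:3, carrier = rep(TRUE, 3),
                   target_feature = "target", odds_multiplier = 4),
    pheno_missing_rate = 0
  )
  expect_equal(rec$mean_or, 4, tolerance = 0.15)
  est <- attr(rec, "estimates")
  expect_equal(nrow(est), 50)
  expect_true(all(est$or > 0))

  null_rec <- estimate_or_recovery(
    n_reps = 30, seed = 54321,
    n_individuals = 2000, n_snps = 3, maf_range = c(0.268, 0.268),
    feature_prevalences = c(target = 0.2),
    planted = list(snp_indices = 1:3, carrier = rep(TRUE, 3),
                   target_feature = "target", odds_multiplier = 1),
    pheno_missing_rate = 0
  )
  expect_equal(null_rec$mean_or, 1, tolerance = 0.15)
})
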