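---
title: "Mining and validating genotype-phenotype association rules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining and validating genotype-phenotype association rules}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprules)
library(dplyr)
```

## The problem and the model

Genome-wide association studies of heterogeneous disorders such as bipolar
disorder test one variant at a time against one diagnosis. snprules
implements the complementary strategy of association rule mining: search
case-only data for *frequent multi-SNP genotype patterns* (up to three
SNPs) whose carriers are enriched for a *phenotype cluster* (one or two
binary clinical features), and treat each such pair as a candidate rule

> genotype pattern A  =>  phenotype cluster B.

Because rule mining generates an enormous number of hypotheses, the
procedure is three-staged: discovery in one cohort, replication of every
candidate in an independent cohort under family-wise correction, and
post-hoc permutation nulls for individual rules.

### Binary genotype items

Dosages (0/1/2 copies of a counted allele) are collapsed under a dominant
model into two mutually exclusive items per SNP: `<snp>_<allele>_1` for
carriers of at least one copy and `<snp>_<allele>_0` for non-carriers, so
`s` SNPs yield exactly `2s` items (1581 SNPs give the 3162 binary
variables of the motivating study). A missing dosage propagates to both
items; no imputation is attempted, and every statistic downstream is
complete-case over the variables it involves. The dominant collapse is
lossless for carrier status, but it cannot distinguish heterozygotes from
homozygotes — a recessive or additive encoding would need different items.

### Mining

`apriori_frequent()` enumerates patterns level-wise. The support of a
pattern is the absolute number of individuals matching *all* its items
(complete-case per pattern); support is anti-monotone under item
addition, which is what allows candidate pruning. Items are ordered
lexicographically, candidates are generated by prefix joins, a candidate
is discarded if any sub-pattern is infrequent, and the two items of one
SNP are never joined (their co-support is structurally zero). The set is
then reduced to *closed* patterns — those with no strict superset of
identical support — by `closed_filter()`. Two choices deserve note:

* Closure is evaluated within the length-bounded frequent set. A
  length-3 pattern cannot be unseated by a length-4 superset because
  none is enumerated.
* Because the mined set is complete up to the length bound and support
  is anti-monotone, a pattern is non-closed exactly when some one-item
  extension has equal support, so the reduction only inspects immediate
  extensions; this keeps it linear in the number of patterns.

### Rule statistics

For a pattern and a cluster, individuals with complete data on all
involved variables are cross-classified into the 2x2 table (a, b, c, d)
= (both present, pattern only, cluster only, neither). All statistics
derive from it:

* Pearson chi-squared, 1 df, no continuity correction:
  `chi2 = n(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. The choice of no
  correction is validated by exact reproduction of the published
  worked-example p-values from their printed counts.
* The interestingness z-score is the signed root of chi-squared, with
  the sign of `a` minus its independence expectation. `z^2 = chi2` is an
  algebraic identity, so the discovery threshold z >= 5 is "chi2 >= 25
  and positively associated". Only positive associations become
  candidates: rules predict phenotype presence.
* The odds ratio is the raw cross-product `ad/bc` with a 95% Wald
  interval on the log scale; `correction = "haldane"` adds 0.5 to every
  cell when any cell is zero. The motivating study prints slightly
  different odds ratios (e.g. 3.566 where the cross-product gives 3.556)
  computed by an unstated method; snprules deliberately reports the raw
  cross-product and does not attempt to guess the variant.
* A table with a zero margin is degenerate: chi2 = 0, p = 1, z = 0,
  flagged rather than dropped silently.

Default thresholds follow the motivating analysis: absolute minimum
support 50, maximum pattern length 3, z >= 5.0. Phenotype clusters are
all single features plus all unordered pairs whose joint (complete-case)
prevalence reaches 5%, mirroring the study's feature-frequency floor;
the consequent is a conjunction, and `max_rhs_len = 1` restricts to
single features.

### Replication and multiple testing

`replicate_rules()` recomputes every candidate's table on independent
data. With `n_CR` candidate rules, the Bonferroni test-wide level is
`alpha_adj = alpha / n_CR`; Benjamini-Hochberg adjusted p-values are
reported alongside because mined rules are strongly dependent and
Bonferroni is conservative for them. The BH implementation supports
adjusting a top-k list against the full family size, under the
assumption that the unobserved p-values are large enough not to lower
the step-up running minimum; that assumption is exact for the published
worked example and is the intended use (a top table carried forward,
corrected against all of `n_CR`). Rules whose items or features are
absent from the replication data are flagged untestable and, by
default, still count in `n_CR` (the conservative choice).

### Permutation nulls

Two schemes estimate how surprising a single rule is:

* `permute_phenotype()` re-assigns whole phenotype rows to individuals,
  preserving inter-feature correlation. Permuting rows jointly (rather
  than single features) was chosen because the consequent may be a
  two-feature cluster whose internal correlation must survive the
  permutation.
* `random_patterns()` draws random item sets of the same length
  (distinct SNPs, one of the two items each, uniformly), asking how
  often an arbitrary pattern associates as strongly.

Empirical p is `n_exceed / n_perm`, matching the granularity of printed
values like 4.000e-06 at one million trials; the positively biased
add-one estimator is available via `add_one = TRUE`. Exceedances are
counted with `>=`, which makes the estimate valid but slightly
conservative on discrete statistics.

## The synthetic-data generator

`simulate_rule_data()` produces datasets with the structure the analysis
assumes: independent SNPs in Hardy-Weinberg equilibrium at MAFs uniform
in a range, and independent Bernoulli features; defaults emulate the
study conditions (cohorts of ~1000-2000 cases, 23 features with
prevalences spanning 5-80%, phenotype missingness 5%, genotypes complete
as after imputation). A planted rule multiplies the odds of one target
feature for carriers of a chosen pattern, so the planted parameter is
exactly the odds ratio the pipeline estimates; planted effect sizes of
3-4 mirror the magnitude of the study's replicated rules. An optional
block-LD mode (adjacent-SNP copying with probability `ld_copy_prob`)
exists solely to exercise `ld_prune()`; the analysis proper operates on
pruned data, so the default is independence.

What the generator does **not** emulate: population structure and
relatedness, realistic LD beyond the toy block mode, imputation
uncertainty, correlated clinical features, and ascertainment effects.
Passing tests on synthetic data therefore demonstrate the correctness
and calibration of the machinery, not robustness to those real-data
complications.

## Validation experiments and problem sizes

The test suite validates the machinery at scales chosen to keep the full
suite in a few minutes while leaving no statistical check underpowered:

* **Equivalence with enumeration.** Mining (and closure) equals
  brute-force subset enumeration on 1000 random instances of up to 12
  items and 40 individuals, with and without missingness.
* **Worked examples.** The ten published replication tables reproduce
  their chi-squared p-values to the printed 4 significant digits, the
  Bonferroni and FDR columns, the adjusted level 2.394e-06, and the
  published outcome pattern (2 rules Bonferroni-significant, 5 at
  FDR <= 0.05).
* **Power.** A planted 3-SNP rule (odds ratio 4, 10% pattern frequency,
  10% feature prevalence, n = 2000, 12 SNPs, 6 features) is recovered
  among candidates in >= 80% of 100 seeded runs; the normal
  approximation predicts z around 8.5, far above the threshold of 5.
* **Estimation.** Over 200 replicates the estimated odds ratio is
  within 10% of the planted value and the Wald interval covers it 95%
  +/- 3% of the time.
* **Null calibration.** On null data the candidate yield is compared
  with the analytic expectation `n_tests x P(chi2_1 >= 25)/2` within 3
  binomial standard deviations. This oracle is only meaningful where
  the asymptotic chi-squared tail is accurate, so the null experiment
  is run at n = 2000 with single-feature clusters of prevalence
  0.30-0.50 and MAFs 0.3-0.5 — keeping every expected cell above ~15 —
  and pooled over five seeds (~8 million tests) so that clusters of
  correlated sibling patterns cannot dominate the count. At the study's
  rarest prevalences the same comparison would be invalid: with
  expected cells of 3-6 the chi-squared tail at 25 is severely
  anti-conservative and the yield exceeds the analytic value many-fold.
  That behaviour is a property of the Pearson statistic on sparse
  tables (and one reason the motivating design insists on replication),
  not an implementation artifact.
* **Permutation calibration.** Under independence the empirical
  permutation p is uniform (Kolmogorov-Smirnov at the 1% level over 500
  replicates of 200 permutations each, n = 500); results are exactly
  reproducible by seed.

## Numerical and design choices

* Ties in BH rank assignment are broken by stable input order;
  `bh_adjust()` delegates the step-up to `stats::p.adjust(method =
  "BH", n = n_tests)` after validation, and the tests cross-check it
  against an independent rank-definition implementation.
* The Cochran-Armitage trend test (`trend_test()`, scores 0/1/2) wraps
  `stats::prop.trend.test` and attaches the trend direction as a sign;
  the tests cross-check it against a logistic-regression Rao score
  test.
* LD pruning is greedy PLINK-style pairwise pruning (default r2 > 0.5
  within 50-SNP windows sliding by 5): the later SNP of an offending
  pair is dropped, sweeps repeat to a fixed point, so the result is
  idempotent. r2 uses pairwise-complete dosages; zero-variance SNPs
  get r2 = 0 and never evict others.
* Rule IDs are deterministic enumeration indices over (pattern,
  cluster) order. The published rule labels (e.g. #12978) are opaque
  and not reconstructible; the bundled worked-example table simply
  carries them as labels.
* All randomness flows through explicit integer seeds pinned to the
  Mersenne-Twister generator, so results are identical across
  platforms.

## Limitations

Only the dominant genetic model is implemented; the discovery-stage
correction universe of the motivating study (its exact pattern count) is
not reconstructible from the publication, so discovery-stage adjusted
p-values are left to the user via `n_tests`; and the 2x2 machinery
offers no covariate adjustment — rules found here are unadjusted
associations, not effect estimates conditioned on ancestry or site.
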