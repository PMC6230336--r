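#' Example replication-stage contingency tables
#'
#' The replication 2x2 counts of the ten strongest candidate rules from a
#' published bipolar-disorder rule-mining study (replication cohort of
#' n = 1835 patients; 20,882 candidate rules carried forward from
#' discovery). Each row gives the rule label, the counts `a` (genotype
#' pattern and phenotype cluster both present) through `d` (neither
#' present), and the p-value, odds ratio and adjusted p-values as printed
#' in the source table, for cross-checking the package's statistics.
#'
#' @return A tibble with columns `rule_id`, `a`, `b`, `c`, `d`,
#'   `p_printed`, `or_printed`, `bonferroni_printed`, `fdr_printed`.
#' @examples
#' tab <- example_replication_rules()
#' chi2_test(tab$a, tab$b, tab$c, tab$d)
#' @export
example_replication_rules <- function() {
  tibble::tribble(
    ~rule_id, ~a,  ~b,   ~c,   ~d,    ~p_printed, ~or_printed, ~bonferroni_printed, ~fdr_printed,
    12978L,   25L, 105L, 107L, 1598L, 3.576e-08,  3.566,       0.00075,             0.00075,
    6221L,    26L, 84L,  162L, 1563L, 1.780e-06,  2.995,       0.03717,             0.01859,
    12681L,   33L, 103L, 187L, 1512L, 4.648e-06,  2.596,       0.09706,             0.02771,
    12981L,   25L, 129L, 107L, 1574L, 5.720e-06,  2.860,       0.11944,             0.02771,
    6225L,    25L, 84L,  163L, 1563L, 6.635e-06,  2.862,       0.13855,             0.02771,
    6228L,    26L, 93L,  162L, 1554L, 1.585e-05,  2.690,       0.33102,             0.05517,
    4428L,    31L, 88L,  212L, 1504L, 2.021e-05,  2.505,       0.42198,             0.06028,
    6111L,    21L, 109L, 111L, 1594L, 4.096e-05,  2.779,       0.85530,             0.10654,
    6183L,    20L, 66L,  168L, 1581L, 4.592e-05,  2.864,       0.95887,             0.10654,
    6178L,    20L, 68L,  168L, 1579L, 7.577e-05,  2.777,       1.00000,             0.15823
  )
}

#' Number of candidate rules in the example study
#'
#' The discovery stage of the study behind
#' [example_replication_rules()] carried 20,882 candidate rules to
#' replication; this constant sizes the multiple-testing family for the
#' worked examples.
#'
#' @return Integer.
#' @export
example_n_candidate_rules <- function() 20882L
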