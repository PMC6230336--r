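Package: snprules
Title: Association Rule Mining for Genotype-Phenotype Dissection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Mines frequent multi-SNP genotype patterns in binarized
    GWAS-style case data with the Apriori algorithm, extracts candidate
    association rules linking genotype patterns to clusters of binary
    clinical features via 2x2 contingency statistics (z-score, Pearson
    chi-squared, odds ratio), and validates candidate rules in an
    independent replication dataset with Bonferroni and
    Benjamini-Hochberg correction and permutation nulls. Includes a
    PLINK additive-dosage ('recode A') reader/writer, dominant-model
    binarization, sliding-window LD pruning, and a synthetic-data
    generator with planted rules for power and calibration studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
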