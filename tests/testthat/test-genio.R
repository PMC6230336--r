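test_that("PLINK recode-A parsing handles dosages, alleles and missing cells", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_G",
    "f1 i1 0 0 1 2 0 NA",
    "f2 i2 0 0 2 1 2 1"
  ), path)
  g <- read_plink_raw(path)
  expect_equal(g$IID, c("i1", "i2"))
  expect_equal(g$rs1_A, c(0L, 2L))
  expect_equal(g$rs2_G, c(NA, 1L))
  meta <- snp_meta(g)
  expect_equal(meta$snp_id, c("rs1", "rs2"))
  expect_equal(meta$counted_allele, c("A", "G"))
})

test_that("malformed headers and out-of-range dosages are rejected with context", {
  bad_header <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID SEX rs1_A", "f1 i1 1 0"), bad_header)
  expect_error(read_plink_raw(bad_header), class = "snprules_format_error")

  bad_value <- withr::local_tempfile(fileext = ".raw")
  writeLines(c(
    "FID IID PAT MAT SEX PHENOTYPE rs1_A",
    "f1 i1 0 0 1 2 3"
  ), bad_value)
  expect_error(read_plink_raw(bad_value), "row 1, column 'rs1_A'",
               class = "snprules_value_error")
})

test_that("write/read of a .raw file round-trips a random dosage matrix", {
  withr::local_seed(11)
  geno <- simulate_rule_data(n_individuals = 10, n_snps = 5,
                             geno_missing_rate = 0.1, seed = 7)$genotypes
  path <- withr::local_tempfile(fileext = ".raw")
  write_plink_raw(geno, path)
  expect_equal(read_plink_raw(path), geno)
})

test_that("phenotype reading maps codes, rejects duplicates and non-binary values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "IID\tf1\tf2",
    "i1\t1\t-9",
    "i2\t1\t0",
    "i3\t1\t1"
  ), path)
  ph <- read_phenotypes(path, missing_codes = "-9")
  expect_equal(mean(ph$f1), 1.0)
  expect_equal(ph$f2, c(NA, FALSE, TRUE))

  dup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IID\tf1", "i1\t1", "i1\t0"), dup)
  expect_error(read_phenotypes(dup), class = "snprules_value_error")

  nonbin <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IID\tf1", "i1\t2"), nonbin)
  expect_error(read_phenotypes(nonbin), class = "snprules_value_error")
})

test_that("a phenotype fixture with planted missingness reads back exactly", {
  withr::local_seed(3)
  n <- 50
  vals <- rep(c("0", "1"), length.out = n)
  vals[sample.int(n, 5)] <- "-9"
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("IID\tf1", paste0(sprintf("i%02d", 1:n), "\t", vals)), path)
  ph <- read_phenotypes(path, missing_codes = "-9")
  expect_equal(mean(is.na(ph$f1)), 0.10)
  rt <- withr::local_tempfile(fileext = ".tsv")
  write_phenotypes(ph, rt)
  expect_equal(read_phenotypes(rt), ph)
})

test_that("dominant binarization yields two complementary items per SNP", {
  geno <- tibble::tibble(IID = c("i1", "i2", "i3", "i4"),
                         rs1_A = c(0L, 1L, 2L, NA))
  items <- binarize_dominant(geno)
  expect_equal(setdiff(names(items), "IID"), c("rs1_A_0", "rs1_A_1"))
  expect_equal(items$rs1_A_0, c(TRUE, FALSE, FALSE, NA))
  expect_equal(items$rs1_A_1, c(FALSE, TRUE, TRUE, NA))

  # item count is exactly twice the SNP count at study scale
  wide <- simulate_rule_data(n_individuals = 2, n_snps = 1581, seed = 5)$genotypes
  expect_equal(ncol(binarize_dominant(wide)) - 1L, 3162L)
})

test_that("binarization is complementary and lossless on a random matrix", {
  sim <- simulate_rule_data(n_individuals = 50, n_snps = 20,
                            geno_missing_rate = 0.07, seed = 21)
  items <- binarize_dominant(sim$genotypes)
  for (s in setdiff(names(sim$genotypes), "IID")) {
    d <- sim$genotypes[[s]]
    i0 <- items[[paste0(s, "_0")]]
    i1 <- items[[paste0(s, "_1")]]
    obs <- !is.na(d)
    # exactly one item true wherever the dosage is observed
    expect_true(all(xor(i0[obs], i1[obs])))
    # carrier status reconstructs exactly; missing propagates to both
    expect_equal(i1[obs], d[obs] >= 1)
    expect_true(all(is.na(i0[!obs]) & is.na(i1[!obs])))
  }
})

test_that("LD pruning drops duplicated SNPs and spares independent ones", {
  sim <- simulate_rule_data(n_individuals = 300, n_snps = 6, seed = 2)
  geno <- sim$genotypes
  geno$dupl_A <- geno[[2]]  # exact copy, r2 = 1
  kept <- ld_prune(geno, r2_max = 0.5, window = 10, step = 2)
  expect_true(xor("dupl_A" %in% kept, names(geno)[2] %in% kept))
  expect_lte(length(kept), ncol(geno) - 1L)

  # independent SNPs at MAF 0.3 survive pruning almost always
  frac_kept <- vapply(1:20, function(s) {
    g <- simulate_rule_data(n_individuals = 500, n_snps = 30,
                            maf_range = c(0.3, 0.3), seed = 100 + s)$genotypes
    length(ld_prune(g, r2_max = 0.5, window = 50, step = 5)) / 30
  }, numeric(1))
  expect_gte(mean(frac_kept), 0.95)
})

test_that("LD pruning is idempotent and ignores zero-variance SNPs", {
  sim <- simulate_rule_data(n_individuals = 200, n_snps = 20,
                            ld_block_size = 4, ld_copy_prob = 0.95, seed = 9)
  geno <- sim$genotypes
  geno$mono_A <- 1L  # zero variance: must never cause another SNP's removal
  kept <- ld_prune(geno, r2_max = 0.5, window = 10, step = 2)
  expect_lt(length(kept), ncol(geno) - 1L)  # blocks got pruned
  expect_true("mono_A" %in% kept)
  pruned <- geno[, c("IID", kept)]
  expect_equal(ld_prune(pruned, r2_max = 0.5, window = 10, step = 2), kept)
})
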