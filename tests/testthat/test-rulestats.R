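test_that("contingency builds the 2x2 with complete-case handling", {
  m <- tibble::tibble(IID = sprintf("i%02d", 1:4),
                      x_1 = c(TRUE, TRUE, TRUE, TRUE))
  p <- tibble::tibble(IID = sprintf("i%02d", 1:4),
                      f = c(TRUE, TRUE, TRUE, TRUE))
  expect_equal(contingency(m, p, "x_1", "f"),
               tibble::tibble(a = 4L, b = 0L, c = 0L, d = 0L, n_effective = 4L))

  p$f[1] <- NA
  expect_equal(contingency(m, p, "x_1", "f")$n_effective, 3L)
  expect_error(contingency(m, p, character(0), "f"),
               class = "snprules_value_error")
})

test_that("contingency counts equal a hand row-scan on random data", {
  withr::local_seed(19)
  m <- random_items(20, 3, density = 0.5, na_rate = 0.1)
  p <- random_pheno(20, 2, prev = 0.4, na_rate = 0.1)
  lhs <- setdiff(names(m), "IID")[1:2]
  rhs <- setdiff(names(p), "IID")
  ct <- contingency(m, p, lhs, rhs)
  pat <- m[[lhs[1]]] & m[[lhs[2]]]
  ph <- p[[rhs[1]]] & p[[rhs[2]]]
  # strict complete case: any NA among involved columns drops the row
  pat[is.na(m[[lhs[1]]]) | is.na(m[[lhs[2]]])] <- NA
  ph[is.na(p[[rhs[1]]]) | is.na(p[[rhs[2]]])] <- NA
  ok <- !is.na(pat) & !is.na(ph)
  expect_equal(ct$a, sum(pat & ph, na.rm = TRUE))
  expect_equal(ct$b, sum(pat[ok] & !ph[ok]))
  expect_equal(ct$c, sum(!pat[ok] & ph[ok]))
  expect_equal(ct$d, sum(!pat[ok] & !ph[ok]))
  expect_equal(ct$n_effective, sum(ok))
})

test_that("chi-squared reproduces published 2x2 p-values to 4 significant digits", {
  tab <- example_replication_rules()
  res <- chi2_test(tab$a, tab$b, tab$c, tab$d)
  expect_equal(signif(res$p, 4), tab$p_printed, tolerance = 1e-12)
})

test_that("chi-squared is zero under independence and flags zero margins", {
  even <- chi2_test(10, 10, 10, 10)
  expect_equal(even$chi2, 0)
  expect_equal(even$p, 1)
  expect_false(even$degenerate)

  deg <- chi2_test(0, 0, 10, 10)
  expect_true(deg$degenerate)
  expect_equal(deg$chi2, 0)
  expect_equal(deg$p, 1)
})

test_that("chi-squared matches the expected-counts formulation on random tables", {
  withr::local_seed(55)
  tabs <- random_tables(1000)
  res <- chi2_test(tabs$a, tabs$b, tabs$c, tabs$d)
  oracle <- purrr::pmap_dbl(tabs, function(a, b, c, d) {
    chi2_expected_counts(a, b, c, d)
  })
  expect_equal(res$chi2, oracle, tolerance = 1e-9)
  # p is monotone decreasing in chi2
  ord <- order(res$chi2)
  expect_true(all(diff(res$p[ord]) <= 1e-15))
})

test_that("z-score is the signed root of chi-squared with the expected sign", {
  expect_equal(z_score(10, 10, 10, 10), 0)
  expect_equal(signif(z_score(25, 105, 107, 1598), 4), 5.511)
  # swapping the phenotype labels flips the sign, same magnitude
  expect_equal(z_score(105, 25, 1598, 107), -z_score(25, 105, 107, 1598))
})

test_that("odds ratio, Haldane correction and Wald interval behave as defined", {
  expect_equal(odds_ratio(1, 1, 1, 1)$or, 1)
  top <- odds_ratio(25, 105, 107, 1598)
  expect_equal(signif(top$or, 4), 3.556)  # raw cross-product
  expect_true(top$ci_low < top$or && top$or < top$ci_high)

  inf <- odds_ratio(2, 0, 1, 5)
  expect_false(inf$or_defined)
  expect_equal(inf$or, Inf)
  hald <- odds_ratio(2, 0, 1, 5, correction = "haldane")
  expect_true(is.finite(hald$or))
  expect_equal(hald$or, (2.5 * 5.5) / (0.5 * 1.5))
})

test_that("trend test matches a logistic score-test oracle", {
  same <- trend_test(c(30, 10, 5), c(30, 10, 5))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)

  tt <- trend_test(c(30, 10, 0), c(10, 10, 20))
  oracle <- trend_oracle(c(30, 10, 0), c(10, 10, 20))
  expect_equal(tt$chi2, oracle$chi2, tolerance = 1e-3)
  expect_equal(tt$p, oracle$p, tolerance = 1e-3)
  expect_lt(tt$z, 0)  # case fraction decreases with dosage here

  withr::local_seed(8)
  for (i in 1:20) {
    cases <- sample.int(40, 3)
    controls <- sample.int(40, 3)
    got <- trend_test(cases, controls)
    want <- trend_oracle(cases, controls)
    expect_equal(got$chi2, want$chi2, tolerance = 1e-3)
  }

  # swapping groups flips the trend sign, same p
  sw <- trend_test(c(10, 10, 20), c(30, 10, 0))
  expect_equal(sw$z, -tt$z)
  expect_equal(sw$p, tt$p)

  # concentrated genotype distribution is degenerate
  deg <- trend_test(c(10, 0, 0), c(5, 0, 0))
  expect_true(deg$degenerate)
  expect_equal(deg$p, 1)
})

test_that("pattern case-control test composes contingency and chi-squared", {
  withr::local_seed(23)
  m <- random_items(80, 4, density = 0.6)
  lhs <- setdiff(names(m), "IID")[1:2]
  group <- runif(80) < 0.5
  got <- pattern_group_test(m, lhs, group)

  ph <- dplyr::bind_cols(m["IID"], tibble::tibble(grp = group))
  want_ct <- contingency(m, ph, lhs, "grp")
  want <- chi2_test(want_ct$a, want_ct$b, want_ct$c, want_ct$d)
  expect_equal(got[c("a", "b", "c", "d")], want_ct[c("a", "b", "c", "d")])
  expect_equal(got$chi2, want$chi2)
  expect_equal(got$p, want$p)

  # jointly permuting individuals leaves the result unchanged
  perm <- sample.int(80)
  got2 <- pattern_group_test(m[perm, ], lhs, group[perm])
  expect_equal(got2, got)

  # labels identical to carrier status: single-group columns are degenerate
  carrier <- m[[lhs[1]]] & m[[lhs[2]]]
  ident <- pattern_group_test(m, lhs, carrier)
  expect_equal(ident$b, 0)
  expect_equal(ident$c, 0)
  expect_equal(ident$chi2, ident$n_effective)  # maximal chi2 for these margins
})
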