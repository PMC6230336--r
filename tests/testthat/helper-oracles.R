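# Independent oracles and fixture builders shared across tests. These stay
# deliberately naive (row scans, exhaustive enumeration, textbook formulas)
# so they check the optimized implementations from the outside.

# exhaustive frequent-itemset enumeration by row scan
brute_force_frequent <- function(items, min_support, max_len) {
  ids <- sort(setdiff(names(items), "IID"))
  m <- as.matrix(items[, ids, drop = FALSE])
  out <- list()
  for (k in seq_len(min(max_len, length(ids)))) {
    for (s in combn(ids, k, simplify = FALSE)) {
      status <- rowSums(m[, s, drop = FALSE]) == k
      sup <- sum(status, na.rm = TRUE)
      if (sup >= min_support) {
        out[[length(out) + 1L]] <- list(pattern = paste(s, collapse = ","),
                                        support = sup)
      }
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(pattern = character(0), support = integer(0)))
  }
  tibble::tibble(
    pattern = vapply(out, `[[`, character(1), "pattern"),
    support = vapply(out, function(x) as.integer(x$support), integer(1))
  )
}

# closed reduction by direct definition on the brute-force set
brute_force_closed <- function(freq) {
  keep <- vapply(seq_len(nrow(freq)), function(i) {
    si <- strsplit(freq$pattern[i], ",", fixed = TRUE)[[1]]
    for (j in seq_len(nrow(freq))) {
      if (j == i || freq$support[j] != freq$support[i]) next
      sj <- strsplit(freq$pattern[j], ",", fixed = TRUE)[[1]]
      if (length(sj) > length(si) && all(si %in% sj)) return(FALSE)
    }
    TRUE
  }, logical(1))
  freq[keep, , drop = FALSE]
}

# textbook chi-squared via expected counts
chi2_expected_counts <- function(a, b, c, d) {
  o <- c(a, b, c, d)
  n <- sum(o)
  e <- c((a + b) * (a + c), (a + b) * (b + d),
         (c + d) * (a + c), (c + d) * (b + d)) / n
  sum((o - e)^2 / e)
}

# step-up BH by the rank definition, independent of stats::p.adjust
bh_oracle <- function(p, n_tests = length(p)) {
  ord <- order(p)
  ps <- p[ord]
  k <- length(p)
  adj <- numeric(k)
  for (i in seq_len(k)) {
    adj[i] <- min(1, min(ps[i:k] * n_tests / (i:k)))
  }
  out <- numeric(k)
  out[ord] <- adj
  out
}

# Cochran-Armitage oracle: Rao score test of a binomial GLM in the dosage
trend_oracle <- function(case_counts, control_counts) {
  df <- data.frame(
    dose = rep(0:2, times = 2),
    y = rep(c(1, 0), each = 3),
    w = c(case_counts, control_counts)
  )
  df <- df[df$w > 0, ]
  fit <- glm(y ~ dose, family = binomial, data = df, weights = df$w)
  an <- anova(fit, test = "Rao")
  list(chi2 = an$Rao[2], p = an$`Pr(>Chi)`[2])
}

# random binary item tibble; items get distinct SNP stems
random_items <- function(n, k, density = 0.5, na_rate = 0,
                         ids = sprintf("it%02d_X_1", seq_len(k))) {
  vals <- matrix(runif(n * k) < density, nrow = n)
  if (na_rate > 0) vals[matrix(runif(n * k) < na_rate, nrow = n)] <- NA
  tbl <- tibble::as_tibble(as.data.frame(vals))
  names(tbl) <- ids
  dplyr::bind_cols(tibble::tibble(IID = sprintf("i%03d", seq_len(n))), tbl)
}

random_pheno <- function(n, k, prev = 0.4, na_rate = 0) {
  vals <- matrix(runif(n * k) < prev, nrow = n)
  if (na_rate > 0) vals[matrix(runif(n * k) < na_rate, nrow = n)] <- NA
  tbl <- tibble::as_tibble(as.data.frame(vals))
  names(tbl) <- sprintf("feat%02d", seq_len(k))
  dplyr::bind_cols(tibble::tibble(IID = sprintf("i%03d", seq_len(n))), tbl)
}

# the 4-individual worked mining fixture: A = 1111, B = 1100, C = 1000
mining_fixture <- function() {
  tibble::tibble(
    IID = sprintf("i%d", 1:4),
    A = c(TRUE, TRUE, TRUE, TRUE),
    B = c(TRUE, TRUE, FALSE, FALSE),
    C = c(TRUE, FALSE, FALSE, FALSE)
  )
}

# random non-degenerate 2x2 tables
random_tables <- function(n_tables, max_cell = 200) {
  repeat {
    a <- sample.int(max_cell, n_tables, replace = TRUE)
    b <- sample.int(max_cell, n_tables, replace = TRUE)
    c <- sample.int(max_cell, n_tables, replace = TRUE)
    d <- sample.int(max_cell, n_tables, replace = TRUE)
    return(tibble::tibble(a = a, b = b, c = c, d = d))
  }
}
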