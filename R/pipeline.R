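#' Enumerate phenotype clusters
#'
#' Rule consequents are conjunctions of 1 to `max_rhs_len` clinical
#' features. All single features and (for `max_rhs_len = 2`) all unordered
#' feature pairs are enumerated, and a cluster is kept when its joint
#' prevalence among individuals with complete data on its features is at
#' least `min_prevalence` (mirroring the 5% feature-frequency selection
#' floor).
#'
#' @param pheno Phenotype tibble (`IID` + logical feature columns).
#' @param max_rhs_len Maximum number of features per cluster (1 or 2).
#' @param min_prevalence Minimum joint prevalence, complete-case.
#' @return Tibble with `cluster` (comma-joined feature names), `features`
#'   (list column) and `prevalence`.
#' @export
phenotype_clusters <- function(pheno, max_rhs_len = 2, min_prevalence = 0.05) {
  stopifnot(max_rhs_len %in% c(1, 2), min_prevalence >= 0, min_prevalence < 1)
  feats <- setdiff(names(pheno), "IID")
  sets <- lapply(feats, identity)
  if (max_rhs_len >= 2 && length(feats) >= 2) {
    prs <- combn(feats, 2, simplify = FALSE)
    sets <- c(sets, prs)
  }
  prev <- vapply(sets, function(fs) {
    status <- conjunction_status(pheno, fs)
    if (all(is.na(status))) return(NA_real_)
    mean(status, na.rm = TRUE)
  }, numeric(1))
  keep <- !is.na(prev) & prev >= min_prevalence
  tibble(
    cluster = vapply(sets[keep], paste, character(1), collapse = ","),
    features = sets[keep],
    prevalence = prev[keep]
  )
}

#' Discover candidate genotype-phenotype association rules
#'
#' The discovery stage: mines closed frequent genotype patterns in the
#' (case-only) item matrix with [apriori_frequent()] and [closed_filter()],
#' then tests every pattern against every phenotype cluster with the 2x2
#' chi-squared machinery, keeping rules whose signed z-score reaches
#' `z_min` (positive associations only: rules predict phenotype presence).
#' Individuals are aligned between the two tables by `IID` before mining.
#'
#' @param items Binary item tibble (`IID` + logical item columns).
#' @param pheno Phenotype tibble (`IID` + logical feature columns).
#' @param min_support Absolute minimum pattern support (default 50).
#' @param max_len Maximum pattern length (default 3).
#' @param z_min Candidate z-score threshold (default 5.0).
#' @param max_rhs_len Maximum features per phenotype cluster (default 2).
#' @param min_cluster_prev Minimum cluster prevalence (default 0.05).
#' @return A `snprules_rules` tibble with one row per candidate rule:
#'   `rule_id`, `lhs_items`, `rhs_features`, `support`, counts `a`..`d`,
#'   `n_effective`, `z`, `chi2`, `p_chisq`, `odds_ratio`, `ci_low`,
#'   `ci_high`. Attributes record the configuration and the counts at each
#'   stage (`n_patterns`, `n_closed`, `n_clusters`, `n_tests`).
#' @export
discover <- function(items, pheno, min_support = 50, max_len = 3,
                     z_min = 5.0, max_rhs_len = 2, min_cluster_prev = 0.05) {
  validate_items(items)
  common <- intersect(items$IID, pheno$IID)
  if (length(common) == 0) {
    abort("no overlapping individuals between item and phenotype tables",
          class = "snprules_value_error")
  }
  items <- items[match(common, items$IID), , drop = FALSE]
  pheno <- pheno[match(common, pheno$IID), , drop = FALSE]
  n <- length(common)

  freq <- apriori_frequent(items, min_support = min_support, max_len = max_len)
  closed <- closed_filter(freq)
  clusters <- phenotype_clusters(pheno, max_rhs_len = max_rhs_len,
                                 min_prevalence = min_cluster_prev)

  cfg <- list(min_support = min_support, max_len = max_len, z_min = z_min,
              max_rhs_len = max_rhs_len, min_cluster_prev = min_cluster_prev)
  counts <- list(n_individuals = n, n_items = ncol(items) - 1L,
                 n_patterns = nrow(freq), n_closed = nrow(closed),
                 n_clusters = nrow(clusters),
                 n_tests = nrow(closed) * nrow(clusters))
  if (nrow(closed) == 0 || nrow(clusters) == 0) {
    return(new_rules(empty_rules(), cfg, counts))
  }

  # cluster status indicators (missing contributes to neither)
  ph_status <- vapply(clusters$features,
                      function(fs) conjunction_status(pheno, fs), logical(n))
  ph_status <- matrix(ph_status, nrow = n)
  pht <- ifelse(is.na(ph_status), 0, as.numeric(ph_status))
  phf <- ifelse(is.na(ph_status), 0, as.numeric(!ph_status))

  item_na <- lapply(setdiff(names(items), "IID"),
                    function(it) which(is.na(items[[it]])))
  names(item_na) <- setdiff(names(items), "IID")
  idx_sets <- attr(closed, "index_sets")

  res <- list()
  block_size <- 2000L
  n_pat <- nrow(closed)
  for (b0 in seq(1L, n_pat, by = block_size)) {
    b1 <- min(b0 + block_size - 1L, n_pat)
    bidx <- b0:b1
    patt <- matrix(0, nrow = n, ncol = length(bidx))
    patf <- matrix(0, nrow = n, ncol = length(bidx))
    for (k in seq_along(bidx)) {
      true_rows <- idx_sets[[bidx[k]]]
      na_rows <- unique(unlist(item_na[closed$items[[bidx[k]]]], use.names = FALSE))
      patt[true_rows, k] <- 1
      patf[, k] <- 1
      patf[true_rows, k] <- 0
      if (length(na_rows) > 0) patf[na_rows, k] <- 0
    }
    a <- crossprod(patt, pht)
    b <- crossprod(patt, phf)
    cc <- crossprod(patf, pht)
    d <- crossprod(patf, phf)
    z <- z_score(as.vector(a), as.vector(b), as.vector(cc), as.vector(d))
    hit <- which(z >= z_min)
    if (length(hit) > 0) {
      pi <- ((hit - 1L) %% length(bidx)) + 1L   # pattern within block
      ci <- ((hit - 1L) %/% length(bidx)) + 1L  # cluster index
      res[[length(res) + 1L]] <- tibble(
        pattern_index = bidx[pi], cluster_index = ci,
        a = as.vector(a)[hit], b = as.vector(b)[hit],
        c = as.vector(cc)[hit], d = as.vector(d)[hit], z = z[hit]
      )
    }
  }

  if (length(res) == 0) {
    return(new_rules(empty_rules(), cfg, counts))
  }
  hits <- bind_rows(res) %>%
    arrange(.data$pattern_index, .data$cluster_index)
  ct <- chi2_test(hits$a, hits$b, hits$c, hits$d)
  or <- odds_ratio(hits$a, hits$b, hits$c, hits$d)
  rules <- tibble(
    rule_id = seq_len(nrow(hits)),
    lhs_items = closed$pattern[hits$pattern_index],
    rhs_features = clusters$cluster[hits$cluster_index],
    support = closed$support[hits$pattern_index],
    a = hits$a, b = hits$b, c = hits$c, d = hits$d,
    n_effective = hits$a + hits$b + hits$c + hits$d,
    z = hits$z, chi2 = ct$chi2, p_chisq = ct$p,
    odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high
  )
  counts$n_candidates <- nrow(rules)
  new_rules(rules, cfg, counts)
}

empty_rules <- function() {
  tibble(
    rule_id = integer(0), lhs_items = character(0), rhs_features = character(0),
    support = integer(0), a = numeric(0), b = numeric(0), c = numeric(0),
    d = numeric(0), n_effective = numeric(0), z = numeric(0), chi2 = numeric(0),
    p_chisq = numeric(0), odds_ratio = numeric(0), ci_low = numeric(0),
    ci_high = numeric(0)
  )
}

new_rules <- function(tbl, config, counts) {
  if (is.null(counts$n_candidates)) counts$n_candidates <- nrow(tbl)
  structure(tbl, config = config, counts = counts,
            class = c("snprules_rules", class(tibble())))
}

#' Replicate candidate rules in an independent dataset
#'
#' Recomputes each candidate rule's contingency table and statistics on
#' the replication data, then applies Bonferroni and Benjamini-Hochberg
#' correction with the family size `n_CR` (by default the full number of
#' candidate rules, including any that cannot be evaluated in the
#' replication data). A rule is significant under Bonferroni when its
#' replication p-value is at or below `alpha / n_CR`, and under FDR when
#' its BH-adjusted p-value is at or below `alpha`.
#'
#' @param rules Candidate rules: a tibble with `lhs_items` and
#'   `rhs_features` columns (comma-joined IDs), as from [discover()].
#' @param items Replication binary item tibble.
#' @param pheno Replication phenotype tibble.
#' @param alpha Family-wise significance level (default 0.05).
#' @param n_cr Family size for correction; defaults to `nrow(rules)`.
#' @return A `snprules_replication` tibble: `rule_id`, `lhs_items`,
#'   `rhs_features`, replication counts and statistics, `bonferroni`,
#'   `fdr`, `significant_bonferroni`, `significant_fdr`, and `untestable`
#'   (true when a rule's items or features are absent from the
#'   replication data).
#' @export
replicate_rules <- function(rules, items, pheno, alpha = 0.05,
                            n_cr = nrow(rules)) {
  stopifnot(is.data.frame(rules),
            all(c("lhs_items", "rhs_features") %in% names(rules)))
  validate_items(items)
  if (nrow(rules) == 0) {
    abort("no candidate rules to replicate", class = "snprules_value_error")
  }
  stopifnot(n_cr >= nrow(rules))
  rule_id <- if ("rule_id" %in% names(rules)) rules$rule_id else seq_len(nrow(rules))

  item_names <- names(items)
  feat_names <- names(pheno)
  out <- purrr::map(seq_len(nrow(rules)), function(i) {
    lhs <- strsplit(rules$lhs_items[i], ",", fixed = TRUE)[[1]]
    rhs <- strsplit(rules$rhs_features[i], ",", fixed = TRUE)[[1]]
    if (!all(lhs %in% item_names) || !all(rhs %in% feat_names)) {
      return(tibble(a = NA_real_, b = NA_real_, c = NA_real_, d = NA_real_,
                    n_effective = NA_real_, untestable = TRUE))
    }
    ct <- contingency(items, pheno, lhs, rhs)
    ct$untestable <- FALSE
    ct
  }) %>% bind_rows()

  stats <- chi2_test(out$a, out$b, out$c, out$d)
  or <- odds_ratio(out$a, out$b, out$c, out$d)
  p <- ifelse(out$untestable, NA_real_, stats$p)

  testable <- which(!out$untestable)
  fdr <- rep(NA_real_, nrow(out))
  if (length(testable) > 0) {
    fdr[testable] <- bh_adjust(p[testable], n_tests = n_cr)
  }
  thr <- alpha_adjusted(n_cr, alpha)

  rep_tbl <- tibble(
    rule_id = rule_id,
    lhs_items = rules$lhs_items,
    rhs_features = rules$rhs_features,
    a = out$a, b = out$b, c = out$c, d = out$d,
    n_effective = out$n_effective,
    z = ifelse(out$untestable, NA_real_,
               z_score(out$a, out$b, out$c, out$d)),
    chi2 = ifelse(out$untestable, NA_real_, stats$chi2),
    p_chisq = p,
    odds_ratio = ifelse(out$untestable, NA_real_, or$or),
    ci_low = or$ci_low, ci_high = or$ci_high,
    bonferroni = ifelse(out$untestable, NA_real_, bonferroni_adjust_na(p, n_cr)),
    fdr = fdr,
    significant_bonferroni = !out$untestable & !is.na(p) & p <= thr,
    significant_fdr = !out$untestable & !is.na(fdr) & fdr <= alpha,
    untestable = out$untestable
  )
  structure(rep_tbl,
            alpha = alpha, n_cr = n_cr, alpha_adjusted = thr,
            class = c("snprules_replication", class(tibble())))
}

bonferroni_adjust_na <- function(p, n_tests) {
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  if (any(ok)) out[ok] <- bonferroni_adjust(p[ok], n_tests)
  out
}

#' Pool datasets and re-evaluate one rule
#'
#' Concatenates the individuals of several dataset pairs (e.g. discovery
#' plus replication cohorts), rebuilds the rule's 2x2 table on the pooled
#' data and returns the full statistics. Individual IDs must be disjoint
#' across datasets.
#'
#' @param rule One-row tibble (or list) with `lhs_items` and
#'   `rhs_features` (comma-joined IDs).
#' @param datasets List of `list(items = , pheno = )` pairs.
#' @return One-row tibble with pooled counts and statistics.
#' @export
combine_and_test <- function(rule, datasets) {
  stopifnot(length(datasets) >= 1)
  lhs <- strsplit(rule$lhs_items[1], ",", fixed = TRUE)[[1]]
  rhs <- strsplit(rule$rhs_features[1], ",", fixed = TRUE)[[1]]
  ids <- unlist(lapply(datasets, function(d) d$items$IID), use.names = FALSE)
  if (anyDuplicated(ids)) {
    abort("individual IDs collide across datasets",
          class = "snprules_value_error")
  }
  items <- bind_rows(lapply(datasets, function(d) {
    d$items[, c("IID", lhs), drop = FALSE]
  }))
  pheno <- bind_rows(lapply(datasets, function(d) {
    d$pheno[, c("IID", rhs), drop = FALSE]
  }))
  ct <- contingency(items, pheno, lhs, rhs)
  stats <- chi2_test(ct$a, ct$b, ct$c, ct$d)
  or <- odds_ratio(ct$a, ct$b, ct$c, ct$d)
  tibble(
    lhs_items = rule$lhs_items[1], rhs_features = rule$rhs_features[1],
    a = ct$a, b = ct$b, c = ct$c, d = ct$d, n_effective = ct$n_effective,
    z = z_score(ct$a, ct$b, ct$c, ct$d), chi2 = stats$chi2, p_chisq = stats$p,
    odds_ratio = or$or, ci_low = or$ci_low, ci_high = or$ci_high
  )
}

#' Write / read a rule table as TSV
#'
#' @param rules Rule tibble from [discover()] or [replicate_rules()].
#' @param path Output path.
#' @return `path` invisibly; `read_rules()` returns a tibble.
#' @export
write_rules <- function(rules, path) {
  readr::write_tsv(as_tibble(rules), path)
  invisible(path)
}

#' @rdname write_rules
#' @export
read_rules <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    lhs_items = readr::col_character(),
                    rhs_features = readr::col_character()
                  ))
}

#' Write a JSON run configuration
#'
#' Records the parameters, input paths, seed and package version of a run
#' so it can be reproduced exactly.
#'
#' @param path Output path.
#' @param ... Named configuration entries.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(path, ...) {
  cfg <- list(...)
  cfg$package <- "snprules"
  cfg$version <- as.character(packageVersion("snprules"))
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
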