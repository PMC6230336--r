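#' Support of a genotype pattern
#'
#' Counts the individuals matching every item of a pattern. An individual
#' with a missing value on any of the pattern's items is not counted
#' (complete-case per pattern).
#'
#' @param items Binary item tibble (`IID` + logical item columns), as from
#'   [binarize_dominant()].
#' @param pattern Character vector of item IDs.
#' @return Integer count.
#' @export
pattern_support <- function(items, pattern) {
  validate_items(items)
  if (length(pattern) < 1) {
    abort("pattern must contain at least one item", class = "snprules_value_error")
  }
  missing_items <- setdiff(pattern, names(items))
  if (length(missing_items) > 0) {
    abort(paste0("unknown item(s): ", paste(missing_items, collapse = ", ")),
          class = "snprules_value_error")
  }
  idx <- lapply(pattern, function(it) which(items[[it]]))
  length(Reduce(intersect, idx))
}

validate_items <- function(items) {
  if (!is.data.frame(items) || !"IID" %in% names(items) ||
      names(items)[1] != "IID") {
    abort("item matrix must be a data frame with 'IID' as first column",
          class = "snprules_value_error")
  }
  invisible(items)
}

#' Apriori enumeration of frequent genotype patterns
#'
#' Level-wise Apriori over the binary items: length-1 patterns are items
#' meeting the absolute support threshold; longer candidates are generated
#' by lexicographic prefix joins, pruned if any sub-pattern is infrequent,
#' and counted by intersecting the matching-individual sets of their
#' parents. The two items derived from one SNP are mutually exclusive and
#' are never joined (their co-support is structurally zero).
#'
#' @param items Binary item tibble (`IID` + logical item columns).
#' @param min_support Absolute minimum number of matching individuals
#'   (default 50, the discovery setting used throughout the package).
#' @param max_len Maximum pattern length (default 3).
#' @return A tibble with columns `pattern` (comma-joined item IDs), `items`
#'   (list column of item ID vectors), `length` and `support`, sorted by
#'   length then pattern. The matching-individual index sets are attached
#'   as attribute `"index_sets"` for internal reuse.
#' @export
apriori_frequent <- function(items, min_support = 50, max_len = 3) {
  validate_items(items)
  stopifnot(min_support >= 1, max_len >= 1)
  item_ids <- sort(setdiff(names(items), "IID"))
  stems <- setNames(item_stem(item_ids), item_ids)

  true_idx <- lapply(item_ids, function(it) which(items[[it]]))
  names(true_idx) <- item_ids

  # level 1
  sup1 <- lengths(true_idx)
  l1 <- item_ids[sup1 >= min_support]
  pats <- lapply(l1, function(i) i)
  idxs <- true_idx[l1]
  sups <- as.integer(sup1[l1])

  all_pats <- pats
  all_sups <- sups
  frequent <- new.env(parent = emptyenv())
  for (p in l1) assign(p, TRUE, envir = frequent)

  level_pats <- pats
  level_idxs <- unname(idxs)
  k <- 2L
  while (k <= max_len && length(level_pats) >= 2) {
    prefixes <- vapply(level_pats, function(p) {
      paste(p[-length(p)], collapse = ",")
    }, character(1))
    last <- vapply(level_pats, function(p) p[length(p)], character(1))
    ord <- order(prefixes, last)
    prefixes <- prefixes[ord]
    last <- last[ord]
    level_pats <- level_pats[ord]
    level_idxs <- level_idxs[ord]

    next_pats <- list()
    next_idxs <- list()
    next_sups <- integer(0)
    groups <- split(seq_along(prefixes), prefixes)
    for (grp in groups) {
      if (length(grp) < 2) next
      for (ai in seq_len(length(grp) - 1L)) {
        for (bi in seq.int(ai + 1L, length(grp))) {
          ia <- grp[ai]; ib <- grp[bi]
          if (stems[[last[ia]]] == stems[[last[ib]]]) next
          cand <- c(level_pats[[ia]], last[ib])
          if (!subsets_frequent(cand, frequent)) next
          idx <- intersect(level_idxs[[ia]], true_idx[[last[ib]]])
          if (length(idx) >= min_support) {
            next_pats[[length(next_pats) + 1L]] <- cand
            next_idxs[[length(next_idxs) + 1L]] <- idx
            next_sups <- c(next_sups, length(idx))
          }
        }
      }
    }
    for (p in next_pats) assign(paste(p, collapse = ","), TRUE, envir = frequent)
    all_pats <- c(all_pats, next_pats)
    all_sups <- c(all_sups, next_sups)
    idxs <- c(idxs, next_idxs)
    level_pats <- next_pats
    level_idxs <- next_idxs
    k <- k + 1L
  }

  key <- vapply(all_pats, paste, character(1), collapse = ",")
  len <- lengths(all_pats)
  ord <- order(len, key)
  out <- tibble(
    pattern = key[ord],
    items = all_pats[ord],
    length = as.integer(len[ord]),
    support = as.integer(all_sups[ord])
  )
  attr(out, "index_sets") <- unname(idxs)[ord]
  out
}

# every (k-1)-subset of cand must be frequent; the two parents are by
# construction, so only subsets dropping a prefix item need checking
subsets_frequent <- function(cand, frequent) {
  k <- length(cand)
  if (k <= 2) return(TRUE)
  for (drop in seq_len(k - 2L)) {
    key <- paste(cand[-drop], collapse = ",")
    if (!exists(key, envir = frequent, inherits = FALSE)) return(FALSE)
  }
  TRUE
}

#' Reduce frequent patterns to closed patterns
#'
#' A pattern is closed when no strict superset in the mined set has the
#' same support. Closure is evaluated within the length-bounded frequent
#' set produced by [apriori_frequent()]: a pattern at the maximum length
#' cannot be removed by a longer superset, since none is enumerated.
#'
#' Because the input holds the complete frequent set and support is
#' anti-monotone, a pattern has an equal-support strict superset iff it has
#' an equal-support superset one item larger, so only immediate extensions
#' need checking; this keeps the reduction linear in the pattern count.
#'
#' @param patterns Tibble from [apriori_frequent()] (the complete frequent
#'   set up to the length bound).
#' @return The closed subset, same columns, supports unchanged, input order
#'   preserved.
#' @export
closed_filter <- function(patterns) {
  stopifnot(is.data.frame(patterns),
            all(c("pattern", "items", "length", "support") %in% names(patterns)))
  n <- nrow(patterns)
  if (n == 0) return(patterns)
  keep <- rep(TRUE, n)
  for (len in sort(unique(patterns$length))) {
    if (len < 2) next
    rows <- which(patterns$length == len)
    mat <- matrix(unlist(patterns$items[rows], use.names = FALSE), nrow = len)
    for (drop in seq_len(len)) {
      sub_key <- if (len == 2) {
        mat[-drop, ]
      } else {
        do.call(paste, c(as.data.frame(t(mat[-drop, , drop = FALSE]),
                                       stringsAsFactors = FALSE), sep = ","))
      }
      hit <- match(sub_key, patterns$pattern)
      same <- !is.na(hit) & patterns$support[hit] == patterns$support[rows]
      keep[hit[same]] <- FALSE
    }
  }
  out <- patterns[keep, , drop = FALSE]
  if (!is.null(attr(patterns, "index_sets"))) {
    attr(out, "index_sets") <- attr(patterns, "index_sets")[keep]
  }
  out
}
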