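#' Read a PLINK additive-dosage text file (recode A)
#'
#' Parses the text format written by `plink --recode A`: a header line
#' `FID IID PAT MAT SEX PHENOTYPE` followed by one column per SNP named
#' `<snp>_<counted allele>`, with per-individual dosages of the counted
#' allele coded 0/1/2 and missing genotypes coded `NA`.
#'
#' @param path Path to a `.raw` file (whitespace-delimited text).
#' @return A tibble with an `IID` character column followed by one integer
#'   dosage column per SNP, named `<snp>_<allele>`. Missing dosages are `NA`.
#' @seealso [binarize_dominant()], [ld_prune()], [write_plink_raw()]
#' @export
read_plink_raw <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "snprules_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           na.strings = "NA", stringsAsFactors = FALSE)
  fam_cols <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (ncol(raw) < 7 || !identical(names(raw)[1:6], fam_cols)) {
    abort("malformed .raw header: expected FID IID PAT MAT SEX PHENOTYPE then SNP columns",
          class = "snprules_format_error")
  }
  snp_cols <- names(raw)[-(1:6)]
  bad_name <- snp_cols[!grepl("^.+_[A-Za-z0-9]+$", snp_cols)]
  if (length(bad_name) > 0) {
    abort(paste0("SNP column not named '<snp>_<allele>': ", bad_name[1]),
          class = "snprules_format_error")
  }
  if (anyDuplicated(snp_cols)) {
    abort("duplicated SNP columns in .raw file", class = "snprules_format_error")
  }
  geno <- tibble(IID = as.character(raw$IID))
  for (s in snp_cols) {
    v <- raw[[s]]
    ok <- is.na(v) | v %in% c(0, 1, 2)
    if (!all(ok)) {
      i <- which(!ok)[1]
      abort(sprintf("dosage outside {0,1,2,NA} at row %d, column '%s': %s",
                    i, s, as.character(v[i])),
            class = "snprules_value_error")
    }
    geno[[s]] <- as.integer(v)
  }
  geno
}

#' Write a genotype tibble as PLINK recode-A text
#'
#' Inverse of [read_plink_raw()]. Pedigree fields not carried by the tibble
#' (FID, PAT, MAT, SEX, PHENOTYPE) are written as placeholders.
#'
#' @param geno Genotype tibble (`IID` + dosage columns), as returned by
#'   [read_plink_raw()] or [simulate_rule_data()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plink_raw <- function(geno, path) {
  validate_genotypes(geno)
  out <- data.frame(FID = geno$IID, IID = geno$IID, PAT = 0L, MAT = 0L,
                    SEX = 0L, PHENOTYPE = -9L, check.names = FALSE)
  out <- cbind(out, as.data.frame(geno[, -1, drop = FALSE], check.names = FALSE))
  utils::write.table(out, path, quote = FALSE, sep = " ",
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' SNP metadata parsed from dosage column names
#'
#' @param geno Genotype tibble (`IID` + `<snp>_<allele>` dosage columns).
#' @return A tibble with columns `column` (the dosage column name), `snp_id`
#'   and `counted_allele`.
#' @export
snp_meta <- function(geno) {
  validate_genotypes(geno)
  cols <- setdiff(names(geno), "IID")
  tibble(
    column = cols,
    snp_id = sub("_[A-Za-z0-9]+$", "", cols),
    counted_allele = sub("^.+_", "", cols)
  )
}

validate_genotypes <- function(geno) {
  if (!is.data.frame(geno) || !"IID" %in% names(geno)) {
    abort("genotypes must be a data frame with an 'IID' column",
          class = "snprules_value_error")
  }
  if (names(geno)[1] != "IID") {
    abort("'IID' must be the first column of a genotype table",
          class = "snprules_value_error")
  }
  if (anyDuplicated(geno$IID)) {
    abort("duplicated individual IDs in genotype table",
          class = "snprules_value_error")
  }
  snp_cols <- setdiff(names(geno), "IID")
  if (anyDuplicated(snp_cols)) {
    abort("duplicated SNP columns", class = "snprules_value_error")
  }
  invisible(geno)
}

#' Read a binary phenotype table
#'
#' Reads a TSV with an ID column (`IID` or `ID`, first column) followed by
#' one column per clinical feature, coded 0/1 with configurable missing
#' codes.
#'
#' @param path Path to a tab-separated file.
#' @param missing_codes Character vector of codes to read as missing.
#' @return A tibble with `IID` (character) plus one logical column per
#'   feature (`NA` = missing).
#' @export
read_phenotypes <- function(path, missing_codes = c("-9", "NA")) {
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "snprules_io_error")
  }
  raw <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                           colClasses = "character", na.strings = character())
  if (!names(raw)[1] %in% c("IID", "ID")) {
    abort("first column of a phenotype table must be 'IID' or 'ID'",
          class = "snprules_format_error")
  }
  if (anyDuplicated(raw[[1]])) {
    abort("duplicated individual IDs in phenotype table",
          class = "snprules_value_error")
  }
  if (anyDuplicated(names(raw)[-1])) {
    abort("duplicated feature names", class = "snprules_value_error")
  }
  pheno <- tibble(IID = as.character(raw[[1]]))
  for (f in names(raw)[-1]) {
    v <- raw[[f]]
    v[v %in% missing_codes] <- NA
    bad <- !is.na(v) & !v %in% c("0", "1")
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf("non-binary phenotype value at row %d, feature '%s': %s",
                    i, f, v[i]),
            class = "snprules_value_error")
    }
    pheno[[f]] <- v == "1"
  }
  pheno
}

#' Write a binary phenotype table as TSV
#'
#' @param pheno Phenotype tibble (`IID` + logical feature columns).
#' @param path Output path.
#' @param missing_code Code written for `NA` values.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path, missing_code = "-9") {
  out <- as.data.frame(lapply(pheno[-1], function(x) {
    y <- as.character(as.integer(x))
    y[is.na(y)] <- missing_code
    y
  }), check.names = FALSE)
  out <- cbind(data.frame(IID = pheno$IID), out)
  utils::write.table(out, path, quote = FALSE, sep = "\t", row.names = FALSE)
  invisible(path)
}

#' Binarize genotypes under a dominant model
#'
#' Each SNP yields two mutually exclusive binary items: `<snp>_<allele>_1`
#' is true for carriers of at least one counted allele (dosage 1 or 2) and
#' `<snp>_<allele>_0` is true for non-carriers (dosage 0). A missing dosage
#' propagates to both items, so every individual with observed genotype has
#' exactly one of the two items set.
#'
#' @param geno Genotype tibble (`IID` + dosage columns).
#' @return A tibble with `IID` plus two logical item columns per SNP
#'   (`NA` = missing), `_0` before `_1` for each SNP.
#' @export
binarize_dominant <- function(geno) {
  validate_genotypes(geno)
  items <- tibble(IID = geno$IID)
  for (s in setdiff(names(geno), "IID")) {
    d <- geno[[s]]
    items[[paste0(s, "_0")]] <- d == 0L
    items[[paste0(s, "_1")]] <- d >= 1L
  }
  items
}

# SNP stem of an item: "<snp>_<allele>_0/1" -> "<snp>_<allele>".
# Items without a _0/_1 suffix are their own stem.
item_stem <- function(items) sub("_[01]$", "", items)

#' Greedy sliding-window LD pruning
#'
#' PLINK-style pairwise pruning: within a sliding window over the SNPs still
#' kept, whenever two SNPs have squared Pearson correlation of dosages above
#' `r2_max` (computed over individuals with both genotypes observed), the
#' later SNP of the pair is dropped. The window then slides by `step` kept
#' SNPs; sweeps repeat until no SNP is removed, so the kept set contains no
#' within-window pair above the threshold and the operation is idempotent.
#' A zero-variance SNP never causes the removal of another SNP (its r² is
#' taken as 0).
#'
#' @param geno Genotype tibble (`IID` + dosage columns).
#' @param r2_max Maximum allowed squared correlation, in (0, 1].
#' @param window Window size in SNPs (>= 2).
#' @param step Number of SNPs the window slides by.
#' @return Character vector of kept dosage column names, in input order.
#' @export
ld_prune <- function(geno, r2_max = 0.5, window = 50, step = 5) {
  validate_genotypes(geno)
  stopifnot(r2_max > 0, r2_max <= 1, window >= 2, step >= 1)
  snps <- setdiff(names(geno), "IID")
  if (length(snps) < 2) return(snps)
  dos <- as.matrix(geno[, snps, drop = FALSE])
  kept <- snps
  repeat {
    removed_any <- FALSE
    start <- 1L
    while (start <= length(kept)) {
      win <- kept[start:min(start + window - 1L, length(kept))]
      if (length(win) >= 2) {
        r <- suppressWarnings(
          stats::cor(dos[, win, drop = FALSE], use = "pairwise.complete.obs")
        )
        r[!is.finite(r)] <- 0
        drop <- character(0)
        for (i in seq_len(length(win) - 1L)) {
          if (win[i] %in% drop) next
          for (j in seq.int(i + 1L, length(win))) {
            if (win[j] %in% drop) next
            if (r[i, j]^2 > r2_max) drop <- c(drop, win[j])
          }
        }
        if (length(drop) > 0) {
          kept <- setdiff(kept, drop)
          removed_any <- TRUE
        }
      }
      if (start + window - 1L >= length(kept)) break
      start <- start + step
    }
    if (!removed_any) break
  }
  kept
}
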