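# Phenotype and covariate tables are data frames whose first two columns
# are FID and IID (the .phen dialect), followed by one column per trait or
# covariate. Missing values are NA.

id_key <- function(df) paste(df$FID, df$IID, sep = "\r")

check_pheno_table <- function(x, what = "phenotype") {
  if (!is.data.frame(x) || ncol(x) < 3 ||
      !all(c("FID", "IID") == names(x)[1:2]))
    stop(what, " table must be a data frame with columns FID, IID, ...")
  if (anyDuplicated(id_key(x)))
    stop("duplicate sample ids in ", what, " table")
  invisible(x)
}

#' Read a phenotype or covariate file
#'
#' Whitespace- or tab-delimited text; first two columns are FID and IID,
#' remaining columns are traits or covariates; `NA` (or `-9`) denotes
#' missing.
#'
#' @param path file path.
#' @param header logical; does the file carry a header line? When `FALSE`,
#'   columns are named `FID`, `IID`, `V1..Vk` (or `col_names` if given).
#' @param col_names optional names for the value columns when
#'   `header = FALSE`.
#' @return a data frame with columns `FID`, `IID`, then value columns.
#' @export
read_phen <- function(path, header = TRUE, col_names = NULL) {
  if (!file.exists(path)) stop("phenotype file not found: ", path)
  dat <- utils::read.table(path, header = header, stringsAsFactors = FALSE,
                           na.strings = c("NA", "-9"))
  if (!header) {
    nm <- if (!is.null(col_names)) col_names
          else paste0("V", seq_len(ncol(dat) - 2L))
    names(dat) <- c("FID", "IID", nm)
  }
  names(dat)[1:2] <- c("FID", "IID")
  dat$FID <- as.character(dat$FID)
  dat$IID <- as.character(dat$IID)
  check_pheno_table(dat)
}

#' Residualize a phenotype on covariates by ordinary least squares
#'
#' Regresses `y` on the covariate columns (an intercept is always added)
#' and returns the residuals. Rows with missing `y` or any missing
#' covariate are returned as `NA`; the fit uses the remaining rows.
#'
#' @param y numeric vector.
#' @param covariates numeric matrix or data frame of covariates aligned
#'   row-wise with `y` (id columns `FID`/`IID` are dropped if present).
#' @return numeric vector of residuals, same length as `y`.
#' @export
residualize <- function(y, covariates) {
  X <- covariates
  if (is.data.frame(X)) {
    X <- X[, setdiff(names(X), c("FID", "IID")), drop = FALSE]
    X <- as.matrix(X)
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  if (nrow(X) != length(y))
    stop("'y' and 'covariates' must have the same number of rows")
  ok <- !is.na(y) & stats::complete.cases(X)
  if (sum(ok) < ncol(X) + 1L)
    stop("too few complete rows (", sum(ok), ") to fit ", ncol(X) - 1L,
         " covariates")
  qr_x <- qr(X[ok, , drop = FALSE])
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient covariate design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- rep(NA_real_, length(y))
  res[ok] <- qr.resid(qr_x, y[ok])
  res
}

#' Rank-based inverse normal transformation
#'
#' Replaces each non-missing value by the standard-normal quantile of its
#' offset-adjusted rank, \eqn{\Phi^{-1}((r - c)/(n - 2c + 1))}. The default
#' offset is Blom's \eqn{c = 3/8}; `"none"` uses \eqn{c = 0} and
#' `"rankit"` uses \eqn{c = 1/2}. Ties receive the average rank before
#' transformation, so the output is deterministic and order-independent.
#'
#' @param x numeric vector with at least 3 non-missing values.
#' @param offset rank offset variant: `"blom"`, `"none"` or `"rankit"`.
#' @return numeric vector; missing entries stay missing, non-missing
#'   entries preserve their rank order.
#' @export
inverse_normal_transform <- function(x, offset = c("blom", "none", "rankit")) {
  offset <- match.arg(offset)
  k <- switch(offset, blom = 3 / 8, none = 0, rankit = 1 / 2)
  ok <- !is.na(x)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 non-missing values")
  if (diff(range(x[ok])) == 0)
    stop("all values identical: inverse normal transformation undefined")
  r <- rank(x[ok], ties.method = "average")
  out <- rep(NA_real_, length(x))
  out[ok] <- stats::qnorm((r - k) / (n - 2 * k + 1))
  out
}

#' Restrict a phenotype table to complete cases on selected traits
#'
#' @param pheno phenotype data frame (`FID`, `IID`, trait columns).
#' @param traits character vector of trait column names (default: all
#'   trait columns).
#' @return the phenotype table restricted to rows non-missing on every
#'   requested trait, input order preserved.
#' @export
complete_cases <- function(pheno, traits = NULL) {
  check_pheno_table(pheno)
  if (is.null(traits)) traits <- setdiff(names(pheno), c("FID", "IID"))
  missing_tr <- setdiff(traits, names(pheno))
  if (length(missing_tr))
    stop("trait(s) not found: ", paste(missing_tr, collapse = ", "))
  keep <- stats::complete.cases(pheno[, traits, drop = FALSE])
  out <- pheno[keep, , drop = FALSE]
  if (nrow(out) == 0)
    warning("no samples remain after complete-case restriction")
  rownames(out) <- NULL
  out
}

#' Align a GRM and phenotype/covariate tables on shared samples
#'
#' Restricts all supplied objects to the intersection of their sample ids
#' and reorders every object identically, sorted by (FID, IID).
#'
#' @param grm optional `grm` or `eigen_grm`-compatible object; only plain
#'   `grm` objects are subset (eigendecompose after aligning).
#' @param ... named data frames with `FID`/`IID` columns (phenotypes,
#'   covariates).
#' @return a list with the aligned `grm` (if supplied) and each named
#'   table, plus `ids`, the common id data frame.
#' @export
align_samples <- function(grm = NULL, ...) {
  tables <- list(...)
  keysets <- list()
  if (!is.null(grm)) {
    stopifnot(inherits(grm, "grm"))
    keysets$grm <- id_key(grm$sample_ids)
  }
  for (nm in names(tables)) {
    check_pheno_table(tables[[nm]], nm)
    keysets[[nm]] <- id_key(tables[[nm]])
  }
  if (length(keysets) == 0) stop("nothing to align")
  common <- Reduce(intersect, keysets)
  if (length(common) == 0) stop("no samples shared between inputs")
  parts <- do.call(rbind, strsplit(common, "\r", fixed = TRUE))
  ord <- order(parts[, 1], parts[, 2])
  common <- common[ord]
  out <- list()
  if (!is.null(grm))
    out$grm <- subset_grm(grm, match(common, keysets$grm))
  for (nm in names(tables)) {
    tab <- tables[[nm]][match(common, keysets[[nm]]), , drop = FALSE]
    rownames(tab) <- NULL
    out[[nm]] <- tab
  }
  out$ids <- data.frame(FID = parts[ord, 1], IID = parts[ord, 2],
                        stringsAsFactors = FALSE)
  out
}

#' Prepare phenotypes for model fitting
#'
#' Applies the standard preprocessing pipeline per trait: covariate
#' residualization by OLS on all samples with complete covariates, then
#' rank-based inverse normal transformation. Complete-case restriction on
#' the traits is left to the caller (fitting requires it) so that each
#' score is adjusted on the largest available sample.
#'
#' @param pheno phenotype table (`FID`, `IID`, traits).
#' @param covariates optional covariate table (`FID`, `IID`, covariates);
#'   must cover the phenotype samples it is used for.
#' @param traits trait columns to prepare (default all).
#' @param transform apply the inverse normal transformation (default TRUE).
#' @param offset rank offset passed to [inverse_normal_transform()].
#' @return phenotype table with the selected traits replaced by prepared
#'   scores.
#' @export
prep_phenotypes <- function(pheno, covariates = NULL, traits = NULL,
                            transform = TRUE,
                            offset = c("blom", "none", "rankit")) {
  offset <- match.arg(offset)
  check_pheno_table(pheno)
  if (is.null(traits)) traits <- setdiff(names(pheno), c("FID", "IID"))
  if (!is.null(covariates)) {
    check_pheno_table(covariates, "covariate")
    cov_aligned <- covariates[match(id_key(pheno), id_key(covariates)), ,
                              drop = FALSE]
  }
  for (tr in traits) {
    y <- pheno[[tr]]
    if (!is.null(covariates)) y <- residualize(y, cov_aligned)
    if (transform) y <- inverse_normal_transform(y, offset = offset)
    pheno[[tr]] <- y
  }
  pheno
}
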