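#' Estimate a genetic relationship matrix from SNP dosages
#'
#' Computes the realized genome-wide relationship between all pairs of
#' individuals from standardized allele counts,
#' \deqn{A_{jk} = \frac{1}{M_{jk}} \sum_i
#'   \frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2 p_i (1 - p_i)},}
#' where the sum runs over SNPs \eqn{i} with non-missing calls in both
#' individuals and \eqn{M_{jk}} counts those SNPs (pairwise-complete
#' handling of missing genotypes). Monomorphic SNPs (frequency 0 or 1),
#' where the standardization is undefined, are excluded and counted in the
#' returned object.
#'
#' @param geno a [genotype_matrix()] object.
#' @return an object of class `grm` with elements `values` (n x n symmetric
#'   matrix), `sample_ids`, `pair_counts` (n x n SNP counts per pair),
#'   `n_snps` (SNPs used) and `n_monomorphic` (SNPs excluded).
#' @export
compute_grm <- function(geno) {
  stopifnot(inherits(geno, "gsem_geno"))
  X <- geno$dosages
  n <- nrow(X)
  if (n < 2) stop("need at least 2 samples to compute a GRM")
  obs <- !is.na(X)
  all_miss <- rowSums(obs) == 0
  if (any(all_miss)) {
    ids <- geno$sample_ids
    stop("sample(s) with all-missing genotypes: ",
         paste(ids$FID[all_miss], ids$IID[all_miss], sep = ":",
               collapse = ", "))
  }
  p <- geno$allele_freq
  if (is.null(p)) p <- colMeans(X, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  n_mono <- sum(!poly)
  if (!any(poly))
    stop("no informative SNPs: all ", ncol(X), " SNPs are monomorphic")
  if (n_mono > 0)
    message("compute_grm: excluded ", n_mono, " monomorphic SNP(s)")
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  W <- sweep(Xp, 2, 2 * pp, "-")
  W <- sweep(W, 2, sqrt(2 * pp * (1 - pp)), "/")
  if (anyNA(W)) {
    obs_p <- obs[, poly, drop = FALSE]
    W[!obs_p] <- 0
    S <- tcrossprod(W)
    M <- tcrossprod(obs_p * 1)
    if (any(M == 0)) {
      warning("pair(s) with no overlapping SNPs; relationship set to 0")
      S[M == 0] <- 0
      M_div <- ifelse(M == 0, 1, M)
    } else M_div <- M
    A <- S / M_div
  } else {
    m_used <- ncol(W)
    A <- tcrossprod(W) / m_used
    M <- matrix(m_used, n, n)
  }
  A <- (A + t(A)) / 2
  structure(list(values = A,
                 sample_ids = geno$sample_ids,
                 pair_counts = M,
                 n_snps = sum(poly),
                 n_monomorphic = n_mono),
            class = "grm")
}

#' Construct a GRM object from a relationship matrix
#'
#' Wraps an existing symmetric relationship matrix (for example a simulated
#' one) in the container used throughout the package.
#'
#' @param values n x n symmetric numeric matrix.
#' @param fid,iid sample identifiers (defaults `fam1..n` / `ind1..n`).
#' @param pair_counts optional n x n matrix of per-pair SNP counts.
#' @return an object of class `grm`.
#' @export
as_grm <- function(values, fid = NULL, iid = NULL, pair_counts = NULL) {
  values <- as.matrix(values)
  n <- nrow(values)
  if (ncol(values) != n) stop("'values' must be square")
  if (max(abs(values - t(values))) > 1e-8)
    stop("'values' must be symmetric")
  if (is.null(fid)) fid <- paste0("fam", seq_len(n))
  if (is.null(iid)) iid <- paste0("ind", seq_len(n))
  if (is.null(pair_counts)) pair_counts <- matrix(0L, n, n)
  structure(list(values = (values + t(values)) / 2,
                 sample_ids = data.frame(FID = as.character(fid),
                                         IID = as.character(iid),
                                         stringsAsFactors = FALSE),
                 pair_counts = pair_counts,
                 n_snps = max(pair_counts),
                 n_monomorphic = 0L),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  n <- nrow(x$values)
  off <- x$values[upper.tri(x$values)]
  cat("GRM:", n, "samples,", x$n_snps, "SNPs\n")
  cat("  diagonal mean", format(mean(diag(x$values)), digits = 4),
      "; off-diagonal range [",
      format(min(off), digits = 3), ",", format(max(off), digits = 3), "]\n")
  invisible(x)
}

#' Greedy relatedness pruning of a GRM
#'
#' Removes individuals until no retained pair has a relationship above
#' `threshold` (default 0.025, the conventional cutoff for declaring a
#' sample "unrelated"). Removal is greedy: the individual involved in the
#' most threshold-violating pairs is dropped first; ties are broken by
#' dropping the sample that appears later in the input order.
#'
#' @param grm a `grm` object.
#' @param threshold positive relatedness cutoff; pairs with off-diagonal
#'   value strictly greater than this are violations.
#' @return a list with `keep` (retained sample ids, a data frame),
#'   `keep_index` (row indices into the input GRM), `removed` (dropped
#'   sample ids) and `n_violations` (violating pairs in the input).
#' @export
prune_related <- function(grm, threshold = 0.025) {
  stopifnot(inherits(grm, "grm"))
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  A <- grm$values
  n <- nrow(A)
  V <- A > threshold
  diag(V) <- FALSE
  n_viol <- sum(V) / 2
  keep <- rep(TRUE, n)
  repeat {
    deg <- rowSums(V[, keep, drop = FALSE]) * keep
    if (all(deg == 0)) break
    # ties: later sample in input order
    worst <- max(deg)
    drop_i <- max(which(deg == worst))
    keep[drop_i] <- FALSE
    V[drop_i, ] <- FALSE
    V[, drop_i] <- FALSE
  }
  if (!any(keep))
    warning("relatedness pruning removed every sample")
  list(keep = grm$sample_ids[keep, , drop = FALSE],
       keep_index = which(keep),
       removed = grm$sample_ids[!keep, , drop = FALSE],
       n_violations = n_viol)
}

#' Subset a GRM to a set of row indices
#'
#' @param grm a `grm` object.
#' @param index integer row indices to retain (order defines the output
#'   order).
#' @return a `grm` object restricted to those samples.
#' @export
subset_grm <- function(grm, index) {
  stopifnot(inherits(grm, "grm"))
  structure(list(values = grm$values[index, index, drop = FALSE],
                 sample_ids = grm$sample_ids[index, , drop = FALSE],
                 pair_counts = grm$pair_counts[index, index, drop = FALSE],
                 n_snps = grm$n_snps,
                 n_monomorphic = grm$n_monomorphic),
            class = "grm")
}

#' Eigendecomposition of a GRM
#'
#' Decomposes the relationship matrix as \eqn{A = U D U^\top} with
#' orthonormal eigenvectors and nonincreasing eigenvalues. The rotation
#' \eqn{U^\top Y} makes the model covariance of the phenotypes block
#' diagonal, which is the computational device the likelihood engine uses.
#'
#' @param grm a `grm` object (or a plain symmetric matrix).
#' @param tol symmetry tolerance.
#' @return an object of class `eigen_grm` with `values` (eigenvalues),
#'   `vectors` (n x n orthonormal matrix) and `sample_ids`.
#' @export
eigen_grm <- function(grm, tol = 1e-8) {
  if (inherits(grm, "grm")) {
    A <- grm$values
    ids <- grm$sample_ids
  } else {
    A <- as.matrix(grm)
    ids <- data.frame(FID = paste0("fam", seq_len(nrow(A))),
                      IID = paste0("ind", seq_len(nrow(A))),
                      stringsAsFactors = FALSE)
  }
  if (nrow(A) != ncol(A) || max(abs(A - t(A))) > tol)
    stop("GRM is not symmetric within tolerance ", tol)
  e <- eigen((A + t(A)) / 2, symmetric = TRUE)
  structure(list(values = e$values, vectors = e$vectors, sample_ids = ids),
            class = "eigen_grm")
}

#' @export
print.eigen_grm <- function(x, ...) {
  cat("Eigendecomposed GRM:", length(x$values), "samples; eigenvalues in [",
      format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}
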