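# Independent oracle implementations and small data builders used across
# the test files. These deliberately use the slowest, most literal form
# of each computation.

# entry-by-entry GRM estimator with pairwise-complete missing handling
brute_force_grm <- function(X, p = NULL) {
  n <- nrow(X)
  if (is.null(p)) p <- colMeans(X, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  A <- matrix(0, n, n)
  M <- matrix(0L, n, n)
  for (j in seq_len(n)) for (k in seq_len(n)) {
    s <- 0; cnt <- 0L
    for (i in which(poly)) {
      if (!is.na(X[j, i]) && !is.na(X[k, i])) {
        s <- s + (X[j, i] - 2 * p[i]) * (X[k, i] - 2 * p[i]) /
          (2 * p[i] * (1 - p[i]))
        cnt <- cnt + 1L
      }
    }
    A[j, k] <- if (cnt > 0) s / cnt else 0
    M[j, k] <- cnt
  }
  list(values = A, pair_counts = M)
}

# -2 log-likelihood via the dense nt x nt multivariate normal density
dense_neg2ll <- function(sigma_g, sigma_e, Y, A) {
  n <- nrow(Y); t <- ncol(Y)
  V <- kronecker(sigma_g, A) + kronecker(sigma_e, diag(n))
  y <- as.vector(Y)
  n * t * log(2 * pi) +
    as.numeric(determinant(V, logarithm = TRUE)$modulus) +
    drop(crossprod(y, solve(V, y)))
}

# small genotype matrix with optional missingness
make_geno <- function(n, m, seed = 1, miss = 0, maf = c(0.1, 0.5)) {
  set.seed(seed)
  p <- runif(m, maf[1], maf[2])
  X <- matrix(rbinom(n * m, 2, rep(p, each = n)), n, m)
  if (miss > 0) X[runif(n * m) < miss] <- NA
  genotype_matrix(X, paste0("f", seq_len(n)), paste0("i", seq_len(n)))
}

# GRM + eigendecomposition + rotated model-consistent phenotypes
make_small_study <- function(n, m, sigma_g, sigma_e, seed = 1) {
  geno <- make_geno(n, m, seed = seed)
  grm <- compute_grm(geno)
  eig <- eigen_grm(grm)
  pheno <- simulate_phenotypes_grm(eig, sigma_g, sigma_e, seed = seed + 7)
  list(geno = geno, grm = grm, eig = eig, pheno = pheno,
       rot = rotate_phenotypes(pheno, eig))
}

psd2 <- function(v1, v2, cov12) matrix(c(v1, cov12, cov12, v2), 2, 2)
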