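# Genotype-phenotype simulation with prescribed SNP-tagged genetic
# covariance, and the replicate accuracy study (bias / RMSE / MAD of the
# saturated multivariate fit).

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv())
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# symmetric PSD square root (tolerates rank-deficient targets)
psd_sqrt <- function(S) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) < -1e-8 * max(abs(e$values), 1))
    stop("matrix is not positive semidefinite")
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Define a simulation design
#'
#' Describes a study of `n` unrelated individuals genotyped at `m`
#' independent SNPs in Hardy-Weinberg equilibrium, of which `m_causal`
#' carry effects on `t` standardized traits, with target genetic
#' covariance `sigma_g` and residual covariance `sigma_e`. Defaults
#' describe a bivariate standardized trait with SNP-tagged variance
#' fractions 0.25 and 0.47, genetic correlation 0.5 and residual
#' correlation 0.3, studied in 5000 individuals over 10 replicates.
#'
#' @param n individuals.
#' @param m genotyped SNPs.
#' @param m_causal causal SNPs (`<= m`).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param h2 per-trait SNP-tagged variance fractions (used when
#'   `sigma_g` is not given).
#' @param r_g genetic correlation between traits (scalar, used with
#'   `h2`).
#' @param r_e residual correlation between traits (scalar, used with
#'   `h2`).
#' @param sigma_g,sigma_e explicit t x t PSD target matrices (override
#'   `h2`/`r_g`/`r_e`).
#' @param n_replicates replicates for [run_accuracy_study()].
#' @param seed base seed; all randomness in the study flows from it.
#' @param standardized require unit total variance per trait.
#' @return an object of class `gsem_sim_design`.
#' @export
sim_design <- function(n = 5000, m = 5000, m_causal = 1000,
                       maf_range = c(0.05, 0.5),
                       h2 = c(0.25, 0.47), r_g = 0.5, r_e = 0.3,
                       sigma_g = NULL, sigma_e = NULL,
                       n_replicates = 10, seed = 1,
                       standardized = TRUE) {
  if (m_causal > m) stop("m_causal must not exceed m")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 ||
      maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (is.null(sigma_g)) {
    t <- length(h2)
    Rg <- matrix(r_g, t, t); diag(Rg) <- 1
    Re <- matrix(r_e, t, t); diag(Re) <- 1
    sigma_g <- outer(sqrt(h2), sqrt(h2)) * Rg
    sigma_e <- outer(sqrt(1 - h2), sqrt(1 - h2)) * Re
  }
  sigma_g <- as.matrix(sigma_g)
  sigma_e <- as.matrix(sigma_e)
  t <- nrow(sigma_g)
  for (S in list(sigma_g, sigma_e)) {
    ev <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop("target covariance is not PSD")
  }
  if (standardized &&
      max(abs(diag(sigma_g) + diag(sigma_e) - 1)) > 1e-8)
    stop("standardized design requires unit total variance per trait")
  traits <- default_traits(t)
  dimnames(sigma_g) <- dimnames(sigma_e) <- list(traits, traits)
  structure(list(n = n, m = m, m_causal = m_causal,
                 maf_range = maf_range, t = t, traits = traits,
                 sigma_g = sigma_g, sigma_e = sigma_e,
                 n_replicates = n_replicates, seed = seed,
                 standardized = standardized),
            class = "gsem_sim_design")
}

#' @export
print.gsem_sim_design <- function(x, ...) {
  cat("Simulation design:", x$t, "traits, n =", x$n, ", m =", x$m,
      "SNPs (", x$m_causal, "causal ),", x$n_replicates, "replicates\n")
  cat("  sigma_g diagonal:", paste(round(diag(x$sigma_g), 3),
                                   collapse = ", "), "\n")
  invisible(x)
}

#' Simulate unlinked HWE genotypes
#'
#' Per-SNP allele frequencies are drawn uniformly on `maf_range`; dosages
#' are Binomial(2, p) independently per individual (Hardy-Weinberg,
#' linkage equilibrium).
#'
#' @param design a [sim_design()].
#' @param seed seed (default: the design's base seed).
#' @return a [genotype_matrix()] object.
#' @export
simulate_genotypes <- function(design, seed = design$seed) {
  stopifnot(inherits(design, "gsem_sim_design"))
  with_seed(seed, {
    p <- stats::runif(design$m, design$maf_range[1], design$maf_range[2])
    X <- matrix(stats::rbinom(design$n * design$m, 2L, rep(p, each = design$n)),
                design$n, design$m)
    genotype_matrix(X,
                    fid = paste0("fam", seq_len(design$n)),
                    iid = paste0("ind", seq_len(design$n)),
                    snp_ids = paste0("snp", seq_len(design$m)))
  })
}

#' Simulate phenotypes through causal SNP effects
#'
#' Draws per-SNP effect vectors beta_i ~ MVN(0, sigma_g / m_causal) for a
#' seed-chosen subset of causal SNPs, builds genetic values from
#' standardized causal dosages and adds MVN(0, sigma_e) residuals, so the
#' expected SNP-tagged covariance of the traits is `sigma_g` and the
#' expected total covariance is `sigma_g + sigma_e`.
#'
#' @param geno a [genotype_matrix()] (typically from
#'   [simulate_genotypes()]).
#' @param design a [sim_design()].
#' @param seed seed for effects, causal-set choice and residuals.
#' @return phenotype data frame (`FID`, `IID`, traits).
#' @export
simulate_phenotypes_causal <- function(geno, design, seed = design$seed + 1) {
  stopifnot(inherits(geno, "gsem_geno"), inherits(design, "gsem_sim_design"))
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  if (design$m_causal > m) stop("m_causal exceeds available SNPs")
  with_seed(seed, {
    causal <- sample.int(m)[seq_len(design$m_causal)]
    Z <- geno$dosages[, causal, drop = FALSE]
    mu <- colMeans(Z)
    sdv <- sqrt(pmax(matrixStats_colVars(Z), 0))
    Z <- sweep(Z, 2, mu, "-")
    keep <- sdv > 0
    Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, sdv[keep], "/")
    Z[, !keep] <- 0
    beta <- matrix(stats::rnorm(design$m_causal * design$t),
                   design$m_causal, design$t) %*%
      psd_sqrt(design$sigma_g) / sqrt(design$m_causal)
    E <- matrix(stats::rnorm(n * design$t), n, design$t) %*%
      psd_sqrt(design$sigma_e)
    Y <- Z %*% beta + E
    colnames(Y) <- design$traits
    cbind(geno$sample_ids, as.data.frame(Y))
  })
}

# column variances without an extra matrix copy of scale()
matrixStats_colVars <- function(X) {
  n <- nrow(X)
  (colSums(X^2) - n * colMeans(X)^2) / (n - 1)
}

#' Simulate phenotypes directly from the model covariance
#'
#' Draws vec(Y) ~ MVN(0, sigma_g (x) A + sigma_e (x) I) through the GRM
#' eigendecomposition: each rotated row is MVN(0, d_i sigma_g + sigma_e)
#' and is back-rotated. Negative GRM eigenvalues (possible with fewer
#' SNPs than individuals or pairwise-complete estimation) are clipped at
#' zero to keep the covariance valid; a message reports the clip.
#'
#' @param grm a `grm` or `eigen_grm` object.
#' @param sigma_g,sigma_e t x t PSD matrices.
#' @param seed seed.
#' @return phenotype data frame (`FID`, `IID`, traits), exactly
#'   model-consistent with the FIML likelihood.
#' @export
simulate_phenotypes_grm <- function(grm, sigma_g, sigma_e, seed = 1) {
  eig <- if (inherits(grm, "eigen_grm")) grm else eigen_grm(grm)
  sigma_g <- as.matrix(sigma_g)
  sigma_e <- as.matrix(sigma_e)
  t <- nrow(sigma_g)
  n <- length(eig$values)
  d <- eig$values
  n_clip <- sum(d < 0)
  if (n_clip > 0) {
    message("simulate_phenotypes_grm: clipped ", n_clip,
            " negative eigenvalue(s); most negative ",
            format(min(d), digits = 3))
    d <- pmax(d, 0)
  }
  Ag <- psd_sqrt(sigma_g)
  Ae <- psd_sqrt(sigma_e)
  with_seed(seed, {
    G <- matrix(stats::rnorm(n * t), n, t) %*% Ag
    E <- matrix(stats::rnorm(n * t), n, t) %*% Ae
    ytilde <- sqrt(d) * G + E
    Y <- eig$vectors %*% ytilde
    colnames(Y) <- if (!is.null(colnames(sigma_g))) colnames(sigma_g)
                   else default_traits(t)
    cbind(eig$sample_ids, as.data.frame(Y))
  })
}

#' Replicate accuracy study of the multivariate estimator
#'
#' For each replicate: simulate genotypes and causal-effect phenotypes,
#' estimate the GRM from all genotyped SNPs, fit the saturated Cholesky
#' AE model by FIML, and record the estimated genetic/residual variances,
#' covariances and loadings. Reports bias (mean estimate minus truth),
#' squared bias, root mean squared error and mean absolute deviation per
#' parameter across converged replicates.
#'
#' @param design a [sim_design()].
#' @param verbose print per-replicate progress.
#' @return an object of class `gsem_sim_report` with `metrics` (one row
#'   per parameter), `estimates` (replicates x parameters),
#'   `n_converged`, `n_replicates` and the design.
#' @export
run_accuracy_study <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "gsem_sim_design"))
  t <- design$t
  spec <- gsem_cholesky(t, traits = design$traits)
  La_true <- t(chol(design$sigma_g))
  Le_true <- t(chol(design$sigma_e))
  idx <- which(lower.tri(matrix(0, t, t), diag = TRUE))
  cov_labels <- function(tag) {
    jj <- row(diag(t))[idx]; kk <- col(diag(t))[idx]
    sprintf("%s[%d,%d]", tag, jj, kk)
  }
  par_names <- c(cov_labels("sigma_g"), cov_labels("sigma_e"),
                 spec$params$name)
  truth <- c(design$sigma_g[idx], design$sigma_e[idx],
             La_true[idx], Le_true[idx])
  names(truth) <- par_names

  est <- matrix(NA_real_, design$n_replicates, length(par_names),
                dimnames = list(NULL, par_names))
  converged <- logical(design$n_replicates)
  for (r in seq_len(design$n_replicates)) {
    seed_r <- design$seed + 1000L * r
    geno <- simulate_genotypes(design, seed = seed_r)
    pheno <- simulate_phenotypes_causal(geno, design, seed = seed_r + 1L)
    grm <- compute_grm(geno)
    rm(geno)
    eig <- eigen_grm(grm)
    rm(grm)
    rot <- rotate_phenotypes(pheno, eig)
    rm(eig)
    fit <- gsem_fit(spec, rotated = rot, se = FALSE, starts = 2L,
                    seed = seed_r)
    converged[r] <- fit$converged
    if (!fit$converged) {
      message("replicate ", r, " did not converge; excluded")
    } else {
      lm_ <- loading_matrices(spec, fit$theta_hat)
      est[r, ] <- c(fit$sigma_g[idx], fit$sigma_e[idx],
                    lm_$La[idx], lm_$Le[idx])
    }
    if (verbose)
      message("replicate ", r, "/", design$n_replicates,
              " -2LL = ", format(fit$minus2LL, digits = 8))
    gc(verbose = FALSE)
  }
  ok <- which(converged)
  metrics <- do.call(rbind, lapply(par_names, function(pn) {
    e <- est[ok, pn]
    bias <- mean(e) - truth[pn]
    data.frame(parameter = pn, truth = truth[pn],
               mean_estimate = mean(e), bias = bias, bias2 = bias^2,
               rmse = sqrt(mean((e - truth[pn])^2)),
               mad = mean(abs(e - truth[pn])),
               stringsAsFactors = FALSE)
  }))
  rownames(metrics) <- NULL
  structure(list(metrics = metrics, estimates = est,
                 n_replicates = design$n_replicates,
                 n_converged = length(ok), design = design),
            class = "gsem_sim_report")
}

#' @export
print.gsem_sim_report <- function(x, digits = 4, ...) {
  cat("Accuracy study:", x$n_converged, "/", x$n_replicates,
      "converged replicates, n =", x$design$n, "\n")
  m <- x$metrics
  m[, -1] <- round(m[, -1], digits)
  print(m)
  invisible(x)
}

#' Serialize a simulation report as JSON
#'
#' @param report a `gsem_sim_report`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sim_report_json <- function(report, path) {
  stopifnot(inherits(report, "gsem_sim_report"))
  d <- report$design
  obj <- list(design = list(n = d$n, m = d$m, m_causal = d$m_causal,
                            maf_range = d$maf_range, t = d$t,
                            sigma_g = d$sigma_g, sigma_e = d$sigma_e,
                            n_replicates = d$n_replicates, seed = d$seed),
              n_converged = report$n_converged,
              metrics = report$metrics)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}
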