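# Full-information maximum likelihood for AE models over GRM-structured
# covariance. With A = U D U' the model covariance of vec(Y) is
# sigma_g (x) A + sigma_e (x) I; rotating the phenotypes by U' makes it
# block diagonal, so the -2 log-likelihood decomposes over individuals:
#   sum_i [ t log 2pi + log|Omega_i| + y_i' Omega_i^{-1} y_i ],
#   Omega_i = d_i sigma_g + sigma_e.
# Each evaluation diagonalizes (sigma_g, sigma_e) simultaneously once
# (t x t work) and then costs O(n t).

#' Rotate phenotypes into the eigenbasis of the GRM
#'
#' @param pheno phenotype table (`FID`, `IID`, trait columns) or a numeric
#'   matrix with samples in rows. Must be complete (no missing values) and
#'   aligned row-for-row with the eigendecomposition (see
#'   [align_samples()] and [complete_cases()]).
#' @param eig an [eigen_grm()] object.
#' @param traits optional trait columns to use (default: all non-id
#'   columns).
#' @return an object of class `gsem_rotated` with `ytilde` (n x t rotated
#'   phenotypes), `d` (eigenvalues), `u1` (rotated intercept column),
#'   `traits`, `n`, and the column means of the unrotated phenotypes.
#' @export
rotate_phenotypes <- function(pheno, eig, traits = NULL) {
  stopifnot(inherits(eig, "eigen_grm"))
  if (is.data.frame(pheno)) {
    check_pheno_table(pheno)
    if (!identical(id_key(pheno), id_key(eig$sample_ids)))
      stop("phenotype rows do not match the GRM sample order; ",
           "run align_samples() first")
    if (is.null(traits)) traits <- setdiff(names(pheno), c("FID", "IID"))
    Y <- as.matrix(pheno[, traits, drop = FALSE])
  } else {
    Y <- as.matrix(pheno)
    if (is.null(colnames(Y))) colnames(Y) <- default_traits(ncol(Y))
  }
  if (anyNA(Y))
    stop("phenotypes contain missing values; apply complete_cases() first")
  n <- nrow(Y)
  if (n != length(eig$values))
    stop("phenotype rows (", n, ") do not match GRM size (",
         length(eig$values), ")")
  structure(list(ytilde = crossprod(eig$vectors, Y),
                 d = eig$values,
                 u1 = as.vector(crossprod(eig$vectors, rep(1, n))),
                 traits = colnames(Y),
                 n = n,
                 ybar = colMeans(Y)),
            class = "gsem_rotated")
}

# -2 log-likelihood given implied covariance matrices; Y is the rotated
# n x t matrix, d the aligned eigenvalues. Returns +Inf when any Omega_i
# is not positive definite.
neg2ll_core <- function(sigma_g, sigma_e, Y, d) {
  n <- nrow(Y)
  t <- ncol(Y)
  R <- tryCatch(chol(sigma_e), error = function(e) NULL)
  if (!is.null(R)) {
    Rinv <- backsolve(R, diag(t))
    B <- crossprod(Rinv, sigma_g) %*% Rinv
    eB <- eigen((B + t(B)) / 2, symmetric = TRUE)
    omega <- 1 + outer(d, pmax(eB$values, 0))
    if (any(omega <= 1e-12)) return(Inf)
    Z <- Y %*% (Rinv %*% eB$vectors)
    n * t * log(2 * pi) + 2 * n * sum(log(diag(R))) +
      sum(log(omega)) + sum(Z^2 / omega)
  } else {
    # sigma_e singular: evaluate per individual
    val <- n * t * log(2 * pi)
    for (i in seq_len(n)) {
      ch <- tryCatch(chol(d[i] * sigma_g + sigma_e),
                     error = function(e) NULL)
      if (is.null(ch)) return(Inf)
      z <- backsolve(ch, Y[i, ], transpose = TRUE)
      val <- val + 2 * sum(log(diag(ch))) + sum(z^2)
    }
    val
  }
}

#' Evaluate the -2 log-likelihood of an AE model
#'
#' @param spec a `gsem_spec`.
#' @param theta parameter vector of length `spec$k`.
#' @param rotated a [rotate_phenotypes()] object.
#' @param mu optional per-trait intercepts (default: mean fixed at 0, the
#'   convention for pre-residualized, transformed phenotypes).
#' @return the -2 log-likelihood (`Inf` when the implied covariance is not
#'   positive definite for some individual).
#' @export
neg2_loglik <- function(spec, theta, rotated, mu = NULL) {
  stopifnot(inherits(spec, "gsem_spec"), inherits(rotated, "gsem_rotated"))
  if (anyNA(theta) || any(!is.finite(theta)))
    stop("non-finite values in theta")
  ic <- implied_covariances(spec, theta)
  Y <- rotated$ytilde
  if (!is.null(mu)) Y <- Y - outer(rotated$u1, mu)
  neg2ll_core(ic$sigma_g, ic$sigma_e, Y, rotated$d)
}

# Starting values. St is a rough total phenotypic covariance estimate.
start_theta <- function(spec, St, mode = c("half", "null_g", "jitter"),
                        jitter_seed = 1L) {
  mode <- match.arg(mode)
  t <- spec$t
  svar <- pmax(diag(St), 1e-3)
  if (mode == "half" && spec$structure %in% c("cholesky", "custom") &&
      identical(dim(spec$genetic_mask), c(t, t)) &&
      identical(dim(spec$residual_mask), c(t, t))) {
    L <- t(chol((St + t(St)) / 2 / 2 + diag(1e-4, t)))
    th <- c(L[which(spec$genetic_mask)], L[which(spec$residual_mask)])
    return(stats::setNames(th, spec$params$name))
  }
  pp <- spec$params
  th <- numeric(spec$k)
  if (spec$structure == "common") {
    g_share <- if (mode == "null_g") 0.05 else 0.5
    th[pp$part == "lambda"] <- sqrt(svar[pp$row[pp$part == "lambda"]] / 2)
    th[pp$part == "fg"] <- sqrt(g_share)
    th[pp$part == "fe"] <- sqrt(1 - g_share)
    th[pp$part == "spec_a"] <-
      sqrt(g_share * svar[pp$row[pp$part == "spec_a"]] / 2)
    th[pp$part == "spec_e"] <-
      sqrt((1 - g_share) * svar[pp$row[pp$part == "spec_e"]] / 2)
  } else {
    n_g <- tabulate(pp$row[pp$part == "genetic"], t)
    n_e <- tabulate(pp$row[pp$part == "residual"], t)
    g_share <- if (mode == "null_g") 0.02 else 0.5
    for (i in seq_len(spec$k)) {
      j <- pp$row[i]
      th[i] <- if (pp$part[i] == "genetic")
        sqrt(g_share * svar[j] / max(n_g[j], 1))
      else
        sqrt((1 - g_share) * svar[j] / max(n_e[j], 1))
    }
  }
  if (mode == "jitter") {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(jitter_seed)
    th <- th * (1 + 0.25 * stats::rnorm(length(th)))
  }
  stats::setNames(th, spec$params$name)
}

# flip whole factor columns so that leading loadings are nonnegative
# (likelihood-invariant; gives a unique sign convention for reporting)
apply_sign_convention <- function(spec, theta) {
  pp <- spec$params
  if (spec$structure == "common") {
    il <- which(pp$part == "lambda")
    if (length(il) && theta[il[1]] < 0) theta[il] <- -theta[il]
    for (part in c("fg", "fe")) {
      i <- which(pp$part == part)
      if (length(i) && theta[i] < 0) theta[i] <- -theta[i]
    }
    for (part in c("spec_a", "spec_e")) {
      i <- which(pp$part == part)
      theta[i] <- abs(theta[i])     # each is its own factor column
    }
  } else {
    for (part in c("genetic", "residual")) {
      sel <- pp$part == part
      for (cc in unique(pp$col[sel])) {
        i <- which(sel & pp$col == cc)
        if (theta[i[1]] < 0) theta[i] <- -theta[i]
      }
    }
  }
  theta
}

central_gradient <- function(fn, x, step = 1e-6) {
  g <- numeric(length(x))
  f0 <- NULL
  for (j in seq_along(x)) {
    h <- step * max(1, abs(x[j]))
    xp <- x; xp[j] <- x[j] + h
    xm <- x; xm[j] <- x[j] - h
    fp <- fn(xp); fm <- fn(xm)
    if (is.finite(fp) && is.finite(fm)) {
      g[j] <- (fp - fm) / (2 * h)
    } else {
      # boundary of the feasible region: use a one-sided difference
      if (is.null(f0)) f0 <- fn(x)
      g[j] <- if (is.finite(fp)) (fp - f0) / h
              else if (is.finite(fm)) (f0 - fm) / h
              else NaN
    }
  }
  g
}

#' Fit an AE model by full-information maximum likelihood
#'
#' Minimizes the -2 log-likelihood by quasi-Newton optimization with
#' numerically approximated gradients from multiple starting points:
#' (i) an even split of the sample covariance between the genetic and
#' residual sides (Cholesky factors of half the sample covariance for
#' triangular patterns), (ii) a near-null genetic side, and (iii) a
#' deterministic jittered version of (i). Standard errors come from the
#' observed information: the parameter covariance is twice the inverse of
#' the numerical Hessian of the -2 log-likelihood at the optimum.
#'
#' @param spec a `gsem_spec`.
#' @param pheno phenotype table aligned with `grm` (ignored when
#'   `rotated` is given).
#' @param grm a `grm` or `eigen_grm` object (ignored when `rotated` is
#'   given).
#' @param rotated optionally, a precomputed [rotate_phenotypes()] object
#'   (reuse it to fit several models to the same data).
#' @param intercepts estimate per-trait means (default `FALSE`: phenotypes
#'   are assumed pre-residualized and transformed, mean fixed at 0).
#' @param se compute the Hessian-based parameter covariance (default
#'   `TRUE`).
#' @param starts number of starting points (1-3).
#' @param seed seed for the deterministic jitter of the third start.
#' @param control list with `maxit` (default 2000) and `reltol`
#'   (default 1e-10) passed to the optimizer.
#' @return an object of class `gsem_fit`: `theta_hat`, `minus2LL`,
#'   `param_cov`, `se_theta`, `sigma_g`, `sigma_e`, `converged`, `k`,
#'   `n`, `n_obs`, `diagnostics`.
#' @export
gsem_fit <- function(spec, pheno = NULL, grm = NULL, rotated = NULL,
                     intercepts = FALSE, se = TRUE, starts = 3L, seed = 1L,
                     control = list()) {
  stopifnot(inherits(spec, "gsem_spec"))
  if (is.null(rotated)) {
    if (is.null(pheno) || is.null(grm))
      stop("supply either 'rotated' or both 'pheno' and 'grm'")
    eig <- if (inherits(grm, "eigen_grm")) grm else eigen_grm(grm)
    tr <- if (all(spec$traits %in% colnames_of(pheno))) spec$traits else NULL
    rotated <- rotate_phenotypes(pheno, eig, traits = tr)
  }
  n <- rotated$n
  t <- ncol(rotated$ytilde)
  if (t != spec$t)
    stop("spec has ", spec$t, " traits but data has ", t)
  k_free <- spec$k + if (intercepts) t else 0L
  if (n < k_free + 1)
    stop("need at least k + 1 = ", k_free + 1, " complete cases, have ", n)
  ctl <- utils::modifyList(list(maxit = 2000L, reltol = 1e-10), control)

  obj <- if (intercepts) {
    function(par) neg2_loglik(spec, par[seq_len(spec$k)], rotated,
                              mu = par[spec$k + seq_len(t)])
  } else {
    function(par) neg2_loglik(spec, par, rotated)
  }

  St <- crossprod(rotated$ytilde) / n
  modes <- c("half", "null_g", "jitter")[seq_len(max(1, min(starts, 3)))]
  runs <- lapply(modes, function(mode) {
    th0 <- start_theta(spec, St, mode, jitter_seed = seed + 2L)
    if (intercepts) th0 <- c(th0, stats::setNames(rotated$ybar,
                                                  paste0("mu_",
                                                         rotated$traits)))
    if (!is.finite(obj(th0))) th0 <- th0 + 0.05
    stats::optim(th0, obj, method = "BFGS",
                 control = list(maxit = ctl$maxit, reltol = ctl$reltol))
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best <- runs[[which.min(vals)]]
  # Nelder-Mead polish if the quasi-Newton run did not report convergence
  if (best$convergence != 0) {
    nm <- stats::optim(best$par, obj, method = "Nelder-Mead",
                       control = list(maxit = 5000L))
    if (nm$value < best$value) best <- nm
  }

  par_hat <- best$par
  grad <- central_gradient(obj, par_hat)
  scaled_grad <- if (all(is.finite(grad)))
    max(abs(grad) * pmax(1, abs(par_hat))) / max(1, abs(best$value))
  else Inf
  converged <- is.finite(best$value) && scaled_grad <= 1e-5

  theta <- par_hat[seq_len(spec$k)]
  mu <- if (intercepts) par_hat[spec$k + seq_len(t)] else NULL
  theta <- apply_sign_convention(spec, theta)
  par_hat <- c(theta, mu)

  param_cov <- matrix(NA_real_, length(par_hat), length(par_hat))
  if (se) {
    H <- tryCatch(pracma::hessian(obj, par_hat), error = function(e) NULL)
    ok <- !is.null(H) && all(is.finite(H))
    if (ok) {
      H <- (H + t(H)) / 2
      ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
      ok <- all(ev > 1e-8 * max(abs(ev), 1))
      if (ok) param_cov <- 2 * solve(H)
    }
    if (!ok)
      warning("observed information is not positive definite ",
              "(boundary or unidentified solution); SEs set to NA")
  }
  pnames <- c(spec$params$name,
              if (intercepts) paste0("mu_", rotated$traits))
  names(par_hat) <- pnames
  dimnames(param_cov) <- list(pnames, pnames)
  ic <- implied_covariances(spec, theta)

  structure(list(spec = spec,
                 theta_hat = stats::setNames(theta, spec$params$name),
                 mu = mu,
                 minus2LL = best$value,
                 param_cov = param_cov,
                 se_theta = stats::setNames(sqrt(pmax(diag(param_cov), 0)),
                                            pnames),
                 sigma_g = ic$sigma_g,
                 sigma_e = ic$sigma_e,
                 converged = converged,
                 k = k_free,
                 n = n,
                 n_obs = n * t,
                 traits = rotated$traits,
                 rotated = rotated,
                 diagnostics = list(start_values = vals,
                                    best_start = modes[which.min(vals)],
                                    optim_convergence = best$convergence,
                                    scaled_gradient = scaled_grad)),
            class = "gsem_fit")
}

colnames_of <- function(x) if (is.data.frame(x)) names(x) else colnames(x)

#' @export
print.gsem_fit <- function(x, ...) {
  print(x$spec)
  cat("  -2LL = ", format(x$minus2LL, digits = 10),
      ", n = ", x$n, " (", x$n_obs, " observations), ",
      if (x$converged) "converged" else "NOT converged", "\n", sep = "")
  est <- data.frame(estimate = round(x$theta_hat, 4),
                    se = round(x$se_theta[seq_along(x$theta_hat)], 4))
  print(est)
  invisible(x)
}

#' Univariate AE model (single variance component)
#'
#' Fits the one-trait AE model (a single genetic and a single residual
#' loading) and reports the genetic and residual variance components with
#' delta-method standard errors. For unit-variance phenotypes the genetic
#' variance is the SNP heritability.
#'
#' @param pheno phenotype table or numeric vector.
#' @param grm a `grm` or `eigen_grm` aligned with the phenotypes.
#' @param trait trait column to analyse (default: the single trait
#'   column).
#' @param ... passed to [gsem_fit()].
#' @return a `gsem_fit` with an additional element `vc`, a data frame of
#'   variance components (`Var_g`, `Var_e`, `h2`) with SEs and a Wald
#'   p-value for `Var_g`.
#' @export
gsem_univariate <- function(pheno, grm, trait = NULL, ...) {
  if (is.data.frame(pheno)) {
    if (is.null(trait)) {
      tr_cols <- setdiff(names(pheno), c("FID", "IID"))
      if (length(tr_cols) != 1)
        stop("specify 'trait' (table has ", length(tr_cols), " columns)")
      trait <- tr_cols
    }
    pheno <- pheno[, c("FID", "IID", trait)]
  } else {
    pheno <- as.matrix(pheno)
    trait <- if (!is.null(colnames(pheno))) colnames(pheno)[1] else "P1"
    colnames(pheno) <- trait
  }
  fit <- gsem_fit(gsem_cholesky(1, traits = trait), pheno, grm, ...)
  vg <- delta_method_se(fit, function(th) th[1]^2)
  ve <- delta_method_se(fit, function(th) th[2]^2)
  h2 <- delta_method_se(fit, function(th) th[1]^2 / (th[1]^2 + th[2]^2))
  z <- vg$estimate / vg$se
  fit$vc <- data.frame(component = c("Var_g", "Var_e", "h2"),
                       estimate = c(vg$estimate, ve$estimate, h2$estimate),
                       se = c(vg$se, ve$se, h2$se),
                       p_wald = c(2 * stats::pnorm(-abs(z)), NA, NA))
  fit
}

#' Restandardized path coefficients
#'
#' Divides each loading on a trait by the square root of the model-implied
#' total variance of that trait, so that the squared standardized loadings
#' on a trait sum to one and each squared standardized loading is the
#' share of phenotypic variance explained by that path. For the common
#' pathway model the common-factor rows report the identified products
#' `f_g * lambda_j` and `f_e * lambda_j`.
#'
#' @param fit a `gsem_fit`.
#' @param se compute delta-method SEs for the standardized loadings
#'   (default `TRUE` when the parameter covariance is available).
#' @return data frame with columns `path`, `trait`, `factor`, `type`,
#'   `estimate` (unstandardized), `std_estimate`, `std_se`,
#'   `pct_variance` (100 x squared standardized loading).
#' @export
standardize_paths <- function(fit, se = !anyNA(fit$param_cov)) {
  stopifnot(inherits(fit, "gsem_fit"))
  spec <- fit$spec
  lm_ <- loading_matrices(spec, fit$theta_hat)
  tot <- diag(fit$sigma_g + fit$sigma_e)
  if (any(tot <= 0))
    stop("zero model-implied variance for trait(s): ",
         paste(spec$traits[tot <= 0], collapse = ", "))
  rows <- list()
  for (side in c("La", "Le")) {
    M <- lm_[[side]]
    type <- if (side == "La") "genetic" else "residual"
    nz <- which(M != 0, arr.ind = TRUE)
    for (r in seq_len(nrow(nz))) {
      j <- nz[r, 1]; cc <- nz[r, 2]
      g <- local({
        j0 <- j; c0 <- cc; side0 <- side
        function(th) {
          l <- loading_matrices(spec, th)
          ic <- implied_covariances(spec, th)
          l[[side0]][j0, c0] / sqrt((ic$sigma_g + ic$sigma_e)[j0, j0])
        }
      })
      std_se <- NA_real_
      std_est <- M[j, cc] / sqrt(tot[j])
      if (se) {
        dm <- delta_method_se(fit, g)
        std_se <- dm$se
      }
      rows[[length(rows) + 1]] <-
        data.frame(path = paste0(colnames(M)[cc], "->", spec$traits[j]),
                   trait = spec$traits[j], factor = colnames(M)[cc],
                   type = type, estimate = M[j, cc],
                   std_estimate = std_est, std_se = std_se,
                   pct_variance = 100 * std_est^2,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Serialize a fit as JSON
#'
#' Writes the specification, estimates, standard errors, fit statistics
#' and derived covariance matrices with stable key names.
#'
#' @param fit a `gsem_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gsem_json <- function(fit, path) {
  stopifnot(inherits(fit, "gsem_fit"))
  obj <- list(
    spec = list(structure = fit$spec$structure, t = fit$spec$t,
                traits = fit$spec$traits,
                parameters = fit$spec$params$name,
                fixed_to_zero = fit$spec$fixed),
    estimates = as.list(fit$theta_hat),
    se = as.list(fit$se_theta[seq_along(fit$theta_hat)]),
    minus2LL = fit$minus2LL,
    k = fit$k,
    n = fit$n,
    n_obs = fit$n_obs,
    converged = fit$converged,
    convergence = fit$diagnostics,
    sigma_g = fit$sigma_g,
    sigma_e = fit$sigma_e)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
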