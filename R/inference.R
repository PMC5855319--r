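# Post-fit statistics: delta-method SEs for functions of the estimated
# loadings, Wald tests, likelihood-ratio tests, information criteria and
# the stepwise model-reduction procedure.

#' Delta-method standard error for a function of the parameters
#'
#' First-order propagation: `SE = sqrt(grad' V grad)` where `V` is the
#' parameter covariance of the fit and the gradient is computed by central
#' finite differences with step `1e-5 * max(1, |theta_j|)`.
#'
#' @param fit a `gsem_fit` with available parameter covariance.
#' @param g function mapping the parameter vector to a scalar.
#' @return list with `estimate` and `se`.
#' @export
delta_method_se <- function(fit, g) {
  stopifnot(inherits(fit, "gsem_fit"))
  theta <- fit$theta_hat
  V <- fit$param_cov[seq_along(theta), seq_along(theta), drop = FALSE]
  if (anyNA(V))
    stop("parameter covariance unavailable (refit with se = TRUE)")
  est <- g(theta)
  grad <- numeric(length(theta))
  for (j in seq_along(theta)) {
    h <- 1e-5 * max(1, abs(theta[j]))
    tp <- theta; tp[j] <- theta[j] + h
    tm <- theta; tm[j] <- theta[j] - h
    grad[j] <- (g(tp) - g(tm)) / (2 * h)
  }
  if (any(!is.finite(grad))) stop("non-finite gradient in delta method")
  list(estimate = est,
       se = sqrt(max(0, drop(t(grad) %*% V %*% grad))))
}

#' Genetic and residual covariances and genetic correlations with SEs
#'
#' Computes the model-implied genetic covariance matrix (for unit-variance
#' traits its diagonal is the SNP heritability), the residual covariance
#' matrix, and the genetic correlations
#' `r_g(j,k) = sigma_g(j,k) / sqrt(sigma_g(j,j) sigma_g(k,k))`, all with
#' delta-method standard errors.
#'
#' @param fit a converged `gsem_fit`.
#' @return an object of class `gsem_estimates` with matrices `sigma_g`,
#'   `sigma_g_se`, `sigma_e`, `sigma_e_se`, `r_g`, `r_g_se`.
#' @export
genetic_correlations <- function(fit) {
  stopifnot(inherits(fit, "gsem_fit"))
  spec <- fit$spec
  t <- spec$t
  sg_se <- se_se <- rg <- rg_se <- matrix(NA_real_, t, t)
  dimnames(sg_se) <- dimnames(se_se) <- dimnames(rg) <- dimnames(rg_se) <-
    list(spec$traits, spec$traits)
  vg <- diag(fit$sigma_g)
  diag(rg) <- 1
  diag(rg_se) <- 0
  warned <- FALSE
  for (j in seq_len(t)) for (k in seq_len(j)) {
    dm <- delta_method_se(fit, function(th)
      implied_covariances(spec, th)$sigma_g[j, k])
    sg_se[j, k] <- sg_se[k, j] <- dm$se
    dm <- delta_method_se(fit, function(th)
      implied_covariances(spec, th)$sigma_e[j, k])
    se_se[j, k] <- se_se[k, j] <- dm$se
    if (j != k) {
      if (vg[j] <= 0 || vg[k] <= 0) {
        warned <- TRUE
      } else {
        dm <- delta_method_se(fit, function(th) {
          sg <- implied_covariances(spec, th)$sigma_g
          sg[j, k] / sqrt(sg[j, j] * sg[k, k])
        })
        rg[j, k] <- rg[k, j] <- dm$estimate
        rg_se[j, k] <- rg_se[k, j] <- dm$se
      }
    }
  }
  if (warned)
    warning("zero/negative genetic variance; some genetic correlations NA")
  structure(list(sigma_g = fit$sigma_g, sigma_g_se = sg_se,
                 sigma_e = fit$sigma_e, sigma_e_se = se_se,
                 r_g = rg, r_g_se = rg_se, traits = spec$traits),
            class = "gsem_estimates")
}

#' @export
print.gsem_estimates <- function(x, digits = 3, ...) {
  cat("Genetic variances/covariances (SE):\n")
  print(round(x$sigma_g, digits))
  cat("Genetic correlations:\n")
  print(round(x$r_g, digits))
  invisible(x)
}

#' Share of a trait's genetic variance due to a subset of factors
#'
#' For a trait j and genetic factors F, returns
#' `sum_{c in F} La[j,c]^2 / sum_c La[j,c]^2` with a delta-method SE --
#' e.g. the fraction of the genetic variance at the last age that is
#' already captured by the first genetic factor.
#'
#' @param fit a `gsem_fit`.
#' @param trait trait name or index.
#' @param factors character names (or indices) of genetic factor columns.
#' @return list with `estimate` and `se`.
#' @export
genetic_variance_share <- function(fit, trait, factors) {
  spec <- fit$spec
  j <- if (is.character(trait)) match(trait, spec$traits) else trait
  if (is.na(j)) stop("unknown trait: ", trait)
  La0 <- loading_matrices(spec, fit$theta_hat)$La
  fidx <- if (is.character(factors)) match(factors, colnames(La0))
          else as.integer(factors)
  if (anyNA(fidx)) stop("unknown genetic factor(s)")
  delta_method_se(fit, function(th) {
    La <- loading_matrices(spec, th)$La
    sum(La[j, fidx]^2) / sum(La[j, ]^2)
  })
}

#' Wald test of a single loading
#'
#' @param fit a `gsem_fit`.
#' @param parameter_name free parameter name.
#' @param one_tailed report a one-tailed p-value (default two-sided).
#' @return list with `estimate`, `se`, `z`, `p`.
#' @export
wald_test <- function(fit, parameter_name, one_tailed = FALSE) {
  stopifnot(inherits(fit, "gsem_fit"))
  i <- match(parameter_name, names(fit$theta_hat))
  if (is.na(i)) stop("unknown parameter: ", parameter_name)
  se <- fit$se_theta[i]
  if (!is.finite(se) || se <= 0)
    stop("no standard error available for ", parameter_name)
  z <- unname(fit$theta_hat[i] / se)
  p <- if (one_tailed) stats::pnorm(-abs(z)) else 2 * stats::pnorm(-abs(z))
  list(estimate = unname(fit$theta_hat[i]), se = unname(se), z = z, p = p)
}

#' Wald tests for all free parameters
#'
#' @inheritParams wald_test
#' @return data frame with one row per free parameter.
#' @export
wald_tests <- function(fit, one_tailed = FALSE) {
  nm <- names(fit$theta_hat)
  se <- fit$se_theta[seq_along(nm)]
  z <- fit$theta_hat / se
  p <- if (one_tailed) stats::pnorm(-abs(z)) else 2 * stats::pnorm(-abs(z))
  data.frame(parameter = nm, estimate = unname(fit$theta_hat),
             se = unname(se), z = unname(z), p = unname(p),
             stringsAsFactors = FALSE)
}

#' Likelihood-ratio test between nested fits
#'
#' @param fit_full fit of the larger model.
#' @param fit_nested fit of the nested (reduced) model on the same data.
#' @param mixture use a 50:50 chi-square mixture reference with
#'   `df` and `df - 1` degrees of freedom (sensitivity analysis for
#'   variance parameters on the boundary); default is the standard
#'   chi-square reference.
#' @return list with `delta_chi2`, `delta_df`, `p`.
#' @export
gsem_lrt <- function(fit_full, fit_nested, mixture = FALSE) {
  stopifnot(inherits(fit_full, "gsem_fit"), inherits(fit_nested, "gsem_fit"))
  if (fit_full$n != fit_nested$n)
    stop("fits use different samples (n = ", fit_full$n, " vs ",
         fit_nested$n, ")")
  if (!identical(fit_full$traits, fit_nested$traits))
    stop("fits use different trait sets")
  if (fit_full$k <= fit_nested$k)
    stop("models are not properly nested (k_full = ", fit_full$k,
         ", k_nested = ", fit_nested$k, ")")
  nested_ok <- is_nested_spec(fit_nested$spec, fit_full$spec)
  if (isFALSE(nested_ok))
    stop("nested spec is not expressible within the full spec")
  if (is.na(nested_ok))
    warning("nesting of the two specifications could not be verified")
  dchi <- fit_nested$minus2LL - fit_full$minus2LL
  if (dchi < 0) {
    if (dchi < -1e-4)
      warning("negative LRT statistic (", format(dchi, digits = 4),
              "); clamped to 0 - check convergence of the full model")
    dchi <- 0
  }
  ddf <- fit_full$k - fit_nested$k
  p <- if (mixture) {
    p_hi <- stats::pchisq(dchi, ddf, lower.tail = FALSE)
    p_lo <- if (ddf > 1) stats::pchisq(dchi, ddf - 1, lower.tail = FALSE)
            else as.numeric(dchi <= 0)
    0.5 * (p_hi + p_lo)
  } else {
    stats::pchisq(dchi, ddf, lower.tail = FALSE)
  }
  list(delta_chi2 = dchi, delta_df = ddf, p = p)
}

#' Akaike information criterion from -2 log-likelihood
#'
#' @param minus2LL -2 log-likelihood.
#' @param k number of free parameters.
#' @return `minus2LL + 2k`.
#' @export
aic_gsem <- function(minus2LL, k) minus2LL + 2 * k

#' Bayesian information criterion from -2 log-likelihood
#'
#' The sample size is the number of participants, not the number of
#' trait observations.
#'
#' @inheritParams aic_gsem
#' @param n number of participants.
#' @return `minus2LL + k * log(n)`.
#' @export
bic_gsem <- function(minus2LL, k, n) {
  if (!is.numeric(n) || n < 2) stop("'n' must be the participant count (>= 2)")
  minus2LL + k * log(n)
}

#' @export
AIC.gsem_fit <- function(object, ..., k = 2) aic_gsem(object$minus2LL,
                                                      object$k)

#' @export
BIC.gsem_fit <- function(object, ...) bic_gsem(object$minus2LL, object$k,
                                               object$n)

#' Model comparison table
#'
#' Summarizes a set of fits to the same data against a baseline model:
#' -2LL, k, likelihood-ratio chi-square and degrees of freedom versus the
#' baseline, p-value, AIC and BIC.
#'
#' @param ... `gsem_fit` objects; the first is the baseline unless
#'   `baseline` says otherwise. A single list may also be supplied.
#' @param baseline index of the baseline (full) model.
#' @param labels optional model labels.
#' @return data frame, one row per model.
#' @export
gsem_compare <- function(..., baseline = 1L, labels = NULL) {
  fits <- list(...)
  if (length(fits) == 1 && is.list(fits[[1]]) &&
      !inherits(fits[[1]], "gsem_fit"))
    fits <- fits[[1]]
  if (is.null(labels)) {
    labels <- names(fits)
    if (is.null(labels) || any(labels == ""))
      labels <- paste0("model", seq_along(fits))
  }
  base <- fits[[baseline]]
  rows <- lapply(seq_along(fits), function(i) {
    f <- fits[[i]]
    if (i == baseline) {
      dchi <- ddf <- p <- NA_real_
    } else {
      lr <- tryCatch(gsem_lrt(base, f), error = function(e) {
        warning("no LRT for ", labels[i], ": ", conditionMessage(e))
        list(delta_chi2 = NA_real_, delta_df = NA_real_, p = NA_real_)
      })
      dchi <- lr$delta_chi2; ddf <- lr$delta_df; p <- lr$p
    }
    data.frame(model = labels[i], minus2LL = f$minus2LL, k = f$k,
               delta_chi2 = dchi, delta_df = ddf, p = p,
               AIC = aic_gsem(f$minus2LL, f$k),
               BIC = bic_gsem(f$minus2LL, f$k, f$n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

genetic_param_parts <- c("genetic", "lambda", "spec_a")

# standardized values of the free genetic loadings of a fit
std_genetic_loadings <- function(fit) {
  spec <- fit$spec
  tot <- diag(fit$sigma_g + fit$sigma_e)
  lm_ <- loading_matrices(spec, fit$theta_hat)
  pp <- spec$params
  sel <- which(pp$part %in% genetic_param_parts)
  std <- vapply(sel, function(i) {
    j <- pp$row[i]
    val <- if (pp$part[i] == "lambda") {
      fg <- fit$theta_hat[pp$part == "fg"]
      fg * fit$theta_hat[i]
    } else if (pp$part[i] == "spec_a") {
      fit$theta_hat[i]
    } else {
      lm_$La[j, pp$col[i]]
    }
    val / sqrt(tot[j])
  }, numeric(1))
  stats::setNames(std, pp$name[sel])
}

#' Stepwise reduction of the genetic factor structure
#'
#' Starting from a fitted model, successively fixes to zero the genetic
#' loading with the smallest absolute standardized value, refits, and
#' compares the reduced model with the starting model by likelihood-ratio
#' test. The procedure stops when every remaining free genetic loading is
#' significant by Wald test (`p < alpha`) or when a drop would cause a
#' significant loss of fit versus the starting model (that drop is then
#' reverted). Ties on the smallest loading are resolved by dropping the
#' one with the later trait/factor index.
#'
#' @param fit_start a converged `gsem_fit` (the reference model for all
#'   LRTs).
#' @param alpha significance level for both the Wald and the LRT stopping
#'   conditions (default 0.05).
#' @param ... passed to [gsem_fit()] for the refits.
#' @return an object of class `gsem_reduction`: `final` (the retained
#'   fit), `start`, and `steps`, a data frame auditing each attempted
#'   drop (parameter, -2LL, k, cumulative LRT versus the start, action).
#' @export
reduce_model <- function(fit_start, alpha = 0.05, ...) {
  stopifnot(inherits(fit_start, "gsem_fit"))
  current <- fit_start
  steps <- list()
  repeat {
    pp <- current$spec$params
    g_idx <- which(pp$part %in% genetic_param_parts)
    if (!length(g_idx)) break
    wt <- wald_tests(current)
    pvals <- wt$p[g_idx]
    if (all(is.finite(pvals)) && all(pvals < alpha)) break
    std <- abs(std_genetic_loadings(current))
    cand <- which(std == min(std))
    drop_name <- names(std)[max(cand)]   # ties: later trait/factor index
    new_spec <- drop_loading(current$spec, drop_name)
    new_fit <- gsem_fit(new_spec, rotated = current$rotated, ...)
    lr <- gsem_lrt(fit_start, new_fit)
    rejected <- is.finite(lr$p) && lr$p < alpha
    steps[[length(steps) + 1]] <-
      data.frame(dropped = drop_name, minus2LL = new_fit$minus2LL,
                 k = new_fit$k, delta_chi2 = lr$delta_chi2,
                 delta_df = lr$delta_df, p = lr$p,
                 action = if (rejected) "reverted" else "accepted",
                 stringsAsFactors = FALSE)
    if (rejected) break
    current <- new_fit
  }
  steps <- if (length(steps)) do.call(rbind, steps) else
    data.frame(dropped = character(), minus2LL = numeric(), k = integer(),
               delta_chi2 = numeric(), delta_df = integer(), p = numeric(),
               action = character(), stringsAsFactors = FALSE)
  rownames(steps) <- NULL
  structure(list(final = current, start = fit_start, steps = steps,
                 alpha = alpha),
            class = "gsem_reduction")
}

#' @export
print.gsem_reduction <- function(x, ...) {
  cat("Stepwise genetic-loading reduction (alpha =", x$alpha, ")\n")
  cat("  start: k =", x$start$k, ", -2LL =",
      format(x$start$minus2LL, digits = 10), "\n")
  cat("  final: k =", x$final$k, ", -2LL =",
      format(x$final$minus2LL, digits = 10), "\n")
  if (nrow(x$steps)) print(x$steps) else cat("  (no loadings dropped)\n")
  invisible(x)
}
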