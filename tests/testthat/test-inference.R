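# delta method, genetic correlations, Wald tests, LRT, AIC/BIC,
# model comparison and stepwise reduction

fit_bivariate <- function(n = 400, m = 300, sg = psd2(0.3, 0.45, 0.2),
                          se = psd2(0.7, 0.55, 0.25), seed = 90) {
  st <- make_small_study(n, m, sg, se, seed = seed)
  list(st = st, fit = gsem_fit(gsem_cholesky(2), rotated = st$rot))
}

test_that("delta method reduces to known closed forms", {
  fb <- fit_bivariate()
  fit <- fb$fit
  # identity function: SE equals the parameter SE exactly
  dm <- delta_method_se(fit, function(th) th[2])
  expect_equal(dm$se, unname(fit$se_theta[2]), tolerance = 1e-6)
  # g = a^2: SE = 2|a| sqrt(var(a))
  dm2 <- delta_method_se(fit, function(th) th[1]^2)
  expect_equal(dm2$se,
               2 * abs(fit$theta_hat[1]) * sqrt(fit$param_cov[1, 1]),
               tolerance = 1e-4, ignore_attr = TRUE)
})

test_that("genetic correlations match the direct formula with bounds", {
  fb <- fit_bivariate()
  est <- genetic_correlations(fb$fit)
  sg <- fb$fit$sigma_g
  expect_equal(est$r_g[1, 2], sg[1, 2] / sqrt(sg[1, 1] * sg[2, 2]),
               tolerance = 1e-10)
  expect_equal(diag(est$r_g), c(P1 = 1, P2 = 1))
  expect_lte(abs(est$r_g[1, 2]), 1 + 1e-8)
  expect_true(all(est$r_g_se >= 0, na.rm = TRUE))
  expect_true(all(est$sigma_g_se >= 0))
})

test_that("rank-1 and diagonal genetic structures bound r_g", {
  # a fit object with hand-set parameters: rank-1 sigma_g -> |r_g| = 1
  st <- make_small_study(60, 80, psd2(0.3, 0.3, 0.3 * 0.999),
                         psd2(0.7, 0.7, 0.2), seed = 91)
  spec <- gsem_cholesky(2)
  mock <- gsem_fit(spec, rotated = st$rot, se = FALSE)
  mock$theta_hat[] <- c(0.6, 0.5, 0, 0.6, 0.1, 0.7)   # a22 = 0: rank 1
  ic <- implied_covariances(spec, mock$theta_hat)
  rg <- ic$sigma_g[1, 2] / sqrt(ic$sigma_g[1, 1] * ic$sigma_g[2, 2])
  expect_equal(abs(rg), 1, tolerance = 1e-12)
  mock$theta_hat[] <- c(0.6, 0, 0.5, 0.6, 0.1, 0.7)   # a21 = 0: diagonal
  ic <- implied_covariances(spec, mock$theta_hat)
  expect_equal(ic$sigma_g[1, 2], 0)
})

test_that("delta-method r_g SE calibrates against replicate spread", {
  # empirical SD of r_g over repeated simulate+fit versus the mean
  # delta-method SE (stochastic tolerance)
  sg <- psd2(0.35, 0.4, 0.5 * sqrt(0.35 * 0.4))
  se <- psd2(0.65, 0.6, 0.2)
  geno <- make_geno(400, 300, seed = 92)
  eig <- eigen_grm(compute_grm(geno))
  rgs <- ses <- numeric(60)
  for (r in 1:60) {
    ph <- simulate_phenotypes_grm(eig, sg, se, seed = 5000 + r)
    fit <- gsem_fit(gsem_cholesky(2),
                    rotated = rotate_phenotypes(ph, eig), starts = 1)
    est <- genetic_correlations(fit)
    rgs[r] <- est$r_g[1, 2]
    ses[r] <- est$r_g_se[1, 2]
  }
  expect_lt(abs(mean(ses) - sd(rgs)) / sd(rgs), 0.35)
})

test_that("Wald tests follow the normal reference", {
  fb <- fit_bivariate()
  w <- wald_test(fb$fit, "a11")
  expect_equal(w$z, w$estimate / w$se)
  expect_equal(w$p, 2 * pnorm(-abs(w$z)))
  expect_equal(wald_test(fb$fit, "a11", one_tailed = TRUE)$p, w$p / 2)
  expect_error(wald_test(fb$fit, "zz"), "unknown")
  # z = 1.96 -> p ~ 0.05; z = 0 -> p = 1 (checked on the formula the
  # implementation exposes through wald_tests)
  wt <- wald_tests(fb$fit)
  expect_equal(wt$p, 2 * pnorm(-abs(wt$z)))
  expect_equal(2 * pnorm(-1.96), 0.05, tolerance = 1e-3)
})

test_that("LRT degrees of freedom and guards follow nesting", {
  st <- make_small_study(300, 250, diag(c(0.3, 0.35, 0.3, 0.4)) +
                           0.08, diag(c(0.62, 0.57, 0.62, 0.52)) + 0.1,
                         seed = 94)
  full <- gsem_fit(gsem_cholesky(4), rotated = st$rot, se = FALSE)
  two_factor <- Reduce(drop_loading, c("a33", "a43", "a44"),
                       gsem_cholesky(4))
  red <- gsem_fit(two_factor, rotated = st$rot, se = FALSE)
  lr <- gsem_lrt(full, red)
  expect_equal(lr$delta_df, 3L)
  expect_gte(lr$delta_chi2, 0)
  ip <- gsem_fit(gsem_independent_pathway(4), rotated = st$rot,
                 se = FALSE)
  cp <- gsem_fit(gsem_common_pathway(4), rotated = st$rot, se = FALSE)
  expect_equal(gsem_lrt(full, ip)$delta_df, 4L)
  expect_equal(gsem_lrt(full, cp)$delta_df, 6L)
  # identical specs are not nested-proper
  expect_error(gsem_lrt(full, full), "not properly nested")
  # mixture reference is never larger than the standard p-value
  expect_lte(gsem_lrt(full, red, mixture = TRUE)$p, 1)
})

test_that("information criteria use the participant-count convention", {
  expect_equal(aic_gsem(7900.97, 20), 7940.97)
  expect_equal(bic_gsem(7900.97, 20, 3295), 7900.97 + 20 * log(3295))
  expect_equal(aic_gsem(123.4, 0), 123.4)
  expect_equal(bic_gsem(123.4, 0, 50), 123.4)
  expect_error(bic_gsem(1, 2, 1), "participant")
})

test_that("model comparison table mirrors per-fit statistics", {
  sg <- diag(c(0.25, 0.3, 0.35)) + 0.08
  se <- diag(c(0.6, 0.55, 0.5)) + 0.1
  st <- make_small_study(300, 250, sg, se, seed = 95)
  fits <- list(cholesky = gsem_fit(gsem_cholesky(3), rotated = st$rot,
                                   se = FALSE),
               common = gsem_fit(gsem_common_pathway(3),
                                 rotated = st$rot, se = FALSE))
  cmp <- gsem_compare(fits)
  expect_equal(cmp$AIC, cmp$minus2LL + 2 * cmp$k)
  expect_equal(cmp$BIC, cmp$minus2LL + cmp$k * log(300))
  expect_true(is.na(cmp$delta_chi2[1]))
  expect_equal(cmp$delta_df[2], fits$cholesky$k - fits$common$k)
})

test_that("LRT is invariant to consistent trait reordering", {
  sg <- psd2(0.3, 0.45, 0.2); se <- psd2(0.7, 0.55, 0.25)
  st <- make_small_study(250, 200, sg, se, seed = 96)
  rot1 <- st$rot
  ph2 <- st$pheno[, c("FID", "IID", "P2", "P1")]
  rot2 <- rotate_phenotypes(ph2, st$eig)
  spec <- gsem_cholesky(2)
  f1 <- gsem_fit(spec, rotated = rot1, se = FALSE)
  f2 <- gsem_fit(gsem_cholesky(2, traits = c("P2", "P1")),
                 rotated = rot2, se = FALSE)
  expect_equal(f1$minus2LL, f2$minus2LL, tolerance = 1e-4)
})

test_that("stepwise reduction honours its stopping contract", {
  # strong two-factor truth on three traits
  La <- rbind(c(0.55, 0), c(0.5, 0.45), c(0.45, 0.5))
  sg <- tcrossprod(La)
  se <- diag(1 - diag(sg))
  st <- make_small_study(800, 500, sg, se, seed = 97)
  start <- gsem_fit(gsem_cholesky(3), rotated = st$rot)
  red <- reduce_model(start, alpha = 0.05)
  final <- red$final
  # contract: all remaining genetic loadings significant, or the next
  # drop was rejected by the cumulative LRT
  wt <- wald_tests(final)
  gnames <- final$spec$params$name[final$spec$params$part == "genetic"]
  last_rejected <- nrow(red$steps) > 0 &&
    red$steps$action[nrow(red$steps)] == "reverted"
  expect_true(all(wt$p[wt$parameter %in% gnames] < 0.05) || last_rejected)
  # every accepted step kept the cumulative LRT non-significant
  acc <- red$steps[red$steps$action == "accepted", ]
  if (nrow(acc)) expect_true(all(acc$p >= 0.05))
  # audit trail bookkeeping
  if (nrow(red$steps))
    expect_equal(red$steps$delta_df,
                 start$k - red$steps$k)
  # reduction never drops residual loadings
  expect_false(any(grepl("^e", red$steps$dropped)))
})

test_that("strong loadings everywhere lead to no drops", {
  La <- rbind(c(0.6, 0), c(0.45, 0.5))
  sg <- tcrossprod(La)
  se <- diag(1 - diag(sg))
  st <- make_small_study(1200, 600, sg, se, seed = 98)
  start <- gsem_fit(gsem_cholesky(2), rotated = st$rot)
  red <- reduce_model(start)
  expect_true(nrow(red$steps) == 0 ||
                all(red$steps$action == "reverted"))
  expect_equal(red$final$k, 6L)
})

test_that("genetic variance share isolates factor contributions", {
  fb <- fit_bivariate(n = 600, m = 400)
  sh <- genetic_variance_share(fb$fit, "P2", "A1")
  La <- loading_matrices(fb$fit$spec, fb$fit$theta_hat)$La
  expect_equal(sh$estimate, La[2, 1]^2 / sum(La[2, ]^2), tolerance = 1e-10)
  expect_gte(sh$estimate, 0)
  expect_lte(sh$estimate, 1)
  expect_gt(sh$se, 0)
})
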