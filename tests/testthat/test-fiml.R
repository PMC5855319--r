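# rotation, likelihood evaluation against the dense oracle, fitting,
# path standardization

test_that("rotation preserves per-trait sums of squares", {
  st <- make_small_study(30, 100, psd2(0.3, 0.4, 0.1),
                         psd2(0.7, 0.6, 0.2), seed = 61)
  Y <- as.matrix(st$pheno[, -(1:2)])
  expect_equal(colSums(st$rot$ytilde^2), colSums(Y^2), tolerance = 1e-8,
               ignore_attr = TRUE)
  # orthogonal rotation: Frobenius norm and per-trait SS preserved even
  # for the degenerate identity GRM (any orthonormal eigenbasis)
  eye <- eigen_grm(as_grm(diag(5)))
  Y5 <- matrix(rnorm(10), 5, 2)
  yt <- rotate_phenotypes(Y5, eye)$ytilde
  expect_equal(colSums(yt^2), colSums(Y5^2), ignore_attr = TRUE)
  Yna <- st$pheno; Yna[1, 3] <- NA
  expect_error(rotate_phenotypes(Yna, st$eig), "complete_cases")
})

test_that("likelihood at a point matches the standard normal density", {
  # n = 1, t = 1, sigma_g = 0, sigma_e = 1, y = 0 -> log(2 pi)
  rot <- structure(list(ytilde = matrix(0, 1, 1), d = 0.7,
                        u1 = 1, traits = "P1", n = 1L, ybar = 0),
                   class = "gsem_rotated")
  spec <- gsem_cholesky(1)
  expect_equal(neg2_loglik(spec, c(0, 1), rot), 1.83787706641,
               tolerance = 1e-10)
  expect_error(neg2_loglik(spec, c(NA, 1), rot), "non-finite")
})

test_that("rotated likelihood equals the dense Kronecker evaluation", {
  set.seed(62)
  for (case in list(list(n = 50, t = 3, m = 120),
                    list(n = 60, t = 4, m = 80),
                    list(n = 25, t = 2, m = 200))) {
    geno <- make_geno(case$n, case$m, seed = case$n)
    grm <- compute_grm(geno)
    eig <- eigen_grm(grm)
    t <- case$t
    L <- matrix(rnorm(t * t, sd = 0.5), t, t); L[upper.tri(L)] <- 0
    sg <- tcrossprod(L) + diag(0.05, t)
    se <- diag(runif(t, 0.3, 0.8))
    ph <- simulate_phenotypes_grm(eig, sg, se, seed = case$n + 1)
    rot <- rotate_phenotypes(ph, eig)
    spec <- gsem_cholesky(t)
    th <- runif(spec$k, 0.1, 0.7)
    expect_equal(neg2_loglik(spec, th, rot),
                 dense_neg2ll(implied_covariances(spec, th)$sigma_g,
                              implied_covariances(spec, th)$sigma_e,
                              as.matrix(ph[, -(1:2)]), grm$values),
                 tolerance = 1e-6)
  }
})

test_that("doubling the covariance scale shifts -2LL by the identity", {
  st <- make_small_study(40, 100, psd2(0.3, 0.4, 0.1),
                         psd2(0.7, 0.6, 0.2), seed = 63)
  spec <- gsem_cholesky(2)
  th <- c(0.5, 0.2, 0.4, 0.8, 0.1, 0.7)
  v1 <- neg2_loglik(spec, th, st$rot)
  v2 <- neg2_loglik(spec, sqrt(2) * th, st$rot)
  # log|2 Omega| = t log 2 + log|Omega|; quadratic term halves
  ic <- implied_covariances(spec, th)
  quad <- v1 - 40 * 2 * log(2 * pi) -
    sum(vapply(seq_len(40), function(i)
      determinant(st$rot$d[i] * ic$sigma_g + ic$sigma_e,
                  logarithm = TRUE)$modulus, numeric(1)))
  expect_equal(v2 - v1, 40 * 2 * log(2) - quad / 2, tolerance = 1e-6)
})

test_that("non-PD implied covariance yields +Inf, not an error", {
  st <- make_small_study(20, 60, psd2(0.3, 0.4, 0.1),
                         psd2(0.7, 0.6, 0.2), seed = 64)
  expect_identical(neg2_loglik(gsem_cholesky(2), c(0, 0, 0, 0, 0, 0),
                               st$rot), Inf)
})

test_that("likelihood is invariant under genetic-factor rotation", {
  st <- make_small_study(35, 90, psd2(0.3, 0.4, 0.1),
                         psd2(0.7, 0.6, 0.2), seed = 65)
  spec <- gsem_cholesky(2)
  th <- c(0.5, 0.2, 0.4, 0.8, 0.1, 0.7)
  La <- loading_matrices(spec, th)$La
  ang <- 0.6
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2, 2)
  La_rot <- La %*% R
  # re-triangularize: same sigma_g, different factor basis
  Lr <- t(chol(tcrossprod(La_rot)))
  th2 <- c(Lr[lower.tri(Lr, diag = TRUE)], th[4:6])
  expect_equal(neg2_loglik(spec, th, st$rot),
               neg2_loglik(spec, th2, st$rot), tolerance = 1e-8)
})

test_that("saturated fit recovers generating parameters at moderate n", {
  sg <- psd2(0.3, 0.45, 0.5 * sqrt(0.3 * 0.45))
  se <- psd2(0.7, 0.55, 0.25)
  st <- make_small_study(1000, 800, sg, se, seed = 66)
  fit <- gsem_fit(gsem_cholesky(2), rotated = st$rot)
  expect_true(fit$converged)
  # each sigma_g entry within 2 delta-method SEs of the truth
  est <- genetic_correlations(fit)
  for (j in 1:2) for (k in 1:j)
    expect_lt(abs(fit$sigma_g[j, k] - sg[j, k]),
              2.5 * est$sigma_g_se[j, k])
  # implied total covariance tracks the sample covariance
  S <- cov(as.matrix(st$pheno[, -(1:2)]))
  tot <- fit$sigma_g + fit$sigma_e
  expect_lt(max(abs(tot - S) / diag(S)), 0.10)
})

test_that("minimized -2LL is monotone in nesting", {
  st <- make_small_study(300, 250, psd2(0.3, 0.4, 0.15),
                         psd2(0.7, 0.6, 0.2), seed = 67)
  full <- gsem_fit(gsem_cholesky(2), rotated = st$rot, se = FALSE)
  red <- gsem_fit(drop_loading(gsem_cholesky(2), "a21"),
                  rotated = st$rot, se = FALSE)
  ip <- gsem_fit(gsem_independent_pathway(2), rotated = st$rot, se = FALSE)
  cp <- gsem_fit(gsem_common_pathway(2), rotated = st$rot, se = FALSE)
  expect_gte(red$minus2LL, full$minus2LL - 1e-4)
  expect_gte(cp$minus2LL, full$minus2LL - 1e-4)
  # bivariate independent pathway has k = 8 > 6: it nests the saturated
  # model, so its optimum cannot be worse
  expect_lte(abs(ip$minus2LL - full$minus2LL), 1)
})

test_that("null genetic variance is estimated near zero", {
  vg <- numeric(6)
  for (r in 1:6) {
    st <- make_small_study(500, 400, matrix(0, 1, 1),
                           matrix(1, 1, 1), seed = 70 + r)
    fit <- gsem_fit(gsem_cholesky(1), rotated = st$rot, se = FALSE)
    vg[r] <- fit$sigma_g[1, 1]
  }
  expect_lte(median(vg), 0.05)
})

test_that("univariate fit partitions the phenotypic variance", {
  sg <- matrix(0.25, 1, 1); se <- matrix(0.75, 1, 1)
  st <- make_small_study(800, 600, sg, se, seed = 77)
  fit <- gsem_univariate(st$pheno, st$eig)
  vc <- fit$vc
  expect_equal(vc$component, c("Var_g", "Var_e", "h2"))
  y <- st$pheno[[3]]
  total <- vc$estimate[1] + vc$estimate[2]
  expect_lt(abs(total - var(y)) / var(y), 0.05)
  expect_lt(abs(vc$estimate[1] - 0.25), 2.5 * vc$se[1])
})

test_that("an identity GRM leaves the variance split unidentified", {
  # with A = I the likelihood depends on a^2 + e^2 only: it is exactly
  # flat along the genetic/residual split, so Var_g carries no
  # information and the curvature-based SEs degenerate
  eye <- eigen_grm(as_grm(diag(120)))
  set.seed(79)
  ph <- matrix(rnorm(120), 120, 1)
  rot <- rotate_phenotypes(ph, eye)
  spec <- gsem_cholesky(1)
  v <- neg2_loglik(spec, c(0.6, 0.8), rot)      # a^2 + e^2 = 1
  expect_equal(neg2_loglik(spec, c(0.8, 0.6), rot), v, tolerance = 1e-10)
  expect_equal(neg2_loglik(spec, c(0, 1), rot), v, tolerance = 1e-10)
  fit <- suppressWarnings(gsem_fit(spec, rotated = rot))
  cov_ok <- !anyNA(fit$param_cov)
  if (cov_ok) {
    # any reported curvature must be near-singular: the SE of the
    # genetic loading blows up relative to the estimate scale
    expect_gt(max(fit$se_theta), 1)
  } else {
    expect_true(anyNA(fit$se_theta))
  }
})

test_that("standardized loadings square-sum to one per trait", {
  st <- make_small_study(400, 300, psd2(0.3, 0.45, 0.2),
                         psd2(0.7, 0.55, 0.25), seed = 80)
  for (spec in list(gsem_cholesky(2), gsem_independent_pathway(2),
                    gsem_common_pathway(2))) {
    fit <- gsem_fit(spec, rotated = st$rot, se = FALSE)
    sp <- standardize_paths(fit, se = FALSE)
    sums <- tapply(sp$std_estimate^2, sp$trait, sum)
    expect_equal(as.vector(sums), rep(1, 2), tolerance = 1e-8)
    # squared standardized loading is the variance share in percent
    expect_equal(sp$pct_variance, 100 * sp$std_estimate^2)
  }
  # a unit-variance trait leaves loadings unchanged by standardization
  fit <- gsem_fit(gsem_cholesky(2), rotated = st$rot, se = FALSE)
  tot <- diag(fit$sigma_g + fit$sigma_e)
  sp <- standardize_paths(fit, se = FALSE)
  j <- match(sp$trait, fit$spec$traits)
  expect_equal(sp$std_estimate, unname(sp$estimate / sqrt(tot[j])))
})

test_that("fit results serialize to JSON with stable keys", {
  st <- make_small_study(150, 120, psd2(0.3, 0.4, 0.1),
                         psd2(0.7, 0.6, 0.2), seed = 81)
  fit <- gsem_fit(gsem_cholesky(2), rotated = st$rot)
  path <- file.path(withr::local_tempdir(), "fit.json")
  write_gsem_json(fit, path)
  parsed <- jsonlite::fromJSON(path)
  expect_equal(parsed$minus2LL, fit$minus2LL)
  expect_equal(parsed$k, 6)
  expect_named(parsed$estimates, names(fit$theta_hat))
  expect_equal(unlist(parsed$sigma_g[1, ]), unname(fit$sigma_g[1, ]))
})
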