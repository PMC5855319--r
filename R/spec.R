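# AE latent factor structures. A model specification holds boolean masks
# of free factor loadings: genetic factors A1..Aq act on the genetic side,
# residual factors E1..Eq on the residual side. Latent factor variances
# are fixed at 1, so the implied covariances are products of loading
# matrices. The common pathway model is parameterized separately because
# its genetic side is the product of a latent-factor path (f_g) and
# latent-to-trait loadings (lambda).

default_traits <- function(t) paste0("P", seq_len(t))

build_mask_params <- function(mask, prefix) {
  idx <- which(mask)             # column-major order
  if (!length(idx)) return(NULL)
  rows <- row(mask)[idx]
  cols <- col(mask)[idx]
  data.frame(name = sprintf("%s%d%d", prefix, rows, cols),
             part = if (prefix == "a") "genetic" else "residual",
             row = rows, col = cols, stringsAsFactors = FALSE)
}

new_gsem_spec <- function(t, traits, structure, genetic_mask = NULL,
                          residual_mask = NULL, lambda_mask = NULL,
                          spec_a_mask = NULL, spec_e_mask = NULL,
                          fixed = character()) {
  if (structure == "common") {
    params <- rbind(
      if (any(lambda_mask))
        data.frame(name = paste0("l", which(lambda_mask)), part = "lambda",
                   row = which(lambda_mask), col = 1L,
                   stringsAsFactors = FALSE),
      data.frame(name = c("fg", "fe"), part = c("fg", "fe"),
                 row = 0L, col = 1L, stringsAsFactors = FALSE),
      if (any(spec_a_mask))
        data.frame(name = paste0("as", which(spec_a_mask)), part = "spec_a",
                   row = which(spec_a_mask), col = 1L,
                   stringsAsFactors = FALSE),
      if (any(spec_e_mask))
        data.frame(name = paste0("es", which(spec_e_mask)), part = "spec_e",
                   row = which(spec_e_mask), col = 1L,
                   stringsAsFactors = FALSE))
  } else {
    params <- rbind(build_mask_params(genetic_mask, "a"),
                    build_mask_params(residual_mask, "e"))
  }
  rownames(params) <- NULL
  structure(list(t = t, traits = traits, structure = structure,
                 genetic_mask = genetic_mask, residual_mask = residual_mask,
                 lambda_mask = lambda_mask, spec_a_mask = spec_a_mask,
                 spec_e_mask = spec_e_mask,
                 params = params, k = nrow(params), fixed = fixed),
            class = "gsem_spec")
}

#' Cholesky decomposition AE model
#'
#' The saturated multivariate AE model: as many latent genetic factors as
#' traits and as many residual factors, with lower-triangular loading
#' patterns, giving `k = t(t+1)` free parameters (e.g. 20 for four traits,
#' 2 for the univariate AE model).
#'
#' @param t number of traits (>= 1).
#' @param traits optional trait labels.
#' @return an object of class `gsem_spec`.
#' @export
gsem_cholesky <- function(t, traits = NULL) {
  if (!is.numeric(t) || t < 1) stop("'t' must be >= 1")
  t <- as.integer(t)
  if (is.null(traits)) traits <- default_traits(t)
  mask <- lower.tri(matrix(TRUE, t, t), diag = TRUE)
  dimnames(mask) <- list(traits, paste0("A", seq_len(t)))
  rmask <- mask
  colnames(rmask) <- paste0("E", seq_len(t))
  new_gsem_spec(t, traits, "cholesky", mask, rmask)
}

#' Independent pathway AE model
#'
#' One common genetic factor and one common residual factor load on every
#' trait, plus one trait-specific genetic and one trait-specific residual
#' factor per trait: `k = 4t` free parameters (16 for four traits).
#'
#' @inheritParams gsem_cholesky
#' @return an object of class `gsem_spec`.
#' @export
gsem_independent_pathway <- function(t, traits = NULL) {
  if (!is.numeric(t) || t < 2) stop("'t' must be >= 2")
  t <- as.integer(t)
  if (is.null(traits)) traits <- default_traits(t)
  mask <- cbind(rep(TRUE, t), diag(TRUE, t))
  dimnames(mask) <- list(traits, c("AC", paste0("AS", seq_len(t))))
  rmask <- mask
  colnames(rmask) <- c("EC", paste0("ES", seq_len(t)))
  new_gsem_spec(t, traits, "independent", mask, rmask)
}

#' Common pathway AE model
#'
#' A single latent phenotypic factor with loadings `lambda_j` on the
#' traits is itself decomposed into a genetic path `f_g` and a residual
#' path `f_e`; trait-specific genetic and residual factors complete the
#' model: `k = 3t + 2` free parameters (14 for four traits). The classical
#' unit-variance constraint `f_g^2 + f_e^2 = 1` is not imposed (it renders
#' the Hessian singular); the scale indeterminacy between `lambda` and
#' `(f_g, f_e)` is handled by reporting the identified products
#' `f_g * lambda_j` and `f_e * lambda_j` alongside the raw parameters.
#'
#' @inheritParams gsem_cholesky
#' @return an object of class `gsem_spec`.
#' @export
gsem_common_pathway <- function(t, traits = NULL) {
  if (!is.numeric(t) || t < 2) stop("'t' must be >= 2")
  t <- as.integer(t)
  if (is.null(traits)) traits <- default_traits(t)
  new_gsem_spec(t, traits, "common",
                lambda_mask = rep(TRUE, t),
                spec_a_mask = rep(TRUE, t),
                spec_e_mask = rep(TRUE, t))
}

#' Custom AE loading pattern
#'
#' @param genetic_mask logical t x q_a matrix marking free genetic
#'   loadings.
#' @param residual_mask logical t x q_e matrix marking free residual
#'   loadings.
#' @param traits optional trait labels.
#' @return an object of class `gsem_spec` with `structure = "custom"`.
#' @export
gsem_custom <- function(genetic_mask, residual_mask, traits = NULL) {
  genetic_mask <- as.matrix(genetic_mask) > 0
  residual_mask <- as.matrix(residual_mask) > 0
  t <- nrow(genetic_mask)
  if (nrow(residual_mask) != t)
    stop("masks must have the same number of trait rows")
  if (is.null(traits)) traits <- default_traits(t)
  if (is.null(colnames(genetic_mask)))
    colnames(genetic_mask) <- paste0("A", seq_len(ncol(genetic_mask)))
  if (is.null(colnames(residual_mask)))
    colnames(residual_mask) <- paste0("E", seq_len(ncol(residual_mask)))
  rownames(genetic_mask) <- rownames(residual_mask) <- traits
  new_gsem_spec(t, traits, "custom", genetic_mask, residual_mask)
}

#' Fix a free loading to zero
#'
#' Returns a copy of the specification in which the named loading is no
#' longer free (fixed at 0); the free-parameter count drops by one. The
#' latent paths `fg`/`fe` of the common pathway model cannot be dropped.
#'
#' @param spec a `gsem_spec`.
#' @param parameter_name name of a free parameter (see
#'   `spec$params$name`).
#' @return the reduced `gsem_spec`.
#' @export
drop_loading <- function(spec, parameter_name) {
  stopifnot(inherits(spec, "gsem_spec"))
  i <- match(parameter_name, spec$params$name)
  if (is.na(i)) stop("unknown or already fixed parameter: ", parameter_name)
  p <- spec$params[i, ]
  if (p$part %in% c("fg", "fe"))
    stop("latent path ", parameter_name, " cannot be fixed to zero")
  gm <- spec$genetic_mask; rm_ <- spec$residual_mask
  lm_ <- spec$lambda_mask; am <- spec$spec_a_mask; em <- spec$spec_e_mask
  switch(p$part,
         genetic = { gm[p$row, p$col] <- FALSE },
         residual = { rm_[p$row, p$col] <- FALSE },
         lambda = { lm_[p$row] <- FALSE },
         spec_a = { am[p$row] <- FALSE },
         spec_e = { em[p$row] <- FALSE })
  new_gsem_spec(spec$t, spec$traits, spec$structure, gm, rm_, lm_, am, em,
                fixed = c(spec$fixed, parameter_name))
}

#' Loading matrices implied by a parameter vector
#'
#' Returns the genetic and residual loading matrices `Lambda_a`,
#' `Lambda_e` such that `sigma_g = Lambda_a %*% t(Lambda_a)` and
#' `sigma_e = Lambda_e %*% t(Lambda_e)`. For the common pathway model the
#' genetic columns are the identified products (`f_g * lambda`, specific
#' loadings), and likewise for the residual side.
#'
#' @param spec a `gsem_spec`.
#' @param theta numeric parameter vector of length `spec$k`.
#' @return list with matrices `La` (t x q_a) and `Le` (t x q_e).
#' @export
loading_matrices <- function(spec, theta) {
  stopifnot(inherits(spec, "gsem_spec"))
  if (length(theta) != spec$k)
    stop("theta has length ", length(theta), ", expected k = ", spec$k)
  t <- spec$t
  if (spec$structure == "common") {
    lam <- as_full <- es_full <- numeric(t)
    pp <- spec$params
    lam[pp$row[pp$part == "lambda"]] <- theta[pp$part == "lambda"]
    as_full[pp$row[pp$part == "spec_a"]] <- theta[pp$part == "spec_a"]
    es_full[pp$row[pp$part == "spec_e"]] <- theta[pp$part == "spec_e"]
    fg <- theta[pp$part == "fg"]
    fe <- theta[pp$part == "fe"]
    La <- cbind(fg * lam, diag(as_full, t))
    Le <- cbind(fe * lam, diag(es_full, t))
    colnames(La) <- c("AC", paste0("AS", seq_len(t)))
    colnames(Le) <- c("EC", paste0("ES", seq_len(t)))
  } else {
    La <- matrix(0, t, ncol(spec$genetic_mask),
                 dimnames = dimnames(spec$genetic_mask))
    Le <- matrix(0, t, ncol(spec$residual_mask),
                 dimnames = dimnames(spec$residual_mask))
    is_g <- spec$params$part == "genetic"
    La[which(spec$genetic_mask)] <- theta[is_g]
    Le[which(spec$residual_mask)] <- theta[!is_g]
  }
  rownames(La) <- rownames(Le) <- spec$traits
  list(La = La, Le = Le)
}

#' Model-implied genetic and residual covariance matrices
#'
#' @inheritParams loading_matrices
#' @return list with `sigma_g` and `sigma_e` (t x t, symmetric positive
#'   semidefinite by construction for any real theta).
#' @export
implied_covariances <- function(spec, theta) {
  lm_ <- loading_matrices(spec, theta)
  sg <- tcrossprod(lm_$La)
  se <- tcrossprod(lm_$Le)
  dimnames(sg) <- dimnames(se) <- list(spec$traits, spec$traits)
  list(sigma_g = sg, sigma_e = se)
}

is_saturated_cholesky <- function(spec) {
  spec$structure == "cholesky" && spec$k == spec$t * (spec$t + 1)
}

# nested = free-parameter pattern expressible inside 'full'
is_nested_spec <- function(nested, full) {
  if (nested$t != full$t) return(FALSE)
  if (nested$k >= full$k) return(FALSE)
  if (is_saturated_cholesky(full)) return(TRUE)
  same_family <- nested$structure == full$structure ||
    (nested$structure == "custom" && full$structure != "common")
  if (!same_family) return(NA)
  if (full$structure == "common") {
    all(nested$lambda_mask <= full$lambda_mask) &&
      all(nested$spec_a_mask <= full$spec_a_mask) &&
      all(nested$spec_e_mask <= full$spec_e_mask)
  } else {
    if (!identical(dim(nested$genetic_mask), dim(full$genetic_mask)) ||
        !identical(dim(nested$residual_mask), dim(full$residual_mask)))
      return(NA)
    all(nested$genetic_mask <= full$genetic_mask) &&
      all(nested$residual_mask <= full$residual_mask)
  }
}

#' @export
print.gsem_spec <- function(x, ...) {
  lab <- switch(x$structure,
                cholesky = "Cholesky decomposition",
                independent = "independent pathway",
                common = "common pathway",
                custom = "custom pattern")
  cat("AE model (", lab, "): ", x$t, " trait(s), k = ", x$k,
      " free parameters\n", sep = "")
  if (length(x$fixed))
    cat("  loadings fixed to zero:", paste(x$fixed, collapse = ", "), "\n")
  invisible(x)
}

#' Read a model specification from a YAML config file
#'
#' The config names the structure (`cholesky`, `independent`, `common`
#' or `custom`), the number of traits `t` and optional `traits` labels.
#' Custom patterns supply `genetic_mask` and `residual_mask` as lists of
#' 0/1 rows (one per trait). A `drop` list of parameter names fixes
#' further loadings to zero, so reduced forms of the named structures
#' are expressible without code changes.
#'
#' @param path YAML file.
#' @return a `gsem_spec`.
#' @export
read_model_spec <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read model configs")
  cfg <- yaml::read_yaml(path)
  known <- c("structure", "t", "traits", "genetic_mask", "residual_mask",
             "drop")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (is.null(cfg$structure)) stop("config must name a 'structure'")
  traits <- if (!is.null(cfg$traits)) as.character(cfg$traits) else NULL
  spec <- switch(cfg$structure,
    cholesky = gsem_cholesky(cfg$t, traits),
    independent = gsem_independent_pathway(cfg$t, traits),
    common = gsem_common_pathway(cfg$t, traits),
    custom = {
      if (is.null(cfg$genetic_mask) || is.null(cfg$residual_mask))
        stop("custom structure requires genetic_mask and residual_mask")
      gm <- do.call(rbind, cfg$genetic_mask)
      rm_ <- do.call(rbind, cfg$residual_mask)
      gsem_custom(gm, rm_, traits)
    },
    stop("unknown structure: ", cfg$structure))
  for (nm in cfg$drop) spec <- drop_loading(spec, nm)
  spec
}
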