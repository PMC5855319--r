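---
title: "Latent factor models of SNP-tagged genetic variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Latent factor models of SNP-tagged genetic variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsemr)
```

## The model

`gsemr` fits multivariate AE variance-component models in samples of
nominally unrelated, genotyped individuals. For `t` traits measured on
`n` individuals, the model for the stacked phenotype vector is

$$
\mathrm{vec}(Y) \sim \mathcal{N}\!\left(0,\;
  \Sigma_g \otimes A + \Sigma_e \otimes I_n\right),
$$

where `A` is the genetic relationship matrix (GRM) estimated from
genome-wide SNP dosages, $\Sigma_g$ is the `t x t` covariance of
additive genetic effects tagged by those SNPs, and $\Sigma_e$ collects
everything else: untagged genetic variation, environment, and
measurement error. For phenotypes standardized to unit variance the
diagonal of $\Sigma_g$ is the SNP heritability of each trait.

The structural part of the model is borrowed from twin methodology.
$\Sigma_g = \Lambda_a \Lambda_a^\top$ and
$\Sigma_e = \Lambda_e \Lambda_e^\top$ are written as products of factor
loadings on latent factors with unit variance, and hypotheses about
developmental structure become patterns of free and zero loadings:

* **Cholesky decomposition** (`gsem_cholesky(t)`): as many genetic and
  residual factors as traits, triangular loading patterns,
  `k = t(t+1)` free parameters (20 for four traits). This is the
  saturated baseline model.
* **Independent pathway** (`gsem_independent_pathway(t)`): one common
  genetic and one common residual factor plus trait-specific factors,
  `k = 4t` (16 for four traits).
* **Common pathway** (`gsem_common_pathway(t)`): a single latent
  phenotypic factor with loadings $\lambda_j$, decomposed into a
  genetic path $f_g$ and a residual path $f_e$, plus trait-specific
  factors, `k = 3t + 2` (14 for four traits).

Arbitrary reduced patterns are formed with `drop_loading()` or
`gsem_custom()`; dropping the three loadings of the third and fourth
genetic factors of a four-trait Cholesky model gives the
two-genetic-factor model with `k = 17`.

### The common pathway parameterization

The classical common pathway model constrains
$f_g^2 + f_e^2 = 1$ so the latent factor has unit variance. Under that
constraint the observed information is singular, so the constraint is
not imposed here and `k` is counted as `3t + 2`. The cost is a known
scale indeterminacy — $(\lambda, f_g, f_e)$ and
$(c\lambda, f_g/c, f_e/c)$ imply the same covariance — so the raw
parameters have no finite standard errors (the package warns and
reports `NA`), while the identified products $f_g\lambda_j$ and
$f_e\lambda_j$ are what `standardize_paths()` and all derived
quantities use.

## Likelihood evaluation and optimization

With the eigendecomposition $A = U D U^\top$, rotating the phenotypes
by $U^\top$ makes the model covariance block diagonal: row `i` of the
rotated data is an independent $\mathcal{N}(0, d_i \Sigma_g + \Sigma_e)$
draw. The -2 log-likelihood is evaluated by simultaneously
diagonalizing $(\Sigma_g, \Sigma_e)$ once per evaluation (a `t x t`
Cholesky and eigendecomposition), after which the per-individual terms
cost `O(t)` each. Unit tests verify this evaluation against the dense
`nt x nt` multivariate normal density to `1e-6` on every tested
instance; that equivalence is the core correctness oracle of the
engine.

Numerical choices, all configurable through `gsem_fit()` arguments:

* **Optimizer**: BFGS with numerically approximated gradients,
  `reltol = 1e-10`, followed by a Nelder-Mead polish if the
  quasi-Newton run does not report convergence. A fit is flagged
  `converged` when the scaled gradient norm is at most `1e-5`.
* **Starting values** (three by default): (i) an even split of the
  sample covariance between the genetic and residual sides, using
  Cholesky factors of half the sample covariance for triangular
  patterns; (ii) a near-null genetic side, which guards against
  spurious genetic optima when the true heritability is small;
  (iii) a deterministic 25% jitter of (i) under the fit seed.
* **Boundary handling**: parameter vectors implying a non-positive
  definite covariance for some individual receive `+Inf` rather than a
  reparameterization; the factor parameterization already keeps
  $\Sigma_g$ and $\Sigma_e$ positive semidefinite for any real
  parameter vector.
* **Sign convention**: the likelihood is invariant to flipping the
  sign of a whole factor column; after optimization each column is
  flipped so its leading loading is nonnegative, giving unique
  reported loadings.
* **Standard errors**: the parameter covariance is
  $2 H^{-1}$ with `H` the central-finite-difference Hessian of the
  -2 log-likelihood (observed information). When `H` is not positive
  definite — boundary solutions, the common pathway indeterminacy, or
  an uninformative GRM — SEs are reported as `NA` with a warning
  rather than silently pseudo-inverted.
* **Mean structure**: phenotypes are assumed pre-residualized and
  rank-transformed, so the model mean is fixed at zero;
  `intercepts = TRUE` estimates per-trait means instead.

Derived quantities — genetic correlations
$r_g = \Sigma_{g,jk}/\sqrt{\Sigma_{g,jj}\Sigma_{g,kk}}$, variance
shares, standardized loadings — carry first-order delta-method SEs
(`delta_method_se()`), with gradients by central differences at step
`1e-5 * max(1, |theta|)`.

## Phenotype preparation

`prep_phenotypes()` mirrors the standard preparation for this model
family: each trait is residualized on covariates (sex, age, ancestry
principal components) by OLS on all samples with complete covariates,
then mapped to normal quantiles by the rank-based inverse normal
transformation. The Blom offset (3/8) is the default; `"none"` and
`"rankit"` are available because the literature is not unanimous and
the choice is immaterial beyond roughly `n = 50`. Ties receive average
ranks before transformation, which keeps the output deterministic and
order-independent. Model fitting itself is complete-case: the
likelihood above assumes every individual is observed on every trait,
and `complete_cases()` + `align_samples()` enforce the bookkeeping.

## Model comparison and stepwise reduction

Nested models are compared by likelihood-ratio test, and all models by
AIC (`-2LL + 2k`) and BIC (`-2LL + k log n` with `n` the number of
participants, not the number of trait observations — the convention
that reproduces published fit tables for this model family).
Loadings are tested by two-sided Wald tests on the normal reference.
Because genetic variance components live on a boundary, the LRT
statistic need not follow the nominal chi-square reference exactly;
`gsem_lrt(..., mixture = TRUE)` provides a 50:50 chi-square mixture
reference as a sensitivity analysis.

`reduce_model()` automates the second, data-driven stage of model
identification: it repeatedly fixes to zero the genetic loading with
the smallest absolute standardized value, refits, and tracks the
cumulative LRT against the starting model. It stops when every
remaining genetic loading is Wald-significant at `alpha`, or reverts
the last drop if it costs a significant amount of likelihood. Exact
ties on the smallest loading are resolved by dropping the one with the
later trait/factor index, making the procedure deterministic.

## What the simulator emulates

`sim_design()` describes unlinked SNPs in Hardy-Weinberg equilibrium
with allele frequencies uniform on a MAF range, a subset of causal
SNPs whose standardized dosages carry multivariate normal effects
scaled so the SNP-tagged covariance equals the target $\Sigma_g$, and
multivariate normal residuals. Defaults define the package's reference
validation study: a bivariate standardized trait in `n = 5000`
individuals, `m = 5000` SNPs of which 1000 are causal, SNP-tagged
variance fractions 0.25 and 0.47 (echoing published univariate
estimates for a childhood and a late-adolescence measure of the same
behavioral trait), genetic correlation 0.5, residual correlation 0.3,
and 10 replicates. The SNP count is a deliberate scale-down from the
hundreds of thousands of genotyped SNPs in a real cohort; it preserves
the estimator's behavior while keeping a replicate study tractable on
a desktop.

Two phenotype routes are provided. The causal route
(`simulate_phenotypes_causal()`) generates traits mechanistically from
SNP effects, so the GRM "sees" the causal architecture with sampling
noise — this is the honest end-to-end test and is what
`run_accuracy_study()` uses. The model route
(`simulate_phenotypes_grm()`) draws directly from the likelihood's own
covariance and is exactly model-consistent, which makes it the right
tool for calibration checks of SEs and test sizes. Negative GRM
eigenvalues (possible when SNPs are fewer than individuals) are
clipped at zero in the model route, with a message.

What the simulator does **not** emulate: linkage disequilibrium
(the likelihood is agnostic to LD given the GRM), ascertainment and
attrition, family structure, binary traits on the liability scale, and
genotyping error. Passing accuracy tests therefore demonstrate
estimator correctness under the model's own assumptions, not
robustness to those complications.

`run_accuracy_study()` reports, per parameter, the bias of the mean
estimate, its square, the root mean squared error and the mean
absolute deviation across converged replicates. Under the reference
design the squared bias of every genetic and residual variance and
covariance estimate is below `1e-3`, the benchmark the estimator was
validated against; `RMSE^2 >= bias^2` holds by construction and is
asserted.

## Problem sizes and runtime

The `n x n` eigendecomposition dominates: roughly a minute at
`n = 5000` on one core, a few seconds at `n = 1000`. One
eigendecomposition per dataset suffices for any number of model fits
on it (pass a precomputed `rotated` object to `gsem_fit()`). The unit
test suite exercises fits at `n` between 120 and 1200 and the full
reference design once; `sim_design(n = 1000)` gives a faster smoke
version of the accuracy study. Memory at the reference scale peaks
around 1 GB (the dosage matrix and the GRM).

## Known limitations

* Complete-case analysis only; there is no FIML over partially
  observed trait vectors.
* A single GRM: no partitioned heritability, no multiple variance
  components, no gene-environment interaction terms.
* AE models only — no shared-environment (C) or dominance (D)
  components, which are not identifiable from a single GRM in
  unrelated individuals anyway.
* The Wald and LRT references are asymptotic; for variance parameters
  near zero they are conservative/anticonservative in the usual ways,
  and the mixture reference is offered only as a sensitivity check.
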