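# gsemr — structural equation models of genetic variance in unrelated individuals

`gsemr` fits multivariate **AE variance-component structural equation
models** in which the additive-genetic side is anchored by a
genome-wide **genetic relationship matrix (GRM)** instead of twin
correlations. It is aimed at statistical geneticists and developmental
researchers who want to go beyond bivariate GREML and model *latent
genetic factor structures* — e.g. whether the genetic influences on a
trait measured repeatedly across childhood and adolescence reflect one
stable factor or several age-specific ones.

## The model

For `t` traits on `n` unrelated genotyped individuals,

```
vec(Y) ~ N( 0 ,  Σ_g ⊗ A  +  Σ_e ⊗ I_n )
```

where `A` is the GRM, `Σ_g` the SNP-tagged genetic covariance (its
diagonal is the SNP-h² for unit-variance traits) and `Σ_e` the
residual covariance. Both are structured as factor products
`Σ_g = Λ_a Λ_aᵀ`, `Σ_e = Λ_e Λ_eᵀ` with unit-variance latent factors,
and fitted by full-information maximum likelihood after rotating the
data into the GRM eigenbasis (which makes the likelihood separable
across individuals). Supported structures and free-parameter counts:

| structure | constructor | k | k at t = 4 |
|---|---|---|---|
| Cholesky (saturated) | `gsem_cholesky(t)` | t(t+1) | 20 |
| independent pathway | `gsem_independent_pathway(t)` | 4t | 16 |
| common pathway (relaxed) | `gsem_common_pathway(t)` | 3t+2 | 14 |
| arbitrary reduced patterns | `drop_loading()`, `gsem_custom()` | — | e.g. 17 |

Post-fit tooling: delta-method SEs for genetic variances, covariances
and correlations, two-sided Wald tests on loadings, likelihood-ratio
tests, AIC, BIC (participant-count convention), restandardized path
coefficients, and a stepwise procedure (`reduce_model()`) that prunes
non-significant genetic loadings under a cumulative LRT guard.

The surrounding workflow is covered end to end: GRM estimation from
0/1/2 dosages with pairwise-complete missing handling
(`compute_grm()`), greedy relatedness pruning at a cutoff such as
0.025 (`prune_related()`), GCTA binary GRM triples in and out
(`read_grm_gcta()`, `write_grm_gcta()`), covariate residualization and
rank-based inverse normal transformation (`prep_phenotypes()`), and a
genotype–phenotype simulator with a replicate accuracy harness
(`sim_design()`, `run_accuracy_study()`).

## Worked example

Simulate a bivariate standardized trait (SNP-h² of 0.25 and 0.47,
genetic correlation 0.5) in 1000 individuals, estimate the GRM from
all 1500 simulated SNPs, and fit the saturated bivariate model:

```r
library(gsemr)

design <- sim_design(n = 1000, m = 1500, m_causal = 300, seed = 42,
                     n_replicates = 1)
geno  <- simulate_genotypes(design)
pheno <- simulate_phenotypes_causal(geno, design)
eig   <- eigen_grm(compute_grm(geno))
rot   <- rotate_phenotypes(pheno, eig)

fit <- gsem_fit(gsem_cholesky(2), rotated = rot)
fit
#> AE model (Cholesky decomposition): 2 trait(s), k = 6 free parameters
#>   -2LL = 5489.524101, n = 1000 (2000 observations), converged
#>     estimate     se
#> a11   0.4228 0.0676
#> a21   0.3744 0.0980
#> a22   0.6043 0.0602
#> e11   0.8950 0.0345
#> e21   0.2157 0.0446
#> e22   0.7018 0.0336

genetic_correlations(fit)
#> Genetic variances/covariances (SE):
#>       P1    P2
#> P1 0.179 0.158
#> P2 0.158 0.505
#> Genetic correlations:
#>       P1    P2
#> P1 1.000 0.527
#> P2 0.527 1.000
```

The loadings `a11, a21, a22` are the genetic factor loadings (trait 1
on factor A1; trait 2 on A1 and A2), `e*` the residual ones. The
implied genetic variances 0.18 and 0.51 estimate the simulated
SNP-h² of 0.25 and 0.47, and the genetic correlation 0.53
(delta-method SE 0.125) estimates the simulated 0.5 — each within two
SEs at this deliberately small sample size. A univariate fit of the
first trait partitions its variance the same way:

```r
gsem_univariate(pheno[, c("FID", "IID", "P1")], eig)$vc
#>  component estimate     se p_wald
#>      Var_g   0.1782 0.0572 0.0018
#>      Var_e   0.8015 0.0618     NA
#>         h2   0.1819 0.0566     NA
```

A command-line interface with subcommands `make-grm`, `prep`, `fit`,
`simulate` and `benchmark` is installed at
`system.file("cli", "gsemr.R", package = "gsemr")`.

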