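# missdiag

Diagnosis of missing-data mechanisms and benchmarked imputation for
rectangular numeric data.

Missing values are commonly classified by the mechanism that produced them:
**MCAR** (missing completely at random — the probability of a cell being
missing depends on nothing), **MAR** (missing at random — it depends only on
observed values), and **MNAR** (missing not at random — it depends on the
unobserved value itself). The distinction decides which downstream analyses
and imputation strategies are trustworthy, so `missdiag` answers two
questions for biostatisticians and epidemiologists working with incomplete
tables: *which mechanism produced my missing values?* and *which imputation
method should I use?*

## What it computes

**Mechanism diagnosis.** The workflow starts with Little's MCAR test: an EM
algorithm estimates the mean vector μ and covariance matrix Σ of the data
under multivariate normality (handling the incomplete rows by their
missingness patterns), and the statistic

d² = Σⱼ mⱼ (ȳ₍obs,j₎ − μ̂₍obs,j₎)ᵀ Σ̂₍obs,j₎⁻¹ (ȳ₍obs,j₎ − μ̂₍obs,j₎)

sums, over the distinct missingness patterns j with mⱼ member rows, the
Mahalanobis deviations of each pattern's observed-variable means from the EM
estimates. Under MCAR, d² is asymptotically χ² with Σⱼ pⱼ − p degrees of
freedom. A Henze–Zirkler multivariate-normality check gates the test
advisorily (a warning, never a refusal). If MCAR is rejected, each incomplete
feature gets a MAR-versus-MNAR likelihood-ratio test: two nested logistic
regressions of the missingness indicator D (1 = observed) are compared —

- MAR model: logit P(D = 1) = β₀ + β₁ᵀ(other features)
- MNAR model: the same plus one regressor, the outcome Y if present,
  otherwise the feature itself with missing cells filled at its observed mean

and 2(l_MNAR − l_MAR) is referred to χ²(1). A significant result says
missingness depends on the feature's own value: MNAR.

**Imputation and benchmarking.** Simple (mean/median/mode), k-nearest
neighbour (nan-Euclidean distances), iterative round-robin regression with
pluggable learners (linear, lasso with cross-validation, random forest,
gradient boosting), and multiple imputation with Rubin pooling. Quality is
assessed by plausibility checks (range violations, distribution shift of
imputed versus observed values) and by `compare_methods()`, which hides a
random 10–20% of the observed cells, re-imputes, and ranks methods by RMSE on
the hidden cells plus a bias p-value.

Univariate normality tests (Shapiro–Wilk, Kolmogorov–Smirnov), missingness
pattern/percentage summaries, and seeded MCAR/MAR/MNAR data generators round
out the toolkit.

## Worked example

```r
library(missdiag)

# a benchmark dataset: 300 x 5 correlated Gaussian features, 15% MCAR
sim <- generate_synthetic(synthetic_spec("mcar", n = 300, p = 5,
                                         target_rate = 0.15,
                                         correlation = 0.8, seed = 7))

compare_methods(sim$data, list("mean", "knn", "iterative"),
                mask_fraction = 0.15, seed = 7)
#> compare_report: 188 cells masked (15.0% of observed), seed 7
#>  rank    method   rmse bias_p_value
#>     1 iterative 0.5339       0.9542
#>     2       knn 0.6024       0.1864
#>     3      mean 1.0672       0.5633
```

With strongly correlated features, regression-based imputation halves the
error of the column mean on the probe-masked cells; none of the methods shows
a systematic bias (all bias p-values above 0.05). Diagnosing a self-masked
(MNAR) dataset:

```r
fx <- table_fixtures(seed = 42)      # preset MCAR / MAR / MNAR benchmarks
combined_test(fx$mnar$data)
#> Little's MCAR test: chi2 = 3765.452, df = 3530, p = 0.002979 -> mcar_rejected
#> per-feature MAR/MNAR likelihood-ratio tests:
#>    feature lrt_stat         p     p_adj conclusion
#> 1       X1    8.281 0.0040052 0.0040052       mnar
#> ...
#> Little's MCAR test mcar rejected (p = 0.002979);
#> feature-wise LRTs: 0 MAR, 10 MNAR, 0 skipped.
```

Little's test rejects MCAR and every one of the ten self-masked features is
flagged MNAR.

A command-line wrapper covering the same functionality ships at
`inst/cli/missdiag` (subcommands `diagnose`, `impute`, `assess`, `compare`,
`simulate`).

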