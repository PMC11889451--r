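---
title: "Diagnosing missing-data mechanisms and choosing an imputer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnosing missing-data mechanisms and choosing an imputer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(missdiag)
```

## The problem

An incomplete numeric table can mislead every analysis run on it, and how
badly depends on *why* the cells are missing. Under MCAR (the missingness is
pure chance) complete-case analyses stay unbiased and almost any sensible
imputation works. Under MAR (missingness depends on observed values) the
relationships among observed variables can be exploited to impute without
bias. Under MNAR (missingness depends on the unobserved value itself) no
purely data-driven correction is guaranteed; the analyst needs to know they
are in this regime. `missdiag` implements a diagnosis workflow and an
imputation test-bench around that decision.

## Little's MCAR test and its EM engine

Rows are grouped by their missingness pattern (the binary signature of which
features are observed). Assuming the complete data are multivariate normal,
`em_fit()` finds the maximum-likelihood mean $\mu$ and covariance $\Sigma$
from the incomplete data: the E-step replaces each pattern's missing block
with its conditional expectation given the observed block (and adds the
conditional covariance to the second moments), the M-step re-estimates
$(\mu, \Sigma)$ from the completed sufficient statistics. The observed-data
log-likelihood is non-decreasing across iterations — the test-suite asserts
this on every fit — and iteration stops when its relative change drops below
`tol` (default `1e-6`) or at `max_iter` (default 200; non-convergence is
reported in a flag, never as an error). Initialisation is deterministic
(observed column means, diagonal of observed column variances), so repeated
fits agree. When an observed-block inverse fails, a ridge of
`1e-6 * trace(sigma)/p` is added once — only on failure, so the estimate is
untouched on well-conditioned data.

`little_mcar()` then computes
$$ d^2 = \sum_j m_j\,(\bar y_{\mathrm{obs},j} - \hat\mu_{\mathrm{obs},j})^\top
   \hat\Sigma_{\mathrm{obs},j}^{-1}\,(\bar y_{\mathrm{obs},j} -
   \hat\mu_{\mathrm{obs},j}), $$
which under MCAR is asymptotically $\chi^2$ with $\sum_j p_j - p$ degrees of
freedom ($p_j$ = observed variables in pattern $j$). Patterns with no
observed variables are excluded from both the statistic and the degrees of
freedom; `min_pattern_size` (default 1, the classic test) optionally drops
rare patterns. If the exclusions leave no degrees of freedom the verdict is
`indeterminate` rather than a number that means nothing.

Because the reference distribution leans on multivariate normality, a
Henze–Zirkler test runs first on the complete rows: a weighted $L^2$ distance
between the empirical characteristic function and the normal one, with the
standard sample-size-dependent smoothing parameter and a lognormal p-value
approximation. The gate is advisory — its failure (or inability to run, e.g.
fewer than $p+2$ complete rows) is recorded as a warning on the result and
the MCAR test still runs. It deliberately uses complete cases only, so the
gate never depends on the EM machinery it is gating.

## The MAR/MNAR likelihood-ratio test

When MCAR is rejected, `feature_lrt()` tests each incomplete feature. With
$D_i = 1$ when the feature is observed in row $i$, two nested logistic models
are fitted by maximum likelihood:

* MAR: $\operatorname{logit} P(D=1) = \beta_0 + \beta_1^\top Z$, where $Z$
  are all other features, their own missing cells mean-filled for the fit
  only (listwise deletion would drop exactly the rows where $D=0$);
* MNAR: the same model plus one regressor — the outcome $Y$ when the dataset
  has one, otherwise the feature itself with its missing cells filled at its
  observed column mean.

The statistic $2(l_{\mathrm{MNAR}} - l_{\mathrm{MAR}})$ is referred to
$\chi^2(1)$; significance means the missingness depends on the feature's own
value beyond what the other features explain.

Two numerical choices matter here. First, both fits carry the same tiny ridge
penalty ($\lambda = 10^{-4}$ on the slopes, intercept unpenalised) so that
perfect separation cannot blow up either fit and the two penalised
likelihoods remain exactly nested — the statistic is nonnegative by
construction, and a separation flag is recorded whenever fitted logits hit
the clamp. Second, the construction of the self-feature regressor is the one
genuinely open design point, and we chose a **mean-anchored fill** (missing
cells at the observed column mean) deliberately. A fill predicted by a
regression trained on the observed rows looks natural but makes the test
blind to self-masking: the trained model's residuals are mean-zero on the
observed class *by construction*, so the added regressor reduces to the MAR
predictors plus noise that carries no class information, and the LRT stays at
its null level no matter how strong the self-masking is. Anchoring the
missing rows at a constant instead preserves the selection signal: under
self-masking, the conditional location of the observed values given the
other features is shifted relative to that constant in a way the linear MAR
predictors cannot reproduce. Under MCAR the anchored regressor carries no
class information and the test is conservative (its rejection rate on MCAR
data sits below the nominal level — verified in the suite). When an outcome
$Y$ is present it takes precedence as the added regressor, and the clean
nested-model case then follows the $\chi^2(1)$ reference closely (the suite
checks the Kolmogorov distance of the null statistic's distribution).

Edge cases are verdicts, not errors: fully observed or fully missing
features, samples below 20 rows, and single-variable data without an outcome
are all returned as `skipped` with a reason. Per-feature p-values are
reported raw and Benjamini–Hochberg adjusted; conclusions use the raw values
at $\alpha$ (default 0.05) to keep the per-feature framing, with
`use_adjusted = TRUE` available. `combined_test()` wires the workflow: the
feature-wise tests run only when Little's test rejects, unless
`force_featurewise = TRUE`.

MNAR is not point-identifiable from observed data alone; any feature-wise
verdict rests on the multivariate-normal working model and the mean-anchored
construction above. The report therefore keeps the raw LRT components
alongside the conclusions so a sceptical reader can reconstruct either
reading.

## The imputer suite

* `impute_simple()`: column mean, median, or mode (ties to the smallest
  value).
* `impute_knn()`: nan-Euclidean row distances (squared distance over mutually
  observed coordinates, scaled by $p/\#\text{shared}$), $k$ donors (default
  5) that must have the target observed; uniform or inverse-distance weights;
  a cell with no eligible donor falls back to the column mean and is flagged.
* `impute_iterative()`: column-mean initialisation, then round-robin
  regression of each incomplete feature on all others, most complete feature
  first (order exposed as `visit_order`). Learners: linear least squares,
  cross-validated lasso (5 seeded folds), random forest, gradient boosting
  with squared-error loss. Stops when the largest change of any imputed cell
  falls below `tol` (default `1e-3`) times its column's standard deviation,
  or at `max_iter` (default 10). All learners are deterministic given `seed`.
* `impute_mice()`: $m \ge 2$ (default 5) independent stochastic round-robin
  runs — predictions perturbed by Gaussian noise at the learner's training
  residual standard deviation, each run on a sub-seed derived from the master
  seed — pooled by Rubin's rules (total variance $= W + (1+1/m)B$).

Observed cells are never altered by any method (asserted structurally in the
result constructor and property-tested on random masks).

## Quality assessment and the mask-and-score protocol

`assess_quality()` compares, per feature, the imputed cells against the
observed values: summary statistics, a count of fills outside the observed
range, and a two-sample Kolmogorov–Smirnov test of distribution shift (not
applicable below 3 imputed cells). `compare_methods()` hides a seeded random
10–20% of the *observed* cells (default 0.15, the band's midpoint; the band
is enforced, and pre-existing missing cells stay missing so every method
faces the original missingness plus the probe), runs every candidate method
on the identical masked dataset, and reports RMSE over the hidden cells plus
a two-sided paired t-test on the true-minus-imputed differences as a bias
p-value (a two-sample KS alternative is available via `bias_test = "ks"`).
Masking keeps at least 2 observed values per column. The t-test was chosen
because it detects systematic bias, the failure mode RMSE is blind to.

## Normality tests

`shapiro_wilk()` and `ks_normal()` wrap the standard implementations with
missing-value handling and guarded degenerate inputs (fewer than 3 observed
values, zero variance). The KS test standardises by the sample's own mean and
standard deviation by default, which makes the nominal p-value conservative —
the Lilliefors situation — and the result carries a `lilliefors_caveat` flag
instead of silently switching critical values; supplying known `mean` and
`sd` gives the exactly calibrated fixed-null test, which is also the variant
the calibration suite sizes. Shapiro–Wilk warns and truncates beyond
n = 5000 where its approximation degrades.

## The synthetic benchmarks

`generate_synthetic()` draws complete data from a multivariate normal with
unit variances and exchangeable correlation (default 0.3 — modest, realistic
dependence for clinical tables), then masks cells by mechanism: MCAR masks
each cell independently at the target rate; MAR masks non-driver features
with probability $\operatorname{logit}^{-1}(a + b^\top \text{drivers})$; MNAR
with probability $\operatorname{logit}^{-1}(a + c\,x_{ij})$. In both logistic
mechanisms the intercept $a$ is calibrated by bisection so the expected
overall missing fraction hits the target (for MAR the per-feature rate is
scaled up so the overall rate lands on target despite the drivers staying
complete). The ground truth of masked cells is always returned, so RMSE
scoring never regenerates data.

`table_fixtures()` declares the three preset scenarios the test-bench runs
on: MCAR (n = 500, p = 5, 10% missing), MAR (n = 500, p = 10, 30% overall,
two fully observed drivers with slopes 1.5), and MNAR (n = 2000, p = 10, 30%,
self coefficient 2). The MNAR preset's larger n is a deliberate choice:
Little's statistic gains its power against self-masking only through the
cross-feature correlation of pattern means, and ten features at a 30% rate
fragment 500 rows into hundreds of near-singleton patterns where that signal
drowns; at n = 2000 the test rejects the scenario reliably, which is the
behaviour the fixture exists to exhibit. These generators emulate correlated
Gaussian features with logistic missingness only — they do not produce skewed
or heavy-tailed marginals, outliers, mixed scales, or categorical codes, so
green tests on them certify the mechanics of the tests and imputers, not
their behaviour on arbitrary real data (where the normality gate earns its
keep).

## Problem sizes and calibration checks in the test-bench

The suite sizes its Monte-Carlo checks to be statistically meaningful yet
small: type-I error of the normality tests over 1000 replicates (Shapiro–Wilk
at n = 50, fixed-null KS at n = 200, Henze–Zirkler at n = 100, p = 3);
uniformity of Little's p-value under MCAR over 1000 replicates at n = 200,
p = 3 (the probability transform handles the pattern-dependent degrees of
freedom); the LRT's $\chi^2(1)$ null over 1000 replicates at n = 500 with an
irrelevant outcome as the added regressor; EM parameter recovery at n = 5000
bivariate with 20% MCAR; and 200 replicates of the MCAR benchmark scenario,
where Little's verdict and the normality gate are each required to pass at
least 90% of the time.

## Known limitations

* Every mechanism test assumes (approximate) multivariate normality; the gate
  warns but cannot fix real-data violations.
* Little's test addresses pattern means only (no covariance-homogeneity
  extension), has low power against self-masking at small n (see above), and
  its upper-tail form cannot flag the variance *shrinkage* strong
  self-masking induces.
* The feature-wise MNAR verdict is model-dependent — MNAR is untestable in
  general — and should be read as evidence, not proof.
* Imputers handle numeric columns only; categorical data must arrive as
  numeric codes and are treated as continuous.
* The KS normality p-value with estimated parameters is conservative by
  design (flagged, not corrected).
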