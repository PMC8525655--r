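---
title: "Doubly-robust additive risk estimation for continuous exposures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly-robust additive risk estimation for continuous exposures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drarisk)
```

## The estimand and the model

The package targets the *absolute* change in annual death probability per
unit of a continuous environmental exposure (µg/m³ for fine particulate
matter, ppb for nitrogen dioxide and warm-season ozone) in an open cohort of
older adults observed as person-years. Working on the additive scale has two
practical consequences: the coefficient is collapsible (it does not change
meaning with the covariate distribution), and it converts directly into
attributable deaths.

Confounding is controlled twice, and the estimator is consistent if either
control is correctly specified:

1. **Stabilized inverse-probability weights for a continuous exposure.**
   The generalized propensity score of exposure $x$ given covariates $v$ is
   a conditional density, and the stabilized weight is
   $SW = f(x)\,/\,f(x \mid v)$. Both densities are Gaussian: the numerator
   from an intercept-only linear regression of $x$ (mean = sample mean,
   sd = residual sd), the denominator from a linear regression of $x$ on the
   covariates with quadratic terms for every continuous confounder (cubic in
   the sensitivity specification). In the weighted pseudo-population the
   exposure is independent of the covariates, so weights alone would suffice
   under a correct exposure model.
2. **Covariate-adjusted weighted outcome model.** A linear probability
   model $\Pr(\text{death}=1) = \beta_0 + \beta x + s(v, \gamma)$ is fitted
   by weighted least squares, with cubic polynomial terms for copollutants,
   the two seasonal temperatures, age and median household income, linear
   terms for remaining continuous covariates, and reference-coded indicators
   for categorical ones. A correct outcome model alone would also suffice.

Because death is binary and the model linear, residuals are intrinsically
heteroscedastic; the reported variance is a heteroscedasticity-consistent
sandwich. HC1 (with its $n/(n-k)$ small-sample factor) is the default. A
person-clustered sandwich is available (`cluster = "person"`), since persons
contribute multiple annual rows; in the synthetic cohort annual deaths are
conditionally independent given covariates, so the two agree, but on real
data with unmodelled within-person dependence the clustered flavour is the
safer choice.

For tables too large to fit at once, persons are randomly partitioned into
$G$ groups (a person is never split), each group fitted separately, and
estimates pooled by fixed-effects inverse-variance meta-analysis:
$\hat\beta = \sum_i b_i/v_i \,/\, \sum_i 1/v_i$ with variance
$1/\sum_i 1/v_i$. $G = 1$ reduces exactly to the single fit. The source
analyses do not state their $G$ or the split unit; the package defaults to
$G = 10$ and person-level assignment, which keeps the clustered structure
intact within groups.

## Cohort restriction rules

The low-concentration design restricts to persons *always* exposed below a
regulatory cap (12 µg/m³ for PM2.5, 53 ppb for NO2, and a pragmatic 50 ppb
for O3, which has no long-term standard): one above-cap year excludes the
person's entire history, and comparison is `> cap`, so years exactly at the
cap stay. The lowest 3 percent of the post-cap exposure distribution is then
dropped (exposure-model predictions are least reliable where monitoring data
are scarce), and finally incomplete rows are removed (missingness is assumed
rare and at random; a warning fires above 10%).

Three conventions here were genuinely open and are fixed as follows:

- the percentile cut is applied *after* the cap and at the *record*
  (person-year) level; a person-level variant sits behind
  `percentile_level = "person"` for sensitivity;
- the percentile threshold uses R's default linear-interpolation quantile
  (type 7), and ties at the threshold are kept (strict `<` removal), so a
  degenerate constant exposure column removes nothing;
- applying the cap or the complete-case filter twice is a no-op; the
  percentile rule is *not* idempotent under re-application because the
  threshold is recomputed on the survivors — the pipeline therefore applies
  it exactly once, in the fixed order cap → percentile → missing.

## Weight handling

Raw weights are winsorized — clamped, not trimmed — at the 1st and 99th
percentiles of the weight distribution (type-7 quantiles, computed globally
before any splitting). Winsorization preserves the ordering of weights and
all rows. Under a correctly specified exposure model the raw weights average
approximately 1; the package errors on conditional densities below 1e-300
(positivity violations) and on degenerate (zero-residual) density fits.
Continuous covariates are standardized internally before polynomial
expansion; this spans the same column space and changes no estimate, but
keeps cubic designs well-conditioned.

## Reporting-scale summaries

- **Attributable cases** per year per unit exposure:
  $RD \times \text{person-years} / \text{study duration}$, evaluated exactly;
  CI endpoints are passed through the same formula. Non-positive risk
  differences return `NA`: a negative attributable count on a probability
  scale is not meaningful.
- **E-value**: the point estimate is converted to a risk ratio against the
  cohort's annual baseline risk and
  $E = rr + \sqrt{rr(rr-1)}$ (protective ratios are inverted first). The
  published analyses this design follows do not state their additive-to-
  multiplicative conversion and their printed E-values are not reproducible
  from printed numbers alone; the package therefore makes the choice
  explicit: baseline = deaths/person-years of the analysis dataset, unless
  `baseline_risk` is supplied.
- **Duration** defaults to the calendar-year span of the analysis table (17
  for 2000–2016).

## Balance diagnostics

Balance is the average absolute Pearson correlation between the exposure and
each continuous covariate, unweighted versus weighted (weighted moments
throughout). The winsorized weights — the weights actually used in fitting —
are used by default; `use_raw = TRUE` shows the untruncated picture, and a
second weight set (e.g. cubic versus quadratic propensity model) can be
reported side by side. Categorical covariates are excluded from this metric.

## Effect-measure modification

`stratified_fit()` reruns the entire weighted analysis within strata —
Medicaid eligibility, race, sex, age group (65–74, 75–84, 85+), and
quartiles of area-level income, population density or Hispanic percentage
cut over the person-year distribution of the analysis dataset. Weights are
refit within each stratum by default (stratum-specific confounding
structure); reusing globally fitted weights is available behind
`refit_weights = FALSE`. Differences between stratum coefficients use the
two-sample z-test $z = (b_a - b_b)/\sqrt{se_a^2 + se_b^2}$, valid because
strata contain disjoint persons. p-values are reported raw, without
multiplicity adjustment, matching the design this reproduces; treat a single
starred contrast among many accordingly.

## The synthetic cohort: what it emulates, and what it does not

`generate_cohort()` provides the ground truth that every statistical claim
in the test suite is checked against.

- **Structure**: an open cohort (default 2000–2016) with entry years uniform
  over the study window, one row per person-year, annual death draws, and
  administrative censoring at end of study; persons aged 65+ at entry,
  nested in (default 500) synthetic postal areas whose continuous covariates
  are drawn once per area.
- **Exposures**: multivariate Gaussian with means/SDs calibrated to
  published low-concentration US distributions (PM2.5 8.18 ± 1.85 µg/m³,
  NO2 19.8 ± 9.5 ppb, O3 41.94 ± 4.1 ppb — SDs back-solved from printed
  10th/90th percentiles) and pairwise correlations (0.45, 0.30, 0.20) inside
  the printed 0.11–0.59 range. Gaussian marginals are appropriate because
  the printed quantiles are near-symmetric (median ≈ mean). A 0.1-unit floor
  enforces positivity.
- **Confounding**: a scalar index $h$ loads on standardized near-Gaussian
  covariates (income −0.20, poverty 0.15, smoking 0.20, education 0.15, and
  0.10 on the standardized *square* of income). Exposures are built as
  $x_j = \mu_j + s_j h + e_j$ with the residual covariance chosen so the
  *marginal* means, SDs and correlations are exactly the configured ones
  whatever the loadings. Two deliberate consequences: (a) the Gaussian
  quadratic propensity model is *exactly* correct, while a linear-only one
  is genuinely misspecified (it misses the income² loading) — making the
  double-robustness tests meaningful rather than vacuous; (b) loadings sit
  on near-Gaussian covariates, not on the heavily skewed density column,
  which keeps true weights from having pathological tails.
- **Mortality**: $p = b_0 + \sum_j rd_j (x_j - \mu_j) + \sum_k \beta_k g_k$
  with standardized covariate terms (including the income² term), clipped to
  $[10^{-4}, 1-10^{-4}]$ (clipped fraction logged, warning above 1%). The
  stated baseline 0.039 is the cohort's annual mortality (deaths per
  person-year of the motivating population), so exposures and covariates
  enter centered: the intercept is reparameterized as
  $b_0 = \text{baseline} - \sum_j rd_j \mu_j$ and mean annual risk ≈
  baseline, while the exposure coefficients are exactly the configured risk
  differences (7.3e-4 for PM2.5, 3e-5 for NO2, 8.1e-4 for O3 — central
  estimates of the published main analysis). Because the model is linear in
  exposure, these equal the marginal causal risk differences up to clipping.
- **Not emulated**: geographic realism (no real postal codes, no spatial
  autocorrelation), exposure-model measurement error, within-person
  autocorrelation of exposure beyond the shared covariate index, loss to
  follow-up other than death, and comorbidities. A green test therefore
  establishes the statistical machinery under the stated data-generating
  process — not robustness to misspecifications the generator cannot
  produce.

## Numerical choices

- Quantiles everywhere (percentile drop, winsorization, quartile strata) use
  the linear-interpolation convention (`quantile(type = 7)`), frozen in
  tests.
- CI multipliers use `qnorm(0.975)`; normal, not t, given the sample sizes
  this design targets.
- Weighted least squares is solved by `lm.wfit` (QR); the sandwich bread is
  computed from the Cholesky factor of $X'WX$ after standardization of the
  design.
- Degenerate inputs error early and descriptively: zero-variance exposures,
  perfect (zero-residual) conditional fits, rank-deficient designs (the
  collinear columns are named), non-positive weights, empty restriction
  results.
- Determinism: a cohort is a byte-identical function of its configuration
  (including seed); pipeline stages draw their seeds from a single root seed
  recorded in the manifest.

## Known limitations

- The variance does not account for estimation of the weights (matching the
  reproduced design); the person-bootstrap comparison in the test suite
  conditions on the fitted weights.
- The linear probability model can fit probabilities outside [0, 1]; they
  are reported as-is, which is the cost of the additive-scale rationale.
- E-values use the point estimate only, and depend on the baseline-risk
  conversion discussed above.
- Quartile strata are defined over person-years of the analysis dataset;
  person-level quartiles would differ slightly.
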