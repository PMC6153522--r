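---
title: "Trend estimation for spatially balanced panel surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trend estimation for spatially balanced panel surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paneltrend)
```

## The problem

Long-term monitoring programs for discrete natural resources — the
motivating case is a population of 684 mountain lakes surveyed for water
chemistry — typically combine three layers of design complexity:

1. **Spatially balanced probability sampling** (GRTS-style), possibly
   stratified by elevation or with unequal inclusion probabilities driven by
   travel cost;
2. **Temporal revisit designs** in McDonald notation (`[1-0]` annual,
   `[1-3]` serially alternating, `[1-0,1-3]` augmented), which trade
   site-level replication against the number of unique sites;
3. **Model-based trend analysis**, which usually ignores both.

`paneltrend` implements three trend-analysis approaches for this setting,
together with a synthetic population generator and a Monte Carlo engine
that measures, for any design cell: relative bias of the trend slope, 90%
confidence-interval coverage, test size at \(\alpha = 0.10\), and power.

## The generating and analysis model

All responses live on the natural-log scale, so a trend of \(r\)% per year
is a slope of \(\gamma_1 = \log(1 + r/100)\). The core mixed model
(`fit_po()`) is

\[
y_{ij} = \gamma_0 + x_j\gamma_1 + b_j + a_i + x_j t_i + e_{ij},
\]

with \(b_j \sim N(0,\sigma_b^2)\) a year effect shared by all sites,
\((a_i, t_i)\) bivariate-normal site intercept/slope deviations with
variances \(\sigma_a^2, \sigma_t^2\) and covariance \(\sigma_{at}\), and
residual \(e_{ij} \sim N(0,\sigma_e^2)\). Estimation is REML (via
`lmerTest`), and the trend test refers \(\hat\gamma_1/se(\hat\gamma_1)\) to
a *t* distribution with Satterthwaite (Giesbrecht–Burns) degrees of
freedom. Under a stratified design a separate-slopes model adds fixed
stratum intercepts \(\delta_{h0}\) and slope deviations \(\delta_{h1}\);
the population-level slope is the stratum-size-weighted combination
\(\gamma_1^* = \gamma_1 + \sum_{h\ge2} N_h \delta_{h1}/N\), its standard
error is the contrast quadratic form on the fixed-effect covariance, and
its reference *t* has the **sum** of the stratum-level Satterthwaite df.

The two design-based alternatives regress annual status on year
(`fit_slrdb()`, `fit_wlrdb()`): status is the Horvitz–Thompson mean
\(\hat\mu_j = \sum y_{ij}/\pi_{ij} \big/ \sum 1/\pi_{ij}\) with the
local-neighborhood variance estimator for spatially balanced samples, and
the slope test uses \(n-2\) df. WLRDB weights each year by
\(1/\hat V_{NBH}(\hat\mu_j)\).

The probability-weighted route (`fit_pwigls()`) treats sites as stage-1
units and years within site as stage-2 units, absorbs the design weights by
the Step-A transformation \(z_{ij} \leftarrow w_i^{-1/2} z_{ij}\),
\(z_{0ij} \leftarrow w_{ij}^{-1/2} z_{0ij}\), and iterates GLS to
convergence. Fixed-effect standard errors come from the cluster-level
linearization (sandwich) estimator. Degrees of freedom for trend testing
are deliberately taken from the *unweighted* fit on the same records:
weighted variance components are inflated (they absorb the weight scale —
visible immediately with a constant stage-1 weight \(w\), which multiplies
\(\hat\Omega\) by \(w\)), and df derived from them would be too.

## What the synthetic generator emulates — and what it does not

`build_frame()` produces a finite population mirroring the lake frame:
684 sites with uniform planar coordinates, 598 high-elevation (≥ 3100 m)
and 86 low-elevation sites, and six travel-cost classes with population
shares 6/13/29/25/18/8% whose latent travel-time proxy correlates with
elevation at \(r \approx 0.72\). The printed stratum counts in the source
material (598 + 84) disagree with the frame total (684) by two sites; the
default resolves the inconsistency in favour of the frame total by using 86
low-elevation sites, which keeps the high-elevation share at 87.4% ≈ 88%.
Cost-class shares are normalized to sum to one (the printed percentages sum
to 99), and integer class counts come from largest-remainder rounding.

Two variance structures are built in. The high year-variance structure uses
\(\sigma_b^2 = 0.0157\) (log-ANC-like). Its low year-variance counterpart is
produced by `modify_variance_composition()`, which moves variance from the
year to the site component while conserving the total exactly: reducing
\(\sigma_b^2\) to 0.0001 transfers 0.0156 into \(\sigma_a^2\). The
remaining defaults — \(\sigma_a^2 = 0.5\), \(\sigma_t^2 = 5\times10^{-4}\),
\(\sigma_{at} = 0\), \(\sigma_e^2 = 0.1\), \(\gamma_0 = 4\) — are documented
stand-ins at realistic orders of magnitude for log-scale lake chemistry,
not estimates from any survey; results that depend on their exact values
(e.g., absolute power) should be read accordingly. The generator also omits
features of real data by design: no nonresponse, no detection-limit
censoring, no serial correlation beyond the shared year effect, and no GIS
cost surface (travel cost is a statistical emulation). Passing tests
therefore demonstrate the estimators' design properties under the stated
model, not robustness to those complications.

## Sampling and panel machinery

`grts_draw()` implements the spatially balanced draw as recursive-quadrant
hierarchical randomization: sites are addressed on a randomized 4-ary tree
over the unit square, a systematic \(\pi\)-sample with a uniform random
start is taken along the randomized address order, and the selections are
returned in reverse hierarchical order. This reproduces the two properties
the analysis relies on — each site enters with its intended inclusion
probability, and any contiguous prefix of the ordered list is itself
spatially balanced (checked against simple random sampling with a Voronoi
balance statistic). Unequal-probability designs hold \(\pi\) constant
within cost class (`n_c/N_c`, largest-remainder allocation); when the
rounded allocation would leave a positive-share class with no slots, one
slot is moved from the largest class so no site is unsampleable.

`parse_revisit_design()` supports `[1-0]`, `[1-b]`, and `[1-0,1-b]`. The
augmented design's annual panel is fixed at 10 sites; with 20 annual visits
it therefore needs 50 unique sites. Panels fill with contiguous blocks of
the draw order (annual panel first), so each panel is spatially balanced;
under stratification the blocks are taken within each stratum's own ordered
list (giving the 6-high/4-low annual panel at a 60/40 allocation) and
merged. Panel inclusion probabilities are 1 for annual panels and
\(1/\text{cycle}\) (0.25 for `[1-3]`) for alternating panels. The rotation
starts with panel 1 in year 1; this is configurable because the convention
is not dictated by the design notation.

## Numerical choices

* **Neighborhood variance.** Neighborhoods are the site plus its three
  nearest sampled neighbors (Euclidean, ties by site order); the pattern is
  symmetrized, weights start uniform and are iteratively proportionally
  scaled until rows and columns sum to one (the scaling ends on a row
  normalization, so a constant \(y/\pi\) yields exactly zero). The
  estimator's calibration is checked against the simple-random-sampling
  variance on spatially unstructured data (agreement within 10% on
  average). Within a year the status weights use \(\pi_i\) only: a panel is
  a complete spatially balanced subsample, so the constant panel factor
  cancels from the mean (the variance is not invariant to this choice,
  which is why it is exposed as `include_panel_pi`).
* **Mixed-model fitting.** REML via `lmerTest` with up to three optimizer
  restarts; singular (boundary) fits are accepted, genuine non-convergence
  is retried and reported. If the Satterthwaite information is singular the
  df fall back to \(n_\text{years} - 2\) with a warning. Heterogeneous
  stratum residual variance is available via a `glmmTMB` dispersion model;
  its df (and, at boundary fits, its standard error) are taken from the
  homoscedastic fit.
* **PWIGLS.** Iterated GLS with the variance update solved from the
  Fisher-scoring normal equations; \(\Omega\) is projected onto the
  positive-semidefinite cone each iteration and \(\sigma^2\) floored at
  \(10^{-10}\) — the same constraint surface as a log-Cholesky
  parameterization, but compatible with the closed-form quadratic update.
  Convergence is a relative parameter change below \(10^{-7}\). Optional
  weight scalings (`s1mean`, `s2mean`, `effn`) are provided; the default is
  unscaled Step-A-only weighting, which is the configuration whose results
  are reported. A "Step B" variance-component correction is deliberately
  not implemented.
* **WLRDB scale.** Weights are treated as known up to a constant and the
  residual scale is re-estimated on \(n-2\) df, matching the stated
  reference distribution; the alternative (weights as exact variances) was
  rejected because it changes the df convention.
* **Replicate seeding.** Each Monte Carlo replicate is seeded as a fixed
  integer mix of the scenario seed and replicate index (kept within 32-bit
  range), so any cell is bit-for-bit reproducible and independent of
  execution order.

## Monte Carlo conventions and problem sizes

A scenario cell simulates a fresh population per replicate, draws a sample,
allocates panels, and applies the requested estimators; failed fits are
excluded with the exclusion rate reported. Relative bias uses the
\((\hat\gamma_1-\gamma_1)/\gamma_1\) convention with a 5% threshold for
calling an estimator biased; when the generating slope is zero the engine
reports absolute bias instead. Test size is assessed only in no-trend
cells; power only where the matched null cell's size is at most 0.13
(roughly nominal at \(\alpha = 0.10\)); coverage is at the 90% level. When
a subpopulation trend \(\Delta\) applies to the high-elevation stratum, the
population-level truth is \(\gamma_1 + (N_\text{high}/N)\,\Delta\).

The shipped checks use two 500-replicate equiprobable `[1-0]` cells (12
years; 20 sites with the high year-variance structure for size and
coverage, 35 sites with the low year-variance structure for bias and
variance-component recovery). The bias cell uses the low year-variance
structure because the year effect is a mean-zero disturbance common to all
estimators: removing it isolates estimator bias in a 500-replicate mean
rather than enlarging its Monte Carlo error. Smaller replicate counts
(120–400) are used for purely comparative properties (e.g., weighted vs
unweighted bias under an informative design), where only an ordering is
asserted.

## A worked example

```{r example, eval = FALSE}
model <- population_model(gamma1 = log(1.02), years = 0:11)
frame <- build_frame(model = model, seed = 1)
responses <- simulate_response(frame, model, seed = 2)

design <- sample_design("equiprobable", n = 50)
pi_i <- inclusion_probabilities(frame, design)
draw <- grts_draw(frame, pi_i, seed = 3)

revisit <- parse_revisit_design("[1-0,1-3]", annual_n = 20, period_years = 12)
survey <- assemble_survey(responses, allocate_panels(draw, revisit), revisit)

fit_po(survey)
fit_slrdb(status_series(survey))
fit_pwigls(survey)
```

## Known limitations

* The PWIGLS stage-2 model treats the shared year effect as independent
  within-site noise; this misspecification is intrinsic to the two-stage
  formulation and is the reason its interval coverage degrades when
  year-to-year variance is large.
* Serial correlation beyond the year effect is not modeled; an AR(1) hook
  exists on the status regressions but is off by default and untuned.
* Only single-visit panel terms (`[1-b]`) are supported in the revisit
  grammar; multi-visit terms such as `[2-3]` are out of scope.
* Variance components from weighted fits are reported but should not be
  used for power planning; use the unweighted fit.
* Kenward–Roger df, pairwise-inclusion HT variance, and nonresponse or
  detection-limit adjustments are out of scope.
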