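---
title: "Methods: from transect counts to the habitat quality-quantity trade-off"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from transect counts to the habitat quality-quantity trade-off}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

pollscape estimates how many wild bees and hoverflies an agricultural
landscape supports, and asks a policy question: given a landscape with a
certain share of seminatural habitat (SNH — grassland, verges, hedgerows,
forest edge), is it more effective to *add* habitat or to *improve* the
flower availability of the habitat already there?  This vignette is the
package's own account of the method: the model, its assumptions, the
tunable parameters, what the synthetic data do and do not emulate, and the
numerical choices made where the design was open.

## The density model

The observational unit is a standardized transect: 150 m² of seminatural
habitat searched for 15 minutes, yielding a wild bee count, a hoverfly
count, the total flower cover (% of transect area, recorded no lower than
the 0.025% field floor) and the number of flowering species.  Counts are
treated purely as densities per area; the pipeline never rescales by time.

Transects are averaged to one analysis row per landscape × sampling round
(the cell).  Letting $y$ be the cell-mean density, the model for each
taxon is a Gaussian linear mixed model on a transformed scale:

$$
f(y_{lr}) = \beta_0 + \beta_1\,\mathrm{SNH}_l + \beta_2\,\log_{10}(\mathrm{cover}_{lr})
 + \beta_3\,\mathrm{rich}_{lr} + \beta_4\,\mathrm{MFC}_{lr}
 + \beta_5\,\mathrm{SNH}_l\!\cdot\!\mathrm{MFC}_{lr}
 + u_l + v_r + \varepsilon_{lr},
$$

with crossed random intercepts $u_l \sim N(0, \sigma^2_L)$ for landscape
and $v_r \sim N(0, \sigma^2_R)$ for round, and
$\varepsilon_{lr} \sim N(0, \sigma^2)$.  The response transform $f$ is
$\log_{10}$ for wild bees and $\log_{10}(y + 1)$ for hoverflies, whose
cell means contain genuine zeros.  MFC is an indicator for a
mass-flowering crop (e.g. faba bean, onion) blooming in the landscape
that round.  Fitting is by `lme4::lmer`; reported coefficients come from
REML fits, all likelihood-ratio tests (LRTs) from ML refits — standard
mixed-model practice where the two objectives disagree.

Model selection mirrors the field protocol the package encodes: the
SNH × MFC interaction is tested by LRT at $\alpha = 0.05$ and dropped when
non-significant (marginal cases such as $p = 0.06$ are dropped), so main
effects stay interpretable; the four main effects are *always* retained,
both because each has an a-priori rationale and because the landscape
extrapolation needs the SNH and quality terms present.  Variance
inflation factors of the fixed design are reported
($\mathrm{VIF}_j = 1/(1 - R^2_j)$); on data with this design they stay
well below 1.5.

## Landscape extrapolation

The fitted fixed effects are evaluated over a 15 × 20 prediction grid:
SNH cover at $0.35, 5, 10, \ldots, 70\%$ (the observed gradient in 5-point
steps, anchored at the observed minimum) crossed with 20 habitat-quality
levels Q1–Q20.  Quality levels are empirical 5%-quantiles of cell-mean
flower cover and of cell-mean richness, computed independently and paired
by rank, collapsing both quality proxies onto one "flower availability"
axis.  Predictions hold MFC at "no" and random effects at zero, are
back-transformed ($10^\eta$, or $10^\eta - 1$ clamped at zero for
hoverflies), divided by the 150 m² transect area, and scaled to the
landscape:

$$
P_{ij} = \frac{d_{ij}}{150}\;\times\;\frac{\mathrm{SNH}_i}{100}\,\pi\,750^2 .
$$

SNH thus enters twice — as a covariate (where retained) and as the
habitat-area multiplier — which is exactly the mechanism behind the
trade-off: quality improvements scale with the habitat already present,
while area additions do not.

## The trade-off and its thresholds

At each grid cell, the quality:quantity response ratio is the population
gain from $k$ quality steps divided by the gain from one 5-point SNH
step, $k \in \{1, 2, 3\}$; ratios of 2:1 and 3:1 proxy the greater
feasibility of managing existing habitat versus taking cropland out of
production.  The break-even threshold at a quality level is the smallest
SNH cover at which the ratio crosses 1 from below, located by
piecewise-linear interpolation between the 5-point grid columns (the
ratio is exactly linear in SNH for a quality-only model, so linear
interpolation is exact there; a monotone-spline alternative is
available).  Scenario queries invert the same arithmetic: the quality
increase equivalent to, say, raising SNH from 5% to 10% is the smallest
number of quality steps whose gain at 5% SNH meets the gain of the
quantity move, evaluated at the median quality level Q10.

## The synthetic-data generator

Because the analysis is exercised without the deposited field data, the
generator reproduces the study conditions: 26 landscapes of 750 m radius
with SNH uniform on 0.35–70% (the first landscape pinned to the low
anchor), 8 rounds, a discretised-normal number of transects per cell
(mean 2.8, SD 0.8, at least 1), per-transect flower cover lognormal with
geometric mean 2.0% and arithmetic mean 4.6% (floored at 0.025%),
richness a rounded normal with mean 12.8 and SD 5.8 (clamped at 0), and
an independent Bernoulli(0.4) crop-bloom flag per cell.

The latent density process lives at the cell — the level the model is
fitted at: the linear predictor is evaluated at the cell-mean covariates
and receives the landscape, round and residual noise terms there;
transects within a cell share the latent density and contribute counts by
rounding it to integers (a Poisson observation option exists for
robustness studies).  This makes the generator match the fitted model's
assumptions exactly, so parameter recovery is a clean test of the whole
chain rather than of an aggregation approximation.  Default standard
deviations (landscape 0.15, round 0.10, residual 0.25, all on the log10
scale) give realistic between-cell variation (residual CV roughly 60% on
the density scale).

No per-taxon coefficient magnitudes are published, so the defaults are
illustrative: bees respond only to flower cover
($\beta_2 = 0.4$ per log10 %), hoverflies to cover (0.35), richness
(0.015 per species), SNH (0.004 per %) and crop bloom (0.23, i.e. about
+70% density when blooming), with intercepts placed so a season totals
thousands of individuals.  Features of real data the generator does *not*
emulate: crop phenology (bloom is independent across cells), spatial
autocorrelation between landscapes, within-season trends beyond the round
intercept, and within-cell density heterogeneity between transects.
Passing recovery tests therefore demonstrate that the estimation
machinery is correct under the model's own assumptions, not that the
model is correct for any particular field system.

## Numerical choices and open design points

* **Aggregation order.** "Average, then transform": the flower-cover
  covariate is $\log_{10}$ of the cell-mean cover, and cell rows (not
  transect rows) are the default unit — the random-effects structure
  (landscape and round only, no transect term) implies one row per cell.
  Both alternatives (`cover_covariate = "mean_of_log"`,
  `aggregate_observations(level = "transect")`) are exposed as switches.
* **Quantile convention.** Quality levels use upper-anchored
  probabilities $0.05, \ldots, 1.00$, so Q20 is the observed maximum;
  lower-anchored and midpoint conventions are available.
* **Woody vs herbaceous transects** are pooled unweighted in cell means
  and carry no model term; the class is kept for descriptive reporting.
* **Degenerate inputs.** LRT statistics are clamped at zero against
  optimizer noise; the hoverfly back-transform is clamped at zero
  density; a positive cover below 0.025% is rejected (or floored under
  `strict = FALSE`); perfect fixed-design collinearity errors with the
  term named, and perfectly collinear VIFs report `Inf`.
* **Convergence honesty.** A fit is flagged non-converged whenever the
  optimiser or lme4's checks complain (singular-fit notes excepted, and
  excepting exact-fit data where the scaled-gradient check is undefined);
  recovery experiments exclude and count such fits rather than hide them.
* **Zero-variance limit.** `fit_lmm(..., zero_random = TRUE)` profiles
  the likelihood at zero random-intercept variances, where the LMM
  provably coincides with ordinary least squares — kept as a verification
  surface.

## Problem sizes

The shipped tests and the acceptance script run entirely on generated
data: single studies of 26 × 8 cells (~590 transects), recovery
experiments of 200 replicates, and a 200-replicate null-interaction
calibration of the LRT (rejection rate checked against the 0.02–0.10
band around the nominal 0.05).  These sizes give Monte-Carlo standard
errors comfortably below the asserted tolerances.

## Known limitations

The extrapolation reports point surfaces only; no uncertainty is
propagated to populations, ratios or thresholds.  Predictions at the
grid's low-SNH anchor sit at the edge of the covariate range (the code
warns on genuine extrapolation).  The quality axis treats cover and
richness as rank-paired, not jointly modelled, and quantile-based quality
steps inherit the spacing of the observed cover distribution: with
heavy-tailed (lognormal-like) cover, per-step density gains — and hence
break-even thresholds — can vary substantially between adjacent quality
levels, especially near the maximum-anchored top level.  Honeybees are
out of scope, as are species-level analyses and any within-landscape
spatial structure: SNH enters as a single scalar proportion.
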