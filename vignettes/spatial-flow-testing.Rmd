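---
title: "Spatial goodness-of-fit testing for origin-destination flow models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial goodness-of-fit testing for origin-destination flow models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flowgof)
```

## The problem

Regression models of bilateral flows — migration between countries being the
motivating case — are conventionally judged by explanatory power: pseudo-R²,
squared correlations, significance of drivers. None of these says whether the
*spatial organisation* of the system the model implies resembles the observed
one: whether flows concentrate in the same few corridors, and whether movers
are matched by counter-movers in the opposite direction. `flowgof` implements
a four-step procedure that treats those spatial patterns as the outcome to be
reproduced:

1. **Estimate** a Poisson pseudo-maximum-likelihood (PPML) regression of
   dyadic flows with origin, destination and year fixed effects
   (`fit_ppml()`).
2. **Simulate** ensembles of complete synthetic flow systems from the fitted
   model, propagating regression uncertainty (`simulate_ensemble()`).
3. **Summarise** every system — observed and simulated — with spatial
   concentration and reciprocity indices (`index_series()`).
4. **Evaluate** whether the observed system is reproducible by the model:
   envelope coverage of the indices, Mahalanobis distances for per-location
   inflow/outflow profiles, and corridor-level checks (`evaluate_flows()`).

## Step 1: the flow regression

The mean model is multiplicative,

$$E[y_{ijt}] = \exp(\alpha_i + \gamma_j + \delta_t + \beta^\top x_{ijt}),$$

estimated by Poisson pseudo-maximum likelihood. PPML is the standard
estimator for dyadic flow data: it keeps zero flows in the sample, is
consistent under correct mean specification whatever the conditional
distribution, and is robust to heteroskedasticity. Fixed effects are encoded
as explicit dummies and solved by iteratively reweighted least squares
(tolerance $10^{-8}$ on the relative deviance change, at most 100
iterations); at the scales this package targets (tens of locations, tens of
years, a few thousand dyad-year records) dense weighted least squares is
fast and exact, so no demeaning/absorption machinery is used.

Standard errors are multiway cluster-robust. For cluster dimensions
$\{d_1, \dots, d_m\}$ (typically origin, destination and year) the
covariance combines one-way cluster sandwiches over every non-empty subset
with inclusion–exclusion signs. Two numerical choices matter:

* **Finite-sample correction.** Each subset's meat is scaled by the
  conventional $G/(G-1)\cdot(n-1)/(n-k)$ factor (HC1-type $n/(n-k)$ when no
  clustering is requested). This is the default of the major
  implementations and measurably improves interval coverage in the
  package's own calibration study.
* **PSD repair.** The inclusion–exclusion combination is not guaranteed
  positive semi-definite; negative eigenvalues are truncated at zero with a
  warning (the raw matrix is available via `psd_repair = FALSE`).

Fit statistics follow the conventions of the PPML literature: the squared
linear correlation between observed and fitted flows; McFadden's adjusted
pseudo-R², $1 - (\ell - k)/\ell_0$, against the intercept-only model; and a
*within* version that uses the fixed-effects-only model as the null and
penalises only the extra parameters — the package's reading of the
fixed-effects-software convention, since no standard definition exists. The
RESET specification test augments the model with the squared fitted linear
predictor (cubes optional) and tests the augmentation with the clustered
covariance; its size is nominal in the package's simulations once mean
flows are of realistic magnitude (tens or more), while small counts make it
conservative-to-liberal in the usual small-sample ways.

Coefficients translate to interpretive percentages through
`effect_size()`: binary predictors use the exact multiplicative form
$100(e^\beta - 1)$; log-transformed predictors use the linear elasticity
approximation $\beta \cdot \Delta\%$. Both conventions are exposed
explicitly because prose in the applied literature mixes them.

## Step 2: ensemble simulation

Each dyad-year receives a fitted flow $\hat y_{ijt}$ and a confidence
interval on the response scale, built on the link scale and exponentiated,
$\exp(\hat\eta \pm z\,\mathrm{se}(\hat\eta))$ — this guarantees positive
bounds, and includes fixed-effect estimation uncertainty since
$\mathrm{se}(\hat\eta)$ uses the full clustered coefficient covariance. A
per-dyad standard deviation is recovered from the interval width,
$\sigma = (\text{upper} - \text{lower})/(2z)$, and simulated flows are drawn
independently per dyad and year from a truncated normal
$\mathcal{TN}(\hat y, \sigma^2; a, b)$.

Numerical choices:

* **Truncation bounds.** $a = 0$ (flows cannot be negative) and
  $b = +\infty$ by default. Any finite upper bound would be an invention;
  both are configurable per run.
* **Sampling.** Inverse-CDF sampling, not rejection: deterministic given
  the seed and efficient even when $\hat y/\sigma$ is far below the lower
  bound. $\sigma = 0$ returns the clamped mean; if the interval probability
  underflows to zero the draw is clamped to the nearest bound.
* **Reproducibility.** One root seed; a per-(year, draw) substream seed is
  derived arithmetically, so ensembles are bit-reproducible and
  order-independent.
* **Row calibration** (optional, on by default): each origin row of a
  simulated matrix is rescaled multiplicatively so its sum matches the
  origin's observed outflow total that year. Scaling preserves within-row
  proportions and the zero pattern — no unobserved corridor can appear —
  and makes every draw's total volume equal the observed system's.

Draws are independent across years; no temporal autocorrelation is imposed.

## Step 3: spatial indices

For a flow matrix $M$ with $n$ locations and structurally zero diagonal
(diagonal cells never enter any sum):

* **ACV** — each origin's coefficient of variation of outflows (variance
  divisor $n-1$ over the $n-1$ off-diagonal cells, i.e. the population
  variance of those outflows), weighted by the origin's share of total
  flow. Unbounded, most sensitive to one or two dominant corridors.
  Origins with zero outflow contribute zero (their weight is zero anyway).
* **Gini** — all ordered pairs of corridor flows compared,
  $\sum |m_{ij} - m_{kl}|$, normalised by $(2n(n-1)-1)\sum m_{ij}$. This
  denominator follows the form used in the migration literature the
  package mirrors; the textbook mean-absolute-difference normalisation
  ($2N \sum m$, $N = n(n-1)$) is available via `normalisation = "pairs"`.
  The vectorised implementation uses the sorted-vector identity and is
  tested to $10^{-12}$ against a brute-force double loop.
* **Migration inequality** — total absolute deviation from the uniform
  system ($m' = \sum m / N$ in every corridor) over twice the total flow:
  0 for uniform, approaching $1 - 1/N$ when one corridor carries
  everything.
* **Reciprocity** — corridor pairs reduced to a single value (minimum by
  default; maximum and geometric mean available) and summed over ordered
  pairs, divided by total flow. The minimum form is the share of movers
  matched by a counter-mover: 0.7 means 70% of movers travel in corridors
  with balancing counter-flows. The geometric mean of a one-way corridor
  contributes zero (its limit); note the maximum form exceeds one by
  construction and is provided only for completeness of the family.

## Step 4: evaluation

**Envelopes.** Observed index values are compared with the full range of
the simulated values per index and year (the ribbon convention of the
motivating literature); quantile envelopes, e.g. 2.5%–97.5%, are available
and are what the package's own calibration study uses, because the full
range of an ever-growing ensemble covers everything eventually.

**Mahalanobis distances.** For a location's inflow (or outflow) profile —
the $(n-1)$-vector of flows from every other location — the package
computes $D^2 = (x-\mu)^\top \Sigma^{-1} (x-\mu)$ against the ensemble mean
and covariance. With a finite ensemble and near-collinear corridors
$\Sigma$ can be ill-conditioned, so it is shrunk linearly toward its
diagonal, $\Sigma^* = (1-\lambda)\Sigma + \lambda\,\mathrm{diag}(\Sigma)$,
with $\lambda$ chosen by the analytic correlation-shrinkage rule (ratio of
the summed sampling variances of the off-diagonal correlations to their
summed squares, clamped to $[0,1]$) unless overridden; a Moore–Penrose
pseudo-inverse is the last resort, with a warning. $\lambda = 1$ reduces
$D^2$ to a sum of squared componentwise z-scores; $\lambda = 0$ is the
raw affine-invariant form. Distances are reported per location and year
and never aggregated, so deterioration over time is visible.

**Corridor checks** compare one directed corridor's observed flow with its
simulated envelope per year.

## The synthetic generator

All calibration and power studies run on panels from a known-truth
generator, so no external data is needed. Flows are drawn as
$y_{ijt} \sim \text{Poisson}(\exp(c + \alpha_i + \gamma_j + \delta_t +
\beta^\top x_{ijt}))$ with three dyadic covariates emulating the structure
of gravity-type migration regressions: log distance between uniformly
placed planar points (symmetric, spatially correlated), a symmetric binary
tie (contiguity / shared-language-like, stated prevalence), and a signed
log-ratio of per-location AR(1) size series (population-ratio-like,
time-varying, antisymmetric). A Poisson generator — rather than the
truncated normal of Step 2 — is deliberate: the estimation contract is the
Poisson pseudo-likelihood, so known-truth coefficient recovery requires a
Poisson design; the truncated-normal machinery is exercised downstream on
fitted values.

Default scale is 15 locations × 5 years with mean corridor flows in the
tens: small enough that the full test suite (200-replication recovery and
coverage studies, 500-replication RESET size study, 200-replication
envelope calibration) runs in about a minute, large enough that asymptotic
approximations hold. A 31 × 20 profile mirroring a continental panel is a
one-line change.

**Reciprocal-exchange regime.** To reproduce the headline misfit pattern —
models matching concentration while under-predicting reciprocity —
`generate_reciprocity_regime()` adds a symmetric dyad-level random
component on the *mean* scale: a circular-exchange flow
$b \cdot \ell_p \cdot \sqrt{\lambda_{ij}\lambda_{ji}}$ shared by both
directions of each pair, with lognormal pair-year level $\ell_p$ of unit
mean. The additive-on-the-mean form is essential and was chosen after
exploring alternatives: a shared *multiplicative* (log-scale) pair effect
rescales both directions equally, leaves every pair's min/total ratio
unchanged, and only reweights pairs randomly — it does not raise expected
reciprocity at all. An additive balanced component, by contrast, lifts the
weaker direction of every touched pair (circular and return migration do
exactly this in real systems), so system reciprocity increases strictly
with the boost while marginal covariate effects are untouched in
expectation. Because the component is proportional to the pair's geometric
mean baseline, the cross-pair size distribution — hence concentration — is
nearly preserved, and a log-linear surface cannot represent the resulting
saturating pair asymmetry $\log(e^{\xi/2} + b)$: the fitted model
over-predicts imbalance, and its simulated ensembles under-predict
reciprocity, which is precisely the misfit signature the evaluation step
is designed to expose.

The integration study that demonstrates this uses 12 locations, 2 years,
intercept 8.5 (mean corridor flows in the thousands, so relative sampling
noise is small, as in continental migration systems), strong
origin/destination heterogeneity (fixed-effect standard deviations 0.9),
boost 1.5 and level noise 0.05 — conditions chosen so the baseline model is
well inside the envelopes and only the omitted circular component pushes
reciprocity out.

## What the synthetic studies do and do not show

Passing calibration on generated panels shows the machinery is correct:
coefficients are recovered without bias, intervals and envelopes attain
their nominal coverage when the data truly come from the fitted model, and
the evaluation step flags a known omitted mechanism. It does not show that
any particular empirical system is well described by a gravity-type model;
real flow data add measurement error, harmonisation artefacts, temporal
dependence and shocks that the generator deliberately omits. The
generator's flows are single Poisson realisations, not posterior estimates
with their own uncertainty ribbons.

## Known limitations

* Dyad-year draws are independent; systems with strong temporal
  persistence in shocks will show envelope misfit that is a property of
  the simulation design, not necessarily of the drivers.
* The Mahalanobis distances are descriptive; no reference distribution or
  p-value is attached (ensemble-based calibration of $D^2$ is possible but
  out of scope).
* The multiway clustered covariance relies on asymptotics in the number of
  clusters per dimension; with very few clusters its PSD repair activates
  frequently and intervals should be read cautiously.
* Row calibration assumes observed outflow totals are trustworthy; with
  noisy margins it transfers that noise into every draw.
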