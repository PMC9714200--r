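---
title: "Spatiotemporal mapping of county mortality: model, sampler and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal mapping of county mortality: model, sampler and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's account of its science: the model and its
assumptions, the knobs that matter, what the synthetic generator does and
does not emulate, the numerical choices inside the sampler, and known
limitations.

## 1. The problem and the model

A county-year death count `Y_it` from a mortality registry is a noisy
realisation of an underlying risk. With expected counts `E_it` from
indirect standardization (population times reference age-sex rates), the
ratio `Y_it / E_it` is the raw SMR — unbiased but, for small counties,
dominated by Poisson noise. The model borrows strength across space and
time:

\[
Y_{it} \sim \mathrm{Poisson}(E_{it}\,\theta_{it}), \qquad
\log\theta_{it} = \alpha + s_i + u_i + b_0 t + v_t + b_{1i} t +
\varepsilon_{it} \;[+ X_i\beta].
\]

Assumptions worth stating explicitly:

* **Conditional Poisson variation.** All extra-Poisson dispersion must be
  absorbed by the random effects; `eps_it` is there precisely to catch
  cell-level overdispersion (a Type-I space-time interaction —
  exchangeable, not structured).
* **BYM spatial decomposition.** `s` follows the *intrinsic* CAR prior on
  the contiguity graph: the prior density penalises squared differences
  across shared boundaries (`w_ij = 1` iff counties share a boundary) and
  is improper with rank `n - c` (`c` = connected components), so each
  component of `s` is constrained to sum to zero. `u` is i.i.d. Gaussian.
  Only the sum `s_i + u_i` is strongly identified; the classification
  therefore uses the sum.
* **Trend decomposition.** `b0` is the average annual log-risk change;
  `v_t` (exchangeable by default, optional first-order random walk via
  `v_model = "rw1"`) captures nonlinearity; `b1_i` are CAR-correlated local
  slope departures, also centered.
* **Time coding.** `t = year - mid-period year`, so `alpha` is the
  mid-period national log-risk and is a priori decorrelated from `b0`.
* **Covariates are county-level and time-fixed.** The ecological
  regression explains the *spatial* pattern; yearly covariate tables
  should be averaged per county first. Coefficients exponentiate to
  relative risks per covariate unit, and covariate columns are only
  mean-centered internally, so the reported `beta` is per the unit you
  supplied (GDP in 10,000 yuan/person, NTL per intensity unit, and so on).

## 2. Priors and their defaults

| parameter | prior | default |
|---|---|---|
| `alpha`, `b0` | uniform | bounds ±50 |
| `beta` | Gaussian | sd 10 |
| precisions of `s, u, v, b1, eps` | gamma on the precision | shape 0.5, rate 5e-4 |
| alternative | half-Gaussian on the sd | scale 1 (`variance_prior = "halfnormal"`) |

The gamma-precision prior is the default because it admits conjugate Gibbs
updates (rank-aware for the CAR terms: shape gains `(n-c)/2`, not `n/2`);
the half-Gaussian-sd alternative is available and handled by a log-scale
Metropolis step with the appropriate Jacobian. At the default data scales
the two give practically indistinguishable fits; the choice is exposed
because weakly informative sd priors behave better when the number of areas
is very small.

## 3. The sampler

`fit_hbstm()` runs an adaptive Metropolis-within-Gibbs sweep:

1. **`alpha` — exact Gibbs.** With a flat prior, the full conditional of
   `exp(alpha)` is `Gamma(sum Y, sum E e^{eta - alpha})`; this is also what
   makes the single-cell model agree exactly with its conjugate closed
   form.
2. **`b0`, `beta` — scalar random-walk Metropolis.**
3. **`s`, `b1` — coloured single-site Metropolis.** A greedy proper
   colouring of the county graph partitions counties into classes with no
   internal edges; within a class the CAR full conditionals are mutually
   independent, so all sites in a class are proposed and accepted in one
   vectorised step.
4. **`u`, `v`, `eps` — vectorised single-site Metropolis** (their full
   conditionals are independent given the rest).
5. **Precisions — conjugate gamma Gibbs** (or log-scale MH under the
   half-Gaussian prior).
6. **Re-centering.** `s`, `v`, `b1` are re-centered to sum to zero each
   sweep with their means absorbed into `alpha` and `b0`; the linear
   predictor is unchanged, so this is a deterministic reparameterisation,
   not a Monte Carlo move.

Two families of *likelihood-invariant* moves are layered on top, and they
are what makes the sampler practical:

* **Shift/swap moves.** `alpha` trades against the free means of `u` and
  `eps`; `b0` against the linear-in-`t` components of `eps` and `v`;
  each `beta_k` against the projections of `eps`, `u` and `s` onto its
  centered covariate; and `s_i` against `u_i` county-wise (coloured).
  Each move changes only Gaussian/CAR prior terms, so acceptance is cheap
  and step sizes can be large. The `beta`–`s` swap matters most: a
  spatially smooth covariate and the CAR field form a classic
  spatial-confounding ridge along which naive samplers stall.
* **Amplitude rescalings.** `s` and `u` are multiplied by `exp(z)` with the
  rank-aware Jacobian (`(n-c) log r` on the centered CAR subspace). The
  structured/unstructured variance split is the slowest direction of the
  BYM posterior; this block cycles three times per sweep with fresh
  precision draws.

Proposal scales adapt by Robbins-Monro toward 44% acceptance during burn-in
and are frozen afterwards, keeping the post-burn-in chain a valid
fixed-kernel Markov chain. Split-R̂ (each chain halved) and Geyer
initial-positive-sequence effective sample sizes are attached for every
scalar parameter. Default lengths (3,500 iterations, 1,000 burn-in, thin 2)
give R̂ ≤ ~1.02 on all scalars for the default 100-county, 15-year problem;
the acceptance experiments use shorter chains where only coverage or sign
probabilities are needed.

Numerical details: the Poisson log-likelihood is evaluated in the
constant-free form `Y*eta - E*exp(eta)` inside acceptance ratios and with
the continuous extension `y log mu - mu - lgamma(y+1)` when full densities
are needed (under-reporting-adjusted counts are non-integer); `E_it <= 0`
cells are rejected at input; a disconnected graph is handled per component
(CAR draws, rank terms, precision updates) with a warning.

## 4. The synthetic generator

`simulate_panel()` draws a complete study from the model's own generative
process: a rook-adjacency lattice (default 10 × 10 counties — large enough
for genuine spatial structure, small enough that a full fit takes seconds),
15 annual time points, two sexes by five age bands with multiplicative
age-sex reference rates, county populations uniform on [20,000, 200,000],
`alpha = 0`, `b0 = -0.012` (≈ −1.2%/yr, the magnitude of national
cardiovascular-mortality declines), `sd_s = 0.3`, `sd_u = 0.1`,
`sd_v = 0.02`, `sd_b1 = 0.01`, `sd_eps = 0.05`. Region labels (eastern /
central / western) come from column tertiles and an urban flag alternates
by row, giving six spatially coherent under-reporting strata whose URR
declines from 12–30% to a 2% floor over the study years. Covariates follow
a west-to-east socioeconomic gradient with substantial county-level noise;
GDP and NTL are correlated (~0.7) but deliberately not collinear, and each
covariate's non-smooth component is what keeps its effect separable from
the CAR field.

Because every age-sex stratum of a county scales by the same `theta_it`,
the county ASMR is `theta_it` times the reference ASMR — this identity is
how `asmr_draws()` pushes posterior risk draws onto the ASMR scale, and it
is exact *within the generator*. Real registries violate it whenever age
groups trend differently.

What the generator does **not** emulate: real county geographies and
boundary changes, age-specific risk trends, migration, cause-of-death
miscoding and garbage-code redistribution, covariate measurement error, and
informative missingness. Passing tests therefore demonstrate that the
estimator recovers the model's own data-generating process — the right
first question for any Bayesian pipeline — not that the model is correct
for any particular registry.

Non-CVD deaths are simulated as independent Poisson counts around their
expectation with no spatial structure; they exist so that all-cause rates
and the completeness filters can be exercised, and carry no signal.

## 5. Preprocessing choices

* **Under-reporting.** Adjusted deaths are `reported / (1 - URR)` by
  stratum-year. URR schedules observed only through an early year are
  extended by a least-squares natural cubic spline on year (knots at
  observed-year quartiles, straight line below six observations, carried
  forward with a warning below four), clamped to [0, 0.95] so the
  adjustment factor stays bounded. Extrapolation is per-stratum.
* **Completeness filters.** A county is excluded when its crude adjusted
  all-cause rate falls below 4.5‰ (before 2013) / 5‰ (2013 on) for
  surveillance-system counties, or 3‰ in any year for others, in at least
  `min_failing_years` years (default 1 — a single bad year is treated as
  disqualifying; raise it to tolerate isolated dips). The crude rate is
  used because the thresholds are stated on that scale.
* **AAPC.** Computed from the log-linear regression over all years, which
  uses the whole series and is robust to single-year noise; the endpoint
  formula is available as `method = "endpoint"` and agrees exactly on
  geometric series.
* **Administrative-code churn** is reduced to a user-applied id mapping
  before analysis; the package keys everything by opaque county ids in the
  graph's node order.

## 6. Classification and summaries

Exceedance probabilities are plain draw fractions (`P(s_i + u_i > 0)`,
`P(b1_i > 0)`). Thresholds 0.8/0.2 define hot/cold/warm spots and the
local-trend categories; a probability exactly at a threshold falls to the
middle category, since strict inequalities on both sides leave equality
unassigned. `p_trend` is computed from the same joint posterior for all
counties — the stage-1 label conditions the *reading* of stage 2, not a
refit. `cross_tabulate()` reports self-consistent row percentages from its
own cell counts; when a published table's stated row totals disagree with
its cells, they can be supplied as denominators and the discrepancy is
flagged rather than silently reproduced.

## 7. Ecological regression

The covariate model is refit per region subset (the CAR prior restricted to
the induced subgraph) rather than interacted, mirroring how region-specific
effects are usually tabulated. Missing covariates are completed by chained
regressions with predictive-mean matching (donor pool of 5, five sweeps,
`m = 5` tables by default); downstream fits run per completion and pool the
coefficient draws, so pooled intervals carry between-imputation variance.
Intervals are posterior credible intervals and are labelled as such.

## 8. Problem sizes used by the tests

The suite exercises: 100 random small instances (≤ 20 cells) against a
brute-force likelihood loop; a 20,000-draw single-cell fit against its
conjugate closed form; 100 replicate reduced-length fits (1,200 iterations)
of the default 10 × 10 × 15 covariate study for interval coverage plus one
default-length two-chain fit for convergence; 100 replicate planted-hot-spot
studies (20 planted counties at `s+u = 0.7` among 80, six years) for
classification sensitivity and specificity; and 1,000-replicate
thinning/adjustment round trips. These sizes were chosen so the full
recovery experiments still run in minutes while leaving the conclusions
statistically sharp.

## 9. Known limitations

* Only the intrinsic CAR is implemented (no proper/Leroux variants, no
  spatially varying coefficients); `eps` is exchangeable (no structured
  space-time interaction).
* Sex-stratified analyses are separate runs on sex-subset panels; there is
  no shared-parameter joint model.
* The sampler stores `eps` draws, so memory grows with
  `draws × counties × years`; at thousands of counties either thin more or
  shorten chains.
* Exceedance probabilities are reported without multiplicity adjustment,
  matching standard disease-mapping practice; interpret county-level
  labels accordingly.
* With internal (panel-pooled) reference rates, `sum(E) = sum(Y)` by
  construction: the intercept then measures risk relative to the panel
  average. Recovery of an absolute baseline requires external reference
  rates, which is why the recovery experiments pass the generator's true
  expected counts.
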