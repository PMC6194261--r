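---
title: "Open-population N-mixture models for lek counts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Open-population N-mixture models for lek counts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`lekdyn` estimates abundance, apparent survival and recruitment of a lekking
bird population from repeated flush counts of unmarked individuals. Counts
`y[i,t,j]` at lek `i`, year `t`, visit `j` are binomial draws from a latent
abundance `N[i,t]` with detection probability `p[i,t,j]`:

- **Initial abundance**: `N[i,1]` follows a Poisson, zero-inflated Poisson
  (ZIP) or negative-binomial distribution with mean `lambda[i]`
  (log link). The ZIP adds a point mass `psi` at zero (logit link); the
  negative binomial has dispersion `alpha` (log link), variance
  `lambda + lambda^2 / alpha`.
- **Dynamics**: between years, survivors are
  `S[i,t] ~ Binomial(N[i,t-1], omega[i,t])` (logit link) and recruits are
  `G[i,t] ~ Poisson(gamma[i,t])` under *constant* dynamics or
  `Poisson(gamma[i,t] * N[i,t-1])` under *autoregressive* (per-capita)
  dynamics; `N[i,t] = S[i,t] + G[i,t]`.
- **Detection**: `y[i,t,j] ~ Binomial(N[i,t], p[i,t,j])` (logit link), with
  daily rainfall, daily maximum temperature and effort (number of visits
  that season) as candidate covariates.

Leks are assumed independent, with no spatial coupling and no temporary
emigration; apparent survival confounds death with emigration and
recruitment confounds birth with immigration, as is inherent to
unmarked-individual counts. Counts are of all birds flushed from the lek,
with no sex adjustment.

The marginal likelihood of a lek's count history is computed by a forward
recursion over the latent states `0..K`. The transition kernel row for
previous abundance `a` is the convolution of a Binomial(`a`, `omega`)
survivor count with a Poisson recruit count; state `K` absorbs all
truncated upper-tail mass so every row sums to exactly one.

## Numerical choices

- **Truncation bound `K`**: maximum observed count + 20 by default. A
  sensitivity check (refitting at `K + 10`) is part of the test suite; with
  the default bound, the change in the optimized log-likelihood is below
  `1e-6` on simulated data, including boom years with heavy upper tails.
- **Scaled filter**: initial and detection mass functions are evaluated in
  log space and max-shifted; the filter itself runs in rescaled probability
  space with a log accumulator (the standard scaled HMM filter), which is
  algebraically identical to a log-space recursion but avoids a
  log-sum-exp per state pair. Binomial and Poisson pmfs inside the kernel
  are built by stable recurrences (Pascal-type for the binomial, ratio
  recurrence for the Poisson, with a fallback to `dpois` when `exp(-rate)`
  underflows). The mass absorbed by state `K` is assembled from an
  accurately anchored Poisson upper tail, never as one minus a row sum —
  the subtraction cancels catastrophically when the tail is small and
  injects noise into the likelihood surface that finite-difference
  gradients then amplify.
- **Optimizer**: BFGS from a deterministic moment-based start plus two
  seeded jittered restarts (three starts in total), relative tolerance
  `1e-8`. The `converged` flag requires optimizer success, a
  positive-definite numerically differentiated Hessian, and a
  finite-difference gradient norm below `1e-3 * (1 + |nll|)`; a tighter raw
  gradient tolerance is not meaningful with finite-difference gradients.
  During covariate scans, candidate models are warm-started from the null
  model's optimum (the null is itself multi-started); a warm-started
  candidate uses a single start.
- **Standardization**: every covariate is z-scored over the cells that
  enter the design (sites for initial abundance, site-by-transition cells
  for demographics, visits for detection); the constants are stored on the
  fit so `predict_effect()` accepts grids on the original scale.
  Demographic slopes are therefore per-SD effects. A covariate that is
  constant after standardization is dropped with a warning, never silently
  zeroed. Missing covariate cells are imputed at the mean (0 after
  z-scoring) and counted on the fit.
- **Degenerate fits**: when the Hessian is not positive definite, standard
  errors and intervals are reported as `NA` and the fit is flagged;
  CI-based screens treat such models as non-informative. All-zero count
  data drive `lambda` to the boundary; the fit carries a `boundary` flag.

## The staged model-building workflow

The workflow mirrors common practice for these models and is exposed step
by step:

1. `step1_distribution()` compares intercept-only null models under the
   three count families by AIC; ties break toward fewer parameters, so a
   Poisson wins an exact tie with either mixture.
2. `step2_screen_detection()` fits the global detection model (rain,
   temperature, effort) once and keeps covariates whose Wald 95% CI
   excludes zero. The screen is single-pass — there is no drop-and-refit
   iteration — and an interval exactly touching zero counts as overlapping.
3. `step3_initial_abundance()` uses each lek's maximum count in the first
   season as a candidate predictor of initial abundance for the remaining
   years (the modeled series therefore starts one season later), with the
   same CI rule. Leks without a first-season count are imputed at the
   covariate mean and flagged.
4. `step4_demographic_scan()` fits one candidate covariate at a time on
   recruitment (autoregressive dynamics) or survival (constant dynamics).
   The annual menu is five weather variables (precipitation, mean and
   minimum drought index, maximum temperature, hot days) in the same year
   and with a one-year lag — 10 covariates, hence 20 models across the two
   processes; the seasonal menu adds seasonal precipitation and drought
   index for the same year and summer/fall lags only, on the premise that
   weather more than about nine months old no longer acts on the
   population.

Ranking uses AIC by default with AICc available (`rank_by = "aicc"`); both
are always reported. Akaike weights are emitted over the full candidate set
and within each demographic process, because either scope can be the
quantity of interest when processes are compared. Ties break by fewer
parameters, then covariate name; non-converged candidates are flagged,
given zero weight and ranked last.

`grazing_scan()` applies the same template to grazing pressure (cow
days/ha = cattle x days / pasture area, area-weighted over the pastures a
lek spans), with the data split into predrought and during/postdrought
periods. A year whose grazing record is entirely missing is dropped from
the leading edge of a period or, in the interior, has its counts marked
missing, so unrecorded years never contribute count information to the
grazing assessment while the dynamics remain connected.

## Abundance series and the drought contrast

`posterior_abundance()` runs a forward–backward smoother at the ML
estimates, giving each lek-year the empirical-Bayes posterior of `N` given
the lek's full history (smoothing, not filtering, because the series is a
retrospective estimate). Site summaries are the posterior mean and central
95% interval; annual summaries are the cross-site mean (default) and
total, with seeded parametric-bootstrap intervals (coefficients drawn from
their asymptotic normal, series re-derived; 500 draws by default in the
workflow commands).

`anova_pre_post()` is a one-way fixed-effects ANOVA on the annual values
with the split at the first drought year, df = (1, T - 2);
`fold_change()` is the ratio of period means with an optional bootstrap
interval. Whether the response is the cross-site mean or the total, and
whether the drought year itself is grouped with the "post" period, are
exposed as arguments because either convention is defensible; the defaults
are the cross-site mean and drought-year-in-post (split at 2011 gives
df = (1, 10) for a 2004–2015 series).

## The synthetic-data generator

`simulate_lek_counts()` draws data from exactly the process the model
assumes, on the study's design: 49 leks, 12 years (2004–2015), 1–5 visits
per lek-season, with the packaged year-level weather record (annual
precipitation, mean and minimum modified Palmer drought index, maximum
temperature, hot days; 2011 is the severe-drought year, with 84 hot days
against at most 59 in any other year). Monthly series consistent with the
annual record (July–August precipitation peak) supply the seasonal
covariates, and pasture-level grazing records give cow days/ha on the
observed scale (about 2.0 declining to 0.2), with the 2004 and 2012
recording gaps reproduced as missing, never zero.

The default generating truth is the drought-collapse scenario:
`lambda = 13` and `p = 0.6` (expected first-year count ~7.8 birds per
visit, matching the observed count scale), survival 0.65 at average
covariates responding to the drought index (+0.5 per SD) and hot days
(−0.4 per SD), and per-capita recruitment 0.20 collapsing with hot days
(−1.0 per SD, the magnitude of the dominant fitted effect on this system).
Under the packaged weather record the expected trajectory declines from
~13 to ~1.5 birds per lek, a seven-fold contrast between the 2004–2010 and
2011–2015 period means — the headline boom–bust pattern. These values were
fixed once from the deterministic expected trajectory before any estimation
runs.

Fixture-mode weather reproduces the packaged record exactly by default.
Gaussian jitter is available (`weather_jitter`, as a fraction of each
covariate's interannual SD) but defaults to zero: the record is treated as
an observed series, and its documented drought structure (the hot-day
spike exceeding 1.4x the second-largest value) is a property the scenario
is meant to preserve, which any default noise would randomly destroy.
"Free" mode draws annual covariates independently around the record's
moments while keeping the hot-day drought profile, giving genuinely
uninformative competitor covariates for selection-power experiments.

What the generator does *not* emulate: spatial correlation between leks,
observer effects, within-season phenology of lek attendance, double
counting, and weather measured with error. Passing recovery tests
therefore demonstrate correctness of the estimator under its own
assumptions — not robustness to these real-data features.

## Problem sizes used by the tests

Unit tests run on small designs (up to ~50 sites or 8 years) plus
brute-force enumeration oracles on tiny instances (3 sites, 3 years,
latent grid 0..8). The statistical acceptance checks use the study design
itself — 49 leks, 12 years, 1–5 visits — with 20–25 seeded replicates per
property: parameter recovery (median relative error and Wald coverage),
selection power over the 20-model annual scan, grazing-contrast recovery
using the published predrought coefficients (0.54 logit-scale on survival,
0.19 log-scale on recruitment, applied per SD of cow days/ha) as
generating truths, a zero-effect grazing null at demographic equilibrium,
and the full drought pipeline (fit, smooth, ANOVA, fold change). The
pipeline check fits the generating model structure directly; the scan's
ability to find that structure is established by the selection-power
check, so the two properties are tested independently rather than nested.

## Known limitations

- Likelihood evaluation is `O(M T K^2)` plus `O(K^3)` per distinct
  (survival, recruitment) pair; designs whose counts reach several hundred
  per lek will be slow and may need a manually chosen `K`.
- Wald intervals can be poor near boundaries (detection near 1, survival
  near 0/1); profile or bootstrap intervals are not implemented for
  coefficients.
- The ZIP zero-inflation and negative-binomial dispersion are shared
  across leks (no covariates on `psi` or `alpha`).
- Model averaging of predictions is deliberately out of scope; the
  workflow fits one demographic covariate at a time, as the candidate-set
  design assumes.
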