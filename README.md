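# lekdyn

Open-population N-mixture models for repeated counts of unmarked animals at
fixed survey sites — written for lek counts of prairie grouse, where the
question is how abundance, apparent survival and recruitment respond to
drought, temperature extremes and grazing management.

Counts `y[i,t,j]` at lek `i`, year `t`, visit `j` are binomial observations
of a latent abundance `N[i,t]` with detection probability `p[i,t,j]`.
Abundance starts from a Poisson, zero-inflated Poisson or negative-binomial
distribution with mean `λ` and evolves as

    N[i,t] = S[i,t] + G[i,t],
    S[i,t] ~ Binomial(N[i,t-1], ω[i,t])          (apparent survival, logit link)
    G[i,t] ~ Poisson(γ[i,t])                     (constant dynamics, log link)
             or Poisson(γ[i,t] · N[i,t-1])       (autoregressive dynamics)

The marginal likelihood is evaluated by a truncated forward recursion over
the latent states and maximized by quasi-Newton search with Wald inference
(the heavy recursions are in C++). Around the estimator the package provides:

- a staged AIC model-building workflow: count-distribution choice,
  detection-covariate screening, a prior-year-count predictor of initial
  abundance, and single-covariate scans of weather (annual + seasonal, with
  one-year lags) on recruitment or survival, plus a pre/post-drought grazing
  scan (`step1_distribution()` … `step4_demographic_scan()`,
  `weather_scan()`, `grazing_scan()`, `four_step_selection()`);
- empirical-Bayes abundance series by forward–backward smoothing, a one-way
  ANOVA contrast of pre- vs post-drought abundance and the fold change
  between period means (`posterior_abundance()`, `anova_pre_post()`,
  `fold_change()`);
- a seeded synthetic generator emulating a 49-lek, 12-year survey with 1–5
  visits per season, the packaged 2004–2015 weather record (severe drought
  in 2011) and pasture-level grazing records (`scenario_config()`,
  `simulate_lek_counts()`);
- plain-CSV/JSON workflow commands (`run_simulate()`, `run_fit()`,
  `run_select()`, `run_estimate()`) and a thin CLI at `inst/cli/lekdyn.R`.

## Worked example

Simulate the default drought-collapse scenario and fit the model whose
recruitment responds to hot days (days above the long-run 90th-percentile
temperature) and whose survival responds to the drought index:

```r
library(lekdyn)

sim <- simulate_lek_counts(scenario_config(seed = 1))
fit <- fit_nmix(sim$data, sim$covs,
                nmix_spec("poisson", "autoregressive",
                          gamma_covariates = "hot_days",
                          omega_covariates = "pmdi_avg"))
fit
#> Open N-mixture fit: poisson / autoregressive dynamics
#>                estimate     se     lcl     ucl
#> lambda_int       2.6407 0.0498  2.5432  2.7383
#> gamma_int       -0.9225 0.1331 -1.1834 -0.6616
#> gamma_hot_days  -0.7488 0.0723 -0.8905 -0.6071
#> omega_int       -0.4126 0.2153 -0.8346  0.0095
#> omega_pmdi_avg   0.4818 0.0921  0.3012  0.6624
#> p_int            0.3648 0.0684  0.2308  0.4988
#> nll = 3237.1644, AIC = 6486.33, AICc = 6486.38, converged: TRUE
```

Coefficients are on the link scale with covariates z-scored: recruitment
drops by a factor `exp(-0.75) ≈ 0.47` per SD of hot days (the generating
truth is −1.0 per SD on a model that also carries a hot-days survival
effect), survival rises with the drought index, and back-transformed
detection is `plogis(0.365) ≈ 0.59` against a true 0.6. Mean initial
abundance `exp(2.64) ≈ 14` birds per lek matches the generating `λ = 13`.

The abundance series and drought contrast:

```r
series <- posterior_abundance(fit, split_year = 2011)
anova_pre_post(series, 2011)   # F on df (1, 10)
fold_change(series, 2011)$ratio
```

On this seed the pipeline gives F(1,10) = 79.6, p = 4.5e-06 and a 7.3-fold
pre/post decline against a true fold of 7.3 — the simulated population
collapses at the 2011 drought and fails to rebound, the boom–bust signature
the survey design is meant to detect.

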