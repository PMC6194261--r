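# Akaike weights, candidate menus, ranking rules, and the staged screens.

test_that("akaike weights follow the closed form", {
  expect_equal(akaike_weights(c(100, 100)), c(0.5, 0.5))
  expect_equal(akaike_weights(c(100, 102)),
               c(1, exp(-1)) / (1 + exp(-1)), tolerance = 1e-12)
  expect_equal(akaike_weights(150), 1)
  expect_error(akaike_weights(numeric(0)), "empty")
  expect_error(akaike_weights(c(1, Inf)), "finite")
})

test_that("the weather menu matches the stated candidate counts", {
  annual <- weather_candidates(seasonal = FALSE)
  expect_equal(nrow(annual), 10)                  # 5 variables x 2 periods
  expect_equal(sum(annual$period == "year before"), 5)
  full <- weather_candidates()
  expect_equal(nrow(full), 22)                    # + 8 seasonal + 4 lagged
  # no winter or breeding-season lags
  expect_false(any(grepl("(winter|breeding)_lag1", full$covariate)))
})

test_that("ranking is deterministic with documented tie-breaks", {
  tab <- data.frame(process = "recruitment",
                    covariate = c("b", "a", "c"),
                    period = "same year",
                    n_params = c(6, 5, 5),
                    aic = c(100, 100, 100), aicc = c(100, 100, 100),
                    beta = 0, se = 0, lcl = 0, ucl = 0,
                    converged = c(TRUE, TRUE, FALSE))
  out <- lekdyn:::finish_candidate_table(tab, "aic", list())
  # ties: fewer parameters first, then name; non-converged last, weight 0
  expect_equal(out$covariate, c("a", "b", "c"))
  expect_equal(out$weight[3], 0)
  expect_equal(sum(out$weight), 1, tolerance = 1e-9)
})

test_that("step 1 selects the generating family", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 30, n_years = 6, lambda = 6, p0 = 0.6,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 31))
  s1 <- suppressWarnings(step1_distribution(sim$data, sim$covs, starts = 1))
  expect_equal(s1$family, "poisson")
  expect_true(all(diff(s1$table$delta) >= 0))
  expect_equal(sum(s1$table$weight), 1, tolerance = 1e-9)

  simz <- simulate_lek_counts(scenario_config(
    n_sites = 40, n_years = 6, family = "zip", psi = 0.4, lambda = 8,
    p0 = 0.6, gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 32))
  s1z <- suppressWarnings(step1_distribution(simz$data, simz$covs, starts = 1))
  expect_equal(s1z$family, "zip")
})

test_that("step 2 retains the active detection covariate and drops the rest", {
  hits <- 0
  for (s in 1:5) {
    sim <- simulate_lek_counts(scenario_config(
      n_sites = 49, n_years = 6, lambda = 8, p0 = 0.6, p_tmax = -0.8,
      gamma_covariates = c(), omega_covariates = c(),
      drought_year = 2004, seed = 40 + s))
    s2 <- step2_screen_detection(sim$data, sim$covs, "poisson", starts = 1)
    if (identical(s2$retained, "tmax")) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("step 3 keeps a real prior-count signal and drops a degenerate one", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 49, n_years = 8, lambda = 10, p0 = 0.7,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 55))
  # under stable dynamics the first-season counts index lambda directly
  s3 <- step3_initial_abundance(sim$data, sim$covs, "poisson", starts = 1)
  expect_true(s3$retained)
  expect_equal(length(s3$data$years), 7)
  expect_equal(s3$data$years[1], 2005)

  # constant prior counts are degenerate after z-scoring
  df <- expand.grid(lek_id = paste0("L", 1:8), year = 2004:2007, visit = 1)
  df$count <- ifelse(df$year == 2004, 5, rpois(nrow(df), 4))
  cd <- lek_count_data(df)
  expect_warning(s3c <- step3_initial_abundance(cd, NULL, "poisson", starts = 1),
                 "constant")
  expect_false(s3c$retained)
})

test_that("single-candidate scans have weight one and report the slope", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 25, n_years = 6, lambda = 6, p0 = 0.6,
    gamma_covariates = c(hot_days = -0.8), omega_covariates = c(),
    drought_year = 2004, seed = 61))
  tab <- step4_demographic_scan(sim$data, sim$covs,
                                nmix_spec("poisson", "constant"),
                                "recruitment", candidates = "hot_days",
                                starts = 1)
  expect_equal(nrow(tab), 1)
  expect_equal(tab$weight, 1)
  expect_equal(tab$delta, 0)
  expect_lt(tab$beta, 0)
})

test_that("grazing scan enforces period structure and missing-record rules", {
  sim <- simulate_lek_counts(scenario_config(seed = 71))
  expect_error(grazing_scan(sim$data, sim$covs, split_year = 2015), "fewer than 3")
  covs_na <- sim$covs
  covs_na$site_year$cow_days[, as.character(2011:2015)] <- NA
  expect_error(grazing_scan(sim$data, covs_na, split_year = 2011),
               "entirely missing in the postdrought")
  covs_none <- sim$covs
  covs_none$site_year$cow_days <- NULL
  expect_error(grazing_scan(sim$data, covs_none), "cow_days")
})
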