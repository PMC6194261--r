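# Empirical-Bayes smoothing, the pre/post ANOVA, and the fold change.

test_that("the ANOVA matches an independent sums-of-squares oracle", {
  g1 <- c(10, 12, 14); g2 <- c(2, 2, 3)
  df <- data.frame(year = 2004:2009, value = c(g1, g2))
  got <- anova_pre_post(df, split_year = 2007)
  want <- oracle_anova(g1, g2)
  expect_equal(got$F, want$F, tolerance = 1e-10)
  expect_equal(got$p, want$p, tolerance = 1e-10)
  expect_equal(c(got$df1, got$df2), c(1, 4))

  # identical groups: no between-group variance
  flat <- data.frame(year = 2004:2009, value = rep(5, 6))
  expect_equal(anova_pre_post(flat, 2007)$F, 0)

  # 12 years split after year 7 gives the (1, 10) structure
  set.seed(1)
  twelve <- data.frame(year = 2004:2015, value = rnorm(12, 10))
  got12 <- anova_pre_post(twelve, split_year = 2011)
  expect_equal(c(got12$df1, got12$df2), c(1, 10))
  expect_equal(got12$F, oracle_anova(twelve$value[1:7], twelve$value[8:12])$F,
               tolerance = 1e-10)

  expect_error(anova_pre_post(twelve, split_year = 2005), "at least 2 years")

  # property: random splits agree with the oracle to 1e-10
  for (s in 1:10) {
    set.seed(100 + s)
    v <- rnorm(10, 5, 2)
    dfr <- data.frame(year = 2001:2010, value = v)
    cut <- sample(3:8, 1)
    expect_equal(anova_pre_post(dfr, 2001 + cut)$F,
                 oracle_anova(v[seq_len(cut)], v[-seq_len(cut)])$F,
                 tolerance = 1e-10)
  }
})

test_that("fold change handles constant and degenerate series", {
  flat <- data.frame(year = 2004:2015, value = rep(4, 12))
  expect_equal(fold_change(flat, 2011)$ratio, 1)
  dead <- data.frame(year = 2004:2015, value = c(rep(4, 7), rep(0, 5)))
  expect_warning(fc <- fold_change(dead, 2011), "infinite")
  expect_true(fc$infinite)
  expect_equal(fc$ratio, Inf)
})

test_that("perfect detection pins the EB posterior to the observed count", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 8, n_years = 5, lambda = 6, p0 = 0.6,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 80))
  spec <- nmix_spec("poisson", "autoregressive")
  prep <- lekdyn:::prepare_nmix(sim$data, sim$covs, spec)
  theta <- lekdyn:::default_start(prep)
  theta[["p_int"]] <- 40                          # detection ~ 1
  post <- lekdyn:::eb_posterior_cube(prep, theta)
  site <- lekdyn:::cube_site_summary(post, prep)
  obs <- apply(sim$data$y, c(1, 2), max, na.rm = TRUE)
  for (i in 1:4) for (t in 1:5) {
    r <- site$site == sim$data$sites[i] & site$year == sim$data$years[t]
    expect_equal(site$mean[r], obs[i, t], tolerance = 1e-6)
    expect_equal(site$lo95[r], site$hi95[r])
  }
})

test_that("an unsurveyed site-year has a wider posterior than its neighbors", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 30, n_years = 6, lambda = 8, p0 = 0.6,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 81))
  masked <- lekdyn:::mask_years(sim$data, 2006)
  masked$y[1, , ] <- sim$data$y[1, , ]            # keep one site complete
  fit <- fit_nmix(masked, sim$covs, nmix_spec("poisson", "autoregressive"),
                  starts = 1)
  series <- posterior_abundance(fit)
  width <- function(site, year) {
    r <- series$site$site == site & series$site$year == year
    series$site$hi95[r] - series$site$lo95[r]
  }
  wider <- vapply(masked$sites[2:20], function(s)
    width(s, 2006) >= max(width(s, 2005), width(s, 2007)), TRUE)
  expect_gte(mean(wider), 0.9)
})

test_that("EB smoothing beats raw maximum counts when detection is imperfect", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 49, n_years = 8, lambda = 8, p0 = 0.55,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2004, seed = 82))
  fit <- fit_nmix(sim$data, sim$covs, nmix_spec("poisson", "autoregressive"))
  series <- posterior_abundance(fit)
  truth <- as.vector(sim$truth$N)           # site varies fastest within year
  ord <- order(match(series$site$year, sim$data$years),
               match(series$site$site, sim$data$sites))
  eb <- series$site$mean[ord]
  rawmax <- as.vector(suppressWarnings(
    apply(sim$data$y, c(1, 2), max, na.rm = TRUE)))
  rawmax[!is.finite(rawmax)] <- NA
  ok <- !is.na(rawmax)
  expect_lt(mean(abs(eb[ok] - truth[ok])), mean(abs(rawmax[ok] - truth[ok])))
})

test_that("bootstrap intervals are ordered and cover the point estimate", {
  sim <- simulate_lek_counts(scenario_config(
    n_sites = 20, n_years = 6, lambda = 8, p0 = 0.6,
    gamma_covariates = c(), omega_covariates = c(),
    drought_year = 2006, seed = 83))
  fit <- fit_nmix(sim$data, sim$covs, nmix_spec("poisson", "autoregressive"),
                  starts = 1)
  series <- posterior_abundance(fit, B = 30, seed = 2, split_year = 2006)
  expect_true(all(series$year$lo95 <= series$year$hi95))
  expect_true(all(c("predrought", "postdrought") %in% series$year$period))
  fc <- fold_change(series, 2006, fit = fit, B = 30, seed = 2)
  expect_true(fc$ci[1] <= fc$ci[2])
  expect_error(posterior_abundance(structure(list(converged = FALSE),
                                             class = "nmix_fit")),
               "converge")
})
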