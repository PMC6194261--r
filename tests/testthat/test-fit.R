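# Packed-parameter contract, objective structure, and the ML fitter.

small_sim <- function(seed = 3, M = 15, T = 5) {
  simulate_lek_counts(scenario_config(
    n_sites = M, n_years = T, first_year = 2004,
    lambda = 6, p0 = 0.6, omega0 = 0.65, gamma0 = 0.3,
    gamma_covariates = c(), omega_covariates = c(),
    dynamics = "autoregressive", drought_year = 2004, seed = seed))
}

test_that("pack/unpack is a bijection over all families", {
  sim <- small_sim()
  for (fam in c("poisson", "zip", "negbin")) {
    spec <- nmix_spec(fam, "autoregressive", gamma_covariates = "hot_days",
                      p_covariates = c("rain", "effort"))
    prep <- lekdyn:::prepare_nmix(sim$data, sim$covs, spec)
    set.seed(1)
    theta <- setNames(rnorm(length(prep$par_names)), prep$par_names)
    roundtrip <- lekdyn:::pack_params(lekdyn:::unpack_params(theta, prep), prep)
    expect_equal(roundtrip, theta, tolerance = 1e-12)
  }
})

test_that("objective is the sum of site log-likelihoods", {
  sim <- small_sim(seed = 9, M = 1, T = 4)
  spec <- nmix_spec("poisson", "autoregressive")
  prep <- lekdyn:::prepare_nmix(sim$data, sim$covs, spec)
  nll <- lekdyn:::nll_factory(prep)
  theta <- lekdyn:::default_start(prep)
  y <- sim$data$y[1, , ]
  single <- site_loglik(y, "poisson",
                        lambda = exp(theta[["lambda_int"]]),
                        omega = rep(plogis(theta[["omega_int"]]), 3),
                        gamma = rep(exp(theta[["gamma_int"]]), 3),
                        dynamics = "autoregressive",
                        p = plogis(theta[["p_int"]]), K = prep$K)
  expect_equal(nll(theta), -single, tolerance = 1e-8)

  # duplicating the site doubles the nll (independence across sites)
  y2 <- sim$data$y[c(1, 1), , , drop = FALSE]
  data2 <- lekdyn:::new_lek_count_data(y2, sim$data$rain[c(1, 1), , , drop = FALSE],
                                       sim$data$tmax[c(1, 1), , , drop = FALSE],
                                       c("A", "B"), sim$data$years)
  prep2 <- lekdyn:::prepare_nmix(data2, sim$covs, spec)
  nll2 <- lekdyn:::nll_factory(prep2)
  expect_equal(nll2(theta), 2 * nll(theta), tolerance = 1e-8)

  # exp(-nll) is a probability for integer counts
  expect_gt(nll(theta), 0)
})

test_that("likelihood is invariant to site ordering", {
  sim <- small_sim(seed = 11)
  df <- as.data.frame(sim$data)
  data_fwd <- lek_count_data(df)
  data_rev <- lek_count_data(df[rev(seq_len(nrow(df))), ])
  spec <- nmix_spec("poisson", "constant")
  th <- lekdyn:::default_start(lekdyn:::prepare_nmix(data_fwd, sim$covs, spec))
  n1 <- lekdyn:::nll_factory(lekdyn:::prepare_nmix(data_fwd, sim$covs, spec))(th)
  n2 <- lekdyn:::nll_factory(lekdyn:::prepare_nmix(data_rev, sim$covs, spec))(th)
  expect_equal(n1, n2, tolerance = 1e-10)
})

test_that("family nesting: ZIP(psi=0) and NB(alpha large) collapse to Poisson", {
  sim <- small_sim(seed = 5)
  pois <- lekdyn:::prepare_nmix(sim$data, sim$covs, nmix_spec("poisson", "constant"))
  zip <- lekdyn:::prepare_nmix(sim$data, sim$covs, nmix_spec("zip", "constant"))
  nb <- lekdyn:::prepare_nmix(sim$data, sim$covs, nmix_spec("negbin", "constant"))
  th <- lekdyn:::default_start(pois)
  nll_p <- lekdyn:::nll_factory(pois)(th)

  th_zip <- lekdyn:::default_start(zip)
  th_zip[names(th)] <- th
  th_zip["psi_logit"] <- -800            # plogis underflows to exactly 0
  expect_equal(lekdyn:::nll_factory(zip)(th_zip), nll_p, tolerance = 1e-10)

  th_nb <- lekdyn:::default_start(nb)
  th_nb[names(th)] <- th
  th_nb["alpha_log"] <- log(1e6)
  expect_equal(lekdyn:::nll_factory(nb)(th_nb), nll_p, tolerance = 1e-4)
})

test_that("fitting recovers truth on a moderate dataset and is deterministic", {
  sim <- small_sim(seed = 21, M = 30, T = 8)
  spec <- nmix_spec("poisson", "autoregressive")
  f1 <- fit_nmix(sim$data, sim$covs, spec, seed = 4)
  f2 <- fit_nmix(sim$data, sim$covs, spec, seed = 4)
  expect_identical(f1$theta, f2$theta)
  expect_true(f1$converged)
  est <- response_estimates(f1)
  expect_lt(abs(est["lambda"] - 6) / 6, 0.4)
  expect_lt(abs(est["p"] - 0.6), 0.25)
  expect_equal(f1$aic, 2 * f1$nll + 2 * f1$n_params, tolerance = 1e-12)
  k <- f1$n_params
  expect_equal(f1$aicc,
               f1$aic + 2 * k * (k + 1) / (f1$n_obs - k - 1),
               tolerance = 1e-12)
  expect_equal(unname(f1$ci95[, 2] - f1$theta),
               unname(qnorm(0.975) * f1$se), tolerance = 1e-12)

  # truncation insensitivity: raising K leaves the optimum unchanged
  fK <- fit_nmix(sim$data, sim$covs,
                 nmix_spec("poisson", "autoregressive",
                           K = max(sim$data$y, na.rm = TRUE) + 30),
                 starts = 1)
  f0 <- fit_nmix(sim$data, sim$covs,
                 nmix_spec("poisson", "autoregressive",
                           K = max(sim$data$y, na.rm = TRUE) + 20),
                 starts = 1)
  expect_lt(abs(fK$nll - f0$nll), 1e-6)
})

test_that("all-zero counts drive lambda to the boundary with nll near 0", {
  df <- expand.grid(lek_id = paste0("L", 1:6), year = 2004:2007, visit = 1:2)
  df$count <- 0
  data <- lek_count_data(df)
  fit <- suppressWarnings(fit_nmix(data, NULL, nmix_spec("poisson", "constant"),
                                   starts = 1))
  expect_lt(fit$nll, 1e-3)
  expect_true(fit$boundary)
  expect_lt(exp(fit$theta[["lambda_int"]]), 0.01)
})

test_that("constant covariates are dropped with a warning", {
  sim <- small_sim(seed = 13)
  covs <- sim$covs
  covs$year$flatline <- 5
  expect_warning(
    fit_nmix(sim$data, covs,
             nmix_spec("poisson", "constant", omega_covariates = "flatline"),
             starts = 1),
    "constant after standardization")
})

test_that("unknown covariate names raise configuration errors", {
  sim <- small_sim(seed = 2, M = 5, T = 3)
  expect_error(fit_nmix(sim$data, sim$covs,
                        nmix_spec("poisson", "constant",
                                  gamma_covariates = "no_such")),
               "unknown demographic covariate")
  expect_error(fit_nmix(sim$data, sim$covs,
                        nmix_spec("poisson", "constant",
                                  p_covariates = "no_such")),
               "unknown detection covariate")
})

test_that("effect predictions back-transform with delta-method intervals", {
  sim <- small_sim(seed = 17, M = 20, T = 6)
  fit <- fit_nmix(sim$data, sim$covs,
                  nmix_spec("poisson", "autoregressive",
                            gamma_covariates = "hot_days"),
                  starts = 1)
  stdc <- fit$prep$std[["gamma.hot_days"]]

  # a log-scale slope of -1.14 multiplies recruitment by e^-1.14 per SD
  fit$theta[["gamma_hot_days"]] <- -1.14
  grid <- stdc["center"] + c(0, 1) * stdc["scale"]
  pr <- predict_effect(fit, "gamma", grid = grid)
  expect_equal(pr$fit[2] / pr$fit[1], exp(-1.14), tolerance = 1e-10)

  # zero slope gives a flat curve at the back-transformed intercept
  fit$theta[["gamma_hot_days"]] <- 0
  pr0 <- predict_effect(fit, "gamma", grid = seq(0, 80, by = 20))
  expect_true(all(abs(pr0$fit - exp(fit$theta[["gamma_int"]])) < 1e-12))

  # logit saturation: a huge survival intercept predicts 1 with CI in [0, 1]
  fit2 <- fit_nmix(sim$data, sim$covs,
                   nmix_spec("poisson", "constant",
                             omega_covariates = "pmdi_avg"),
                   starts = 1)
  fit2$theta[["omega_int"]] <- 50
  pr2 <- predict_effect(fit2, "omega", grid = c(-2, 0, 2))
  expect_true(all(abs(pr2$fit - 1) < 1e-9))
  expect_true(all(pr2$lwr >= 0 & pr2$upr <= 1))

  expect_error(predict_effect(fit, "omega", grid = 1:3), "0 covariates")
})
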