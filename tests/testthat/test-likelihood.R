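# The truncated-grid building blocks: initial pmf, transition kernel,
# detection likelihood, and the forward recursion against brute-force
# trajectory enumeration.

test_that("initial pmf families normalize, fold tails, and nest", {
  p30 <- initial_pmf("poisson", lambda = 3, K = 30)
  expect_equal(sum(p30), 1, tolerance = 1e-12)
  expect_equal(initial_pmf("zip", lambda = 3, psi = 0, K = 30), p30,
               tolerance = 1e-12)

  # closed-form NB mass at zero: (alpha / (alpha + lambda))^alpha
  nb <- initial_pmf("negbin", lambda = 8, alpha = 2, K = 100)
  expect_equal(nb[1], (2 / 10)^2, tolerance = 1e-12)
  expect_equal(sum(nb), 1, tolerance = 1e-12)

  # aggressive truncation folds the tail into state K
  short <- initial_pmf("poisson", lambda = 10, K = 5)
  expect_equal(sum(short), 1, tolerance = 1e-12)
  expect_equal(short[6], ppois(4, 10, lower.tail = FALSE), tolerance = 1e-12)

  for (fam in c("poisson", "zip", "negbin"))
    expect_equal(initial_pmf(fam, 2.5, psi = 0.3, alpha = 1.7, K = 15),
                 oracle_initial_pmf(fam, 2.5, psi = 0.3, alpha = 1.7, K = 15),
                 tolerance = 1e-12)

  expect_error(initial_pmf("poisson", lambda = -1, K = 10), "positive")
  expect_error(initial_pmf("zip", lambda = 2, psi = 1.5, K = 10), "psi")
  expect_error(initial_pmf("negbin", lambda = 2, alpha = 0, K = 10), "alpha")
  expect_error(initial_pmf("zip", lambda = 2, K = 10), "psi required")
})

test_that("transition rows match the convolution oracle and are stochastic", {
  # deterministic persistence and extinction
  expect_equal(build_transition(1, 0, "constant", 3, 5),
               c(0, 0, 0, 1, 0, 0))
  expect_equal(build_transition(0, 0, "constant", 4, 5),
               c(1, 0, 0, 0, 0, 0))
  # survivors x recruits convolution at zero: Binom(0;2,.5) * Pois(0;1)
  row <- build_transition(0.5, 1.0, "constant", 2, 20)
  expect_equal(row[1], 0.25 * exp(-1), tolerance = 1e-12)

  set.seed(42)
  for (i in 1:25) {
    omega <- runif(1); gamma <- runif(1, 0, 3)
    dyn <- sample(c("constant", "autoregressive"), 1)
    K <- sample(6:25, 1); a <- sample(0:K, 1)
    got <- build_transition(omega, gamma, dyn, a, K)
    expect_equal(got, oracle_transition_row(omega, gamma, dyn, a, K),
                 tolerance = 1e-10)
    expect_equal(sum(got), 1, tolerance = 1e-12)   # exact tail folding
  }

  # negligible pre-fold truncation loss when K is generous
  wide <- build_transition(0.7, 2, "constant", 4, 4 + 10 * 2 + 20)
  expect_lt(wide[length(wide)], 1e-9)

  expect_error(build_transition(1.2, 0, "constant", 1, 5), "omega")
  expect_error(build_transition(0.5, -1, "constant", 1, 5), "gamma")
  expect_error(build_transition(0.5, 1, "constant", 9, 5), "prev_state")
})

test_that("detection log-likelihood handles edge cases and products", {
  expect_equal(detection_loglik(2, N = 2, p = 1), 0)
  expect_equal(detection_loglik(3, N = 2, p = 0.5), -Inf)
  expect_equal(detection_loglik(c(1, 2), N = 4, p = c(0.5, 0.5)),
               log(dbinom(1, 4, 0.5) * dbinom(2, 4, 0.5)), tolerance = 1e-12)
  # missing visits are skipped; no visits at all is vacuous
  expect_equal(detection_loglik(c(1, NA), N = 4, p = c(0.5, 0.9)),
               dbinom(1, 4, 0.5, log = TRUE))
  expect_equal(detection_loglik(NA_real_, N = 4, p = 0.5), 0)
  expect_error(detection_loglik(-1, N = 4, p = 0.5), "negative")
})

test_that("forward recursion equals trajectory enumeration on tiny instances", {
  for (s in 1:20) {
    z <- random_tiny_instance(s)
    expect_equal(site_ll_from_instance(z), oracle_ll_from_instance(z),
                 tolerance = 1e-8, label = paste("instance", s))
  }
})

test_that("closed-population limit: omega = 1, gamma = 0 pools all visits", {
  set.seed(7)
  for (s in 1:5) {
    T <- 3; J <- 2; K <- 15
    lambda <- runif(1, 1, 5)
    p <- matrix(runif(T * J, 0.3, 0.9), T, J)
    N <- rpois(1, lambda)
    y <- matrix(rbinom(T * J, min(N, K), p), T, J)
    got <- site_loglik(y, "poisson", lambda, omega = rep(1, T - 1),
                       gamma = rep(0, T - 1), dynamics = "constant",
                       p = p, K = K)
    expect_equal(got, oracle_closed_loglik(as.vector(y), as.vector(p),
                                           "poisson", lambda, K = K),
                 tolerance = 1e-10)
  }
})

test_that("perfect detection with one visit reveals the latent states", {
  y <- matrix(c(3L, 4L, 2L), 3, 1)
  omega <- c(0.6, 0.7); gamma <- c(1.2, 0.4)
  K <- 12
  got <- site_loglik(y, "poisson", lambda = 3, omega = omega, gamma = gamma,
                     dynamics = "constant", p = 1 - 1e-12, K = K)
  expected <- log(initial_pmf("poisson", 3, K = K)[y[1] + 1]) +
    log(build_transition(omega[1], gamma[1], "constant", y[1], K)[y[2] + 1]) +
    log(build_transition(omega[2], gamma[2], "constant", y[2], K)[y[3] + 1])
  expect_equal(got, expected, tolerance = 1e-6)
})

test_that("likelihood is invariant to visit order within a site-period", {
  y <- matrix(c(2, 5, 1, 0, 3, NA), 2, 3)
  p <- matrix(c(0.4, 0.6, 0.7, 0.5, 0.8, 0.3), 2, 3)
  perm <- c(3, 1, 2)
  a <- site_loglik(y, "poisson", 4, omega = 0.7, gamma = 0.5,
                   dynamics = "constant", p = p, K = 15)
  b <- site_loglik(y[, perm], "poisson", 4, omega = 0.7, gamma = 0.5,
                   dynamics = "constant", p = p[, perm], K = 15)
  expect_equal(a, b, tolerance = 1e-12)
})
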