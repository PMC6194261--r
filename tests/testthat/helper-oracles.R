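# Independent oracles, written from the probability definitions directly
# (no calls into the package's likelihood path).

oracle_pois_pmf <- function(n, lambda) {
  if (lambda == 0) return(as.numeric(n == 0))
  exp(n * log(lambda) - lambda - lgamma(n + 1))
}

oracle_initial_pmf <- function(family, lambda, psi = NULL, alpha = NULL, K) {
  n <- 0:K
  base <- switch(family,
    poisson = oracle_pois_pmf(n, lambda),
    zip = {
      p <- (1 - psi) * oracle_pois_pmf(n, lambda)
      p[1] <- p[1] + psi
      p
    },
    negbin = exp(lgamma(n + alpha) - lgamma(alpha) - lgamma(n + 1) +
                   alpha * log(alpha / (alpha + lambda)) +
                   n * log(lambda / (alpha + lambda))))
  base[K + 1] <- base[K + 1] + (1 - sum(base))  # fold tail into state K
  base
}

oracle_transition_row <- function(omega, gamma, dynamics, a, K) {
  rate <- if (dynamics == "autoregressive") gamma * a else gamma
  row <- numeric(K + 1)
  for (b in 0:(K - 1)) {
    s <- 0:min(a, b)
    row[b + 1] <- sum(choose(a, s) * omega^s * (1 - omega)^(a - s) *
                        oracle_pois_pmf(b - s, rate))
  }
  row[K + 1] <- 1 - sum(row[1:K])
  row
}

# Brute-force trajectory enumeration of the open-population likelihood for a
# single site: y is a T x J matrix (NA = no visit), p same shape.
oracle_enum_loglik <- function(y, family, lambda, psi = NULL, alpha = NULL,
                               omega, gamma, dynamics, p, K) {
  T <- nrow(y)
  init <- oracle_initial_pmf(family, lambda, psi, alpha, K)
  det_lik <- function(t, n) {
    keep <- !is.na(y[t, ])
    if (!any(keep)) return(1)
    if (any(y[t, keep] > n)) return(0)
    prod(dbinom(y[t, keep], n, p[t, keep]))
  }
  Q <- if (T > 1) lapply(1:(T - 1), function(t)
    t(sapply(0:K, function(a)
      oracle_transition_row(omega[t], gamma[t], dynamics, a, K)))) else list()
  states <- expand.grid(rep(list(0:K), T))
  total <- 0
  for (r in seq_len(nrow(states))) {
    n <- as.integer(states[r, ])
    pr <- init[n[1] + 1] * det_lik(1, n[1])
    if (T > 1) for (t in 2:T) {
      if (pr == 0) break
      pr <- pr * Q[[t - 1]][n[t - 1] + 1, n[t] + 1] * det_lik(t, n[t])
    }
    total <- total + pr
  }
  log(total)
}

# Closed-population N-mixture likelihood: one latent N shared by all visits.
oracle_closed_loglik <- function(yvec, pvec, family, lambda, psi = NULL,
                                 alpha = NULL, K) {
  init <- oracle_initial_pmf(family, lambda, psi, alpha, K)
  lik <- sum(vapply(0:K, function(n) {
    if (any(yvec > n)) return(0)
    init[n + 1] * prod(dbinom(yvec, n, pvec))
  }, numeric(1)))
  log(lik)
}

# Textbook one-way fixed-effects ANOVA from sums of squares.
oracle_anova <- function(g1, g2) {
  x <- c(g1, g2); n1 <- length(g1); n2 <- length(g2); n <- n1 + n2
  m <- mean(x); m1 <- mean(g1); m2 <- mean(g2)
  ssb <- n1 * (m1 - m)^2 + n2 * (m2 - m)^2
  ssw <- sum((g1 - m1)^2) + sum((g2 - m2)^2)
  f <- (ssb / 1) / (ssw / (n - 2))
  list(F = f, df1 = 1, df2 = n - 2, p = stats::pf(f, 1, n - 2, lower.tail = FALSE))
}

# Random tiny instance for oracle-equivalence checks.
random_tiny_instance <- function(seed, Tmax = 3, K = 8) {
  set.seed(seed)
  T <- sample(2:Tmax, 1)
  J <- sample(1:3, 1)
  family <- sample(c("poisson", "zip", "negbin"), 1)
  dynamics <- sample(c("constant", "autoregressive"), 1)
  lambda <- runif(1, 0.5, 3)
  psi <- if (family == "zip") runif(1, 0, 0.6) else NULL
  alpha <- if (family == "negbin") runif(1, 0.5, 4) else NULL
  omega <- runif(T - 1, 0.2, 0.95)
  gamma <- runif(T - 1, 0, if (dynamics == "autoregressive") 0.6 else 1.5)
  p <- matrix(runif(T * J, 0.3, 0.9), T, J)
  y <- matrix(rpois(T * J, lambda * 0.5), T, J)
  y[y > K] <- K
  if (runif(1) < 0.5) y[sample(length(y), 1)] <- NA  # a missing visit
  list(y = y, family = family, lambda = lambda, psi = psi, alpha = alpha,
       omega = omega, gamma = gamma, dynamics = dynamics, p = p, K = K)
}

site_ll_from_instance <- function(z) {
  site_loglik(z$y, z$family, z$lambda, z$psi, z$alpha, z$omega, z$gamma,
              z$dynamics, z$p, z$K)
}

oracle_ll_from_instance <- function(z) {
  oracle_enum_loglik(z$y, z$family, z$lambda, z$psi, z$alpha, z$omega,
                     z$gamma, z$dynamics, z$p, z$K)
}
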