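#' Initial-abundance probability mass function on the truncated grid
#'
#' Probability of each latent abundance state 0..K in the first primary
#' period, with all mass above K folded into state K. The zero-inflated
#' Poisson puts `psi + (1 - psi) * exp(-lambda)` at zero; the negative
#' binomial is parameterized by mean `lambda` and dispersion `alpha`
#' (variance `lambda + lambda^2 / alpha`).
#'
#' @param family `"poisson"`, `"zip"` or `"negbin"`.
#' @param lambda Mean abundance (> 0).
#' @param psi Zero-inflation probability (zip only).
#' @param alpha Dispersion (> 0, negbin only).
#' @param K Truncation bound.
#' @return Numeric vector of length K + 1 summing to 1.
#' @export
initial_pmf <- function(family = c("poisson", "zip", "negbin"), lambda,
                        psi = NULL, alpha = NULL, K) {
  family <- match.arg(family)
  if (!is.finite(lambda) || lambda <= 0) stop_domain("lambda must be positive")
  if (K < 1 || K %% 1 != 0) stop_domain("K must be a positive integer")
  base <- c(dpois(0:(K - 1), lambda), ppois(K - 1, lambda, lower.tail = FALSE))
  switch(family,
    poisson = base,
    zip = {
      if (is.null(psi)) stop_domain("psi required for the zip family")
      check_prob(psi, "psi")
      out <- (1 - psi) * base
      out[1] <- out[1] + psi
      out
    },
    negbin = {
      if (is.null(alpha)) stop_domain("alpha required for the negbin family")
      if (!is.finite(alpha) || alpha <= 0) stop_domain("alpha must be positive")
      c(dnbinom(0:(K - 1), size = alpha, mu = lambda),
        pnbinom(K - 1, size = alpha, mu = lambda, lower.tail = FALSE))
    })
}

#' One row of the latent-abundance transition kernel
#'
#' Distribution of next-period abundance given `prev_state` individuals:
#' survivors are Binomial(`prev_state`, `omega`) and recruits are Poisson with
#' rate `gamma` (constant dynamics) or `gamma * prev_state` (autoregressive).
#' State K absorbs the truncated upper tail so the row sums to exactly 1.
#'
#' @param omega Apparent survival probability.
#' @param gamma Recruitment rate (>= 0); per capita under autoregressive
#'   dynamics.
#' @param dynamics `"constant"` or `"autoregressive"`.
#' @param prev_state Current abundance (0..K).
#' @param K Truncation bound.
#' @return Probability vector of length K + 1.
#' @export
build_transition <- function(omega, gamma,
                             dynamics = c("constant", "autoregressive"),
                             prev_state, K) {
  dynamics <- match.arg(dynamics)
  check_prob(omega, "omega")
  if (!is.finite(gamma) || gamma < 0) stop_domain("gamma must be nonnegative")
  if (prev_state < 0 || prev_state > K || prev_state %% 1 != 0)
    stop_domain("prev_state must be an integer in 0..K")
  Q <- trans_kernel_cpp(omega, gamma, dynamics == "autoregressive", K)
  drop(Q[prev_state + 1, ])
}

#' Binomial detection log-likelihood for one site-period
#'
#' Sum of log Binomial(y_j; N, p_j) over the non-missing visits of a
#' site-period. Any count exceeding N gives `-Inf`; a site-period with no
#' visits contributes 0 (it is vacuous).
#'
#' @param counts Per-visit counts (`NA` = visit not made).
#' @param N Latent abundance.
#' @param p Per-visit detection probabilities, aligned with `counts`.
#' @return Log-probability.
#' @export
detection_loglik <- function(counts, N, p) {
  keep <- !is.na(counts)
  counts <- counts[keep]
  p <- rep_len(p, length(keep))[keep]
  if (any(counts < 0)) stop_domain("negative counts")
  check_prob(p, "p")
  if (!length(counts)) return(0)
  if (any(counts > N)) return(-Inf)
  sum(dbinom(counts, N, p, log = TRUE))
}

#' Forward log-likelihood of one site's count history
#'
#' Evaluates the marginal likelihood of a T-year visit history by the forward
#' recursion over the truncated latent states 0..K, with parameters given on
#' the response scale. This is the single-site building block of the full
#' model likelihood; [fit_nmix()] drives the same recursion through covariate
#' design matrices.
#'
#' @param y T x J matrix of counts (`NA` = visit not made).
#' @param family Initial-abundance family.
#' @param lambda,psi,alpha Initial-abundance parameters (see [initial_pmf()]).
#' @param omega,gamma Length T-1 vectors of apparent survival and recruitment
#'   for transitions into years 2..T.
#' @param dynamics `"constant"` or `"autoregressive"`.
#' @param p Detection probability: scalar or T x J matrix aligned with `y`.
#' @param K Truncation bound (must be >= max count).
#' @return Log-likelihood of the site history.
#' @export
site_loglik <- function(y, family = "poisson", lambda, psi = NULL,
                        alpha = NULL, omega = numeric(), gamma = numeric(),
                        dynamics = c("constant", "autoregressive"), p, K) {
  dynamics <- match.arg(dynamics)
  y <- rbind(y)
  T <- nrow(y)
  if (T > 1 && (length(omega) != T - 1 || length(gamma) != T - 1))
    stop_domain("omega and gamma must have length T - 1")
  if (!all(is.na(y)) && max(y, na.rm = TRUE) > K)
    stop_domain("K must be at least the maximum observed count")
  if (is.null(dim(p))) p <- matrix(p, T, ncol(y))
  keep <- which(!is.na(y))
  yv <- as.integer(y[keep])
  tv <- as.integer((keep - 1) %% T)           # column-major: row index
  pv <- pmin(pmax(p[keep], 1e-12), 1 - 1e-12)
  lct <- lchoose_table(K)
  logdet <- detection_logdet_cpp(yv, integer(length(yv)), tv, pv, lct, 1L, T, K)
  log_init <- matrix(log(initial_pmf(family, lambda, psi, alpha, K)), 1)
  om <- matrix(omega, 1)
  gm <- matrix(gamma, 1)
  drop(forward_loglik_cpp(log_init, logdet, om, gm,
                          dynamics == "autoregressive", K))
}

lchoose_table <- function(K) {
  n <- 0:K
  outer(n, n, function(a, b) ifelse(b > a, -Inf, lchoose(a, b)))
}
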