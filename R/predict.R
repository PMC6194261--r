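#' Response-scale effect curve for a fitted covariate
#'
#' Predicts a demographic, detection or initial-abundance parameter over a
#' grid of covariate values given on the original (unstandardized) scale,
#' holding every other covariate at its mean. The 95% interval is a delta-
#' method Wald interval on the link scale, back-transformed, so predictions
#' for survival and detection always respect [0, 1].
#'
#' @param fit An [fit_nmix()] result.
#' @param parameter One of `"gamma"`, `"omega"`, `"p"`, `"lambda"`.
#' @param grid Covariate values on the original scale.
#' @param covariate Covariate name; may be omitted when the parameter carries
#'   exactly one covariate.
#' @return Data frame with columns `x`, `fit`, `lwr`, `upr` (response scale)
#'   and `eta`, `se_eta` (link scale).
#' @examples
#' \donttest{
#' sim <- simulate_lek_counts(scenario_config(seed = 1))
#' f <- fit_nmix(sim$data, sim$covs,
#'               nmix_spec("poisson", "autoregressive",
#'                         gamma_covariates = "hot_days"))
#' predict_effect(f, "gamma", grid = seq(10, 90, by = 20))
#' }
#' @export
predict_effect <- function(fit, parameter = c("gamma", "omega", "p", "lambda"),
                           grid, covariate = NULL) {
  parameter <- match.arg(parameter)
  prep <- fit$prep
  covnames <- switch(parameter,
    lambda = fit$spec$lambda_covariates,
    gamma = fit$spec$gamma_covariates,
    omega = fit$spec$omega_covariates,
    p = fit$spec$p_covariates)
  covnames <- setdiff(covnames, prep$dropped)
  if (is.null(covariate)) {
    if (length(covnames) != 1)
      stop_domain("parameter '", parameter, "' has ", length(covnames),
                  " covariates; name one explicitly")
    covariate <- covnames
  }
  if (!covariate %in% covnames)
    stop_domain("covariate '", covariate, "' is not in the fitted model for ",
                parameter)
  key <- paste0(switch(parameter, lambda = "lambda", gamma = "gamma",
                       omega = "omega", p = "p"), ".", covariate)
  stdc <- prep$std[[key]]
  z <- (grid - stdc["center"]) / stdc["scale"]

  block <- prep$idx[[parameter]]
  labels <- sub(paste0("^", parameter, "_"), "", prep$par_names[block])
  j_int <- block[labels == "int"]
  j_cov <- block[labels == covariate]
  b <- fit$theta
  eta <- b[j_int] + b[j_cov] * z
  se_eta <- rep(NA_real_, length(z))
  if (!is.null(fit$vcov)) {
    V <- fit$vcov[c(j_int, j_cov), c(j_int, j_cov)]
    se_eta <- sqrt(V[1, 1] + 2 * z * V[1, 2] + z^2 * V[2, 2])
  }
  zq <- qnorm(0.975)
  inv <- if (parameter %in% c("omega", "p")) plogis else exp
  data.frame(x = grid, fit = unname(inv(eta)),
             lwr = unname(inv(eta - zq * se_eta)),
             upr = unname(inv(eta + zq * se_eta)),
             eta = unname(eta), se_eta = unname(se_eta))
}
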