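#' Open-population N-mixture model specification
#'
#' Describes one candidate model: the initial-abundance family, the dynamics
#' type, which named covariates act on each parameter, and the truncation
#' bound K for the latent abundance grid.
#'
#' Covariate names resolve against a [covariate_table()]: year-level columns
#' (including `_lag1` lags) for survival and recruitment, site-year matrices
#' (e.g. `cow_days`) for either, per-site vectors (e.g. `prior_count`) for
#' initial abundance, and the reserved names `rain`, `tmax`, `effort` for
#' detection (taken from the count data itself). All covariates are z-scored
#' before fitting; the constants are stored on the fit for back-transformation.
#'
#' @param family Initial-abundance family: `"poisson"`, `"zip"` (zero-inflated
#'   Poisson) or `"negbin"`.
#' @param dynamics `"constant"` (recruits ~ Poisson(gamma)) or
#'   `"autoregressive"` (recruits ~ Poisson(gamma * N[t-1])).
#' @param lambda_covariates,gamma_covariates,omega_covariates,p_covariates
#'   Character vectors of covariate names (possibly empty).
#' @param K Latent-abundance truncation bound; default (`NULL`) resolves to
#'   the maximum observed count + 20 at fitting time.
#' @return An object of class `nmix_spec`.
#' @export
nmix_spec <- function(family = c("poisson", "zip", "negbin"),
                      dynamics = c("constant", "autoregressive"),
                      lambda_covariates = character(),
                      gamma_covariates = character(),
                      omega_covariates = character(),
                      p_covariates = character(),
                      K = NULL) {
  family <- match.arg(family)
  dynamics <- match.arg(dynamics)
  if (!is.null(K) && (K < 1 || K %% 1 != 0)) stop_domain("K must be a positive integer")
  structure(list(family = family, dynamics = dynamics,
                 lambda_covariates = as.character(lambda_covariates),
                 gamma_covariates = as.character(gamma_covariates),
                 omega_covariates = as.character(omega_covariates),
                 p_covariates = as.character(p_covariates),
                 K = K),
            class = "nmix_spec")
}

#' @export
print.nmix_spec <- function(x, ...) {
  fmt <- function(v) if (length(v)) paste(v, collapse = " + ") else "1"
  cat(sprintf("N-mixture spec: %s initial abundance, %s dynamics\n",
              x$family, x$dynamics))
  cat(sprintf("  lambda ~ %s | gamma ~ %s | omega ~ %s | p ~ %s\n",
              fmt(x$lambda_covariates), fmt(x$gamma_covariates),
              fmt(x$omega_covariates), fmt(x$p_covariates)))
  if (!is.null(x$K)) cat("  K =", x$K, "\n")
  invisible(x)
}
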