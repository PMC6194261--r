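# Design preparation, packed-parameter objective, and ML fitting.
#
# All covariates are z-scored here; the (center, scale) constants are kept on
# the prepared object so predictions can be made on the original scale.
# Missing covariate cells are imputed at the mean (0 after z-scoring) and
# counted; zero-variance covariates are dropped with a warning.

prepare_nmix <- function(data, covs, spec) {
  stopifnot(inherits(data, "lek_count_data"))
  covs <- covs %||% covariate_table(data.frame(year = data$years))
  M <- length(data$sites); T <- length(data$years)
  ymax <- if (all(is.na(data$y))) 0L else max(data$y, na.rm = TRUE)
  K <- spec$K %||% (ymax + 20L)
  if (K < ymax) stop_domain("K must be at least the maximum observed count")

  std <- list(); imputed <- list(); dropped <- character()
  zcol <- function(x, name) {
    ctr <- mean(x, na.rm = TRUE); scl <- sd(x, na.rm = TRUE)
    if (!is.finite(scl) || scl == 0) {
      warning("covariate '", name, "' is constant after standardization; dropped")
      dropped <<- c(dropped, name)
      return(NULL)
    }
    z <- (x - ctr) / scl
    nimp <- sum(is.na(z))
    if (nimp) { z[is.na(z)] <- 0; imputed[[name]] <<- nimp }
    std[[name]] <<- c(center = ctr, scale = scl)
    z
  }

  # -- initial abundance design (per site) --
  Xlam <- matrix(1, M, 1, dimnames = list(NULL, "int"))
  for (nm in spec$lambda_covariates) {
    v <- covs$site[[nm]]
    if (is.null(v)) stop_domain("unknown initial-abundance covariate '", nm, "'")
    z <- zcol(v, paste0("lambda.", nm))
    if (!is.null(z)) Xlam <- cbind(Xlam, setNames(data.frame(z), nm))
  }
  Xlam <- as.matrix(Xlam)

  # -- demographic designs (site x transition), transitions into years 2..T --
  demo_values <- function(nm) {
    if (nm %in% names(covs$site_year)) {
      mat <- covs$site_year[[nm]]
      cols <- if (!is.null(colnames(mat))) match(data$years[-1], colnames(mat))
              else seq(2L, T)
      if (anyNA(cols)) stop_domain("site-year covariate '", nm,
                                   "' does not cover the modeled years")
      mat[, cols, drop = FALSE]
    } else if (nm %in% names(covs$year)) {
      v <- covs$year[[nm]][match(data$years[-1], covs$year$year)]
      matrix(rep(v, each = M), M)
    } else stop_domain("unknown demographic covariate '", nm, "'")
  }
  demo_design <- function(names, prefix) {
    X <- matrix(1, M * max(T - 1, 0), 1, dimnames = list(NULL, "int"))
    for (nm in names) {
      z <- zcol(as.vector(demo_values(nm)), paste0(prefix, ".", nm))
      if (!is.null(z)) X <- cbind(X, setNames(data.frame(z), nm))
    }
    as.matrix(X)
  }
  Xgam <- demo_design(spec$gamma_covariates, "gamma")
  Xom <- demo_design(spec$omega_covariates, "omega")

  # -- detection design (per non-missing visit) --
  vidx <- which(!is.na(data$y), arr.ind = TRUE)
  vidx <- vidx[order(vidx[, 1], vidx[, 2], vidx[, 3]), , drop = FALSE]
  Xp <- matrix(1, nrow(vidx), 1, dimnames = list(NULL, "int"))
  for (nm in spec$p_covariates) {
    raw <- switch(nm,
      rain = data$rain[vidx],
      tmax = data$tmax[vidx],
      effort = data$effort[vidx[, 1:2, drop = FALSE]],
      stop_domain("unknown detection covariate '", nm,
                  "' (use rain, tmax, effort)"))
    z <- zcol(raw, paste0("p.", nm))
    if (!is.null(z)) Xp <- cbind(Xp, setNames(data.frame(z), nm))
  }
  Xp <- as.matrix(Xp)

  blocks <- list(lambda = colnames(Xlam))
  if (spec$family == "zip") blocks$psi <- "logit"
  if (spec$family == "negbin") blocks$alpha <- "log"
  blocks <- c(blocks, list(gamma = colnames(Xgam), omega = colnames(Xom),
                           p = colnames(Xp)))
  par_names <- unlist(lapply(names(blocks), function(b)
    paste(b, blocks[[b]], sep = "_")))
  idx <- split(seq_along(par_names),
               rep(names(blocks), lengths(blocks)))[names(blocks)]

  list(M = M, T = T, K = K, family = spec$family,
       dynamics = spec$dynamics, spec = spec,
       Xlam = Xlam, Xgam = Xgam, Xom = Xom, Xp = Xp,
       yv = as.integer(data$y[vidx]), iv = vidx[, 1] - 1L, tv = vidx[, 2] - 1L,
       lct = lchoose_table(K), n_obs = nrow(vidx),
       par_names = par_names, idx = idx, std = std,
       imputed = imputed, dropped = dropped,
       data = data, covs = covs)
}

# theta (packed, unconstrained) -> response-scale parameter arrays.
unpack_params <- function(theta, prep) {
  g <- function(b) theta[prep$idx[[b]]]
  list(beta_lambda = g("lambda"),
       psi = if (prep$family == "zip") plogis(g("psi")) else NULL,
       alpha = if (prep$family == "negbin") exp(g("alpha")) else NULL,
       beta_gamma = g("gamma"), beta_omega = g("omega"), beta_p = g("p"))
}

pack_params <- function(par, prep) {
  theta <- numeric(length(prep$par_names))
  theta[prep$idx$lambda] <- par$beta_lambda
  if (prep$family == "zip") theta[prep$idx$psi] <- qlogis(par$psi)
  if (prep$family == "negbin") theta[prep$idx$alpha] <- log(par$alpha)
  theta[prep$idx$gamma] <- par$beta_gamma
  theta[prep$idx$omega] <- par$beta_omega
  theta[prep$idx$p] <- par$beta_p
  names(theta) <- prep$par_names
  theta
}

log_init_matrix <- function(prep, theta) {
  lambda <- exp(drop(prep$Xlam %*% theta[prep$idx$lambda]))
  psi <- if (prep$family == "zip") plogis(theta[prep$idx$psi]) else NULL
  alpha <- if (prep$family == "negbin") exp(theta[prep$idx$alpha]) else NULL
  if (any(!is.finite(lambda)) || any(lambda <= 0)) return(NULL)
  u <- unique(lambda)
  rows <- vapply(u, function(l)
    log(initial_pmf(prep$family, l, psi, alpha, prep$K)),
    numeric(prep$K + 1))
  t(rows)[match(lambda, u), , drop = FALSE]
}

expand_params <- function(prep, theta) {
  li <- log_init_matrix(prep, theta)
  if (is.null(li)) return(NULL)
  nt <- max(prep$T - 1, 0)
  gam <- matrix(exp(drop(prep$Xgam %*% theta[prep$idx$gamma])), prep$M, nt)
  om <- matrix(plogis(drop(prep$Xom %*% theta[prep$idx$omega])), prep$M, nt)
  pv <- plogis(drop(prep$Xp %*% theta[prep$idx$p]))
  pv <- pmin(pmax(pv, 1e-12), 1 - 1e-12)
  if (any(!is.finite(gam))) return(NULL)
  logdet <- detection_logdet_cpp(prep$yv, prep$iv, prep$tv, pv, prep$lct,
                                 prep$M, prep$T, prep$K)
  list(log_init = li, gamma = gam, omega = om, p = pv, logdet = logdet)
}

nll_factory <- function(prep) {
  ar <- as.integer(prep$dynamics == "autoregressive")
  function(theta) {
    ex <- expand_params(prep, theta)
    if (is.null(ex)) return(1e10)
    ll <- forward_loglik_cpp(ex$log_init, ex$logdet, ex$omega, ex$gamma,
                             ar, prep$K)
    val <- -sum(ll)
    if (!is.finite(val)) 1e10 else val
  }
}

default_start <- function(prep) {
  theta <- setNames(numeric(length(prep$par_names)), prep$par_names)
  y1 <- prep$data$y[, 1, , drop = FALSE]
  m1 <- suppressWarnings(mean(apply(y1, 1, max, na.rm = TRUE), na.rm = TRUE))
  if (!is.finite(m1)) m1 <- 2
  theta[prep$idx$lambda][1] <- log((m1 + 0.5) / 0.6)
  if (prep$family == "zip") theta[prep$idx$psi] <- qlogis(0.15)
  if (prep$family == "negbin") theta[prep$idx$alpha] <- log(2)
  theta[prep$idx$gamma][1] <- if (prep$dynamics == "autoregressive")
    log(0.3) else log(max(0.5, 0.3 * m1))
  theta[prep$idx$omega][1] <- qlogis(0.6)
  theta[prep$idx$p][1] <- qlogis(0.5)
  theta
}

num_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    hj <- h * (1 + abs(x[j]))
    e <- numeric(length(x)); e[j] <- hj
    (f(x + e) - f(x - e)) / (2 * hj)
  }, numeric(1))
}

#' Fit an open-population N-mixture model by maximum likelihood
#'
#' Maximizes the truncated forward likelihood by quasi-Newton (BFGS) search
#' from a deterministic moment-based start plus `starts - 1` seeded jittered
#' restarts, keeping the best optimum. Standard errors come from the inverse
#' of a numerically differentiated Hessian; the fit is flagged non-converged
#' when the optimizer fails, the finite-difference gradient norm is large, or
#' the Hessian is not positive definite (in which case SEs are `NA`, never
#' silently zeroed).
#'
#' @param data A [lek_count_data()] object.
#' @param covs A [covariate_table()] (or `NULL` for intercept-only models).
#' @param spec An [nmix_spec()].
#' @param starts Number of optimizer starts (1 deterministic + jittered).
#' @param seed Seed for the jittered restarts.
#' @param start Optional named vector of starting values; names matching the
#'   packed parameter vector override the moment-based defaults (used to
#'   warm-start candidate models from a null fit during scans).
#' @param control List: `maxit` (300), `reltol` (1e-8), `tol_grad` (1e-3,
#'   scaled by 1 + |nll|), `jitter_sd` (0.5).
#' @return An object of class `nmix_fit`: packed estimates, SEs, covariance,
#'   nll, AIC/AICc, Wald 95% intervals and convergence diagnostics.
#' @export
fit_nmix <- function(data, covs = NULL, spec, starts = 3, seed = 1L,
                     start = NULL, control = list()) {
  ctl <- modifyList(list(maxit = 300, reltol = 1e-8, tol_grad = 1e-3,
                         jitter_sd = 0.5), control)
  prep <- prepare_nmix(data, covs, spec)
  nll <- nll_factory(prep)
  start0 <- default_start(prep)
  if (!is.null(start)) {
    hit <- intersect(names(start), names(start0))
    start0[hit] <- start[hit]
  }
  starts_list <- list(start0)
  if (starts > 1) {
    jit <- with_seed(as.integer(seed),
      replicate(starts - 1, start0 + rnorm(length(start0), 0, ctl$jitter_sd),
                simplify = FALSE))
    starts_list <- c(starts_list, jit)
  }
  fits <- lapply(starts_list, function(s)
    tryCatch(optim(s, nll, method = "BFGS",
                   control = list(maxit = ctl$maxit, reltol = ctl$reltol)),
             error = function(e) e))
  ok <- !vapply(fits, inherits, TRUE, "error")
  if (!any(ok))
    stop("all optimizer starts failed: ",
         conditionMessage(fits[[1]]), call. = FALSE)
  fits <- fits[ok]
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  theta <- setNames(best$par, prep$par_names)
  value <- best$value
  conv0 <- best$convergence
  # polish: BFGS can satisfy reltol while the gradient is still descending
  # on large datasets; restart at tighter tolerance until it flattens
  grad <- num_gradient(nll, theta)
  for (round in 1:2) {
    if (max(abs(grad)) <= ctl$tol_grad * (1 + abs(value))) break
    more <- tryCatch(optim(theta, nll, method = "BFGS",
                           control = list(maxit = ctl$maxit, reltol = 1e-11)),
                     error = function(e) NULL)
    if (!is.null(more) && more$value <= value) {
      theta <- setNames(more$par, prep$par_names)
      value <- more$value
      conv0 <- more$convergence
    }
    grad <- num_gradient(nll, theta)
  }
  best$par <- theta; best$value <- value; best$convergence <- conv0

  H <- tryCatch(optimHess(theta, nll), error = function(e) NULL)
  pd <- FALSE; vc <- NULL
  if (!is.null(H)) {
    ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                   error = function(e) NA)
    pd <- all(is.finite(ev)) && all(ev > 1e-10 * max(abs(ev), 1))
    if (pd) vc <- tryCatch(solve(H), error = function(e) NULL)
    pd <- pd && !is.null(vc)
  }
  se <- if (pd) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(theta))
  names(se) <- prep$par_names
  if (!is.null(vc)) dimnames(vc) <- list(prep$par_names, prep$par_names)

  gnorm <- max(abs(grad))
  converged <- best$convergence == 0 && pd &&
    is.finite(gnorm) && gnorm <= ctl$tol_grad * (1 + abs(best$value))
  boundary <- any(abs(theta) > 10)

  k <- length(theta)
  aic <- 2 * best$value + 2 * k
  aicc <- if (prep$n_obs - k - 1 > 0)
    aic + 2 * k * (k + 1) / (prep$n_obs - k - 1) else Inf
  z <- qnorm(0.975)
  ci95 <- cbind(lower = theta - z * se, upper = theta + z * se)

  structure(list(spec = prep$spec, theta = theta, se = se, vcov = vc,
                 nll = best$value, aic = aic, aicc = aicc,
                 n_params = k, n_obs = prep$n_obs,
                 converged = converged, hessian_pd = pd,
                 grad_norm = gnorm, boundary = boundary,
                 ci95 = ci95, prep = prep, optim = best),
            class = "nmix_fit")
}

#' Response-scale estimates of the intercept parameters
#'
#' Back-transforms the fitted intercepts: mean initial abundance `lambda`,
#' recruitment rate `gamma`, apparent survival `omega`, detection `p`, plus
#' `psi` / `alpha` when the family has them. Covariates are z-scored, so these
#' are the rates at average covariate values.
#'
#' @param fit An `nmix_fit`.
#' @return Named numeric vector.
#' @export
response_estimates <- function(fit) {
  th <- fit$theta; idx <- fit$prep$idx
  out <- c(lambda = unname(exp(th[idx$lambda][1])),
           gamma = unname(exp(th[idx$gamma][1])),
           omega = unname(plogis(th[idx$omega][1])),
           p = unname(plogis(th[idx$p][1])))
  if (fit$prep$family == "zip") out["psi"] <- plogis(th[idx$psi])
  if (fit$prep$family == "negbin") out["alpha"] <- exp(th[idx$alpha])
  out
}

#' @export
print.nmix_fit <- function(x, ...) {
  cat(sprintf("Open N-mixture fit: %s / %s dynamics\n",
              x$spec$family, x$spec$dynamics))
  tab <- data.frame(estimate = x$theta, se = x$se,
                    lcl = x$ci95[, 1], ucl = x$ci95[, 2])
  print(round(tab, 4))
  cat(sprintf("nll = %.4f, AIC = %.2f, AICc = %.2f, converged: %s\n",
              x$nll, x$aic, x$aicc, x$converged))
  if (!x$hessian_pd) cat("  (Hessian not positive definite; SEs undefined)\n")
  if (x$boundary) cat("  (estimate at or near a parameter boundary)\n")
  invisible(x)
}

#' @export
coef.nmix_fit <- function(object, ...) object$theta

#' @export
vcov.nmix_fit <- function(object, ...) object$vcov

#' @export
logLik.nmix_fit <- function(object, ...) {
  structure(-object$nll, df = object$n_params, nobs = object$n_obs,
            class = "logLik")
}

#' @export
confint.nmix_fit <- function(object, parm, level = 0.95, ...) {
  z <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(object$theta - z * object$se, object$theta + z * object$se)
  dimnames(ci) <- list(names(object$theta),
                       paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %"))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}
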