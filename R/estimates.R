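# Empirical-Bayes abundance series and the pre/post-drought contrast.

eb_posterior_cube <- function(prep, theta) {
  ex <- expand_params(prep, theta)
  if (is.null(ex)) stop_domain("parameters out of range for EB smoothing")
  forward_backward_cpp(ex$log_init, ex$logdet, ex$omega, ex$gamma,
                       as.integer(prep$dynamics == "autoregressive"), prep$K)
}

cube_site_summary <- function(post, prep) {
  K <- prep$K; states <- 0:K
  out <- expand.grid(site = prep$data$sites, year = prep$data$years,
                     stringsAsFactors = FALSE)
  out$mean <- NA_real_; out$lo95 <- NA_real_; out$hi95 <- NA_real_
  for (i in seq_len(prep$M)) for (t in seq_len(prep$T)) {
    pm <- post[, t, i]
    cdf <- cumsum(pm)
    r <- (out$site == prep$data$sites[i]) & (out$year == prep$data$years[t])
    out$mean[r] <- sum(states * pm)
    out$lo95[r] <- states[which(cdf >= 0.025)[1]]
    out$hi95[r] <- states[which(cdf >= 0.975)[1]]
  }
  out
}

year_means_from_cube <- function(post, prep) {
  states <- 0:prep$K
  means <- apply(post, c(2, 3), function(pm) sum(states * pm)) # T x M
  data.frame(year = prep$data$years,
             mean = rowMeans(means),
             total = rowSums(means))
}

#' Empirical-Bayes annual abundance series
#'
#' Smooths the latent abundance states by a forward-backward pass at the
#' maximum-likelihood estimates, giving for every site-year the posterior
#' distribution of N given *all* of that site's counts. Site-level summaries
#' are the posterior mean and central 95% interval; year-level summaries are
#' the cross-site mean and total of the posterior means, with optional
#' parametric-bootstrap intervals (coefficients resampled from their
#' asymptotic normal and the series re-derived).
#'
#' @param fit A converged [fit_nmix()] result.
#' @param B Bootstrap draws for year-level intervals (0 = none).
#' @param seed Seed for the bootstrap.
#' @param split_year Optional year labelling periods (`predrought` before it,
#'   `postdrought` from it on).
#' @return Object of class `abundance_series`: list with data frames `site`
#'   (site, year, mean, lo95, hi95) and `year` (year, mean, total, and
#'   bootstrap `lo95`/`hi95` when `B > 0`), plus `K`.
#' @export
posterior_abundance <- function(fit, B = 0, seed = 1L, split_year = NULL) {
  if (!inherits(fit, "nmix_fit")) stop_domain("fit must be an nmix_fit")
  if (!fit$converged)
    stop_domain("fit did not converge; abundance series would be unreliable")
  prep <- fit$prep
  post <- eb_posterior_cube(prep, fit$theta)
  site <- cube_site_summary(post, prep)
  year <- year_means_from_cube(post, prep)
  if (B > 0) {
    if (is.null(fit$vcov)) stop_domain("bootstrap needs a covariance matrix")
    draws <- with_seed(as.integer(seed),
      MASS::mvrnorm(B, fit$theta, fit$vcov))
    boot <- vapply(seq_len(B), function(b) {
      yb <- tryCatch(
        year_means_from_cube(eb_posterior_cube(prep, draws[b, ]), prep)$mean,
        error = function(e) rep(NA_real_, prep$T))
      yb
    }, numeric(prep$T))
    year$lo95 <- apply(boot, 1, quantile, 0.025, na.rm = TRUE)
    year$hi95 <- apply(boot, 1, quantile, 0.975, na.rm = TRUE)
  }
  if (!is.null(split_year)) {
    site$period <- ifelse(site$year < split_year, "predrought", "postdrought")
    year$period <- ifelse(year$year < split_year, "predrought", "postdrought")
  }
  structure(list(site = site, year = year, K = prep$K),
            class = "abundance_series")
}

#' @export
print.abundance_series <- function(x, ...) {
  cat("Empirical-Bayes abundance series\n")
  print(round(as.data.frame(x$year), 2))
  invisible(x)
}

series_year_values <- function(series, response = c("mean", "total")) {
  response <- match.arg(response)
  if (inherits(series, "abundance_series")) {
    data.frame(year = series$year$year, value = series$year[[response]])
  } else {
    df <- as.data.frame(series)
    if (!all(c("year", "value") %in% names(df)))
      stop_domain("series must be an abundance_series or a (year, value) frame")
    df[, c("year", "value")]
  }
}

#' One-way ANOVA contrast of pre- vs post-drought abundance
#'
#' Compares the annual abundance estimates between the predrought years
#' (before `split_year`) and the during/postdrought years (from `split_year`
#' on) with a fixed-effects one-way analysis of variance on the yearly
#' values: df = (1, T - 2).
#'
#' @param series An `abundance_series` or data frame with `year`, `value`.
#' @param split_year First during/postdrought year.
#' @param response `"mean"` (cross-site mean, default) or `"total"`.
#' @return List with `F`, `df1`, `df2`, `p` and the per-year data.
#' @export
anova_pre_post <- function(series, split_year = 2011,
                           response = c("mean", "total")) {
  df <- series_year_values(series, match.arg(response))
  df$period <- factor(ifelse(df$year < split_year, "pre", "post"),
                      levels = c("pre", "post"))
  if (any(table(df$period) < 2))
    stop_domain("each period needs at least 2 years for the ANOVA")
  a <- suppressWarnings(anova(lm(value ~ period, data = df)))
  f <- a$`F value`[1]; p <- a$`Pr(>F)`[1]
  if (a$`Sum Sq`[1] <= 1e-12 * max(sum(a$`Sum Sq`), 1)) { f <- 0; p <- 1 }
  list(F = f, df1 = a$Df[1], df2 = a$Df[2], p = p, data = df)
}

#' Pre/post-drought fold change in abundance
#'
#' Ratio of the mean annual abundance before `split_year` to the mean from
#' `split_year` on. An optional seeded parametric bootstrap (coefficient
#' vector resampled from its asymptotic normal, series re-derived through the
#' EB smoother) gives an interval. A zero post-period mean yields an infinite
#' ratio with a flag rather than an error.
#'
#' @param series An `abundance_series` or data frame with `year`, `value`.
#' @param split_year First during/postdrought year.
#' @param response `"mean"` or `"total"`.
#' @param fit Optional `nmix_fit` (required for the bootstrap interval).
#' @param B Bootstrap draws (0 = point estimate only).
#' @param seed Bootstrap seed.
#' @return List with `ratio`, `infinite` flag, and when `B > 0` a `ci`
#'   (2.5/97.5 percentiles) and the bootstrap draws.
#' @export
fold_change <- function(series, split_year = 2011,
                        response = c("mean", "total"),
                        fit = NULL, B = 0, seed = 1L) {
  response <- match.arg(response)
  df <- series_year_values(series, response)
  pre <- mean(df$value[df$year < split_year])
  post <- mean(df$value[df$year >= split_year])
  if (!is.finite(pre) || pre <= 0) stop_domain("predrought mean must be positive")
  inf_flag <- post <= 0
  if (inf_flag) warning("postdrought mean abundance is zero; ratio is infinite")
  out <- list(ratio = if (inf_flag) Inf else pre / post, infinite = inf_flag,
              pre_mean = pre, post_mean = post)
  if (B > 0) {
    if (is.null(fit) || is.null(fit$vcov))
      stop_domain("bootstrap interval needs a fitted model with a covariance")
    prep <- fit$prep
    use_mean <- response == "mean"
    draws <- with_seed(as.integer(seed), MASS::mvrnorm(B, fit$theta, fit$vcov))
    ratios <- vapply(seq_len(B), function(b) {
      yb <- tryCatch(year_means_from_cube(eb_posterior_cube(prep, draws[b, ]),
                                          prep),
                     error = function(e) NULL)
      if (is.null(yb)) return(NA_real_)
      v <- if (use_mean) yb$mean else yb$total
      prev <- mean(v[yb$year < split_year]); postv <- mean(v[yb$year >= split_year])
      if (postv <= 0) Inf else prev / postv
    }, numeric(1))
    out$ci <- quantile(ratios, c(0.025, 0.975), na.rm = TRUE)
    out$boot <- ratios
  }
  out
}
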