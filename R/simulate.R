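# Seeded synthetic lek-count generator emulating the 49-lek, 12-year survey
# design: latent abundance initialized from the chosen count family,
# propagated by binomial survival and Poisson recruitment driven by weather
# and grazing covariates through the link functions, observed through
# binomial detection on 1-5 flush counts per season.

#' Packaged year-level weather and count summary fixture
#'
#' The 2004-2015 year-level record for the study region: per-year average and
#' maximum lek counts, cow days/ha (mean and SD across pastures), percent
#' utilization, annual precipitation (cm), average and minimum modified
#' Palmer drought index, annual maximum temperature (C) and hot days (days
#' above the long-run 90th-percentile temperature). Blank cells in the source
#' (e.g. cow days in 2004 and 2012) are `NA`, never zero-filled.
#'
#' @return Data frame with 12 rows (2004-2015).
#' @export
table1_weather <- function() {
  path <- system.file("extdata", "table1_weather.csv", package = "lekdyn")
  read.csv(path, na.strings = c("", "NA"))
}

#' Simulation scenario configuration
#'
#' Defines the generating truth for [simulate_lek_counts()]. Defaults are the
#' drought-collapse scenario: 49 leks over 2004-2015 with the packaged
#' weather record, initial abundance Poisson(13), detection 0.6, apparent
#' survival 0.65 responding to drought index (+0.5 per SD) and hot days
#' (-0.4 per SD), and autoregressive recruitment 0.20 per capita collapsing
#' with hot days (-1.0 per SD). Under the packaged weather record the
#' expected trajectory declines roughly seven-fold from the predrought to
#' the during/postdrought period while early-year expected counts sit near 8
#' birds per visit, matching the observed count scale.
#'
#' @param n_sites,n_years,first_year Survey dimensions (49 leks, 12 years
#'   from 2004).
#' @param visits_min,visits_max Per-lek-year visit counts are uniform
#'   integers on this range (1-5).
#' @param family,lambda,psi,alpha Initial-abundance family and parameters.
#' @param dynamics `"constant"` or `"autoregressive"` recruitment.
#' @param gamma0,gamma_covariates Recruitment intercept (response scale) and
#'   named per-SD slopes on year-level weather columns.
#' @param omega0,omega_covariates Apparent survival intercept and named
#'   per-SD slopes.
#' @param p0 Detection intercept (response scale).
#' @param p_rain,p_tmax,p_effort Per-SD detection slopes on daily rainfall,
#'   daily maximum temperature and effort.
#' @param cow_omega,cow_gamma Per-SD grazing (cow days/ha) slopes on survival
#'   and recruitment; a scalar applies to all years, a named
#'   `c(pre = , post = )` pair splits at `drought_year`.
#' @param drought_year The severe-drought year (period split).
#' @param weather_mode `"fixture"` reproduces the packaged record (optionally
#'   jittered); `"free"` draws annual covariates independently around the
#'   fixture moments while keeping the hot-days drought profile.
#' @param weather_jitter SD of fixture-mode Gaussian jitter, as a fraction of
#'   each covariate's interannual SD (default 0: the record is treated as an
#'   observed series).
#' @param n_pastures Number of grazing pastures leks are assigned to.
#' @param seed Mandatory integer seed.
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(n_sites = 49, n_years = 12, first_year = 2004,
                            visits_min = 1, visits_max = 5,
                            family = c("poisson", "zip", "negbin"),
                            lambda = 13, psi = NULL, alpha = NULL,
                            dynamics = c("autoregressive", "constant"),
                            gamma0 = 0.20,
                            gamma_covariates = c(hot_days = -1.0),
                            omega0 = 0.65,
                            omega_covariates = c(pmdi_avg = 0.5,
                                                 hot_days = -0.4),
                            p0 = 0.6, p_rain = 0, p_tmax = 0, p_effort = 0,
                            cow_omega = 0, cow_gamma = 0,
                            drought_year = NULL,
                            weather_mode = c("fixture", "free"),
                            weather_jitter = 0,
                            n_pastures = 10, seed) {
  if (missing(seed)) stop_domain("a seed is mandatory")
  family <- match.arg(family)
  dynamics <- match.arg(dynamics)
  weather_mode <- match.arg(weather_mode)
  years <- first_year + seq_len(n_years) - 1L
  drought_year <- drought_year %||% if (2011 %in% years) 2011 else max(years)
  if (!drought_year %in% years)
    stop_domain("drought_year must be one of the simulated years")
  if (weather_mode == "fixture" && n_years > 12)
    stop_domain("fixture weather covers at most 12 years")
  check_prob(p0, "p0"); check_prob(omega0, "omega0")
  if (family == "zip") check_prob(psi %||% stop_domain("psi required for zip"),
                                  "psi")
  if (family == "negbin" && (is.null(alpha) || alpha <= 0))
    stop_domain("alpha must be positive for negbin")
  if (lambda <= 0) stop_domain("lambda must be positive")
  if (gamma0 < 0) stop_domain("gamma0 must be nonnegative")
  if (visits_min < 0 || visits_max < visits_min)
    stop_domain("invalid visits range")
  structure(list(n_sites = n_sites, n_years = n_years, first_year = first_year,
                 years = years, visits_min = visits_min,
                 visits_max = visits_max, family = family, lambda = lambda,
                 psi = psi, alpha = alpha, dynamics = dynamics,
                 gamma0 = gamma0, gamma_covariates = gamma_covariates,
                 omega0 = omega0, omega_covariates = omega_covariates,
                 p0 = p0, p_rain = p_rain, p_tmax = p_tmax,
                 p_effort = p_effort,
                 cow_omega = split_effect(cow_omega),
                 cow_gamma = split_effect(cow_gamma),
                 drought_year = drought_year, weather_mode = weather_mode,
                 weather_jitter = weather_jitter, n_pastures = n_pastures,
                 seed = as.integer(seed)),
            class = "scenario_config")
}

split_effect <- function(x) {
  if (length(x) == 1) c(pre = unname(x), post = unname(x))
  else c(pre = unname(x[["pre"]]), post = unname(x[["post"]]))
}

sim_annual_weather <- function(cfg) {
  fx <- table1_weather()
  cols <- c("precip_cm", "pmdi_avg", "pmdi_min", "tmax_c", "hot_days")
  n <- cfg$n_years
  out <- data.frame(year = cfg$years)
  if (cfg$weather_mode == "fixture") {
    for (v in cols) {
      x <- fx[[v]][seq_len(n)]
      if (cfg$weather_jitter > 0)
        x <- x + rnorm(n, 0, cfg$weather_jitter * sd(fx[[v]]))
      out[[v]] <- x
    }
  } else {
    for (v in cols) out[[v]] <- rnorm(n, mean(fx[[v]]), sd(fx[[v]]))
    # keep the drought spike profile on hot days; align it with drought_year
    hd <- fx$hot_days[seq_len(min(n, 12))]
    hd <- c(hd, rnorm(max(0, n - 12), mean(fx$hot_days), sd(fx$hot_days)))
    di <- match(cfg$drought_year, cfg$years)
    spike <- which.max(hd)
    hd[c(di, spike)] <- hd[c(spike, di)]
    out$hot_days <- hd
    out$precip_cm <- pmax(out$precip_cm, 5)
    out$hot_days <- pmax(round(out$hot_days), 0)
  }
  out
}

# Monthly precipitation (July-August peak) and drought-index series spanning
# December of the year before the first survey year, so every season and lag
# is complete.
sim_monthly <- function(cfg, annual) {
  w <- c(3, 3, 4, 5, 6, 7, 14, 16, 10, 6, 4, 3); w <- w / sum(w)
  years <- c(cfg$first_year - 1L, cfg$years)
  precip <- pmdi <- NULL
  for (y in years) {
    i <- match(y, annual$year)
    a <- if (is.na(i)) mean(annual$precip_cm) else annual$precip_cm[i]
    pa <- if (is.na(i)) mean(annual$pmdi_avg) else annual$pmdi_avg[i]
    mw <- w * exp(rnorm(12, 0, 0.3)); mw <- mw / sum(mw)
    precip <- rbind(precip, data.frame(year = y, month = 1:12, value = a * mw))
    pmdi <- rbind(pmdi, data.frame(year = y, month = 1:12,
                                   value = pa + rnorm(12, 0, 0.4)))
  }
  list(precip = precip, pmdi = pmdi)
}

seasonal_columns <- function(monthly, years) {
  seasons <- c("winter", "breeding", "summer", "fall")
  out <- data.frame(year = years)
  for (s in seasons) {
    out[[paste0("rain_", s)]] <- vapply(years, function(y)
      seasonal_aggregate(monthly$precip, s, y, "total"), numeric(1))
    out[[paste0("pmdi_", s)]] <- vapply(years, function(y)
      seasonal_aggregate(monthly$pmdi, s, y, "mean"), numeric(1))
  }
  out
}

sim_grazing <- function(cfg) {
  fx <- table1_weather()
  mu <- fx$cow_days_mean[seq_len(min(cfg$n_years, 12))]
  sdv <- fx$cow_days_sd[seq_len(min(cfg$n_years, 12))]
  if (cfg$n_years > 12) {
    mu <- c(mu, rep(NA, cfg$n_years - 12)); sdv <- c(sdv, rep(NA, cfg$n_years - 12))
  }
  recorded <- !is.na(mu)
  mu[!recorded] <- if (any(recorded)) mean(mu, na.rm = TRUE) else 1.0
  sdv[is.na(sdv)] <- if (any(!is.na(sdv))) mean(sdv, na.rm = TRUE) else 0.5
  P <- min(cfg$n_pastures, cfg$n_sites)
  pasture_of <- rep_len(seq_len(P), cfg$n_sites)
  area <- 730; days <- 60
  n_cattle <- matrix(0L, P, cfg$n_years)
  for (t in seq_len(cfg$n_years)) {
    target <- pmax(0.05, rnorm(P, mu[t], sdv[t]))
    n_cattle[, t] <- pmax(1L, as.integer(round(target * area / days)))
  }
  cow_pasture <- n_cattle * days / area                  # true cow days/ha
  cow_site <- cow_pasture[pasture_of, , drop = FALSE]
  dimnames(cow_site) <- list(NULL, cfg$years)
  rows <- expand.grid(pasture = seq_len(P), t = seq_len(cfg$n_years))
  rows <- rows[recorded[rows$t], , drop = FALSE]
  grazing <- do.call(rbind, lapply(seq_len(nrow(rows)), function(r) {
    pa <- rows$pasture[r]; t <- rows$t[r]
    leks <- which(pasture_of == pa)
    data.frame(pasture_id = paste0("P", pa),
               lek_id = sprintf("L%02d", leks),
               year = cfg$years[t], n_cattle = n_cattle[pa, t],
               days_grazed = days, area_ha = area)
  }))
  list(grazing = grazing, cow_site = cow_site, recorded = recorded,
       pasture_of = pasture_of)
}

#' Simulate a lek-count dataset with known truth
#'
#' Draws a complete dataset under the generating process the model assumes
#' (see [scenario_config()]) and returns the counts, the covariate table, and
#' the full latent truth so recovery tests never need to re-simulate.
#' Identical seeds give bit-identical output.
#'
#' @param config A [scenario_config()].
#' @return Object of class `lek_simulation`: list with `data`
#'   ([lek_count_data()]), `covs` ([covariate_table()]), `grazing` (the
#'   pasture records data frame), `truth` (latent `N` matrix, per-transition
#'   `omega`/`gamma`, per-visit detection, true cow days, the weather table)
#'   and the echoed `config`.
#' @export
simulate_lek_counts <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  cfg <- config
  with_seed(cfg$seed, {
    M <- cfg$n_sites; T <- cfg$n_years
    annual <- sim_annual_weather(cfg)
    monthly <- sim_monthly(cfg, annual)
    year_df <- merge(annual, seasonal_columns(monthly, cfg$years),
                     by = "year")
    gz <- sim_grazing(cfg)

    zyr <- function(v) (v - mean(v)) / max(sd(v), 1e-12)
    zcov <- list()
    for (nm in union(names(cfg$gamma_covariates), names(cfg$omega_covariates))) {
      if (!nm %in% names(year_df))
        stop_domain("unknown generating covariate '", nm, "'")
      zcov[[nm]] <- zyr(year_df[[nm]])
    }
    zcow <- (gz$cow_site - mean(gz$cow_site)) / max(sd(gz$cow_site), 1e-12)
    post_period <- cfg$years >= cfg$drought_year

    eta_g <- rep(log(max(cfg$gamma0, 1e-12)), T)
    for (nm in names(cfg$gamma_covariates))
      eta_g <- eta_g + cfg$gamma_covariates[[nm]] * zcov[[nm]]
    eta_w <- rep(qlogis(cfg$omega0), T)
    for (nm in names(cfg$omega_covariates))
      eta_w <- eta_w + cfg$omega_covariates[[nm]] * zcov[[nm]]
    cow_g <- ifelse(post_period, cfg$cow_gamma[["post"]], cfg$cow_gamma[["pre"]])
    cow_w <- ifelse(post_period, cfg$cow_omega[["post"]], cfg$cow_omega[["pre"]])
    gamma_mat <- exp(matrix(eta_g, M, T, byrow = TRUE) +
                       sweep(zcow, 2, cow_g, `*`))
    omega_mat <- plogis(matrix(eta_w, M, T, byrow = TRUE) +
                          sweep(zcow, 2, cow_w, `*`))

    N <- matrix(0L, M, T)
    N[, 1] <- switch(cfg$family,
      poisson = rpois(M, cfg$lambda),
      zip = ifelse(runif(M) < cfg$psi, 0L, rpois(M, cfg$lambda)),
      negbin = rnbinom(M, size = cfg$alpha, mu = cfg$lambda))
    if (T > 1) for (t in 2:T) {
      S <- rbinom(M, N[, t - 1], omega_mat[, t])
      rate <- if (cfg$dynamics == "autoregressive")
        gamma_mat[, t] * N[, t - 1] else gamma_mat[, t]
      N[, t] <- S + rpois(M, rate)
    }

    J <- matrix(sample(cfg$visits_min:cfg$visits_max, M * T, replace = TRUE),
                M, T)
    Jmax <- max(J, 1L)
    y <- rain <- tmax <- parr <- array(NA_real_, c(M, T, Jmax))
    for (i in seq_len(M)) for (t in seq_len(T)) {
      if (J[i, t] == 0) next
      j <- seq_len(J[i, t])
      rain[i, t, j] <- round(pmax(0, rnorm(J[i, t], 0.15, 0.25)), 2)
      tmax[i, t, j] <- round(rnorm(J[i, t], 21, 5), 1)
    }
    vis <- which(!is.na(rain))
    zr <- zscore(rain[vis])$z
    zt <- zscore(tmax[vis])$z
    zeff <- zscore(J[arrayInd(vis, dim(rain))[, 1:2, drop = FALSE]])$z
    eta_p <- qlogis(cfg$p0)
    pvis <- plogis(eta_p + cfg$p_rain * zr + cfg$p_tmax * zt +
                     cfg$p_effort * zeff)
    parr[vis] <- pvis
    Nrep <- N[arrayInd(vis, dim(y))[, 1:2]]
    y[vis] <- rbinom(length(vis), Nrep, pvis)

    sites <- sprintf("L%02d", seq_len(M))
    data <- new_lek_count_data(y, rain, tmax, sites, cfg$years)
    recorded_cow <- gz$cow_site
    recorded_cow[, !gz$recorded] <- NA_real_
    rownames(recorded_cow) <- sites
    covs <- covariate_table(year_df,
                            site_year = list(cow_days = recorded_cow))
    truth <- list(N = `dimnames<-`(N, list(sites, cfg$years)),
                  omega = omega_mat[, -1, drop = FALSE],
                  gamma = gamma_mat[, -1, drop = FALSE],
                  p = parr, cow_days = gz$cow_site,
                  pasture_of = gz$pasture_of, weather = year_df)
    structure(list(data = data, covs = covs, grazing = gz$grazing,
                   truth = truth, config = cfg),
              class = "lek_simulation")
  })
}

#' @export
print.lek_simulation <- function(x, ...) {
  cat(sprintf("Simulated lek survey (seed %d): %d leks x %d years, %s/%s\n",
              x$config$seed, x$config$n_sites, x$config$n_years,
              x$config$family, x$config$dynamics))
  print(x$data)
  invisible(x)
}
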