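# Staged AIC model building: (1) pick the count distribution from null
# models, (2) screen detection covariates on the global detection model,
# (3) test the prior-year maximum count as an initial-abundance predictor,
# (4) scan single weather covariates on recruitment (autoregressive dynamics)
# or survival (constant dynamics); a parallel scan handles grazing pressure
# split into pre- and post-drought periods.

#' Akaike weights
#'
#' `w_i = exp(-delta_i / 2) / sum_k exp(-delta_k / 2)` with
#' `delta_i = AIC_i - min(AIC)`.
#'
#' @param aic Vector of finite AIC (or AICc) values.
#' @return Weights summing to 1.
#' @examples
#' akaike_weights(c(100, 102))
#' @export
akaike_weights <- function(aic) {
  if (!length(aic)) stop_domain("empty AIC vector")
  if (any(!is.finite(aic))) stop_domain("AIC values must be finite")
  w <- exp(-(aic - min(aic)) / 2)
  w / sum(w)
}

rank_key <- function(rank_by) match.arg(rank_by, c("aic", "aicc"))

#' Step 1: choose the count distribution
#'
#' Fits intercept-only null models (constant dynamics) under the Poisson,
#' zero-inflated Poisson and negative binomial initial-abundance families and
#' ranks them by AIC. Ties break toward fewer parameters, so the Poisson wins
#' an exact tie against either mixture. Non-converged nulls are excluded with
#' a warning; if all fail, an error is raised.
#'
#' @param data,covs Counts and covariates.
#' @param rank_by `"aic"` (default, the methods choice) or `"aicc"`.
#' @param ... Passed to [fit_nmix()].
#' @return List with `family` (the winner), `table` (ranked AIC table) and
#'   `fits`.
#' @export
step1_distribution <- function(data, covs = NULL, rank_by = "aic", ...) {
  rank_by <- rank_key(rank_by)
  fams <- c("poisson", "zip", "negbin")
  fits <- lapply(fams, function(f)
    tryCatch(fit_nmix(data, covs, nmix_spec(f, "constant"), ...),
             error = function(e) e))
  names(fits) <- fams
  failed <- vapply(fits, inherits, TRUE, "error")
  conv <- !failed & vapply(fits, function(f)
    if (inherits(f, "error")) FALSE else f$converged, TRUE)
  if (!any(conv)) stop("no null model converged", call. = FALSE)
  if (any(!conv))
    warning("null model(s) excluded as non-converged: ",
            paste(fams[!conv], collapse = ", "))
  tab <- data.frame(family = fams[conv],
                    n_params = vapply(fits[conv], `[[`, numeric(1), "n_params"),
                    aic = vapply(fits[conv], `[[`, numeric(1), "aic"),
                    aicc = vapply(fits[conv], `[[`, numeric(1), "aicc"))
  tab$delta <- tab[[rank_by]] - min(tab[[rank_by]])
  tab <- tab[order(tab$delta, tab$n_params, tab$family), ]
  tab$weight <- akaike_weights(tab[[rank_by]])
  rownames(tab) <- NULL
  list(family = tab$family[1], table = tab, fits = fits)
}

ci_excludes_zero <- function(lcl, ucl) {
  is.finite(lcl) & is.finite(ucl) & (lcl > 0 | ucl < 0)
}

slope_row <- function(fit, block, covariate) {
  j <- fit$prep$idx[[block]]
  lab <- sub(paste0("^", block, "_"), "", fit$prep$par_names[j])
  j <- j[lab == covariate]
  if (!length(j)) return(data.frame(beta = NA_real_, se = NA_real_,
                                    lcl = NA_real_, ucl = NA_real_))
  data.frame(beta = unname(fit$theta[j]), se = unname(fit$se[j]),
             lcl = unname(fit$ci95[j, 1]), ucl = unname(fit$ci95[j, 2]))
}

#' Step 2: screen detection covariates on the global model
#'
#' Fits the global detection model (daily rainfall, daily maximum temperature
#' and effort on detection) once and retains the covariates whose Wald 95%
#' confidence interval excludes 0. The screen is single-pass: there is no
#' drop-and-refit iteration. An interval exactly touching 0 counts as
#' overlapping (dropped). If the global model does not converge, the screen
#' falls back to intercept-only detection with a warning.
#'
#' @param data,covs Counts and covariates.
#' @param family Initial-abundance family from [step1_distribution()].
#' @param ... Passed to [fit_nmix()].
#' @return List with `retained` (character vector), `table` (per-covariate
#'   beta and CI) and `fit`.
#' @export
step2_screen_detection <- function(data, covs = NULL, family = "poisson", ...) {
  candidates <- c("rain", "tmax", "effort")
  fit <- tryCatch(
    fit_nmix(data, covs, nmix_spec(family, "constant",
                                   p_covariates = candidates), ...),
    error = function(e) e)
  if (inherits(fit, "error") || !fit$converged) {
    warning("global detection model did not converge; ",
            "falling back to intercept-only detection")
    return(list(retained = character(),
                table = data.frame(covariate = candidates, beta = NA_real_,
                                   se = NA_real_, lcl = NA_real_,
                                   ucl = NA_real_, retained = FALSE),
                fit = if (inherits(fit, "error")) NULL else fit))
  }
  kept <- setdiff(candidates, sub("^p\\.", "", fit$prep$dropped))
  tab <- do.call(rbind, lapply(kept, function(nm)
    cbind(covariate = nm, slope_row(fit, "p", nm))))
  tab$retained <- ci_excludes_zero(tab$lcl, tab$ucl)
  list(retained = tab$covariate[tab$retained], table = tab, fit = fit)
}

#' Step 3: prior-year count as an initial-abundance predictor
#'
#' Uses the maximum count on each lek in the first season as a predictor of
#' initial abundance for the remaining years: the data are trimmed to years
#' 2..T, the prior count enters the lambda design z-scored (sites with no
#' first-season visits are imputed at the covariate mean and flagged), and
#' the covariate is retained when its Wald 95% CI excludes 0, exactly as in
#' step 2.
#'
#' @param data,covs Counts and covariates.
#' @param family Initial-abundance family.
#' @param detection Retained detection covariates from step 2.
#' @param ... Passed to [fit_nmix()].
#' @return List with `retained` (logical), `fit`, `table`, the trimmed
#'   `data`, updated `covs`, and `prior` (the covariate, `NA` where missing).
#'   When no site has a prior-year count the step is skipped with a message
#'   and the data are returned untrimmed.
#' @export
step3_initial_abundance <- function(data, covs = NULL, family = "poisson",
                                    detection = character(), ...) {
  T <- length(data$years)
  if (T < 3) stop_domain("need at least 3 years to spare one for the prior count")
  prior <- apply(data$y[, 1, , drop = FALSE], 1, function(v)
    if (all(is.na(v))) NA_real_ else max(v, na.rm = TRUE))
  if (all(is.na(prior))) {
    message("no site has a prior-year count; step skipped")
    return(list(retained = FALSE, skipped = TRUE, fit = NULL,
                table = NULL, data = data, covs = covs, prior = prior))
  }
  trimmed <- trim_years(data, data$years[-1])
  covs2 <- covs %||% covariate_table(data.frame(year = data$years))
  covs2$site$prior_count <- prior
  if (sd(prior, na.rm = TRUE) == 0 || sum(!is.na(prior)) < 2) {
    warning("prior-year counts are constant; covariate dropped")
    return(list(retained = FALSE, skipped = FALSE, fit = NULL, table = NULL,
                data = trimmed, covs = covs2, prior = prior))
  }
  fit <- fit_nmix(trimmed, covs2,
                  nmix_spec(family, "constant",
                            lambda_covariates = "prior_count",
                            p_covariates = detection), ...)
  tab <- cbind(covariate = "prior_count", slope_row(fit, "lambda", "prior_count"))
  retained <- fit$converged && ci_excludes_zero(tab$lcl, tab$ucl)
  tab$retained <- retained
  list(retained = retained, skipped = FALSE, fit = fit, table = tab,
       data = trimmed, covs = covs2, prior = prior)
}

#' Weather covariate menu
#'
#' The candidate set for the demographic scans: five annual variables
#' (precipitation, average PMDI, minimum PMDI, maximum temperature, hot days)
#' in the same year and with a 1-year lag (10 covariates, hence 20 models
#' over the two demographic processes), plus seasonal precipitation totals
#' and seasonal mean PMDI for winter, breeding, summer and fall in the same
#' year, and summer/fall with a 1-year lag (no winter or breeding-season
#' lags: weather more than ~9 months old is assumed not to act).
#'
#' @param seasonal Include the seasonal block (default `TRUE`).
#' @return Data frame with columns `covariate` (the design column name, lags
#'   carrying the `_lag1` suffix) and `period`.
#' @export
weather_candidates <- function(seasonal = TRUE) {
  annual <- c("precip_cm", "pmdi_avg", "pmdi_min", "tmax_c", "hot_days")
  out <- data.frame(covariate = c(annual, paste0(annual, "_lag1")),
                    period = rep(c("same year", "year before"), each = 5))
  if (seasonal) {
    same <- as.vector(outer(c("rain_", "pmdi_"),
                            c("winter", "breeding", "summer", "fall"),
                            paste0))
    lagged <- as.vector(outer(c("rain_", "pmdi_"), c("summer", "fall"),
                              function(a, b) paste0(a, b, "_lag1")))
    out <- rbind(out,
                 data.frame(covariate = same, period = "same year"),
                 data.frame(covariate = lagged, period = "year before"))
  }
  out
}

#' Step 4: single-covariate demographic scan
#'
#' Fits one model per candidate covariate on the given demographic process:
#' recruitment models use autoregressive dynamics, survival models constant
#' dynamics, and each model carries exactly one demographic covariate. Models
#' are ranked by AIC (or AICc); ties break by fewer parameters then covariate
#' name; non-converged candidates are flagged, given zero weight and ranked
#' last.
#'
#' @param data,covs Counts and covariates.
#' @param base_spec An [nmix_spec()] carrying the chosen family, detection
#'   set and any initial-abundance covariates; its dynamics and demographic
#'   covariates are overridden per candidate.
#' @param process `"recruitment"` or `"survival"`.
#' @param candidates Data frame from [weather_candidates()], or a character
#'   vector of covariate names.
#' @param rank_by `"aic"` or `"aicc"`.
#' @param starts Optimizer starts for the shared null model; candidates are
#'   warm-started from its optimum with a single start.
#' @param ... Passed to [fit_nmix()].
#' @return A `candidate_table` data frame; fitted models in
#'   `attr(, "fits")`.
#' @export
step4_demographic_scan <- function(data, covs, base_spec,
                                   process = c("recruitment", "survival"),
                                   candidates = weather_candidates(),
                                   rank_by = "aic", starts = 3, ...) {
  process <- match.arg(process)
  rank_by <- rank_key(rank_by)
  if (is.character(candidates))
    candidates <- data.frame(covariate = candidates,
                             period = ifelse(grepl("_lag1$", candidates),
                                             "year before", "same year"))
  # candidate models share the null's structure; warm-start from its optimum
  null_spec <- base_spec
  null_spec$dynamics <- if (process == "recruitment") "autoregressive"
                        else "constant"
  null_spec$gamma_covariates <- character()
  null_spec$omega_covariates <- character()
  null_fit <- tryCatch(fit_nmix(data, covs, null_spec, starts = starts, ...),
                       error = function(e) NULL)
  warm <- if (!is.null(null_fit)) null_fit$theta else NULL
  cand_starts <- if (is.null(warm)) starts else 1
  rows <- list(); fits <- list()
  for (r in seq_len(nrow(candidates))) {
    cv <- candidates$covariate[r]
    spec <- base_spec
    if (process == "recruitment") {
      spec$dynamics <- "autoregressive"
      spec$gamma_covariates <- cv
      spec$omega_covariates <- character()
    } else {
      spec$dynamics <- "constant"
      spec$omega_covariates <- cv
      spec$gamma_covariates <- character()
    }
    fit <- tryCatch(fit_nmix(data, covs, spec, start = warm,
                             starts = cand_starts, ...),
                    error = function(e) e)
    if (cand_starts == 1 &&
        (inherits(fit, "error") || !fit$converged)) {
      # warm single-start stalled; retry cold with the full multistart
      retry <- tryCatch(fit_nmix(data, covs, spec, starts = starts, ...),
                        error = function(e) e)
      if (!inherits(retry, "error") &&
          (inherits(fit, "error") || retry$nll <= fit$nll || retry$converged))
        fit <- retry
    }
    if (inherits(fit, "error")) {
      rows[[r]] <- data.frame(process = process, covariate = cv,
                              period = candidates$period[r],
                              n_params = NA, aic = NA, aicc = NA,
                              beta = NA, se = NA, lcl = NA, ucl = NA,
                              converged = FALSE)
      next
    }
    fits[[cv]] <- fit
    block <- if (process == "recruitment") "gamma" else "omega"
    sr <- slope_row(fit, block, cv)
    rows[[r]] <- data.frame(process = process, covariate = cv,
                            period = candidates$period[r],
                            n_params = fit$n_params, aic = fit$aic,
                            aicc = fit$aicc, sr, converged = fit$converged)
  }
  tab <- do.call(rbind, rows)
  finish_candidate_table(tab, rank_by, fits)
}

finish_candidate_table <- function(tab, rank_by, fits) {
  ok <- tab$converged & is.finite(tab[[rank_by]])
  tab$delta <- NA_real_
  if (any(ok)) tab$delta[ok] <- tab[[rank_by]][ok] - min(tab[[rank_by]][ok])
  tab$weight <- 0
  if (any(ok)) tab$weight[ok] <- akaike_weights(tab[[rank_by]][ok])
  if ("process" %in% names(tab)) {
    tab$weight_process <- 0
    for (pr in unique(tab$process)) {
      sel <- ok & tab$process == pr
      if (any(sel)) tab$weight_process[sel] <- akaike_weights(tab[[rank_by]][sel])
    }
  }
  tab <- tab[order(!ok, tab$delta, tab$n_params, tab$covariate), ]
  rownames(tab) <- NULL
  attr(tab, "fits") <- fits
  attr(tab, "rank_by") <- rank_by
  class(tab) <- c("candidate_table", "data.frame")
  tab
}

#' @export
print.candidate_table <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, ...)
  invisible(x)
}

#' Combined weather scan over both demographic processes
#'
#' Runs [step4_demographic_scan()] for recruitment and survival over the same
#' candidate menu and ranks all models jointly; Akaike weights are reported
#' both over the full set (`weight`) and within each process
#' (`weight_process`).
#'
#' @inheritParams step4_demographic_scan
#' @return A `candidate_table` covering both processes.
#' @export
weather_scan <- function(data, covs, base_spec,
                         candidates = weather_candidates(),
                         rank_by = "aic", starts = 3, ...) {
  rank_by <- rank_key(rank_by)
  rec <- step4_demographic_scan(data, covs, base_spec, "recruitment",
                                candidates, rank_by, starts, ...)
  sur <- step4_demographic_scan(data, covs, base_spec, "survival",
                                candidates, rank_by, starts, ...)
  tab <- rbind(as.data.frame(rec), as.data.frame(sur))
  tab$delta <- tab$weight <- tab$weight_process <- NULL
  fits <- c(setNames(attr(rec, "fits"),
                     paste0("recruitment.", names(attr(rec, "fits")))),
            setNames(attr(sur, "fits"),
                     paste0("survival.", names(attr(sur, "fits")))))
  finish_candidate_table(tab, rank_by, fits)
}

#' Grazing scan split into pre- and post-drought periods
#'
#' Partitions the counts at `split_year` (years before it are predrought,
#' `split_year` and later during/postdrought) and, within each period, fits
#' cow days/ha on recruitment (autoregressive dynamics) and on survival
#' (constant dynamics). Years whose grazing record is entirely missing are
#' dropped from the leading edge of a period or, in the interior, have their
#' counts marked missing, so an unrecorded year never contributes counts to
#' the grazing assessment.
#'
#' @param data,covs Counts and covariates; `covs$site_year$cow_days` must
#'   exist (see [cow_days_table()]).
#' @param split_year First during/postdrought year (2011 for the original
#'   design).
#' @param rank_by `"aic"` or `"aicc"`.
#' @param ... Passed to [fit_nmix()].
#' @return List with `candidate_table`s `predrought` and `postdrought`.
#' @export
grazing_scan <- function(data, covs, split_year = 2011, rank_by = "aic", ...) {
  rank_by <- rank_key(rank_by)
  cd <- covs$site_year$cow_days
  if (is.null(cd)) stop_domain("covs$site_year$cow_days is required")
  scan_period <- function(years, label) {
    if (length(years) < 3)
      stop_domain("the ", label, " period has fewer than 3 years; ",
                  "dynamics are unidentifiable")
    cols <- match(years, data$years)
    sub_cd <- cd[, match(years, colnames(cd)), drop = FALSE]
    missing_year <- apply(sub_cd, 2, function(v) all(is.na(v)))
    if (all(missing_year))
      stop_domain("grazing records are entirely missing in the ", label,
                  " period")
    while (length(years) && missing_year[1]) {        # drop leading gap years
      years <- years[-1]; missing_year <- missing_year[-1]
      sub_cd <- sub_cd[, -1, drop = FALSE]
    }
    if (length(years) < 3)
      stop_domain("the ", label, " period has fewer than 3 usable years")
    sub <- trim_years(data, years)
    if (any(missing_year)) sub <- mask_years(sub, years[missing_year])
    covs2 <- covs
    covs2$site_year$cow_days <- sub_cd
    base <- nmix_spec("poisson", "constant")
    rows <- list(); fits <- list()
    for (pr in c("recruitment", "survival")) {
      spec <- base
      if (pr == "recruitment") {
        spec$dynamics <- "autoregressive"; spec$gamma_covariates <- "cow_days"
      } else {
        spec$dynamics <- "constant"; spec$omega_covariates <- "cow_days"
      }
      fit <- fit_nmix(sub, covs2, spec, ...)
      fits[[pr]] <- fit
      block <- if (pr == "recruitment") "gamma" else "omega"
      rows[[pr]] <- data.frame(process = pr, covariate = "cow_days",
                               period = label, n_params = fit$n_params,
                               aic = fit$aic, aicc = fit$aicc,
                               slope_row(fit, block, "cow_days"),
                               converged = fit$converged)
    }
    finish_candidate_table(do.call(rbind, rows), rank_by, fits)
  }
  list(predrought = scan_period(data$years[data$years < split_year],
                                "predrought"),
       postdrought = scan_period(data$years[data$years >= split_year],
                                 "postdrought"))
}

#' Run the full four-step model-building workflow
#'
#' Chains [step1_distribution()], [step2_screen_detection()],
#' [step3_initial_abundance()] and the combined [weather_scan()], returning
#' every intermediate table plus the AIC-best weather model refitted on the
#' working data.
#'
#' @param data,covs Counts and covariates.
#' @param candidates Weather menu (see [weather_candidates()]).
#' @param rank_by `"aic"` or `"aicc"`.
#' @param ... Passed to [fit_nmix()].
#' @return List with elements `step1`, `step2`, `step3`, `weather`
#'   (candidate table), `best_fit`, `data`, `covs`, `base_spec`.
#' @export
four_step_selection <- function(data, covs,
                                candidates = weather_candidates(),
                                rank_by = "aic", ...) {
  s1 <- step1_distribution(data, covs, rank_by = rank_by, ...)
  s2 <- step2_screen_detection(data, covs, family = s1$family, ...)
  s3 <- step3_initial_abundance(data, covs, family = s1$family,
                                detection = s2$retained, ...)
  wdata <- s3$data; wcovs <- s3$covs
  base_spec <- nmix_spec(s1$family, "constant",
                         lambda_covariates = if (isTRUE(s3$retained))
                           "prior_count" else character(),
                         p_covariates = s2$retained)
  scan <- weather_scan(wdata, wcovs, base_spec, candidates, rank_by, ...)
  best_key <- paste0(ifelse(scan$process[1] == "recruitment",
                            "recruitment.", "survival."), scan$covariate[1])
  list(step1 = s1, step2 = s2, step3 = s3, weather = scan,
       best_fit = attr(scan, "fits")[[best_key]],
       data = wdata, covs = wcovs, base_spec = base_spec)
}
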