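# Plain-CSV readers/writers (missing cells are empty strings, never sentinel
# numbers) and the config-driven workflow commands behind the CLI script at
# inst/cli/lekdyn.R.

NA_STRINGS <- c("", "NA")

#' Read a long-format lek-count CSV
#'
#' Expected columns: `lek_id`, `year`, `visit`, `date` (optional, ISO-8601),
#' `count`, `daily_rain_cm`, `daily_tmax_c`. Schema violations are reported
#' with row numbers.
#'
#' @param path CSV file path.
#' @return A [lek_count_data()] object.
#' @export
read_counts <- function(path) {
  df <- read.csv(path, na.strings = NA_STRINGS)
  need <- c("lek_id", "year", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain("counts file lacks columns: ", paste(miss, collapse = ", "))
  if (!is.numeric(df$year) || anyNA(df$year))
    stop_domain("non-numeric or missing year at rows: ",
                paste(head(which(is.na(suppressWarnings(as.numeric(df$year)))), 5),
                      collapse = ", "))
  if ("date" %in% names(df)) {
    d <- as.Date(as.character(df$date), format = "%Y-%m-%d")
    bad <- which(!is.na(df$date) & is.na(d))
    if (length(bad))
      stop_domain("malformed date (expect ISO-8601) at rows: ",
                  paste(head(bad, 5), collapse = ", "))
  }
  lek_count_data(df)
}

#' Write lek-count data to CSV
#' @param data A `lek_count_data` object.
#' @param path Output path.
#' @export
write_counts <- function(data, path) {
  write.csv(as.data.frame(data), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a year-level covariate CSV
#' @param path CSV with a `year` column plus numeric covariates.
#' @param lag Add `_lag1` columns (see [covariate_table()]).
#' @return A data frame (pass to [covariate_table()]).
#' @export
read_year_covariates <- function(path, lag = FALSE) {
  df <- read.csv(path, na.strings = NA_STRINGS)
  if (!"year" %in% names(df)) stop_domain("covariate file needs a 'year' column")
  df
}

#' Read pasture-level grazing records
#' @param path CSV with columns `pasture_id`, `lek_id`, `year`, `n_cattle`,
#'   `days_grazed`, `area_ha`.
#' @return Data frame.
#' @export
read_grazing <- function(path) {
  df <- read.csv(path, na.strings = NA_STRINGS)
  need <- c("pasture_id", "lek_id", "year", "n_cattle", "days_grazed",
            "area_ha")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_domain("grazing file lacks columns: ", paste(miss, collapse = ", "))
  df
}

#' Serialize a fitted model to JSON
#'
#' Writes estimates, standard errors, the covariance matrix, nll, AIC/AICc
#' and convergence diagnostics.
#'
#' @param fit An `nmix_fit`.
#' @param path Output path.
#' @export
write_fit_json <- function(fit, path) {
  obj <- list(family = fit$spec$family, dynamics = fit$spec$dynamics,
              estimates = as.list(fit$theta), se = as.list(fit$se),
              vcov = fit$vcov, nll = fit$nll, aic = fit$aic,
              aicc = fit$aicc, n_params = fit$n_params, n_obs = fit$n_obs,
              converged = fit$converged, hessian_pd = fit$hessian_pd,
              ci95 = fit$ci95)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' Flat coefficient table for a fitted model
#' @param fit An `nmix_fit`.
#' @param path Output CSV path.
#' @export
write_coef_csv <- function(fit, path) {
  df <- data.frame(parameter = names(fit$theta), estimate = fit$theta,
                   se = fit$se, lcl = fit$ci95[, 1], ucl = fit$ci95[, 2])
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write a candidate table as CSV (ranked-model layout)
#' @param tab A `candidate_table`.
#' @param path Output CSV path.
#' @export
write_candidate_csv <- function(tab, path) {
  df <- as.data.frame(tab)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write an abundance series to CSV
#' @param series An `abundance_series`.
#' @param site_path,year_path Output paths for the site-level and year-level
#'   summaries.
#' @export
write_series_csv <- function(series, site_path, year_path) {
  write.csv(series$site, site_path, row.names = FALSE, na = "")
  write.csv(series$year, year_path, row.names = FALSE, na = "")
  invisible(c(site_path, year_path))
}

#' Figure-style abundance plot
#'
#' Year versus mean estimated abundance with interval bars and shading of the
#' during/postdrought period.
#'
#' @param series An `abundance_series` with year-level intervals.
#' @param split_year First during/postdrought year.
#' @param path Optional PNG path; when given the plot is written there.
#' @export
plot_abundance <- function(series, split_year = 2011, path = NULL) {
  yr <- series$year
  if (!is.null(path)) {
    grDevices::png(path, width = 800, height = 500)
    on.exit(grDevices::dev.off())
  }
  ylim <- c(0, max(yr$hi95 %||% yr$mean, yr$mean, na.rm = TRUE) * 1.05)
  plot(yr$year, yr$mean, type = "n", ylim = ylim,
       xlab = "Year", ylab = "Mean estimated abundance per lek")
  graphics::rect(split_year - 0.5, ylim[1], max(yr$year) + 0.5, ylim[2],
                 col = "grey92", border = NA)
  if (!is.null(yr$lo95))
    graphics::arrows(yr$year, yr$lo95, yr$year, yr$hi95, angle = 90,
                     code = 3, length = 0.04)
  graphics::points(yr$year, yr$mean, pch = 19, type = "b")
  invisible(series)
}

read_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop_domain("config must be a list or a YAML path")
  config
}

echo_config <- function(config, out_dir, name = "config.json") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(config, file.path(out_dir, name), auto_unbox = TRUE,
                       digits = NA, na = "null")
  writeLines(c(paste("lekdyn", as.character(utils::packageVersion("lekdyn"))),
               paste("R", paste(R.version$major, R.version$minor, sep = ".")),
               paste("time", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out_dir, "run-info.txt"))
}

take_keys <- function(config, allowed, where) {
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop_domain("unknown ", where, " config keys: ",
                paste(unknown, collapse = ", "))
  config
}

#' Workflow command: simulate a dataset to disk
#'
#' Writes `counts.csv`, `year_covariates.csv`, `grazing.csv`, `truth.csv`
#' and a JSON echo of the scenario configuration. Identical seeds give
#' byte-identical files.
#'
#' @param config List (or YAML path) of [scenario_config()] arguments;
#'   unknown keys are rejected.
#' @param out_dir Output directory (created if needed).
#' @return The simulation object, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  config <- read_config(config)
  cfg <- do.call(scenario_config, config)
  sim <- simulate_lek_counts(cfg)
  echo_config(unclass(cfg), out_dir)
  write_counts(sim$data, file.path(out_dir, "counts.csv"))
  write.csv(sim$covs$year, file.path(out_dir, "year_covariates.csv"),
            row.names = FALSE, na = "")
  write.csv(sim$grazing, file.path(out_dir, "grazing.csv"),
            row.names = FALSE, na = "")
  tr <- as.data.frame(as.table(sim$truth$N))
  names(tr) <- c("site", "year", "N_true")
  write.csv(tr[order(tr$site, tr$year), ], file.path(out_dir, "truth.csv"),
            row.names = FALSE, na = "")
  invisible(sim)
}

load_inputs <- function(config) {
  data <- read_counts(config$counts)
  year_df <- if (!is.null(config$year_covariates))
    read_year_covariates(config$year_covariates)
  else data.frame(year = data$years)
  site_year <- list()
  if (!is.null(config$grazing)) {
    gz <- read_grazing(config$grazing)
    site_year$cow_days <- cow_days_table(gz, data$sites, data$years)
  }
  list(data = data, covs = covariate_table(year_df, site_year = site_year))
}

spec_from_config <- function(model) {
  model <- model %||% list()
  take_keys(model, c("family", "dynamics", "lambda_covariates",
                     "gamma_covariates", "omega_covariates", "p_covariates",
                     "K"), "model")
  nmix_spec(family = model$family %||% "poisson",
            dynamics = model$dynamics %||% "constant",
            lambda_covariates = model$lambda_covariates %||% character(),
            gamma_covariates = model$gamma_covariates %||% character(),
            omega_covariates = model$omega_covariates %||% character(),
            p_covariates = model$p_covariates %||% character(),
            K = model$K)
}

#' Workflow command: fit one model to disk inputs
#'
#' @param config List or YAML path with keys `counts`, `year_covariates`
#'   (optional), `grazing` (optional), `model` (an [nmix_spec()] argument
#'   list), `seed`, `starts`.
#' @param out_dir Output directory; receives `fit.json` and
#'   `coefficients.csv`.
#' @return The `nmix_fit`, invisibly.
#' @export
run_fit <- function(config, out_dir) {
  config <- read_config(config)
  take_keys(config, c("counts", "year_covariates", "grazing", "model",
                      "seed", "starts"), "fit")
  inp <- load_inputs(config)
  fit <- fit_nmix(inp$data, inp$covs, spec_from_config(config$model),
                  starts = config$starts %||% 3,
                  seed = config$seed %||% 1L)
  echo_config(config, out_dir)
  write_fit_json(fit, file.path(out_dir, "fit.json"))
  write_coef_csv(fit, file.path(out_dir, "coefficients.csv"))
  invisible(fit)
}

#' Workflow command: staged model selection to disk
#'
#' Runs the four-step workflow (distribution, detection screen, prior-count
#' screen, weather scan) and, when grazing records are supplied, the
#' pre/post-drought grazing scan; writes ranked candidate CSVs.
#'
#' @param config List or YAML path with input paths plus `rank_by`
#'   (aic/aicc), `split_year`, `seasonal` (include seasonal candidates),
#'   `seed`, `starts`.
#' @param out_dir Output directory.
#' @return The selection result list, invisibly.
#' @export
run_select <- function(config, out_dir) {
  config <- read_config(config)
  take_keys(config, c("counts", "year_covariates", "grazing", "rank_by",
                      "split_year", "seasonal", "seed", "starts"), "select")
  inp <- load_inputs(config)
  sel <- four_step_selection(inp$data, inp$covs,
                             candidates = weather_candidates(
                               config$seasonal %||% TRUE),
                             rank_by = config$rank_by %||% "aic",
                             starts = config$starts %||% 3,
                             seed = config$seed %||% 1L)
  echo_config(config, out_dir)
  write.csv(sel$step1$table, file.path(out_dir, "step1_distribution.csv"),
            row.names = FALSE, na = "")
  write.csv(sel$step2$table, file.path(out_dir, "step2_detection.csv"),
            row.names = FALSE, na = "")
  if (!is.null(sel$step3$table))
    write.csv(sel$step3$table, file.path(out_dir, "step3_prior_count.csv"),
              row.names = FALSE, na = "")
  write_candidate_csv(sel$weather, file.path(out_dir, "weather_models.csv"))
  if (!is.null(inp$covs$site_year$cow_days)) {
    gs <- grazing_scan(sel$data, sel$covs,
                       split_year = config$split_year %||% 2011,
                       rank_by = config$rank_by %||% "aic",
                       starts = config$starts %||% 3,
                       seed = config$seed %||% 1L)
    write_candidate_csv(gs$predrought,
                        file.path(out_dir, "grazing_predrought.csv"))
    write_candidate_csv(gs$postdrought,
                        file.path(out_dir, "grazing_postdrought.csv"))
    sel$grazing <- gs
  }
  invisible(sel)
}

#' Workflow command: abundance series and drought contrast to disk
#'
#' Fits the configured model, derives the empirical-Bayes abundance series,
#' and writes the series CSVs, the pre/post ANOVA and fold change as JSON,
#' and a figure-style abundance plot.
#'
#' @param config List or YAML path: input paths, `model`, `split_year`,
#'   `boot` (bootstrap draws for series intervals), `seed`, `starts`.
#' @param out_dir Output directory.
#' @return List with the fit, series, ANOVA and fold change, invisibly.
#' @export
run_estimate <- function(config, out_dir) {
  config <- read_config(config)
  take_keys(config, c("counts", "year_covariates", "grazing", "model",
                      "split_year", "boot", "seed", "starts"), "estimate")
  inp <- load_inputs(config)
  split_year <- config$split_year %||% 2011
  fit <- fit_nmix(inp$data, inp$covs, spec_from_config(config$model),
                  starts = config$starts %||% 3, seed = config$seed %||% 1L)
  series <- posterior_abundance(fit, B = config$boot %||% 500,
                                seed = config$seed %||% 1L,
                                split_year = split_year)
  av <- anova_pre_post(series, split_year)
  fc <- fold_change(series, split_year, fit = fit,
                    B = config$boot %||% 500, seed = config$seed %||% 1L)
  echo_config(config, out_dir)
  write_series_csv(series, file.path(out_dir, "abundance_site.csv"),
                   file.path(out_dir, "abundance_year.csv"))
  jsonlite::write_json(
    list(anova = av[c("F", "df1", "df2", "p")],
         fold_change = fc[c("ratio", "infinite", "pre_mean", "post_mean")],
         fold_ci = if (!is.null(fc$ci)) as.list(fc$ci)),
    file.path(out_dir, "contrast.json"), auto_unbox = TRUE, digits = NA)
  plot_abundance(series, split_year, file.path(out_dir, "abundance.png"))
  invisible(list(fit = fit, series = series, anova = av, fold = fc))
}
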