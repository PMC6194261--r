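#' Year-level and site-year covariate table
#'
#' Bundles the covariates used on the demographic (survival, recruitment) and
#' initial-abundance parameters: a wide year-level table (annual and seasonal
#' weather), optional site-year matrices (e.g. grazing pressure as cow
#' days/ha), and optional per-site vectors (e.g. the prior-year maximum
#' count). One-year-lag copies of every numeric year-level column are added
#' automatically with suffix `_lag1`, so that the lagged value for year t
#' equals the unlagged value for t - 1.
#'
#' @param year Data frame with a `year` column plus numeric covariate columns
#'   (e.g. `precip_cm`, `pmdi_avg`, `pmdi_min`, `tmax_c`, `hot_days`, seasonal
#'   `rain_winter` ... `pmdi_fall`).
#' @param site_year Named list of site x year matrices (columns aligned with
#'   `year$year`), e.g. `cow_days`.
#' @param site Named list of per-site numeric vectors.
#' @param lag Add `_lag1` columns (default `TRUE`).
#' @return An object of class `lek_covariates`.
#' @export
covariate_table <- function(year, site_year = list(), site = list(),
                            lag = TRUE) {
  year <- as.data.frame(year)
  if (!"year" %in% names(year)) stop_domain("year table needs a 'year' column")
  year <- year[order(year$year), , drop = FALSE]
  if (lag) {
    base <- setdiff(names(year)[vapply(year, is.numeric, TRUE)], "year")
    base <- base[!grepl("_lag1$", base)]
    for (v in base) {
      lagged <- c(NA_real_, year[[v]][-nrow(year)])
      year[[paste0(v, "_lag1")]] <- lagged
    }
  }
  structure(list(year = year, site_year = site_year, site = site),
            class = "lek_covariates")
}

#' @export
print.lek_covariates <- function(x, ...) {
  cat(sprintf("Covariate table: %d years, %d year-level columns\n",
              nrow(x$year), ncol(x$year) - 1L))
  if (length(x$site_year))
    cat("  site-year matrices:", paste(names(x$site_year), collapse = ", "), "\n")
  if (length(x$site))
    cat("  site vectors:", paste(names(x$site), collapse = ", "), "\n")
  invisible(x)
}

#' Count hot days
#'
#' Number of days whose maximum temperature strictly exceeds a threshold; the
#' long-run 90th percentile of daily maxima (35 C for the study region) is the
#' conventional threshold for this covariate.
#'
#' @param daily_tmax Numeric vector, one value per day.
#' @param threshold Temperature in degrees C; days strictly above it count.
#' @return Integer count.
#' @examples
#' hot_days(c(30, 36, 35, 40), threshold = 35) # 2: ties are excluded
#' @export
hot_days <- function(daily_tmax, threshold = 35) {
  if (length(daily_tmax) == 0) stop_domain("empty temperature series")
  sum(daily_tmax > threshold, na.rm = TRUE)
}

#' Grazing pressure in cow days per hectare
#'
#' Number of cattle times days spent in a pasture, divided by pasture area.
#' Rotations within a year are summed by [cow_days_table()].
#'
#' @param n_cattle Head count (nonnegative).
#' @param days Days grazed (nonnegative).
#' @param area_ha Pasture area in hectares (positive).
#' @return Cow days per hectare.
#' @examples
#' cow_days_per_ha(100, 10, 500) # 2, the upper end of the observed range
#' @export
cow_days_per_ha <- function(n_cattle, days, area_ha) {
  if (any(area_ha <= 0)) stop_domain("area_ha must be positive")
  if (any(n_cattle < 0) || any(days < 0))
    stop_domain("n_cattle and days must be nonnegative")
  n_cattle * days / area_ha
}

#' Site-year grazing covariate from pasture records
#'
#' Computes cow days/ha per pasture-year (summing rotations), then assigns
#' each lek the area-weighted mean over the pastures it belongs to. Years with
#' no grazing record stay `NA`.
#'
#' @param grazing Data frame with columns `pasture_id`, `lek_id`, `year`,
#'   `n_cattle`, `days_grazed`, `area_ha`.
#' @param sites,years Site labels and year labels defining the output matrix.
#' @return Site x year matrix of cow days/ha with `NA` for unrecorded cells.
#' @export
cow_days_table <- function(grazing, sites, years) {
  need <- c("pasture_id", "lek_id", "year", "n_cattle", "days_grazed", "area_ha")
  if (!all(need %in% names(grazing)))
    stop_domain("grazing needs columns: ", paste(need, collapse = ", "))
  ok <- !is.na(grazing$n_cattle) & !is.na(grazing$days_grazed)
  grazing <- grazing[ok, , drop = FALSE]
  out <- matrix(NA_real_, length(sites), length(years),
                dimnames = list(sites, years))
  if (!nrow(grazing)) return(out)
  # a rotation record is (pasture, year, head count, days); rows repeat it
  # once per member lek, so dedupe before summing rotations
  rec <- unique(grazing[, c("pasture_id", "year", "n_cattle", "days_grazed",
                            "area_ha")])
  rec$cdh <- cow_days_per_ha(rec$n_cattle, rec$days_grazed, rec$area_ha)
  py <- aggregate(cdh ~ pasture_id + year, rec, sum)
  area <- aggregate(area_ha ~ pasture_id, rec, function(a) a[1])
  membership <- unique(grazing[, c("pasture_id", "lek_id")])
  for (i in seq_along(sites)) {
    pas <- membership$pasture_id[membership$lek_id == sites[i]]
    if (!length(pas)) next
    w <- area$area_ha[match(pas, area$pasture_id)]
    for (t in seq_along(years)) {
      v <- py$cdh[py$pasture_id %in% pas & py$year == years[t]]
      wp <- w[match(py$pasture_id[py$pasture_id %in% pas & py$year == years[t]], pas)]
      if (length(v)) out[i, t] <- sum(v * wp) / sum(wp)
    }
  }
  out
}

#' Seasonal aggregate of a monthly series
#'
#' Seasons partition the year as winter (December of the previous calendar
#' year through February), breeding (March-May), summer (June-August) and fall
#' (September-November). Precipitation is totalled, drought index averaged. A
#' season with any month missing yields `NA`, never a partial value.
#'
#' @param monthly Data frame with columns `year`, `month` (1-12), `value`.
#' @param season One of `"winter"`, `"breeding"`, `"summer"`, `"fall"`.
#' @param year Calendar year the season is attributed to.
#' @param stat `"total"` (precipitation) or `"mean"` (PMDI).
#' @return Scalar aggregate or `NA`.
#' @export
seasonal_aggregate <- function(monthly, season, year,
                               stat = c("total", "mean")) {
  stat <- match.arg(stat)
  season <- match.arg(season, c("winter", "breeding", "summer", "fall"))
  want <- switch(season,
    winter = data.frame(year = c(year - 1, year, year), month = c(12, 1, 2)),
    breeding = data.frame(year = year, month = 3:5),
    summer = data.frame(year = year, month = 6:8),
    fall = data.frame(year = year, month = 9:11))
  v <- monthly$value[match(paste(want$year, want$month),
                           paste(monthly$year, monthly$month))]
  if (anyNA(v)) return(NA_real_)
  if (stat == "total") sum(v) else mean(v)
}

#' Classify a year as dry, normal or wet
#'
#' Strictly below the 25th percentile of the long-run annual precipitation
#' record is dry; strictly above the 75th percentile is wet. The reference
#' percentiles for the study region (1950-2015 record) are 32 and 46 cm.
#'
#' @param annual_precip Annual precipitation (cm), vectorized.
#' @param p25,p75 Long-run percentiles (cm), `p25 < p75`.
#' @return Character vector in `c("dry", "normal", "wet")`.
#' @examples
#' classify_wet_dry(c(20.47, 66.09, 32)) # dry, wet, normal
#' @export
classify_wet_dry <- function(annual_precip, p25 = 32, p75 = 46) {
  if (p25 >= p75) stop_domain("p25 must be below p75")
  ifelse(annual_precip < p25, "dry",
         ifelse(annual_precip > p75, "wet", "normal"))
}

#' Pearson product-moment correlation
#'
#' Pairwise-complete correlation with an explicit degenerate-input contract:
#' fewer than 3 complete pairs or zero variance yields `NA` with a warning.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Correlation coefficient, or `NA` if undefined.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_domain("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop_domain("need at least 3 complete pairs")
  if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
    warning("zero variance; correlation undefined")
    return(NA_real_)
  }
  cor(x[ok], y[ok])
}
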