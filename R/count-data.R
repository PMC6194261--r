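#' Repeated lek-count data
#'
#' Container for counts of birds flushed from leks (display grounds) visited
#' up to several times per breeding season over a series of years. Counts are
#' held as a ragged site x year x visit array with `NA` marking unsurveyed
#' cells; per-visit daily rainfall and daily maximum temperature ride along as
#' detection covariates, and effort is the number of visits to a lek in a
#' season.
#'
#' @param counts Long-format data frame with columns `lek_id`, `year`,
#'   `visit` (optional; visits are ordered within lek-year), `count`,
#'   `daily_rain_cm`, `daily_tmax_c` (the last two optional). A lek-year with
#'   no rows has zero visits and contributes to the model only through the
#'   population dynamics.
#' @return An object of class `lek_count_data` with elements `y`, `rain`,
#'   `tmax` (site x year x visit arrays), `effort` (site x year matrix),
#'   `sites` and `years`.
#' @examples
#' df <- data.frame(lek_id = "L1", year = 2004:2005, visit = 1,
#'                  count = c(4, 2))
#' lek_count_data(df)
#' @export
lek_count_data <- function(counts) {
  counts <- as.data.frame(counts)
  need <- c("lek_id", "year", "count")
  if (!all(need %in% names(counts)))
    stop_domain("counts needs columns: ", paste(need, collapse = ", "))
  bad <- which(!is.na(counts$count) & (counts$count < 0 | counts$count %% 1 != 0))
  if (length(bad))
    stop_domain("negative or non-integer counts at rows: ",
                paste(head(bad, 5), collapse = ", "))
  sites <- sort(unique(as.character(counts$lek_id)))
  years <- seq(min(counts$year), max(counts$year))
  counts <- counts[order(match(as.character(counts$lek_id), sites),
                         counts$year,
                         if (!is.null(counts$visit)) counts$visit else
                           seq_len(nrow(counts))), ]
  key <- paste(counts$lek_id, counts$year)
  counts$.j <- stats::ave(seq_len(nrow(counts)), key, FUN = seq_along)
  jmax <- max(counts$.j, 1L)
  dims <- c(length(sites), length(years), jmax)
  y <- array(NA_real_, dims)
  rain <- array(NA_real_, dims)
  tmax <- array(NA_real_, dims)
  i <- match(as.character(counts$lek_id), sites)
  t <- match(counts$year, years)
  idx <- cbind(i, t, counts$.j)
  y[idx] <- counts$count
  if (!is.null(counts$daily_rain_cm)) rain[idx] <- counts$daily_rain_cm
  if (!is.null(counts$daily_tmax_c)) tmax[idx] <- counts$daily_tmax_c
  new_lek_count_data(y, rain, tmax, sites, years)
}

new_lek_count_data <- function(y, rain = NULL, tmax = NULL, sites = NULL,
                               years = NULL) {
  stopifnot(length(dim(y)) == 3)
  dims <- dim(y)
  rain <- rain %||% array(NA_real_, dims)
  tmax <- tmax %||% array(NA_real_, dims)
  sites <- sites %||% paste0("L", seq_len(dims[1]))
  years <- years %||% seq_len(dims[2])
  effort <- apply(!is.na(y), c(1, 2), sum)
  structure(list(y = y, rain = rain, tmax = tmax, effort = effort,
                 sites = sites, years = as.integer(years)),
            class = "lek_count_data")
}

#' @export
print.lek_count_data <- function(x, ...) {
  cat(sprintf("Lek count data: %d leks x %d years (%d-%d), %d counts\n",
              length(x$sites), length(x$years), min(x$years), max(x$years),
              sum(!is.na(x$y))))
  cat(sprintf("  visits per lek-year: %d-%d; max count %s\n",
              min(x$effort), max(x$effort),
              if (all(is.na(x$y))) "NA" else max(x$y, na.rm = TRUE)))
  invisible(x)
}

#' @export
as.data.frame.lek_count_data <- function(x, ...) {
  idx <- which(!is.na(x$y), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2], idx[, 3]), , drop = FALSE]
  data.frame(lek_id = x$sites[idx[, 1]], year = x$years[idx[, 2]],
             visit = idx[, 3], count = x$y[idx],
             daily_rain_cm = x$rain[idx], daily_tmax_c = x$tmax[idx])
}

# Restrict to a contiguous run of years (labels, not indices).
trim_years <- function(data, years) {
  keep <- match(years, data$years)
  if (anyNA(keep)) stop_domain("years not present in data")
  new_lek_count_data(data$y[, keep, , drop = FALSE],
                     data$rain[, keep, , drop = FALSE],
                     data$tmax[, keep, , drop = FALSE],
                     data$sites, data$years[keep])
}

# Mark all counts in the given years as missing (e.g. a year whose grazing
# covariate was never recorded); the year still participates in dynamics.
mask_years <- function(data, years) {
  keep <- match(years, data$years)
  y <- data$y; y[, keep, ] <- NA_real_
  new_lek_count_data(y, data$rain, data$tmax, data$sites, data$years)
}
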