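# Temperature-driven development of desert locust eggs and hoppers.
#
# Development accrues as a percentage per day determined by temperature:
# a Gaussian-shaped rate for eggs (peaked near the top of the admissible
# range) and a linear rate for hoppers. Rates are integrated over 3-hourly
# temperature records until cumulative development first reaches 100%;
# completion is then filtered by biologically viable duration windows, and
# the hopper stage additionally requires adequate vegetation throughout.

#' Development-rate and viability parameters
#'
#' Default constants of the phenology sub-model: the egg rate
#' a * exp(-b * (T_opt - T)^2) on [10, 34] degC with a = 9.41 %/day,
#' b = 0.00357 /degC^2, T_opt = 35.019 degC, viable duration 11-50 days;
#' the hopper rate 0.222 * T - 3.166 %/day on [23, 32] degC, viable
#' duration 24-95 days; and the NDVI feeding threshold 0.09 (Red Sea
#' regional calibration; 0.14 has been proposed for the western Sahel).
#'
#' @param ndvi_threshold NDVI feeding threshold for the hopper stage.
#' @return List of class `development_params`.
#' @export
development_params <- function(ndvi_threshold = 0.09) {
  list(egg = list(a = 9.41, b = 0.00357, t_opt = 35.019,
                  t_range = c(10, 34), viable_days = c(11L, 50L),
                  max_days = 120L),
       hopper = list(slope = 0.222, intercept = 3.166,
                     t_range = c(23, 32), viable_days = c(24L, 95L),
                     max_days = 200L),
       ndvi_threshold = ndvi_threshold)
}

#' Daily development rates
#'
#' `egg_rate`: percentage daily development of eggs at temperature T,
#' 9.41 * exp(-0.00357 * (35.019 - T)^2) for T in [10, 34] degC and 0
#' outside (closed interval). `hopper_rate`: percentage daily development
#' of hoppers, 0.222 * T - 3.166 for T in [23, 32] degC, 0 outside.
#'
#' @param t_c Temperature(s), degrees Celsius.
#' @param params A `development_params` list.
#' @return Percent development per day (vectorised).
#' @examples
#' egg_rate(25)     # ~6.58 %/day
#' hopper_rate(32)  # ~3.94 %/day
#' @export
egg_rate <- function(t_c, params = development_params()) {
  p <- params$egg
  r <- p$a * exp(-p$b * (p$t_opt - t_c)^2)
  r[!is.finite(t_c) | t_c < p$t_range[1] | t_c > p$t_range[2]] <- 0
  r
}

#' @rdname egg_rate
#' @export
hopper_rate <- function(t_c, params = development_params()) {
  p <- params$hopper
  r <- p$slope * t_c - p$intercept
  r[!is.finite(t_c) | t_c < p$t_range[1] | t_c > p$t_range[2]] <- 0
  r
}

#' Integrate a development rate over a 3-hourly temperature series
#'
#' Accumulates rate(T)/8 per 3-hour record from `start_date` until
#' cumulative development first reaches 100%. The reported duration is the
#' 1-based day index (the lay/hatch day counts as day 1) of the record at
#' which the threshold is first met.
#'
#' @param rate_fn Function mapping temperature (degC) to %/day.
#' @param temp_series A `cell_series` (see [extract_cell()]) of 3-hourly
#'   temperatures covering `[start_date, start_date + max_days]`.
#' @param start_date `Date` development begins (00:00 UTC).
#' @param max_days Give up after this many days (outcome "never-completed").
#' @return List of class `stage_outcome`: `status` ("success" here meaning
#'   the threshold was reached; viability is applied by [egg_stage()] /
#'   [hopper_stage()]), `completion_date`, `duration_days`.
#' @export
development_period <- function(rate_fn, temp_series, start_date, max_days) {
  start_date <- as.Date(start_date)
  t0 <- as.POSIXct(paste(format(start_date), "00:00:00"), tz = "UTC")
  sel <- temp_series$times >= t0 &
    temp_series$times < t0 + as.difftime(max_days, units = "days")
  temps <- temp_series$values[sel]
  n_rec <- sum(sel)
  if (n_rec < 8L) stop("data gap: temperature series does not cover the stage")
  if (anyNA(temps)) stop("data gap: missing temperature records")
  cum <- cumsum(rate_fn(temps) / 8)
  hit <- which(cum >= 100)[1L]
  if (is.na(hit)) {
    if (n_rec < max_days * 8L)
      stop("data gap: temperature series shorter than max_days")
    return(structure(list(status = "never-completed",
                          completion_date = NULL,
                          duration_days = NA_integer_),
                     class = "stage_outcome"))
  }
  dur <- as.integer(ceiling(hit / 8))
  structure(list(status = "success",
                 completion_date = start_date + dur - 1L,
                 duration_days = dur),
            class = "stage_outcome")
}

#' @export
print.stage_outcome <- function(x, ...) {
  cat(sprintf("stage_outcome: %s%s\n", x$status,
              if (x$status == "success")
                sprintf(" in %d days (completed %s)", x$duration_days,
                        format(x$completion_date)) else ""))
  invisible(x)
}

#' Egg incubation at a site
#'
#' Integrates the egg development rate from the lay date; the stage
#' succeeds iff the resulting incubation period lies in the viable window
#' (11-50 days by default), otherwise the cohort is nonviable.
#'
#' @param lay_date `Date` of egg laying.
#' @param temp_series 3-hourly `cell_series` of temperature at the site.
#' @param params A `development_params` list.
#' @return A `stage_outcome` with status "success", "nonviable" or
#'   "never-completed".
#' @export
egg_stage <- function(lay_date, temp_series, params = development_params()) {
  out <- development_period(function(t) egg_rate(t, params), temp_series,
                            lay_date, params$egg$max_days)
  if (out$status != "success") return(out)
  vd <- params$egg$viable_days
  if (out$duration_days < vd[1] || out$duration_days > vd[2]) {
    out$status <- "nonviable"
    out$completion_date <- NULL
  }
  out
}

#' Hopper development at a site
#'
#' Integrates the hopper development rate from the hatch date. Success
#' requires (i) a duration inside the viable window (24-95 days default)
#' and (ii) adequate vegetation at every 16-day NDVI observation between
#' hatch and completion: the smoothed NDVI must be increasing (trend
#' state at that date) or at/above the regional NDVI threshold.
#'
#' @param hatch_date `Date` hoppers emerged.
#' @param temp_series 3-hourly `cell_series` of temperature at the site.
#' @param ndvi_times,ndvi_smoothed NDVI observation dates and smoothed
#'   values at the site (the full series; the 150-day trend window must be
#'   populated before each observation inside the stage).
#' @param params A `development_params` list.
#' @return A `stage_outcome`; status "vegetation-fail" when the duration is
#'   viable but the vegetation condition fails at some observation.
#' @export
hopper_stage <- function(hatch_date, temp_series, ndvi_times, ndvi_smoothed,
                         params = development_params()) {
  out <- development_period(function(t) hopper_rate(t, params), temp_series,
                            hatch_date, params$hopper$max_days)
  if (out$status != "success") return(out)
  vd <- params$hopper$viable_days
  if (out$duration_days < vd[1] || out$duration_days > vd[2]) {
    out$status <- "nonviable"
    out$completion_date <- NULL
    return(out)
  }
  ndvi_times <- as.Date(ndvi_times)
  inside <- ndvi_times >= as.Date(hatch_date) & ndvi_times <= out$completion_date
  if (!any(inside)) stop("data gap: no NDVI observation inside hopper stage")
  for (d in which(inside)) {
    ok <- FALSE
    if (is.finite(ndvi_smoothed[d]) &&
        ndvi_smoothed[d] >= params$ndvi_threshold) ok <- TRUE
    if (!ok) {
      tr <- try(ndvi_trend(ndvi_times, ndvi_smoothed, ndvi_times[d]),
                silent = TRUE)
      if (!inherits(tr, "try-error") && tr$state == "INCREASING") ok <- TRUE
    }
    if (!ok) {
      out$status <- "vegetation-fail"
      out$completion_date <- NULL
      return(out)
    }
  }
  out
}
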