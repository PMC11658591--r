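# NDVI time-series processing: penalised smoothing, piecewise-linear trend
# segmentation, peak detection and vegetation-state classification.

#' Whittaker smoother
#'
#' Penalised least squares with a second-order difference penalty:
#' minimises sum(w_i (y_i - z_i)^2) + lambda * sum((Delta^2 z)^2). Missing
#' observations (weight 0) are interpolated by the smoother. The banded
#' normal equations (W + lambda D'D) z = W y are solved exactly.
#'
#' @param raw Numeric series (NDVI in [-1, 1]; `NA` allowed where weight 0).
#' @param weights 0/1 vector, 0 marking missing observations. Defaults to
#'   1 wherever `raw` is finite.
#' @param lam Smoothing parameter lambda (default 1, the value used for
#'   16-day NDVI throughout the package).
#' @return Numeric vector of smoothed values, same length as `raw`.
#' @examples
#' whittaker_smooth(c(0.1, 0.2, NA, 0.4, 0.5), weights = c(1, 1, 0, 1, 1))
#' @export
whittaker_smooth <- function(raw, weights = NULL, lam = 1) {
  n <- length(raw)
  if (is.null(weights)) weights <- as.numeric(is.finite(raw))
  stopifnot(length(weights) == n, all(weights %in% c(0, 1)))
  if (sum(weights) < 4) stop("insufficient data: need >= 4 observed points")
  y <- raw
  y[weights == 0] <- 0  # masked by W
  D <- diff(diag(n), differences = 2L)
  A <- diag(weights, n) + lam * crossprod(D)
  as.numeric(solve(A, weights * y))
}

#' NDVI trend state at a date
#'
#' Classifies the NDVI trend just before a query date as INCREASING,
#' CONSTANT or DECREASING. A continuous piecewise-linear model with
#' 0..`max_breakpoints` breaks (break positions aligned to observation
#' times) is fitted by exhaustive least squares over the `window_days`
#' preceding the query date; the number of breaks is chosen by BIC.
#' Adjacent segments with the same slope sign are merged, and the final
#' merged segment before the query date gives the state; slopes within
#' `flat_slope_tol` of zero count as CONSTANT.
#'
#' @param times Observation dates (`Date`), 16-day cadence.
#' @param smoothed Smoothed NDVI values at `times`.
#' @param query_date `Date` of interest; observations in
#'   `[query_date - window_days, query_date]` are used.
#' @param window_days Look-back window, days (default 150).
#' @param max_breakpoints Maximum number of breaks (default 3).
#' @param flat_slope_tol Absolute slope (NDVI/day) below which a segment is
#'   CONSTANT (default 5e-4).
#' @return List of class `trend_state`: `state` ("INCREASING", "CONSTANT",
#'   "DECREASING"), `last_segment` (start, end, slope), `n_breaks`.
#' @export
ndvi_trend <- function(times, smoothed, query_date, window_days = 150,
                       max_breakpoints = 3, flat_slope_tol = 5e-4) {
  times <- as.Date(times)
  query_date <- as.Date(query_date)
  keep <- times >= query_date - window_days & times <= query_date
  t <- as.numeric(times[keep] - query_date)  # days, <= 0
  y <- smoothed[keep]
  n <- length(y)
  if (n < 6) stop("insufficient data: need >= 6 observations in window")

  fit_k <- function(breaks) {
    X <- cbind(1, t)
    for (b in breaks) X <- cbind(X, pmax(0, t - b))
    f <- stats::lm.fit(X, y)
    if (anyNA(f$coefficients)) return(NULL)  # rank-deficient break layout
    list(rss = sum(f$residuals^2), coef = f$coefficients, breaks = breaks)
  }
  interior <- t[-c(1L, n)]
  best <- NULL; best_bic <- Inf
  for (k in 0:max_breakpoints) {
    combos <- if (k == 0) list(numeric(0)) else {
      if (length(interior) < k) break
      asplit(utils::combn(interior, k), 2L)
    }
    for (br in combos) {
      f <- fit_k(sort(as.numeric(br)))
      if (is.null(f)) next
      p <- 2 + length(br)
      bic <- n * log(max(f$rss, 1e-12) / n) + p * log(n)
      if (bic < best_bic) { best_bic <- bic; best <- f }
    }
  }
  # per-segment slopes: slope_j = beta1 + sum of hinge coefficients active
  brk <- best$breaks
  seg_bounds <- c(t[1L], brk, t[n])
  slopes <- cumsum(c(best$coef[2L], if (length(brk)) best$coef[-(1:2)]))
  sgn <- ifelse(abs(slopes) <= flat_slope_tol, 0L, sign(slopes))
  # merge adjacent segments of equal sign
  m_start <- seg_bounds[1L]; merged <- list()
  j <- 1L
  while (j <= length(slopes)) {
    k2 <- j
    while (k2 < length(slopes) && sgn[k2 + 1L] == sgn[j]) k2 <- k2 + 1L
    # slope of merged segment: refit a line over that span
    lo <- seg_bounds[j]; hi <- seg_bounds[k2 + 1L]
    idx <- t >= lo & t <= hi
    sl <- unname(slopes[j])
    if (sum(idx) >= 2) {
      cf <- stats::lm.fit(cbind(1, t[idx]), y[idx])$coefficients
      if (!anyNA(cf)) sl <- unname(cf[2L])
    }
    merged[[length(merged) + 1L]] <- c(start = lo, end = hi, slope = sl)
    j <- k2 + 1L
  }
  last <- merged[[length(merged)]]
  state <- if (abs(last["slope"]) <= flat_slope_tol) "CONSTANT"
           else if (last["slope"] > 0) "INCREASING" else "DECREASING"
  structure(list(state = state,
                 last_segment = last,
                 n_breaks = length(brk)),
            class = "trend_state")
}

#' Local peaks of a series
#'
#' Index `i` is a peak iff the `m` points on each side are all lower than
#' or equal to the point. Runs of equal maxima (plateaus) report only the
#' first index; endpoints with fewer than `m` neighbours on a side are
#' never peaks. In NDVI profiles a peak marks the onset of fresh
#' vegetation.
#'
#' @param series Numeric vector, length > 2m.
#' @param m Neighbourhood half-width in observations (default 2, i.e. about
#'   one month either side at 16-day cadence).
#' @return Integer vector of peak indices (possibly empty).
#' @examples
#' find_peaks(c(0, 1, 2, 3, 2, 1, 0))  # 4
#' @export
find_peaks <- function(series, m = 2) {
  n <- length(series)
  if (n <= 2 * m) stop("series too short for m")
  starts <- integer(0)
  for (i in (m + 1):(n - m)) {
    nb <- series[c((i - m):(i - 1), (i + 1):(i + m))]
    if (all(nb <= series[i])) {
      # report the first index of the equal-value run containing i
      j <- i
      while (j > 1 && series[j - 1] == series[i]) j <- j - 1L
      starts <- c(starts, j)
    }
  }
  sort(unique(starts))
}

#' Vegetation-state class of an NDVI value
#'
#' Bins NDVI into the six density classes used for feeding-capacity rules:
#' NOVEG (< 0), LOWEST [0, 0.15), LOWER [0.15, 0.3), DENSE [0.3, 0.45),
#' HIGHER [0.45, 0.6), HIGHEST [0.6, 1].
#'
#' @param ndvi NDVI value(s) in [-1, 1].
#' @return Character vector of class names; ordered factor levels available
#'   via [veg_state_levels()].
#' @export
veg_state <- function(ndvi) {
  stopifnot(all(is.finite(ndvi)), all(ndvi >= -1 & ndvi <= 1))
  as.character(cut(ndvi,
                   breaks = c(-Inf, 0, 0.15, 0.3, 0.45, 0.6, Inf),
                   labels = veg_state_levels(),
                   right = FALSE))
}

#' @rdname veg_state
#' @export
veg_state_levels <- function() {
  c("NOVEG", "LOWEST", "LOWER", "DENSE", "HIGHER", "HIGHEST")
}
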