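# Swarm migration along pre-computed wind-trajectory ensembles: storage,
# random sampling with rigid translation, daily flight windows, coastline
# stopping, and von Mises characterisation of trajectory headings.

#' A single wind trajectory
#'
#' @param day Calendar `Date` of the flight.
#' @param source `c(lon, lat)` of the source cell the trajectory was
#'   released from.
#' @param points Data frame with columns `time` (POSIXct UTC, strictly
#'   increasing, 0.5-h cadence), `lon`, `lat`, `height` (m, in [0, 2000]).
#' @return Object of class `trajectory`.
#' @export
trajectory <- function(day, source, points) {
  stopifnot(is.data.frame(points),
            all(c("time", "lon", "lat", "height") %in% names(points)))
  if (nrow(points) > 1 && any(diff(as.numeric(points$time)) <= 0))
    stop("trajectory timestamps must be strictly increasing")
  structure(list(day = as.Date(day), source = source, points = points),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  n <- nrow(x$points)
  cat(sprintf("trajectory %s: %d points, (%.3f, %.3f) -> (%.3f, %.3f)\n",
              format(x$day), n, x$points$lon[1L], x$points$lat[1L],
              x$points$lon[n], x$points$lat[n]))
  invisible(x)
}

#' Ensemble store of wind trajectories
#'
#' Indexes trajectory realisations by (day, source cell). The realisation
#' count is uniform across the store.
#'
#' @param sources Matrix with columns lon, lat: source-cell centres (a
#'   regular lattice, e.g. 0.18 degree spacing for a nominal 20-km grid).
#' @param days Vector of `Date`s covered.
#' @param trajectories Nested list: `trajectories[[format(day)]][[s]]` is a
#'   list of `trajectory` objects (realisations) for source `s`.
#' @return Object of class `trajectory_store`.
#' @export
trajectory_store <- function(sources, days, trajectories) {
  sources <- as.matrix(sources)
  colnames(sources) <- c("lon", "lat")
  days <- as.Date(days)
  counts <- unlist(lapply(trajectories, function(day_list)
    vapply(day_list, length, 0L)))
  if (length(counts) == 0L || any(counts < 1L))
    stop("every (day, source) must hold at least one realisation")
  if (length(unique(counts)) != 1L)
    stop("realisation count must be uniform across the store")
  structure(list(sources = sources, days = days,
                 trajectories = trajectories,
                 n_realisations = counts[[1L]]),
            class = "trajectory_store")
}

#' @export
print.trajectory_store <- function(x, ...) {
  cat(sprintf("trajectory_store: %d sources x %d days x %d realisations\n",
              nrow(x$sources), length(x$days), x$n_realisations))
  invisible(x)
}

#' Sample a trajectory for a location and day
#'
#' Picks the source cell closest to `cell`, draws one realisation uniformly
#' at random (current RNG stream), and rigidly translates the trajectory so
#' it starts at `cell` (every point shifted by the same lon/lat offset;
#' over sub-20-km offsets the metric distortion is negligible).
#'
#' @param store A `trajectory_store`.
#' @param cell `c(lon, lat)` flight start location.
#' @param day `Date`; must be covered by the store.
#' @return A `trajectory` starting at `cell`.
#' @export
sample_trajectory <- function(store, cell, day) {
  day <- as.Date(day)
  key <- format(day)
  if (!key %in% names(store$trajectories))
    stop("day ", key, " not covered by trajectory store")
  s <- nearest_source_cell(cell, store$sources)
  reals <- store$trajectories[[key]][[s]]
  tr <- reals[[if (length(reals) == 1L) 1L else sample.int(length(reals), 1L)]]
  shift <- c(cell[1L] - tr$source[1L], cell[2L] - tr$source[2L])
  pts <- tr$points
  pts$lon <- pts$lon + shift[1L]
  pts$lat <- pts$lat + shift[2L]
  trajectory(day, source = cell, points = pts)
}

#' Daily swarm flight window
#'
#' Swarms take to the air two hours after local sunrise and settle one hour
#' before local sunset.
#'
#' @param lon,lat Location, decimal degrees.
#' @param day `Date`.
#' @return List with `start` and `end` (POSIXct UTC); on a 12-hour day the
#'   window spans 9 hours.
#' @export
flight_window <- function(lon, lat, day) {
  st <- solar_times(lon, lat, day)
  w <- list(start = st$sunrise + 2 * 3600, end = st$sunset - 3600)
  if (w$start >= w$end) stop("degenerate flight window")
  w
}

#' Stop a trajectory at the coast
#'
#' Ocean crossings are not modelled: if any trajectory point falls on a
#' water cell of the land mask, the trajectory is truncated at the last
#' preceding point over land.
#'
#' @param traj A `trajectory`.
#' @param land_mask `raster_layer` with 1 = land, 0 = water, covering the
#'   trajectory extent (points outside the mask extent are treated as
#'   water).
#' @return A (possibly truncated) `trajectory`.
#' @export
stop_at_coast <- function(traj, land_mask) {
  pts <- traj$points
  on_land <- vapply(seq_len(nrow(pts)), function(i) {
    v <- try(raster_value_at(land_mask, pts$lon[i], pts$lat[i]), silent = TRUE)
    !inherits(v, "try-error") && isTRUE(v == 1)
  }, logical(1))
  if (!on_land[1L]) stop("invalid start: trajectory begins over water")
  if (all(on_land)) return(traj)
  first_water <- which(!on_land)[1L]
  trajectory(traj$day, traj$source, pts[seq_len(first_water - 1L), , drop = FALSE])
}

#' Heading angle of a trajectory
#'
#' Angle between due East and the vector from the start to the end point,
#' in degrees counterclockwise from East in (-180, 180] (+90 = toward
#' North). Longitude displacement is scaled by cos(mean latitude).
#'
#' @param traj A `trajectory` (start and end must differ).
#' @return Angle in degrees.
#' @export
heading_angle <- function(traj) {
  pts <- traj$points
  n <- nrow(pts)
  dlon <- pts$lon[n] - pts$lon[1L]
  dlat <- pts$lat[n] - pts$lat[1L]
  if (dlon == 0 && dlat == 0) stop("undefined heading: zero displacement")
  latbar <- (pts$lat[n] + pts$lat[1L]) / 2
  ang <- atan2(dlat, dlon * cos(latbar * pi / 180)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Fit a von Mises distribution to heading angles
#'
#' Maximum-likelihood fit: the mean direction is the circular mean and the
#' concentration kappa solves A(kappa) = Rbar via the Best-Fisher
#' three-regime approximation, capped at 1e4. With mean resultant length
#' Rbar below 0.01 the mean direction is flagged undefined.
#'
#' @param angles_deg Heading angles in degrees (n >= 5).
#' @return Object of class `von_mises_fit`: `mu` (degrees in (-180, 180],
#'   `NA` when undefined), `kappa`, `rbar`, `n`, `mu_defined`.
#' @export
fit_von_mises <- function(angles_deg) {
  n <- length(angles_deg)
  if (n < 5) stop("insufficient data: need at least 5 angles")
  a <- angles_deg * pi / 180
  c_bar <- mean(cos(a)); s_bar <- mean(sin(a))
  rbar <- sqrt(c_bar^2 + s_bar^2)
  mu_defined <- rbar >= 0.01
  mu <- if (mu_defined) atan2(s_bar, c_bar) * 180 / pi else NA_real_
  if (!is.na(mu) && mu <= -180) mu <- mu + 360
  kappa <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  kappa <- min(max(kappa, 0), 1e4)
  structure(list(mu = mu, kappa = kappa, rbar = rbar, n = n,
                 mu_defined = mu_defined),
            class = "von_mises_fit")
}

#' @export
print.von_mises_fit <- function(x, ...) {
  cat(sprintf("von Mises fit (n = %d): mu = %s deg, kappa = %.3g, Rbar = %.3f\n",
              x$n, if (x$mu_defined) sprintf("%.1f", x$mu) else "undefined",
              x$kappa, x$rbar))
  invisible(x)
}

#' Angular width of a concentration value
#'
#' Converts a von Mises concentration into an approximate angular spread,
#' 2/sqrt(kappa) radians in degrees (valid for large kappa; kappa = 600
#' gives 4.7 degrees).
#'
#' @param kappa Concentration, > 0.
#' @return Width in degrees, rounded to 1 decimal.
#' @export
angular_width <- function(kappa) {
  if (!is.numeric(kappa) || any(!is.finite(kappa)) || any(kappa <= 0))
    stop("kappa must be positive")
  round(2 / sqrt(kappa) * 180 / pi, 1)
}
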