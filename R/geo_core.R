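#' Regular geographic grid specification
#'
#' Defines a regular lon-lat lattice in WGS84 decimal degrees. Cell (1, 1)
#' sits at the north-west corner (lon_min, lat_max); rows run north to
#' south, columns west to east (row-major, north-up). Cell centres are at
#' corner + (i - 0.5) * cell_size.
#'
#' @param lon_min,lon_max,lat_min,lat_max Extent in decimal degrees.
#' @param cell_size Cell edge in degrees (e.g. 1/120 for a nominal 1-km
#'   cell in the tropics).
#' @return An object of class `grid_spec` with fields `lon_min`, `lon_max`,
#'   `lat_min`, `lat_max`, `cell_size`, `n_lon`, `n_lat`.
#' @examples
#' g <- grid_spec(30, 55, -5, 20, 1 / 120)
#' g$n_lon  # 3000
#' @export
grid_spec <- function(lon_min, lon_max, lat_min, lat_max, cell_size) {
  stopifnot(is.finite(lon_min), is.finite(lon_max), is.finite(lat_min),
            is.finite(lat_max), is.finite(cell_size), cell_size > 0)
  if (lon_min >= lon_max) stop("lon_min must be < lon_max")
  if (lat_min >= lat_max) stop("lat_min must be < lat_max")
  n_lon <- as.integer(round((lon_max - lon_min) / cell_size))
  n_lat <- as.integer(round((lat_max - lat_min) / cell_size))
  if (n_lon < 1L || n_lat < 1L) stop("grid must contain at least one cell")
  structure(list(lon_min = lon_min, lon_max = lon_max,
                 lat_min = lat_min, lat_max = lat_max,
                 cell_size = cell_size, n_lon = n_lon, n_lat = n_lat),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d cells of %.6f deg, lon [%g, %g], lat [%g, %g]\n",
              x$n_lat, x$n_lon, x$cell_size, x$lon_min, x$lon_max,
              x$lat_min, x$lat_max))
  invisible(x)
}

#' Cell-centre coordinates of a grid
#'
#' @param grid A `grid_spec`.
#' @return `grid_lons` / `grid_lats`: numeric vectors of cell-centre
#'   longitudes (west to east) and latitudes (north to south, matching row
#'   order of raster values).
#' @export
grid_lons <- function(grid) grid$lon_min + (seq_len(grid$n_lon) - 0.5) * grid$cell_size

#' @rdname grid_lons
#' @export
grid_lats <- function(grid) grid$lat_max - (seq_len(grid$n_lat) - 0.5) * grid$cell_size

#' Row/column index of the cell containing a point
#'
#' @param grid A `grid_spec`.
#' @param lon,lat Point coordinates, decimal degrees.
#' @return Integer vector `c(row, col)` (1-based, row 1 = northernmost).
#'   Errors if the point lies outside the grid extent.
#' @export
cell_index <- function(grid, lon, lat) {
  if (!is.finite(lon) || !is.finite(lat)) stop("non-finite coordinates")
  if (lon < grid$lon_min || lon > grid$lon_max ||
      lat < grid$lat_min || lat > grid$lat_max)
    stop("point outside grid extent")
  col <- min(grid$n_lon, max(1L, as.integer(floor((lon - grid$lon_min) / grid$cell_size)) + 1L))
  row <- min(grid$n_lat, max(1L, as.integer(floor((grid$lat_max - lat) / grid$cell_size)) + 1L))
  c(row = row, col = col)
}

#' Raster layer on a regular grid
#'
#' A single 2-D field (elevation, soil texture, land cover, suitability,
#' one NDVI frame ...) on a `grid_spec`. Values are stored as a
#' (n_lat x n_lon) matrix, row 1 northernmost. Missing data is `NA`; any
#' operation touching an `NA` cell yields `NA`, never zero.
#'
#' @param grid A `grid_spec`.
#' @param values Numeric matrix of dimension (n_lat, n_lon).
#' @param variable Character name of the variable.
#' @param time Optional `Date` timestamp.
#' @return Object of class `raster_layer`.
#' @export
raster_layer <- function(grid, values, variable = "layer", time = NULL) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (!identical(dim(values), c(grid$n_lat, grid$n_lon)))
    stop(sprintf("values must be %d x %d", grid$n_lat, grid$n_lon))
  structure(list(grid = grid, values = values, variable = variable,
                 time = time), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("raster_layer '%s': %d x %d, range [%g, %g], %d NA cells\n",
              x$variable, nrow(x$values), ncol(x$values),
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA,
              sum(is.na(x$values))))
  invisible(x)
}

#' Value of a raster at a point
#'
#' @param layer A `raster_layer`.
#' @param lon,lat Point coordinates.
#' @return The value of the cell containing the point (possibly `NA`).
#' @export
raster_value_at <- function(layer, lon, lat) {
  ij <- cell_index(layer$grid, lon, lat)
  layer$values[ij[1L], ij[2L]]
}

#' Time-stamped stack of gridded fields
#'
#' Holds a uniform-cadence series of 2-D fields sharing one grid: 3-hourly
#' temperature / precipitation / soil moisture, or 16-day NDVI.
#'
#' @param grid A `grid_spec`.
#' @param times `POSIXct` (UTC) timestamps, strictly increasing, uniform
#'   cadence.
#' @param frames Numeric array of dimension (n_time, n_lat, n_lon).
#' @param variable Character name.
#' @return Object of class `gridded_series`.
#' @export
gridded_series <- function(grid, times, frames, variable = "field") {
  stopifnot(inherits(grid, "grid_spec"), inherits(times, "POSIXct"))
  if (length(times) < 2L) stop("need at least two time steps")
  dt <- diff(as.numeric(times))
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6) stop("cadence must be uniform")
  stopifnot(is.array(frames), length(dim(frames)) == 3L)
  if (!identical(dim(frames), c(length(times), grid$n_lat, grid$n_lon)))
    stop("frames must have dimension (n_time, n_lat, n_lon)")
  structure(list(grid = grid, times = times, frames = frames,
                 variable = variable, cadence_hours = dt[1L] / 3600),
            class = "gridded_series")
}

#' @export
print.gridded_series <- function(x, ...) {
  cat(sprintf("gridded_series '%s': %d frames at %.3g h cadence, %s .. %s\n",
              x$variable, length(x$times), x$cadence_hours,
              format(x$times[1L], tz = "UTC"),
              format(x$times[length(x$times)], tz = "UTC")))
  invisible(x)
}

#' Extract the time series of one cell
#'
#' @param series A `gridded_series`.
#' @param lon,lat Point coordinates (the containing cell is used).
#' @return A list of class `cell_series` with `times` (POSIXct UTC) and
#'   `values` (numeric).
#' @export
extract_cell <- function(series, lon, lat) {
  ij <- cell_index(series$grid, lon, lat)
  structure(list(times = series$times,
                 values = series$frames[, ij[1L], ij[2L]]),
            class = "cell_series")
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of radius 6371.0 km.
#'
#' @param a,b Points as `c(lon, lat)` in decimal degrees. `b` may be a
#'   two-column matrix of points.
#' @return Distance(s) in km.
#' @examples
#' haversine_km(c(0, 0), c(0, 1))  # one degree of latitude, ~111.19 km
#' @export
haversine_km <- function(a, b) {
  if (is.matrix(b)) {
    lon2 <- b[, 1L]; lat2 <- b[, 2L]
  } else {
    lon2 <- b[1L]; lat2 <- b[2L]
  }
  if (!all(is.finite(a)) || !all(is.finite(lon2)) || !all(is.finite(lat2)))
    stop("non-finite coordinates")
  if (abs(a[2L]) > 90 || any(abs(lat2) > 90)) stop("latitude outside [-90, 90]")
  rad <- pi / 180
  phi1 <- a[2L] * rad; phi2 <- lat2 * rad
  dphi <- (lat2 - a[2L]) * rad
  dlam <- (lon2 - a[1L]) * rad
  h <- sin(dphi / 2)^2 + cos(phi1) * cos(phi2) * sin(dlam / 2)^2
  2 * 6371.0 * asin(pmin(1, sqrt(h)))
}

#' Local sunrise and sunset
#'
#' Sunrise and sunset instants (UTC) for a calendar day from the standard
#' NOAA solar-position equations (zenith 90.833 deg, accounting for
#' refraction and the solar disc). Accuracy is a few minutes, sufficient to
#' anchor daily swarm flight windows.
#'
#' @param lon,lat Coordinates in decimal degrees; `abs(lat)` must be below
#'   66.5 (tropical/temperate; polar day/night unsupported).
#' @param date A `Date`.
#' @return List with `sunrise` and `sunset` as `POSIXct` (UTC).
#' @export
solar_times <- function(lon, lat, date) {
  if (!is.finite(lon) || !is.finite(lat)) stop("non-finite coordinates")
  if (abs(lat) >= 66.5) stop("unsupported latitude: polar day/night possible")
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j", tz = "UTC"))
  # fractional year (radians), mid-day
  gamma <- 2 * pi / 365 * (doy - 1 + 0.5)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(gamma) - 0.032077 * sin(gamma) -
                        0.014615 * cos(2 * gamma) - 0.040849 * sin(2 * gamma))
  decl <- 0.006918 - 0.399912 * cos(gamma) + 0.070257 * sin(gamma) -
    0.006758 * cos(2 * gamma) + 0.000907 * sin(2 * gamma) -
    0.002697 * cos(3 * gamma) + 0.00148 * sin(3 * gamma)
  rad <- pi / 180
  cos_ha <- cos(90.833 * rad) / (cos(lat * rad) * cos(decl)) -
    tan(lat * rad) * tan(decl)
  if (!is.finite(cos_ha) || abs(cos_ha) > 1)
    stop("unsupported latitude/date: sun does not rise or set")
  ha <- acos(cos_ha) / rad  # degrees
  midnight <- as.POSIXct(paste(format(date), "00:00:00"), tz = "UTC")
  sunrise_min <- 720 - 4 * (lon + ha) - eqtime
  sunset_min <- 720 - 4 * (lon - ha) - eqtime
  list(sunrise = midnight + sunrise_min * 60,
       sunset = midnight + sunset_min * 60)
}

#' Nearest-neighbour upscaling of a coarse raster
#'
#' Assigns to every target cell the value of the enclosing coarse cell (no
#' interpolation), e.g. 10-km model fields carried onto a 1-km grid.
#'
#' @param coarse A `raster_layer` whose extent covers `target`.
#' @param target A `grid_spec`.
#' @return A `raster_layer` on `target`.
#' @export
upscale_nearest <- function(coarse, target) {
  stopifnot(inherits(coarse, "raster_layer"), inherits(target, "grid_spec"))
  cg <- coarse$grid
  lons <- grid_lons(target); lats <- grid_lats(target)
  if (min(lons) < cg$lon_min || max(lons) > cg$lon_max ||
      min(lats) < cg$lat_min || max(lats) > cg$lat_max)
    stop("target extent not covered by coarse raster")
  cols <- pmin(cg$n_lon, pmax(1L, floor((lons - cg$lon_min) / cg$cell_size) + 1L))
  rows <- pmin(cg$n_lat, pmax(1L, floor((cg$lat_max - lats) / cg$cell_size) + 1L))
  vals <- coarse$values[as.matrix(expand.grid(row = rows, col = cols))]
  m <- matrix(vals, nrow = target$n_lat, ncol = target$n_lon)
  raster_layer(target, m, variable = coarse$variable, time = coarse$time)
}

#' Closest source cell to a point
#'
#' Index of the trajectory source cell minimising haversine distance to a
#' point; ties resolve to the lowest index (deterministic).
#'
#' @param p Point `c(lon, lat)`.
#' @param sources Matrix or data frame with columns lon, lat (source-cell
#'   centres).
#' @return Integer index into `sources`.
#' @export
nearest_source_cell <- function(p, sources) {
  sources <- as.matrix(sources)[, 1:2, drop = FALSE]
  if (nrow(sources) == 0L) stop("empty source list")
  d <- haversine_km(p, sources)
  which.min(d)  # which.min takes the first minimum: lowest-index tie rule
}
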