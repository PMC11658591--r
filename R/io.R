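# Plain-text on-disk formats.
#
# Rasters are stored as ESRI ASCII grids (.asc): a 6-line header
# (ncols/nrows/xllcorner/yllcorner/cellsize/NODATA_value) followed by the
# value matrix north-up, row-major — readable by GDAL and most GIS tools.
# Gridded series and trajectory stores are CSV files with a JSON sidecar
# header carrying grid and cadence metadata. Values are written with 17
# significant digits so round-trips are bit-exact.

#' Write / read a raster as an ESRI ASCII grid
#'
#' @param layer A `raster_layer`.
#' @param path Output file path (.asc).
#' @param nodata Sentinel written for `NA` cells.
#' @return `write_raster_asc`: the path, invisibly. `read_raster_asc`: a
#'   `raster_layer` (the `variable` is taken from the file name).
#' @export
write_raster_asc <- function(layer, path, nodata = -9999) {
  g <- layer$grid
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_lon),
               sprintf("nrows %d", g$n_lat),
               sprintf("xllcorner %.17g", g$lon_min),
               sprintf("yllcorner %.17g", g$lat_min),
               sprintf("cellsize %.17g", g$cell_size),
               sprintf("NODATA_value %g", nodata)), con)
  v <- layer$values
  v[is.na(v)] <- nodata
  for (i in seq_len(nrow(v)))
    writeLines(paste(sprintf("%.17g", v[i, ]), collapse = " "), con)
  invisible(path)
}

#' @rdname write_raster_asc
#' @export
read_raster_asc <- function(path) {
  lines <- readLines(path)
  hdr <- lines[1:6]
  val <- function(k) {
    ln <- hdr[grepl(paste0("^", k, " "), hdr, ignore.case = TRUE)]
    as.numeric(strsplit(ln, " +")[[1L]][2L])
  }
  ncols <- as.integer(val("ncols")); nrows <- as.integer(val("nrows"))
  xll <- val("xllcorner"); yll <- val("yllcorner")
  cs <- val("cellsize"); nodata <- val("NODATA_value")
  g <- grid_spec(xll, xll + ncols * cs, yll, yll + nrows * cs, cs)
  body <- lines[-(1:6)]
  m <- matrix(as.numeric(unlist(strsplit(body, " +"))),
              nrow = nrows, ncol = ncols, byrow = TRUE)
  m[m == nodata] <- NA
  raster_layer(g, m, variable = sub("\\.asc$", "", basename(path)))
}

#' Write / read a gridded series as CSV + JSON header
#'
#' The CSV holds one row per (time, row, col) with non-`NA` cells only when
#' `sparse = TRUE`; the `.json` sidecar records the grid, variable, and the
#' timestamps.
#'
#' @param series A `gridded_series`.
#' @param path CSV path; a `.json` sidecar is written next to it.
#' @return `write_series_csv`: path, invisibly; `read_series_csv`: a
#'   `gridded_series`.
#' @export
write_series_csv <- function(series, path) {
  g <- series$grid
  meta <- list(grid = g[c("lon_min", "lon_max", "lat_min", "lat_max", "cell_size")],
               variable = series$variable,
               times = format(series$times, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  nt <- length(series$times)
  flat <- aperm(series$frames, c(3L, 2L, 1L))  # lon fastest, then lat, then time
  df <- data.frame(t = rep(seq_len(nt), each = g$n_lat * g$n_lon),
                   row = rep(rep(seq_len(g$n_lat), each = g$n_lon), nt),
                   col = rep(seq_len(g$n_lon), nt * g$n_lat),
                   value = sprintf("%.17g", as.vector(flat)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_series_csv
#' @export
read_series_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  gm <- meta$grid
  g <- grid_spec(gm$lon_min, gm$lon_max, gm$lat_min, gm$lat_max, gm$cell_size)
  times <- as.POSIXct(meta$times, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  df <- utils::read.csv(path)
  nt <- length(times)
  frames <- array(NA_real_, c(nt, g$n_lat, g$n_lon))
  frames[cbind(df$t, df$row, df$col)] <- as.numeric(df$value)
  gridded_series(g, times, frames, variable = meta$variable)
}

#' Write / read a trajectory store as CSV + JSON header
#'
#' One CSV row per trajectory point with columns day, source, realisation,
#' step, time (ISO-8601 UTC), lon, lat, height_m; the sidecar records the
#' source lattice.
#'
#' @param store A `trajectory_store`.
#' @param path CSV path.
#' @return `write_store_csv`: path, invisibly; `read_store_csv`: a
#'   `trajectory_store`.
#' @export
write_store_csv <- function(store, path) {
  meta <- list(sources = list(lon = store$sources[, "lon"],
                              lat = store$sources[, "lat"]),
               days = format(store$days),
               n_realisations = store$n_realisations)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  rows <- list()
  for (d in seq_along(store$days)) {
    day_key <- format(store$days[d])
    for (s in seq_len(nrow(store$sources))) {
      trajs <- store$trajectories[[day_key]][[s]]
      for (r in seq_along(trajs)) {
        pts <- trajs[[r]]$points
        rows[[length(rows) + 1L]] <- data.frame(
          day = day_key, source = s, realisation = r,
          step = seq_len(nrow(pts)),
          time = format(pts$time, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
          lon = sprintf("%.17g", pts$lon), lat = sprintf("%.17g", pts$lat),
          height_m = sprintf("%.17g", pts$height))
      }
    }
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_store_csv
#' @export
read_store_csv <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sources <- cbind(lon = meta$sources$lon, lat = meta$sources$lat)
  days <- as.Date(meta$days)
  df <- utils::read.csv(path)
  df$time <- as.POSIXct(df$time, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  trajectories <- list()
  for (day_key in format(days)) {
    dsub <- df[df$day == day_key, ]
    per_source <- vector("list", nrow(sources))
    for (s in seq_len(nrow(sources))) {
      ssub <- dsub[dsub$source == s, ]
      per_source[[s]] <- lapply(split(ssub, ssub$realisation), function(r) {
        r <- r[order(r$step), ]
        trajectory(day = as.Date(day_key),
                   source = c(sources[s, "lon"], sources[s, "lat"]),
                   points = data.frame(time = r$time, lon = as.numeric(r$lon),
                                       lat = as.numeric(r$lat),
                                       height = as.numeric(r$height_m)))
      })
    }
    trajectories[[day_key]] <- per_source
  }
  trajectory_store(sources, days, trajectories)
}

#' Read / write survey records
#'
#' Survey CSV schema: columns `class` (Hoppers/Adults/Bands/Swarms/Ecology/
#' Control), `lon`, `lat`, `date` (ISO-8601).
#'
#' @param records Data frame with the survey schema.
#' @param path CSV path.
#' @return `read_surveys_csv`: data frame with `date` parsed to `Date`.
#' @export
write_surveys_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surveys_csv
#' @export
read_surveys_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("class", "lon", "lat", "date")
  if (!all(need %in% names(df)))
    stop("survey CSV must have columns class, lon, lat, date")
  df$date <- as.Date(df$date)
  df
}
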