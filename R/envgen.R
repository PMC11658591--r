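# Synthetic environment generator. Produces terrain/soil/land-cover
# layers, 3-hourly weather, 16-day NDVI, survey records and wind-trajectory
# ensembles with the statistical structure the simulator assumes, so every
# module is testable without external downloads. Every generator is a pure
# function of (scenario, seed): the same scenario yields bit-identical
# output.

#' Synthetic scenario description
#'
#' Bundles every knob of the fixture generator. The defaults describe a
#' 3 x 3 degree semi-arid domain on a 60 x 60 grid (0.05 degree cells)
#' with an ocean margin on the east, a 90-day autumn window, episodic
#' early-season rain, a green-up/senescence NDVI cycle, and a steady
#' south-westward wind regime with moderate turbulence - the conditions a
#' single breeding-to-migration generation needs.
#'
#' @param grid `grid_spec` of the domain.
#' @param start,end `Date` range simulated.
#' @param seed Master integer seed; all generators derive their streams
#'   from it.
#' @param wind_regime Data frame with columns `from`, `to` (Dates),
#'   `bearing_deg` (direction of travel, degrees counterclockwise from
#'   East), `speed_ms`, `turbulence_ms` (OU perturbation sd).
#' @param rain_events Data frame with columns `date`, `lon`, `lat`,
#'   `radius_km`, `depth_mm`.
#' @param ndvi Named list: `base`, `peak`, `green_up` (Date), `rise_days`,
#'   `senescence_start` (Date), `senescence_rate` (per day), `noise_sd`.
#' @param temperature Named list: `mean_c`, `amplitude_c`, `lapse_c_per_m`,
#'   `noise_sd`.
#' @param soil Named list: `init_mm`, `decay_days` (e-folding time).
#' @param ocean_cols Number of easternmost columns that are ocean.
#' @param sources Matrix of trajectory source-cell centres (lon, lat).
#' @param n_realisations Trajectory realisations per (source, day).
#' @return Object of class `synthetic_scenario`.
#' @export
synthetic_scenario <- function(
    grid = grid_spec(40, 43, 6, 9, 0.05),
    start = as.Date("2020-09-01"),
    end = as.Date("2020-11-29"),
    seed = 42L,
    wind_regime = data.frame(from = as.Date("2020-05-01"),
                             to = as.Date("2021-03-01"),
                             bearing_deg = 200, speed_ms = 5,
                             turbulence_ms = 1.0),
    rain_events = data.frame(
      date = as.Date(c("2020-08-31", "2020-09-05", "2020-09-12")),
      lon = c(41.5, 40.8, 42.2), lat = c(7.5, 8.2, 6.8),
      radius_km = c(150, 120, 120), depth_mm = c(14, 10, 8)),
    ndvi = list(base = 0.12, peak = 0.45,
                green_up = as.Date("2020-08-15"), rise_days = 48,
                senescence_start = as.Date("2020-11-10"),
                senescence_rate = 0.01, noise_sd = 0.02),
    temperature = list(mean_c = 29, amplitude_c = 5,
                       lapse_c_per_m = 0.0065, noise_sd = 0.5),
    soil = list(init_mm = 8, decay_days = 5),
    ocean_cols = 5L,
    sources = as.matrix(expand.grid(lon = c(40.5, 41.5, 42.5),
                                    lat = c(6.5, 7.5, 8.5))),
    n_realisations = 20L) {
  stopifnot(inherits(grid, "grid_spec"), end > start)
  structure(list(grid = grid, start = as.Date(start), end = as.Date(end),
                 seed = as.integer(seed), wind_regime = wind_regime,
                 rain_events = rain_events, ndvi = ndvi,
                 temperature = temperature, soil = soil,
                 ocean_cols = as.integer(ocean_cols),
                 sources = as.matrix(sources),
                 n_realisations = as.integer(n_realisations)),
            class = "synthetic_scenario")
}

# smooth random field: a few seeded Fourier modes on [0,1]^2, scaled to sd 1
smooth_field <- function(n_lat, n_lon, seed, n_modes = 6) {
  with_seed(seed, {
    u <- (seq_len(n_lon) - 0.5) / n_lon
    v <- (seq_len(n_lat) - 0.5) / n_lat
    f <- matrix(0, n_lat, n_lon)
    for (m in seq_len(n_modes)) {
      kx <- sample(1:3, 1); ky <- sample(1:3, 1)
      ph1 <- stats::runif(1, 0, 2 * pi); ph2 <- stats::runif(1, 0, 2 * pi)
      amp <- stats::rnorm(1)
      f <- f + amp * outer(sin(2 * pi * ky * v + ph2),
                           sin(2 * pi * kx * u + ph1))
    }
    f / max(stats::sd(f), 1e-9)
  })
}

#' Generate static terrain, soil and land-cover layers
#'
#' Elevation is a smooth non-negative surface; sand and clay are smooth
#' weight-percentage fields with sand + clay <= 100; land cover is drawn
#' from CLC100-coded contiguous patches (sparse 60, shrubs 20, cropland
#' 40, closed forest 111, urban 50) with the scenario's eastern ocean
#' margin as permanent water (80).
#'
#' @param scenario A `synthetic_scenario`.
#' @return Named list of `raster_layer`s: `elevation`, `sand`, `clay`,
#'   `landcover`, plus `land_mask` (1 = land, 0 = water).
#' @export
gen_static_layers <- function(scenario) {
  g <- scenario$grid
  f1 <- smooth_field(g$n_lat, g$n_lon, derive_seed(scenario$seed, 1L))
  f2 <- smooth_field(g$n_lat, g$n_lon, derive_seed(scenario$seed, 2L))
  f3 <- smooth_field(g$n_lat, g$n_lon, derive_seed(scenario$seed, 3L))
  elevation <- pmax(400 + 250 * f1, 0)
  sand <- pmin(pmax(50 + 22 * f2, 5), 95)
  clay <- pmin(pmax(25 + 12 * f3, 2), 100 - sand)
  lc_field <- smooth_field(g$n_lat, g$n_lon, derive_seed(scenario$seed, 4L))
  q <- stats::quantile(lc_field, c(0.35, 0.65, 0.85, 0.97))
  landcover <- matrix(60, g$n_lat, g$n_lon)       # sparse vegetation
  landcover[lc_field > q[1]] <- 20                 # shrubs
  landcover[lc_field > q[2]] <- 40                 # cropland
  landcover[lc_field > q[3]] <- 111                # closed forest
  landcover[lc_field > q[4]] <- 50                 # urban
  if (scenario$ocean_cols > 0)
    landcover[, (g$n_lon - scenario$ocean_cols + 1L):g$n_lon] <- 80  # water
  mask <- (landcover != 80) * 1
  list(elevation = raster_layer(g, elevation, "elevation"),
       sand = raster_layer(g, sand, "sand"),
       clay = raster_layer(g, clay, "clay"),
       landcover = raster_layer(g, landcover, "landcover"),
       land_mask = raster_layer(g, mask, "land_mask"))
}

#' Generate 3-hourly weather series
#'
#' Temperature is mean + diurnal sinusoid (minimum near 03:00, maximum
#' near 15:00 local solar time) - lapse x elevation + seeded noise.
#' Precipitation is zero except inside the scenario's rain events (the
#' event depth falls in the midday record of the event day within the
#' event radius). Soil moisture starts at `init_mm`, decays exponentially
#' with the configured e-folding time, and jumps by the rain depth after
#' each event.
#'
#' @param scenario A `synthetic_scenario`.
#' @param spinup_days Extra days generated before `scenario$start` so
#'   moisture look-back windows are always covered (default 3).
#' @return Named list of `gridded_series`: `temperature` (degC),
#'   `precipitation` (mm per 3 h), `soil_moisture` (mm).
#' @export
gen_weather <- function(scenario, spinup_days = 3L) {
  g <- scenario$grid
  tp <- scenario$temperature
  elev <- gen_static_layers(scenario)$elevation$values
  day0 <- scenario$start - spinup_days
  n_days <- as.integer(scenario$end - day0) + 1L
  times <- as.POSIXct(paste(format(day0), "00:00:00"), tz = "UTC") +
    (seq_len(n_days * 8L) - 1L) * 3 * 3600
  nt <- length(times)
  hours <- (as.numeric(times) / 3600) %% 24
  lon_mid <- (g$lon_min + g$lon_max) / 2
  local_hour <- hours + lon_mid / 15
  diurnal <- -cos((local_hour - 3) / 12 * pi) * tp$amplitude_c
  temp <- array(0, c(nt, g$n_lat, g$n_lon))
  base_map <- tp$mean_c - tp$lapse_c_per_m * elev
  noise <- with_seed(derive_seed(scenario$seed, 10L),
                     stats::rnorm(nt, sd = tp$noise_sd))
  for (k in seq_len(nt)) temp[k, , ] <- base_map + diurnal[k] + noise[k]

  precip <- array(0, c(nt, g$n_lat, g$n_lon))
  lons <- grid_lons(g); lats <- grid_lats(g)
  ev <- scenario$rain_events
  for (i in seq_len(nrow(ev))) {
    if (ev$date[i] < day0 || ev$date[i] > scenario$end) next
    d <- as.integer(as.Date(ev$date[i]) - day0)
    k <- d * 8L + 5L  # 12:00 UTC record of the event day
    dist <- outer(lats, lons, function(la, lo)
      haversine_km(c(ev$lon[i], ev$lat[i]), cbind(as.vector(lo), as.vector(la))))
    hit <- dist <= ev$radius_km[i]
    frame <- precip[k, , ]
    frame[hit] <- frame[hit] + ev$depth_mm[i]
    precip[k, , ] <- frame
  }

  sm <- array(0, c(nt, g$n_lat, g$n_lon))
  decay <- exp(-(3 / 24) / scenario$soil$decay_days)
  state <- matrix(scenario$soil$init_mm, g$n_lat, g$n_lon)
  for (k in seq_len(nt)) {
    state <- state * decay + precip[k, , ]
    sm[k, , ] <- state
  }

  list(temperature = gridded_series(g, times, temp, "temperature"),
       precipitation = gridded_series(g, times, precip, "precipitation"),
       soil_moisture = gridded_series(g, times, sm, "soil_moisture"))
}

#' Generate a 16-day NDVI series
#'
#' Vegetated cells follow green-up (linear rise over `rise_days` from
#' `base` to a cell-modulated peak), a plateau, then exponential
#' senescence toward `base`; water cells sit at -0.1. Additive seeded
#' noise. The series starts 160 days before the scenario start so a full
#' 150-day trend window precedes every simulated date.
#'
#' @param scenario A `synthetic_scenario`.
#' @return A `gridded_series` at 16-day cadence (`variable` "ndvi").
#' @export
gen_ndvi <- function(scenario) {
  g <- scenario$grid
  p <- scenario$ndvi
  statics <- gen_static_layers(scenario)
  water <- statics$landcover$values == 80
  mod <- smooth_field(g$n_lat, g$n_lon, derive_seed(scenario$seed, 20L))
  peak_map <- pmin(pmax(p$peak + 0.08 * mod, p$base + 0.05), 0.95)
  dates <- seq(scenario$start - 160L, scenario$end + 16L, by = 16L)
  times <- as.POSIXct(paste(format(dates), "00:00:00"), tz = "UTC")
  nt <- length(times)
  frames <- array(0, c(nt, g$n_lat, g$n_lon))
  noise <- with_seed(derive_seed(scenario$seed, 21L),
                     array(stats::rnorm(nt * g$n_lat * g$n_lon, sd = p$noise_sd),
                           c(nt, g$n_lat, g$n_lon)))
  season_peak <- p$green_up + p$rise_days
  for (k in seq_len(nt)) {
    d <- dates[k]
    rise <- min(1, max(0, as.numeric(d - p$green_up) / p$rise_days))
    sen <- if (d > p$senescence_start)
      exp(-p$senescence_rate * as.numeric(d - p$senescence_start)) else 1
    # weak annual harmonic so baselines are never perfectly flat
    seasonal <- 0.01 * cos(2 * pi * as.numeric(d - season_peak) / 365)
    frame <- p$base + (peak_map - p$base) * rise * sen + seasonal +
      noise[k, , ]
    frame <- pmin(pmax(frame, -0.2), 1)
    frame[water] <- -0.1
    frames[k, , ] <- frame
  }
  gridded_series(g, times, frames, "ndvi")
}

# wind regime row covering a date (error names the field per the config
# contract)
regime_for_day <- function(scenario, day) {
  w <- scenario$wind_regime
  hit <- which(w$from <= day & w$to >= day)
  if (!length(hit)) stop("wind_regime does not cover day ", format(day))
  w[hit[1L], ]
}

#' Generate a wind-trajectory ensemble store
#'
#' For each (source, day), `n_realisations` trajectories are produced by
#' Euler advection (0.5-h step) of the scenario wind regime plus an
#' independent Ornstein-Uhlenbeck turbulent velocity perturbation per
#' realisation; each trajectory spans the day's flight window (two hours
#' after sunrise to one hour before sunset at the source). Heights follow
#' a reflected random walk inside [0, 2000] m.
#'
#' @param scenario A `synthetic_scenario`.
#' @param sources Source-cell centres (default: the scenario's lattice).
#' @param days `Date` vector (default: the scenario range).
#' @return A `trajectory_store`.
#' @export
gen_trajectories <- function(scenario, sources = scenario$sources,
                             days = seq(scenario$start, scenario$end, by = 1L)) {
  days <- as.Date(days)
  if (any(days < scenario$start - 14L | days > scenario$end + 14L))
    stop("day outside scenario range")
  dt <- 1800  # s
  out <- list()
  for (di in seq_along(days)) {
    day <- days[di]
    reg <- regime_for_day(scenario, day)
    b <- reg$bearing_deg * pi / 180
    u0 <- reg$speed_ms * cos(b); v0 <- reg$speed_ms * sin(b)
    sig <- reg$turbulence_ms
    theta <- 1 / (3 * 3600)  # OU relaxation ~3 h
    per_source <- vector("list", nrow(sources))
    for (s in seq_len(nrow(sources))) {
      fw <- flight_window(sources[s, 1L], sources[s, 2L], day)
      steps <- seq(as.numeric(fw$start), as.numeric(fw$end), by = dt)
      tt <- as.POSIXct(steps, origin = "1970-01-01", tz = "UTC")
      n_step <- length(steps); nr <- scenario$n_realisations
      sims <- with_seed(derive_seed(scenario$seed, 30L, di, s), {
        lon <- matrix(sources[s, 1L], nr, n_step)
        lat <- matrix(sources[s, 2L], nr, n_step)
        # vertical spread scales with turbulence so calm ensembles collapse
        # to a single deterministic track
        hgt <- matrix(700 + sig * stats::runif(nr, -400, 400), nr, n_step)
        up <- rep(0, nr); vp <- rep(0, nr)
        for (k in 2:n_step) {
          up <- up - theta * up * dt + sig * sqrt(2 * theta * dt) * stats::rnorm(nr)
          vp <- vp - theta * vp * dt + sig * sqrt(2 * theta * dt) * stats::rnorm(nr)
          u <- u0 + up; v <- v0 + vp
          lat[, k] <- lat[, k - 1L] + v * dt / 110540
          lon[, k] <- lon[, k - 1L] +
            u * dt / (111320 * cos(lat[, k - 1L] * pi / 180))
          h <- hgt[, k - 1L] + sig * stats::rnorm(nr, sd = 30)
          hgt[, k] <- pmin(pmax(h, 0), 2000)
        }
        list(lon = lon, lat = lat, hgt = hgt)
      })
      per_source[[s]] <- lapply(seq_len(scenario$n_realisations), function(r)
        trajectory(day, sources[s, ],
                   data.frame(time = tt, lon = sims$lon[r, ],
                              lat = sims$lat[r, ], height = sims$hgt[r, ])))
    }
    out[[format(day)]] <- per_source
  }
  trajectory_store(sources, days, out)
}

#' Generate synthetic survey records
#'
#' Samples presence records (Hoppers/Bands, equally mixed) with
#' probability proportional to a suitability truth map, and Ecology
#' records uniformly over land cells; dates are uniform over the scenario
#' range. Positions are jittered uniformly inside the sampled cell.
#'
#' @param suitability_truth `raster_layer` in [0, 1] (0/NA = never
#'   sampled for presence); water cells should be 0 or NA.
#' @param n_presence,n_absence Record counts to draw.
#' @param seed Integer seed.
#' @param date_range Two `Date`s for the survey period.
#' @return Survey data frame (`class`, `lon`, `lat`, `date`).
#' @export
gen_surveys <- function(suitability_truth, n_presence, n_absence, seed,
                        date_range = as.Date(c("2020-01-01", "2020-12-31"))) {
  g <- suitability_truth$grid
  truth <- suitability_truth$values
  stopifnot(all(truth >= 0 & truth <= 1, na.rm = TRUE))
  lons <- grid_lons(g); lats <- grid_lats(g)
  cells <- expand.grid(row = seq_len(g$n_lat), col = seq_len(g$n_lon))
  w <- truth[as.matrix(cells)]
  w[is.na(w)] <- 0
  with_seed(derive_seed(seed, 77L), {
    pick_p <- sample.int(nrow(cells), n_presence, replace = TRUE, prob = w)
    land <- which(w > 0 | !is.na(truth[as.matrix(cells)]))
    pick_a <- sample(land, n_absence, replace = TRUE)
    jitter_pos <- function(pick) {
      data.frame(
        lon = lons[cells$col[pick]] + stats::runif(length(pick), -0.5, 0.5) * g$cell_size,
        lat = lats[cells$row[pick]] + stats::runif(length(pick), -0.5, 0.5) * g$cell_size)
    }
    pos_p <- jitter_pos(pick_p); pos_a <- jitter_pos(pick_a)
    dates <- function(n) date_range[1L] +
      sample.int(as.integer(diff(date_range)) + 1L, n, replace = TRUE) - 1L
    rbind(
      data.frame(class = sample(c("Hoppers", "Bands"), n_presence, replace = TRUE),
                 lon = pos_p$lon, lat = pos_p$lat, date = dates(n_presence)),
      data.frame(class = "Ecology", lon = pos_a$lon, lat = pos_a$lat,
                 date = dates(n_absence)))
  })
}
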