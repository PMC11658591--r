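# Lifecycle orchestration: breeding gates -> egg -> hopper -> adult ->
# alternating feeding stays and daily wind-borne flights, over single
# cohorts and ensembles; ensemble summaries and the short-term forecast
# backtracking filter.

#' Assemble a complete synthetic environment bundle
#'
#' Runs every generator for a scenario and packages the simulator inputs:
#' static layers, weather, NDVI, a suitability map and a trajectory store.
#' The bundled suitability is the scenario's structural truth (a smooth
#' function of sand content, zero on water) scaled to 0-100; a trained map
#' from [predict_suitability()] can be substituted.
#'
#' @param scenario A `synthetic_scenario`.
#' @param store Optionally a pre-built `trajectory_store` (else generated).
#' @return List of class `env_bundle`: `scenario`, `statics`, `weather`,
#'   `ndvi`, `suitability`, `store`.
#' @export
fixture_bundle <- function(scenario = synthetic_scenario(), store = NULL) {
  statics <- gen_static_layers(scenario)
  weather <- gen_weather(scenario)
  ndvi <- gen_ndvi(scenario)
  suit <- suitability_truth(statics)
  suit$values <- suit$values * 100
  suit$variable <- "suitability"
  if (is.null(store)) store <- gen_trajectories(scenario)
  structure(list(scenario = scenario, statics = statics, weather = weather,
                 ndvi = ndvi, suitability = suit, store = store),
            class = "env_bundle")
}

#' Structural suitability truth of a synthetic landscape
#'
#' A smooth [0, 1] surface increasing in sand content (locusts lay in
#' sandy soil), zero on water; used to seed synthetic surveys and as the
#' fixture's reference suitability.
#'
#' @param statics Output of [gen_static_layers()].
#' @return `raster_layer` in [0, 1].
#' @export
suitability_truth <- function(statics) {
  sand <- statics$sand$values
  truth <- pmin(pmax((sand - 30) / 40, 0), 1)
  truth[statics$landcover$values == 80] <- 0
  raster_layer(statics$sand$grid, truth, "suitability_truth")
}

# smoothed NDVI series of one cell
ndvi_cell_smoothed <- function(ndvi_series, lon, lat) {
  cs <- extract_cell(ndvi_series, lon, lat)
  list(dates = as.Date(cs$times),
       smoothed = whittaker_smooth(cs$values, lam = 1))
}

# vegetation conditions and stay class at a landing site on a date
site_stay_class <- function(env, lon, lat, date) {
  sm <- ndvi_cell_smoothed(env$ndvi, lon, lat)
  idx <- which(sm$dates <= as.Date(date))
  if (!length(idx)) stop("data gap: no NDVI observation before date")
  value <- sm$smoothed[length(idx)]
  value <- min(1, max(-1, value))
  state <- veg_state(value)
  tr <- ndvi_trend(sm$dates, sm$smoothed, date)
  lc <- raster_value_at(env$statics$landcover, lon, lat)
  grp <- land_group(lc)
  list(class = stay_class(grp, state, tr$state),
       state = state, trend = tr$state, group = grp, ndvi = value)
}

#' Simulate a single cohort
#'
#' Runs one coherent gregarious unit through the full lifecycle at
#' `origin` from `lay_date`: stochastic breeding-site acceptance, the
#' recent-moisture gate, temperature-driven egg and hopper stages with
#' their viability windows and the hopper vegetation condition, then
#' repeated cycles of feeding (stay class from land cover, vegetation
#' state and NDVI trend; duration sampled from the class range) and
#' one-day wind-borne flights (sampled trajectory, clipped at the coast)
#' until `end_date`. The cohort terminates with a reason at the first
#' failed gate.
#'
#' @param origin `c(lon, lat)` breeding location.
#' @param lay_date `Date` of egg laying.
#' @param env An `env_bundle` (see [fixture_bundle()]).
#' @param store A `trajectory_store` (default: the bundle's).
#' @param params A `development_params` list.
#' @param seed Integer seed for this cohort's private stream.
#' @param end_date Simulation end (default: the scenario end).
#' @return List of class `cohort_history`: `state` (compartment reached,
#'   termination reason, key dates), `landings` (data frame: lon, lat,
#'   arrival, stay_class, stay_days), `legs` (list of flight
#'   `trajectory`s).
#' @export
run_cohort <- function(origin, lay_date, env, store = env$store,
                       params = development_params(), seed = 1L,
                       end_date = env$scenario$end) {
  lay_date <- as.Date(lay_date)
  state <- list(compartment = "EGG", lay_date = lay_date,
                hatch_date = NULL, fledge_date = NULL, reason = NULL,
                origin = origin)
  landings <- NULL; legs <- list()
  done <- function(compartment, reason) {
    state$compartment <<- compartment
    state$reason <<- reason
    structure(list(state = state, landings = landings, legs = legs),
              class = "cohort_history")
  }
  with_seed(seed, {
    s <- raster_value_at(env$suitability, origin[1L], origin[2L])
    if (is.na(s) || !breeding_site_accepted(s))
      return(done("TERMINATED", "site-rejected"))
    pr <- extract_cell(env$weather$precipitation, origin[1L], origin[2L])
    smo <- extract_cell(env$weather$soil_moisture, origin[1L], origin[2L])
    if (!moisture_ok(lay_date, pr, smo))
      return(done("TERMINATED", "moisture-fail"))
    temps <- extract_cell(env$weather$temperature, origin[1L], origin[2L])
    # a stage still developing when the simulated period ends is not a data
    # gap: the run simply stops there
    still_developing <- function(e) {
      if (grepl("shorter than max_days", conditionMessage(e)))
        structure(list(status = "incomplete", completion_date = NULL,
                       duration_days = NA_integer_),
                  class = "stage_outcome")
      else stop(e)
    }
    egg <- tryCatch(egg_stage(lay_date, temps, params),
                    error = still_developing)
    if (egg$status == "incomplete")
      return(done("EGG", "simulation-end"))
    if (egg$status != "success")
      return(done("TERMINATED",
                  if (egg$status == "nonviable") "egg-nonviable"
                  else "egg-never-completed"))
    state$hatch_date <- egg$completion_date
    state$compartment <- "HOPPER"
    nd <- ndvi_cell_smoothed(env$ndvi, origin[1L], origin[2L])
    hop <- tryCatch(hopper_stage(egg$completion_date, temps, nd$dates,
                                 nd$smoothed, params),
                    error = still_developing)
    if (hop$status == "incomplete")
      return(done("HOPPER", "simulation-end"))
    if (hop$status != "success")
      return(done("TERMINATED",
                  switch(hop$status,
                         nonviable = "hopper-nonviable",
                         `vegetation-fail` = "vegetation-fail",
                         "hopper-never-completed")))
    state$fledge_date <- hop$completion_date
    state$compartment <- "ADULT"

    site <- origin
    date <- hop$completion_date
    repeat {
      sc <- site_stay_class(env, site[1L], site[2L], date)
      stay <- sample_stay_days(sc$class)
      landings <- rbind(landings,
                        data.frame(lon = site[1L], lat = site[2L],
                                   arrival = date, stay_class = sc$class,
                                   stay_days = stay))
      depart <- date + stay + 1L
      if (depart > end_date) return(done("ADULT", "simulation-end"))
      traj <- sample_trajectory(store, site, depart)
      traj <- stop_at_coast(traj, env$statics$land_mask)
      legs[[length(legs) + 1L]] <- traj
      n <- nrow(traj$points)
      site <- c(traj$points$lon[n], traj$points$lat[n])
      date <- depart
    }
  })
}

#' @export
print.cohort_history <- function(x, ...) {
  cat(sprintf("cohort: %s (%s); lay %s", x$state$compartment,
              x$state$reason %||% "", format(x$state$lay_date)))
  if (!is.null(x$state$fledge_date))
    cat(sprintf(", fledge %s, %d landings", format(x$state$fledge_date),
                NROW(x$landings)))
  cat("\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate an ensemble of cohorts
#'
#' Samples breeding origins uniformly over the land cells of a rectangular
#' region and lay dates uniformly over a window, then runs each cohort
#' with a seed derived reproducibly from the master seed. Two modes:
#' `"fixed"` runs exactly `n` attempts; `"until_k"` keeps attempting until
#' `k` cohorts reach the adult/migration stage (capped at 1000 k
#' attempts).
#'
#' @param region List/vector with lon_min, lon_max, lat_min, lat_max.
#' @param n Number of attempts (mode "fixed") or ignored (mode "until_k").
#' @param lay_window Two `Date`s.
#' @param env An `env_bundle`.
#' @param params A `development_params`.
#' @param master_seed Integer master seed.
#' @param mode "fixed" or "until_k".
#' @param k Successes required in mode "until_k".
#' @return List of `cohort_history` objects.
#' @export
run_ensemble <- function(region, n, lay_window, env,
                         params = development_params(), master_seed = 1L,
                         mode = c("fixed", "until_k"), k = 25L) {
  mode <- match.arg(mode)
  if (mode == "fixed" && n == 0) return(list())
  g <- env$suitability$grid
  region <- as.list(region)
  lons <- grid_lons(g); lats <- grid_lats(g)
  cols <- which(lons >= region$lon_min & lons <= region$lon_max)
  rows <- which(lats >= region$lat_min & lats <= region$lat_max)
  if (!length(cols) || !length(rows)) stop("invalid region: outside grid")
  land <- env$statics$land_mask$values[rows, cols, drop = FALSE]
  cand <- which(land == 1, arr.ind = TRUE)
  if (nrow(cand) == 0L) stop("invalid region: no land cells")
  window <- as.Date(lay_window)
  draw_one <- function(id) {
    with_seed(derive_seed(master_seed, 500L, id), {
      pick <- cand[sample.int(nrow(cand), 1L), ]
      origin <- c(lons[cols[pick[2L]]], lats[rows[pick[1L]]])
      lay <- window[1L] +
        sample.int(as.integer(window[2L] - window[1L]) + 1L, 1L) - 1L
      list(origin = origin, lay = lay)
    })
  }
  histories <- list()
  if (mode == "fixed") {
    for (id in seq_len(n)) {
      d <- draw_one(id)
      histories[[id]] <- run_cohort(d$origin, d$lay, env, params = params,
                                    seed = derive_seed(master_seed, 600L, id))
    }
  } else {
    id <- 0L; successes <- 0L
    while (successes < k && id < 1000L * k) {
      id <- id + 1L
      d <- draw_one(id)
      h <- run_cohort(d$origin, d$lay, env, params = params,
                      seed = derive_seed(master_seed, 600L, id))
      if (h$state$compartment == "ADULT") {
        successes <- successes + 1L
        histories[[successes]] <- h
      }
    }
  }
  histories
}

#' Summarise an ensemble into arrival-date and visit-fraction maps
#'
#' A history visits a cell when one of its landing sites falls in it (and,
#' with `include_flight = TRUE`, when any flight-leg point does). The
#' visit fraction is the share of histories visiting the cell; the
#' arrival map is the per-cell median (over visiting histories) of each
#' history's first visit date.
#'
#' @param histories List of `cohort_history` (non-empty).
#' @param grid `grid_spec` of the output maps.
#' @param include_flight Count flight-leg overflight as visits (default
#'   FALSE: landings only).
#' @return List of class `ensemble_summary`: `visit_fraction`
#'   (`raster_layer` in [0, 1]), `median_arrival` (`raster_layer` of
#'   numeric dates, NA where unvisited), `n`.
#' @export
summarise_ensemble <- function(histories, grid, include_flight = FALSE) {
  if (!length(histories)) stop("histories must be non-empty")
  n <- length(histories)
  visits <- matrix(0, grid$n_lat, grid$n_lon)
  arrivals <- vector("list", grid$n_lat * grid$n_lon)
  for (h in histories) {
    pts <- NULL
    if (NROW(h$landings))
      pts <- data.frame(lon = h$landings$lon, lat = h$landings$lat,
                        date = as.numeric(h$landings$arrival))
    if (include_flight && length(h$legs)) {
      for (leg in h$legs)
        pts <- rbind(pts, data.frame(lon = leg$points$lon,
                                     lat = leg$points$lat,
                                     date = as.numeric(as.Date(leg$day))))
    }
    if (is.null(pts)) next
    inside <- pts$lon >= grid$lon_min & pts$lon <= grid$lon_max &
      pts$lat >= grid$lat_min & pts$lat <= grid$lat_max
    pts <- pts[inside, , drop = FALSE]
    if (!nrow(pts)) next
    ij <- t(vapply(seq_len(nrow(pts)),
                   function(i) cell_index(grid, pts$lon[i], pts$lat[i]),
                   integer(2)))
    lin <- (ij[, 2L] - 1L) * grid$n_lat + ij[, 1L]
    first <- tapply(pts$date, lin, min)
    cells <- as.integer(names(first))
    visits[cells] <- visits[cells] + 1
    for (ci in seq_along(cells))
      arrivals[[cells[ci]]] <- c(arrivals[[cells[ci]]], first[[ci]])
  }
  med <- matrix(NA_real_, grid$n_lat, grid$n_lon)
  has <- which(vapply(arrivals, length, 0L) > 0)
  med[has] <- vapply(arrivals[has], stats::median, 0)
  structure(list(visit_fraction = raster_layer(grid, visits / n, "visit_fraction"),
                 median_arrival = raster_layer(grid, med, "median_arrival"),
                 n = n),
            class = "ensemble_summary")
}

#' @export
print.ensemble_summary <- function(x, ...) {
  vf <- x$visit_fraction$values
  cat(sprintf("ensemble_summary over %d histories: %d cells visited (max fraction %.2f)\n",
              x$n, sum(vf > 0), max(vf)))
  invisible(x)
}

#' Short-term forecast from a single swarm sighting
#'
#' Backtracking filter for a swarm reported in flight: sample
#' `n_samples` flight start points area-uniformly over the land cells of
#' a disk of `radius_km` around the report, draw one trajectory per start
#' for the report day, retain those passing within `pass_km` of the
#' report, and map the retained trajectories' endpoints as a normalised
#' landing-risk surface.
#'
#' @param report `c(lon, lat)` of the sighting.
#' @param date `Date` of the sighting.
#' @param store A `trajectory_store` covering `date`.
#' @param land_mask `raster_layer`, 1 = land.
#' @param n_samples Start points to sample (default 10000).
#' @param radius_km Sampling radius around the report (default 250).
#' @param pass_km Pass distance for retention (default 5; `Inf` disables
#'   the filter).
#' @param seed Integer seed.
#' @return List of class `forecast_result`: `retained` (list of
#'   trajectories), `min_pass_km` (their minimum pass distances), `risk`
#'   (`raster_layer` summing to 1 over endpoint cells; all zero when
#'   nothing is retained, with a warning).
#' @export
forecast_short_term <- function(report, date, store, land_mask,
                                n_samples = 10000L, radius_km = 250,
                                pass_km = 5, seed = 1L) {
  g <- land_mask$grid
  with_seed(derive_seed(seed, 900L), {
    starts <- matrix(NA_real_, n_samples, 2L)
    got <- 0L; attempts <- 0L
    while (got < n_samples && attempts < 200L * n_samples) {
      m <- n_samples - got
      attempts <- attempts + m
      r <- radius_km * sqrt(stats::runif(m))
      th <- stats::runif(m, 0, 2 * pi)
      lat <- report[2L] + r * sin(th) / 110.54
      lon <- report[1L] + r * cos(th) / (111.32 * cos(report[2L] * pi / 180))
      ok <- lon >= g$lon_min & lon <= g$lon_max &
        lat >= g$lat_min & lat <= g$lat_max
      if (any(ok)) {
        land <- vapply(which(ok), function(i)
          isTRUE(raster_value_at(land_mask, lon[i], lat[i]) == 1), logical(1))
        idx <- which(ok)[land]
        if (length(idx)) {
          take <- idx[seq_len(min(length(idx), n_samples - got))]
          starts[got + seq_along(take), ] <- cbind(lon[take], lat[take])
          got <- got + length(take)
        }
      }
    }
    if (got < n_samples)
      stop("could not sample enough land start points inside the grid")
    retained <- list(); min_pass <- numeric(0)
    for (i in seq_len(n_samples)) {
      tr <- sample_trajectory(store, starts[i, ], date)
      d <- min(haversine_km(report, cbind(tr$points$lon, tr$points$lat)))
      if (d <= pass_km) {
        retained[[length(retained) + 1L]] <- tr
        min_pass <- c(min_pass, d)
      }
    }
    risk <- matrix(0, g$n_lat, g$n_lon)
    if (length(retained)) {
      for (tr in retained) {
        n <- nrow(tr$points)
        lon <- tr$points$lon[n]; lat <- tr$points$lat[n]
        if (lon >= g$lon_min && lon <= g$lon_max &&
            lat >= g$lat_min && lat <= g$lat_max) {
          ij <- cell_index(g, lon, lat)
          risk[ij[1L], ij[2L]] <- risk[ij[1L], ij[2L]] + 1
        }
      }
      if (sum(risk) > 0) risk <- risk / sum(risk)
    } else {
      warning("no sampled trajectory passed within pass_km of the report")
    }
    structure(list(retained = retained, min_pass_km = min_pass,
                   risk = raster_layer(g, risk, "landing_risk"),
                   n_samples = n_samples),
              class = "forecast_result")
  })
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("forecast_result: %d of %d trajectories retained\n",
              length(x$retained), x$n_samples))
  invisible(x)
}

#' Operational-scale trajectory-count arithmetic
#'
#' Planned trajectory count of a configuration: sources x realisations x
#' days. At the full operational scale (3860 sources, 1000 realisations,
#' 1 September 2019 - 31 December 2021) this is nearly 3.3 billion.
#'
#' @param n_sources Number of source cells.
#' @param n_realisations Realisations per (source, day).
#' @param first_day,last_day `Date` range (inclusive).
#' @return Numeric trajectory count.
#' @export
planned_trajectory_count <- function(n_sources = 3860,
                                     n_realisations = 1000,
                                     first_day = as.Date("2019-09-01"),
                                     last_day = as.Date("2021-12-31")) {
  n_days <- as.numeric(as.Date(last_day) - as.Date(first_day)) + 1
  n_sources * n_realisations * n_days
}
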