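test_that("static layers are deterministic and physically consistent", {
  scen <- synthetic_scenario()
  a <- gen_static_layers(scen)
  b <- gen_static_layers(scen)
  for (nm in names(a)) expect_identical(a[[nm]]$values, b[[nm]]$values)

  expect_true(all(a$elevation$values >= 0))
  expect_true(all(a$sand$values >= 0 & a$sand$values <= 100))
  expect_true(all(a$clay$values >= 0 & a$clay$values <= 100))
  expect_true(all(a$sand$values + a$clay$values <= 100 + 1e-9))

  # the designated ocean margin occupies the eastern columns
  lc <- a$landcover$values
  east <- lc[, (ncol(lc) - scen$ocean_cols + 1):ncol(lc)]
  expect_true(all(east == 80))
  expect_true(all(lc[, 1:(ncol(lc) - scen$ocean_cols)] != 80))
  expect_identical(a$land_mask$values == 1, lc != 80)
})

test_that("weather series have the configured structure", {
  scen <- synthetic_scenario(
    grid = grid_spec(40, 41, 6, 7, 0.1),
    end = as.Date("2020-09-20"),
    temperature = list(mean_c = 28, amplitude_c = 0, lapse_c_per_m = 0,
                       noise_sd = 0))
  w <- gen_weather(scen)
  # zero amplitude, zero lapse, zero noise: constant temperature
  expect_true(all(abs(w$temperature$frames - 28) < 1e-9))

  # with a diurnal cycle, daily max - min ~ 2 x amplitude
  scen2 <- synthetic_scenario(
    grid = grid_spec(40, 41, 6, 7, 0.1),
    end = as.Date("2020-09-20"),
    temperature = list(mean_c = 28, amplitude_c = 5, lapse_c_per_m = 0,
                       noise_sd = 0.1))
  w2 <- gen_weather(scen2)
  cell <- extract_cell(w2$temperature, 40.5, 6.5)
  one_day <- cell$values[33:40]
  expect_lt(abs((max(one_day) - min(one_day)) - 10), 1)

  # soil moisture strictly decreasing between rain events
  sm <- extract_cell(w2$soil_moisture, 40.5, 6.5)
  pr <- extract_cell(w2$precipitation, 40.5, 6.5)
  dry <- which(pr$values == 0)
  run <- dry[dry > 1]
  expect_true(all(diff(sm$values)[run - 1] < 0 |
                    pr$values[run] > 0))
  # precipitation is zero outside rain events
  ev_dates <- as.Date(scen2$rain_events$date)
  rec_dates <- as.Date(pr$times)
  expect_true(all(pr$values[!rec_dates %in% ev_dates] == 0))
})

test_that("NDVI phenology is bounded, unimodal and water-negative", {
  scen <- synthetic_scenario(grid = grid_spec(40, 41, 6, 7, 0.1),
                             ndvi = list(base = 0.12, peak = 0.5,
                                         green_up = as.Date("2020-08-15"),
                                         rise_days = 48,
                                         senescence_start = as.Date("2020-11-10"),
                                         senescence_rate = 0.01,
                                         noise_sd = 0))
  nd <- gen_ndvi(scen)
  expect_true(all(nd$frames >= -0.2 & nd$frames <= 1))

  statics <- gen_static_layers(scen)
  water_col <- ncol(statics$landcover$values)  # ocean margin
  water_series <- nd$frames[, 1, water_col]
  expect_true(all(water_series < 0))

  # noise-free vegetated profile: single peak recovered where the rise ends
  cs <- extract_cell(nd, 40.2, 6.5)
  pk <- find_peaks(cs$values, m = 2)
  expect_length(pk, 1L)
  plateau_start <- scen$ndvi$green_up + scen$ndvi$rise_days
  expect_lte(abs(as.numeric(as.Date(cs$times[pk]) - plateau_start)), 16)
})

test_that("trajectory kinematics follow the wind field", {
  # no turbulence, uniform 10 m/s eastward wind: endpoint displacement is
  # speed x window duration, due east
  scen <- calm_east_scenario(speed_ms = 10, turbulence_ms = 0,
                             n_realisations = 2L)
  store <- gen_trajectories(scen, days = scen$start)
  tr <- store$trajectories[[format(scen$start)]][[1]][[1]]
  n <- nrow(tr$points)
  dur_s <- as.numeric(tr$points$time[n] - tr$points$time[1], units = "secs")
  dist <- haversine_km(c(tr$points$lon[1], tr$points$lat[1]),
                       c(tr$points$lon[n], tr$points$lat[n]))
  expect_lt(abs(dist - 10 * dur_s / 1000), 1)
  expect_equal(tr$points$lat[n], tr$points$lat[1], tolerance = 1e-9)
  expect_gt(tr$points$lon[n], tr$points$lon[1])
  # ~9-h windows at these latitudes: a steady 10 m/s wind carries the
  # swarm a bit over 300 km in a day
  expect_gt(dist, 300)

  # without turbulence all realisations coincide
  tr2 <- store$trajectories[[format(scen$start)]][[1]][[2]]
  expect_identical(tr$points, tr2$points)

  # endpoint spread grows with turbulence intensity
  spread <- sapply(c(0.5, 1.5, 3), function(sig) {
    s <- calm_east_scenario(turbulence_ms = sig, n_realisations = 15L)
    st <- gen_trajectories(s, days = s$start)
    ends <- t(sapply(st$trajectories[[format(s$start)]][[1]], function(t2) {
      p <- t2$points
      c(p$lon[nrow(p)], p$lat[nrow(p)])
    }))
    mean(sqrt((ends[, 1] - mean(ends[, 1]))^2 +
                (ends[, 2] - mean(ends[, 2]))^2))
  })
  expect_true(all(diff(spread) > 0))

  # implied point-to-point speed never exceeds wind + 3 sigma turbulence
  scen3 <- calm_east_scenario(speed_ms = 5, turbulence_ms = 1,
                              n_realisations = 10L)
  st3 <- gen_trajectories(scen3, days = scen3$start)
  for (t3 in st3$trajectories[[format(scen3$start)]][[1]]) {
    p <- t3$points
    for (k in 2:nrow(p)) {
      d_km <- haversine_km(c(p$lon[k - 1], p$lat[k - 1]),
                           c(p$lon[k], p$lat[k]))
      expect_lt(d_km * 1000 / 1800, 5 + 3 * 1 + 1)
    }
  }

  expect_error(gen_trajectories(scen, days = as.Date("2021-06-01")),
               "outside")
  # heights bounded
  expect_true(all(tr$points$height >= 0 & tr$points$height <= 2000))
})

test_that("survey generation respects counts, truth and determinism", {
  scen <- synthetic_scenario(grid = grid_spec(40, 41, 6, 7, 0.1))
  statics <- gen_static_layers(scen)
  truth <- suitability_truth(statics)

  s1 <- gen_surveys(truth, 120, 60, seed = 9)
  s2 <- gen_surveys(truth, 120, 60, seed = 9)
  expect_identical(s1, s2)
  expect_equal(sum(s1$class %in% c("Hoppers", "Bands")), 120)
  expect_equal(sum(s1$class == "Ecology"), 60)

  # presence samples concentrate where truth is high
  t_at <- function(df) mapply(function(lo, la)
    raster_value_at(truth, lo, la), df$lon, df$lat)
  pres <- s1[s1$class != "Ecology", ]
  eco <- s1[s1$class == "Ecology", ]
  expect_gt(mean(t_at(pres)), mean(t_at(eco)))

  # truth confined to one patch confines presence points
  patch <- truth
  patch$values[] <- 0
  patch$values[1:3, 1:3] <- 1
  s3 <- gen_surveys(patch, 50, 10, seed = 1)
  pres3 <- s3[s3$class != "Ecology", ]
  expect_true(all(pres3$lon <= 40 + 4 * 0.1))
  expect_true(all(pres3$lat >= 7 - 4 * 0.1))
})

test_that("text round-trips are bit-exact", {
  scen <- synthetic_scenario(grid = grid_spec(40, 41, 6, 7, 0.1),
                             end = as.Date("2020-09-15"),
                             sources = cbind(lon = 40.5, lat = 6.5),
                             n_realisations = 2L)
  statics <- gen_static_layers(scen)
  td <- withr::local_tempdir()

  p <- file.path(td, "elevation.asc")
  write_raster_asc(statics$elevation, p)
  back <- read_raster_asc(p)
  expect_identical(back$values, statics$elevation$values)
  expect_equal(back$grid$lon_min, 40)

  nd <- gen_ndvi(scen)
  ps <- file.path(td, "ndvi.csv")
  write_series_csv(nd, ps)
  nd2 <- read_series_csv(ps)
  expect_identical(nd2$frames, nd$frames)
  expect_equal(nd2$times, nd$times)

  store <- gen_trajectories(scen, days = seq(scen$start, scen$start + 1, 1))
  pt <- file.path(td, "store.csv")
  write_store_csv(store, pt)
  store2 <- read_store_csv(pt)
  expect_equal(store2$n_realisations, store$n_realisations)
  k <- format(scen$start)
  expect_identical(store2$trajectories[[k]][[1]][[2]]$points$lon,
                   store$trajectories[[k]][[1]][[2]]$points$lon)
  expect_equal(store2$trajectories[[k]][[1]][[1]]$points$time,
               store$trajectories[[k]][[1]][[1]]$points$time)
})
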