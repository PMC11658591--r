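# Shared fixtures, built once per test session.

.fixture_cache <- new.env(parent = emptyenv())

# default synthetic study: 60x60 grid, 9 sources, 20 realisations, 90 days
test_bundle <- function() {
  if (is.null(.fixture_cache$bundle))
    .fixture_cache$bundle <- fixture_bundle(synthetic_scenario())
  .fixture_cache$bundle
}

# small quiet scenario for trajectory arithmetic: no turbulence, steady
# eastward wind
calm_east_scenario <- function(speed_ms = 10, turbulence_ms = 0,
                               n_realisations = 3L) {
  synthetic_scenario(
    grid = grid_spec(38, 46, 3, 11, 0.1),
    start = as.Date("2020-09-20"), end = as.Date("2020-09-25"),
    seed = 11L,
    wind_regime = data.frame(from = as.Date("2020-09-01"),
                             to = as.Date("2020-10-01"),
                             bearing_deg = 0, speed_ms = speed_ms,
                             turbulence_ms = turbulence_ms),
    rain_events = data.frame(date = as.Date("2020-09-10"), lon = 42,
                             lat = 7, radius_km = 100, depth_mm = 10),
    ocean_cols = 0L,
    sources = cbind(lon = 40, lat = 7),
    n_realisations = n_realisations)
}

# constant-temperature 3-hourly cell series over n_days from start
const_temp_series <- function(t_c, start, n_days = 220) {
  times <- as.POSIXct(paste(format(as.Date(start)), "00:00:00"), tz = "UTC") +
    (seq_len(n_days * 8L) - 1L) * 3 * 3600
  structure(list(times = times, values = rep(t_c, length(times))),
            class = "cell_series")
}

# brute-force peak scan following the neighbourhood definition directly
brute_force_peaks <- function(series, m) {
  n <- length(series)
  starts <- integer(0)
  for (i in seq_len(n)) {
    if (i - m < 1 || i + m > n) next
    if (all(series[c((i - m):(i - 1), (i + 1):(i + m))] <= series[i])) {
      j <- as.integer(i)
      while (j > 1L && series[j - 1L] == series[i]) j <- j - 1L
      starts <- c(starts, j)
    }
  }
  sort(unique(starts))
}

# serialise a cohort history for bitwise comparison
history_digest <- function(histories) {
  path <- tempfile(fileext = ".jsonl")
  write_history_log(histories, path)
  on.exit(unlink(path))
  paste(readLines(path), collapse = "\n")
}
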