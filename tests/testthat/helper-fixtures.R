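# Fixtures built in code: drifting-circle windows with analytic ground truth.

# Planar window of a balanced turn drifting with constant wind. Coordinates
# are centred so the window is directly comparable with project_window()
# output; no geographic projection is involved.
planar_loop_window <- function(v = 11, r = 30, wind_e = 0, wind_n = 0,
                               turn = 1L, phase0 = 0, altitude = 1000,
                               noise_sigma = 0, seed = NULL, t = 0:30) {
  w <- v / r
  x <- wind_e * t + r * cos(turn * w * t + phase0)
  y <- wind_n * t + r * sin(turn * w * t + phase0)
  if (noise_sigma > 0) {
    if (!is.null(seed)) set.seed(seed)
    x <- x + stats::rnorm(length(t), sd = noise_sigma)
    y <- y + stats::rnorm(length(t), sd = noise_sigma)
  }
  structure(list(lon0 = 0, lat0 = 0, x = x - mean(x), y = y - mean(y),
                 z = rep(altitude, length(t)), t = t - t[1],
                 start = as.POSIXct("2015-03-01 06:00:00", tz = "UTC")),
            class = "planar_window")
}

# loop_segment assembled from a planar window through the same velocity /
# heading operations the segment scanner applies.
planar_loop_segment <- function(...) {
  pw <- planar_loop_window(...)
  vel <- ground_velocity(pw)
  h <- heading_series(vel$ve, vel$vn)
  if (is.null(h)) return(NULL)
  turn <- (h[length(h)] - h[1]) * 30 / 29
  structure(list(segment_id = 1L, individual = "fixture", burst = 1L,
                 start = pw$start, window = pw, velocities = vel,
                 cumulative_turn = turn, duration = 30,
                 turn_direction = if (turn >= 0) 1L else -1L,
                 mean_altitude = mean(pw$z), air_density = NA_real_,
                 vertical_speed = 0), class = "loop_segment")
}

# In-memory straight-flight track (constant ground velocity), never circling.
straight_track <- function(n = 200, speed = 10, lat0 = 27.5, lon0 = 90.5) {
  t <- seq_len(n) - 1
  ll <- xy_to_lonlat(speed * t, 0 * t, lon0, lat0)
  structure(data.frame(individual = "straight",
                       timestamp = as.POSIXct("2015-03-01 06:00:00",
                                              tz = "UTC") + t,
                       lon = ll$lon, lat = ll$lat, altitude = 1000,
                       air_density = NA_real_, burst = 1L,
                       stringsAsFactors = FALSE),
            class = c("soar_track", "data.frame"))
}

# Movebank-style CSV writer for arbitrary fix tables.
write_movebank_csv <- function(track, path, density = FALSE) {
  out <- data.frame(
    timestamp = format(track$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    `location-long` = track$lon, `location-lat` = track$lat,
    `height-above-msl` = track$altitude,
    `individual-local-identifier` = track$individual,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (density) out$`air-density` <- track$air_density
  utils::write.csv(out, path, row.names = FALSE)
  path
}
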