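#' Configuration for a simulated thermalling burst
#'
#' Defaults emulate the observed flights this package analyses: 10-minute
#' 1 Hz bursts of circular thermalling (airspeed 8--16 m s^-1, circle radius
#' 20--60 m) drifting with a constant horizontal wind, climbing at about
#' 1 m s^-1, with metre-scale Gaussian GPS position noise and an ISA
#' altitude-density profile spanning roughly 1.1 down to 0.65 kg m^-3
#' across the flight band.
#'
#' @param airspeed air-relative speed (m s^-1); must exceed the wind speed.
#' @param radius circle radius (m).
#' @param turn_direction +1 counterclockwise, -1 clockwise.
#' @param wind_east,wind_north constant wind (m s^-1) for the whole burst.
#' @param climb_rate vertical speed (m s^-1).
#' @param start_altitude m above mean sea level.
#' @param burst_s burst duration (s); a burst of `burst_s` seconds holds
#'   `burst_s + 1` fixes (t = 0..burst_s).
#' @param gps_noise_sigma std. dev. of Gaussian position noise per
#'   horizontal coordinate (m).
#' @param density_model `"isa"` (density from altitude via the standard
#'   atmosphere), `"fixed"` (constant `fixed_rho`), or `"none"` (no density
#'   column, exercising the downstream fallback).
#' @param fixed_rho density used when `density_model = "fixed"`.
#' @param seed RNG seed; mandatory, there is no implicit randomness.
#' @param phase0 initial phase of the circle (radians).
#' @param start_lon,start_lat reference position (degrees).
#' @param individual id string stamped on the fixes.
#' @param start_time POSIXct of the first fix.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(airspeed = 11, radius = 30,
                              turn_direction = 1L, wind_east = 3,
                              wind_north = -2, climb_rate = 1,
                              start_altitude = 1000, burst_s = 600,
                              gps_noise_sigma = 0.5,
                              density_model = c("isa", "fixed", "none"),
                              fixed_rho = 1.1, seed, phase0 = 0,
                              start_lon = 90.5, start_lat = 27.5,
                              individual = "sim-bird-1",
                              start_time = as.POSIXct("2015-03-01 06:00:00",
                                                      tz = "UTC")) {
  if (missing(seed)) stop("a seed is mandatory: no implicit randomness")
  stopifnot(airspeed > 0, radius > 0, turn_direction %in% c(-1L, 1L),
            gps_noise_sigma >= 0, burst_s >= 30)
  if (airspeed <= sqrt(wind_east^2 + wind_north^2))
    stop("airspeed must exceed the wind speed for a conforming scenario")
  structure(list(airspeed = airspeed, radius = radius,
                 turn_direction = as.integer(turn_direction),
                 wind_east = wind_east, wind_north = wind_north,
                 climb_rate = climb_rate, start_altitude = start_altitude,
                 burst_s = burst_s, gps_noise_sigma = gps_noise_sigma,
                 density_model = match.arg(density_model),
                 fixed_rho = fixed_rho, seed = seed, phase0 = phase0,
                 start_lon = start_lon, start_lat = start_lat,
                 individual = individual, start_time = start_time),
            class = "simulation_config")
}

#' Simulate a thermalling GPS burst with known ground truth
#'
#' Generates the planar path of a balanced turn drifting with a constant
#' wind, p(t) = (wE, wN) t + r (cos(s w t + phi0), sin(s w t + phi0)) with
#' w = v / r, climbs at the configured rate, adds independent Gaussian noise
#' to each horizontal coordinate, and inverse-projects onto the globe about
#' the start position. Ground truth is recorded for every contiguous 30 s
#' window so each pipeline stage can be checked against known values.
#'
#' @param config a [simulation_config()].
#' @return a `soar_simulation`: list with `track` (a `soar_track` in the
#'   same schema the reader produces), `truth` (data frame per 30 s window:
#'   wind, airspeed, omega, r, bank, lift acceleration, C_L, rho, altitude,
#'   vertical speed) and the `config`.
#' @export
simulate_thermalling_track <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  cf <- config
  t <- 0:cf$burst_s
  w <- cf$airspeed / cf$radius
  s <- cf$turn_direction
  x <- cf$wind_east * t + cf$radius * cos(s * w * t + cf$phase0)
  y <- cf$wind_north * t + cf$radius * sin(s * w * t + cf$phase0)
  alt <- cf$start_altitude + cf$climb_rate * t
  if (cf$gps_noise_sigma > 0) {
    old <- if (exists(".Random.seed", .GlobalEnv))
      get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(cf$seed)
    x <- x + stats::rnorm(length(t), sd = cf$gps_noise_sigma)
    y <- y + stats::rnorm(length(t), sd = cf$gps_noise_sigma)
  }
  ll <- xy_to_lonlat(x, y, cf$start_lon, cf$start_lat)
  rho <- switch(cf$density_model,
                isa = isa_density(alt),
                fixed = rep(cf$fixed_rho, length(t)),
                none = rep(NA_real_, length(t)))
  track <- data.frame(individual = cf$individual,
                      timestamp = cf$start_time + t,
                      lon = ll$lon, lat = ll$lat, altitude = alt,
                      air_density = rho, burst = 1L,
                      stringsAsFactors = FALSE)
  class(track) <- c("soar_track", "data.frame")

  starts <- seq(0, cf$burst_s - 30, by = 30)
  truth <- do.call(rbind, lapply(starts, function(t0) {
    h <- cf$start_altitude + cf$climb_rate * (t0 + 15)
    rho_w <- switch(cf$density_model, isa = isa_density(h),
                    fixed = cf$fixed_rho, none = NA_real_)
    l <- lift_acceleration(cf$airspeed, cf$radius)
    data.frame(
      window_start_s = t0, wind_east = cf$wind_east,
      wind_north = cf$wind_north, airspeed = cf$airspeed,
      omega = w, r = cf$radius, bank = bank_angle(cf$airspeed, cf$radius),
      lift_accel = l,
      C_L = if (is.na(rho_w)) NA_real_ else
        lift_coefficient(l, 10.54, rho_w, cf$airspeed),
      rho = rho_w, altitude = h, vertical_speed = cf$climb_rate)
  }))
  structure(list(track = track, truth = truth, config = cf),
            class = "soar_simulation")
}

#' Simulate a population holding the lift coefficient constant
#'
#' The behavioural hypothesis under study: birds keep wing configuration
#' (hence C_L) fixed and compensate for thin air by flying faster and wider.
#' For each flight level the true airspeed is set by inverting the lift
#' balance with l = g, v = sqrt(2 g (m/S) / (rho C_L)), and the circle
#' radius is scaled as r = v^2 / (g tan(bank)) so the bank angle stays
#' constant (r proportional to v^2). Each bird at each level flies one
#' burst with its own random wind (direction uniform, speed uniform on
#' [0, wind_speed_max]), random turn direction and random phase.
#'
#' @param n_birds birds per flight level.
#' @param altitudes flight levels (m); the default spans ISA densities
#'   1.099 down to 0.646 kg m^-3, the observed density range.
#' @param constant_C_L lift coefficient held by every bird, in (0.5, 3).
#' @param wing_loading m/S (kg m^-2).
#' @param bank_deg common bank angle (degrees); default near the observed
#'   low-altitude value.
#' @param gps_noise_sigma GPS noise per coordinate (m).
#' @param wind_speed_max upper bound of per-track wind speed (m s^-1).
#' @param burst_s burst length per track (s).
#' @param climb_rate climb rate (m s^-1).
#' @param seed RNG seed (mandatory).
#' @return a `soar_simulation` with the merged multi-bird `track`, the
#'   per-window `truth` table and a `levels` table (altitude, rho, true v,
#'   true r per level).
#' @export
simulate_population <- function(n_birds = 3,
                                altitudes = NULL,
                                constant_C_L = 1.787,
                                wing_loading = 10.54,
                                bank_deg = 22,
                                gps_noise_sigma = 0.5,
                                wind_speed_max = 3,
                                burst_s = 600,
                                climb_rate = 0,
                                seed) {
  if (missing(seed)) stop("a seed is mandatory: no implicit randomness")
  stopifnot(constant_C_L > 0.5, constant_C_L < 3)
  if (is.null(altitudes))
    altitudes <- seq(isa_altitude(1.099), isa_altitude(0.646), length.out = 12)
  g <- soar_constants$g
  rho <- isa_density(altitudes)
  v <- sqrt(2 * g * wing_loading / (rho * constant_C_L))
  r <- v^2 / (g * tan(bank_deg * pi / 180))
  levels <- data.frame(altitude = altitudes, rho = rho, v = v, r = r)

  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)
  n_tracks <- n_birds * length(altitudes)
  draw <- data.frame(
    wind_speed = stats::runif(n_tracks, 0, wind_speed_max),
    wind_dir = stats::runif(n_tracks, 0, 2 * pi),
    turn = sample(c(-1L, 1L), n_tracks, replace = TRUE),
    phase0 = stats::runif(n_tracks, 0, 2 * pi),
    sub_seed = sample.int(.Machine$integer.max - 1L, n_tracks))

  tracks <- vector("list", n_tracks)
  truths <- vector("list", n_tracks)
  k <- 0L
  for (i in seq_along(altitudes)) {
    for (b in seq_len(n_birds)) {
      k <- k + 1L
      cf <- simulation_config(
        airspeed = v[i], radius = r[i], turn_direction = draw$turn[k],
        wind_east = draw$wind_speed[k] * sin(draw$wind_dir[k]),
        wind_north = draw$wind_speed[k] * cos(draw$wind_dir[k]),
        climb_rate = climb_rate, start_altitude = altitudes[i],
        burst_s = burst_s, gps_noise_sigma = gps_noise_sigma,
        density_model = "isa", seed = draw$sub_seed[k],
        phase0 = draw$phase0[k],
        individual = sprintf("sim-bird-%d", b),
        start_time = as.POSIXct("2015-03-01 06:00:00", tz = "UTC") +
          (k - 1) * 86400)
      sim <- simulate_thermalling_track(cf)
      sim$track$burst <- k
      sim$truth$track <- k
      tracks[[k]] <- sim$track
      truths[[k]] <- sim$truth
    }
  }
  track <- do.call(rbind, tracks)
  class(track) <- c("soar_track", "data.frame")
  structure(list(track = track, truth = do.call(rbind, truths),
                 levels = levels,
                 config = list(n_birds = n_birds, altitudes = altitudes,
                               constant_C_L = constant_C_L,
                               wing_loading = wing_loading,
                               bank_deg = bank_deg,
                               gps_noise_sigma = gps_noise_sigma,
                               wind_speed_max = wind_speed_max,
                               burst_s = burst_s, climb_rate = climb_rate,
                               seed = seed)),
            class = "soar_simulation")
}

#' Write a simulation to Movebank-style CSV files
#'
#' Writes the track in the exact schema [read_track()] consumes, plus a
#' sidecar ground-truth CSV.
#'
#' @param sim a `soar_simulation`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return invisibly, the two file paths.
#' @export
simulate_to_files <- function(sim, dir, stem = "sim") {
  stopifnot(inherits(sim, "soar_simulation"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tr <- sim$track
  out <- data.frame(
    timestamp = format(tr$timestamp, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    `location-long` = tr$lon, `location-lat` = tr$lat,
    `height-above-msl` = tr$altitude,
    `individual-local-identifier` = tr$individual,
    check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(is.na(tr$air_density))) out$`air-density` <- tr$air_density
  track_path <- file.path(dir, paste0(stem, "_track.csv"))
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(out, track_path, row.names = FALSE)
  utils::write.csv(sim$truth, truth_path, row.names = FALSE)
  invisible(c(track = track_path, truth = truth_path))
}
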