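test_that("simulation is deterministic and respects its configuration", {
  cf <- simulation_config(seed = 21, burst_s = 120)
  s1 <- simulate_thermalling_track(cf)
  s2 <- simulate_thermalling_track(cf)
  expect_identical(s1$track, s2$track)
  expect_identical(s1$truth, s2$truth)
  s3 <- simulate_thermalling_track(simulation_config(seed = 22, burst_s = 120))
  expect_false(identical(s1$track$lon, s3$track$lon))

  # a burst of B seconds holds B + 1 fixes; climb accumulates exactly
  cf0 <- simulation_config(seed = 1, burst_s = 600, climb_rate = 1,
                           gps_noise_sigma = 0)
  tr <- simulate_thermalling_track(cf0)$track
  expect_equal(nrow(tr), 601)
  expect_equal(tr$altitude[601] - tr$altitude[1], 600)

  expect_error(simulation_config(burst_s = 60), "seed")
  expect_error(simulation_config(seed = 1, airspeed = 5, wind_east = 6,
                                 wind_north = 0), "exceed")
})

test_that("density models annotate fixes as configured", {
  none <- simulate_thermalling_track(
    simulation_config(seed = 2, burst_s = 60, density_model = "none"))
  expect_true(all(is.na(none$track$air_density)))
  fixed <- simulate_thermalling_track(
    simulation_config(seed = 2, burst_s = 60, density_model = "fixed",
                      fixed_rho = 0.9))
  expect_true(all(fixed$track$air_density == 0.9))
  isa <- simulate_thermalling_track(
    simulation_config(seed = 2, burst_s = 60, gps_noise_sigma = 0))
  expect_equal(isa$track$air_density, isa_density(isa$track$altitude))
})

test_that("noiseless simulate-then-analyse round trip matches ground truth", {
  # low latitude keeps tangent-plane curvature out of a correctness check
  cf <- simulation_config(seed = 3, gps_noise_sigma = 0, airspeed = 11,
                          radius = 30, wind_east = 3, wind_north = -2,
                          burst_s = 90, climb_rate = 1, start_lat = 0.5)
  sim <- simulate_thermalling_track(cf)
  segs <- find_loop_segments(sim$track)
  expect_length(segs, 3)
  for (i in seq_along(segs)) {
    s <- segs[[i]]
    f <- fit_loop_wind(s)
    expect_equal(f$wind_east, 3, tolerance = 1e-6)
    expect_equal(f$wind_north, -2, tolerance = 1e-6)
    expect_equal(airspeed(s, f), 11, tolerance = 0.002 / 11)   # < 0.2%
    expect_equal(f$omega_fit, 11 / 30, tolerance = 1e-6)
    # heading-based rate wobbles with the wind: bounded by 2 (w/a) / |turn|
    wobble <- 2 * (sqrt(13) / 11) / abs(s$cumulative_turn)
    expect_equal(angular_rate(s), 11 / 30, tolerance = wobble)
    expect_equal(s$vertical_speed, 1, tolerance = 1e-9)
    expect_equal(s$air_density, isa_density(s$mean_altitude), tolerance = 1e-6)
  }
})

test_that("estimator error grows monotonically with GPS noise", {
  rmse_at <- function(sigma) {
    errs <- unlist(lapply(1:12, function(i) {
      sim <- simulate_thermalling_track(simulation_config(
        seed = 300 + i, gps_noise_sigma = sigma, burst_s = 60,
        airspeed = 11, radius = 30, wind_east = 3, wind_north = -2))
      segs <- find_loop_segments(sim$track)
      vapply(segs, function(s) {
        f <- fit_loop_wind(s)
        (f$wind_east - 3)^2 + (f$wind_north + 2)^2
      }, numeric(1))
    }))
    sqrt(mean(errs))
  }
  rmse <- vapply(c(0, 0.25, 0.5, 1.0), rmse_at, numeric(1))
  expect_true(all(diff(rmse) > 0))
})

test_that("constant-C_L population places each level on the lift balance", {
  pop <- simulate_population(seed = 5, n_birds = 1, burst_s = 60,
                             gps_noise_sigma = 0)
  g <- soar_constants$g
  lv <- pop$levels
  # closed-form inversion at the densest level
  expect_equal(lv$v[1], sqrt(2 * g * 10.54 / (1.099 * 1.787)),
               tolerance = 1e-6)
  expect_equal(lv$v[1], 10.26, tolerance = 1e-3)
  # halving the density raises the true airspeed by sqrt(2)
  h2 <- isa_altitude(c(1.0, 0.5))
  pop2 <- simulate_population(seed = 5, n_birds = 1, altitudes = h2,
                              burst_s = 60, gps_noise_sigma = 0)
  expect_equal(pop2$levels$v[2] / pop2$levels$v[1], sqrt(2),
               tolerance = 1e-9)
  # radius scales as v^2: bank angle identical across levels
  expect_equal(bank_angle(lv$v, lv$r), rep(22 * pi / 180, nrow(lv)),
               tolerance = 1e-12)
  # the default grid spans the observed density range end to end
  expect_equal(lv$rho[1], 1.099, tolerance = 1e-6)
  expect_equal(lv$rho[nrow(lv)], 0.646, tolerance = 1e-6)
  expect_equal(lv$v[nrow(lv)] / lv$v[1] - 1, 0.3043, tolerance = 1e-3)
})

test_that("simulation files round-trip through the reader", {
  sim <- simulate_thermalling_track(simulation_config(seed = 9, burst_s = 60))
  dir <- withr::local_tempdir()
  paths <- simulate_to_files(sim, dir)
  expect_true(all(file.exists(paths)))
  tr <- read_track(paths[["track"]])
  expect_equal(nrow(tr), 61)
  expect_equal(tr$air_density, sim$track$air_density, tolerance = 1e-9)
  truth <- utils::read.csv(paths[["truth"]])
  expect_equal(nrow(truth), 2)
})
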