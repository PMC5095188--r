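test_that("equal-count bins partition observations with counts differing by at most one", {
  b <- equal_count_bins(rnorm(150), k = 15)
  expect_equal(as.integer(table(b)), rep(10, 15))

  # the field sample size divides evenly into 15 bins of 573
  b2 <- equal_count_bins(seq_len(8595), k = 15)
  expect_equal(as.integer(table(b2)), rep(573, 15))

  expect_error(equal_count_bins(1:7, k = 15), "at least k")

  set.seed(42)
  for (n in c(16, 97, 1000)) {
    v <- runif(n)
    b <- equal_count_bins(v, k = 15)
    counts <- as.integer(table(factor(b, levels = 1:15)))
    expect_equal(sum(counts), n)           # partition: every obs in one bin
    expect_lte(diff(range(counts)), 1)
    # bins are ordered: max of bin i never exceeds min of bin i+1
    for (i in 1:14) expect_lte(max(v[b == i]), min(v[b == i + 1]))
  }
})

test_that("density tail groups take round(fraction N) from each extreme", {
  kin <- data.frame(rho = seq(0.6, 1.2, length.out = 8595))
  tg <- density_tail_groups(kin, fraction = 0.05)
  expect_equal(tg$n, 430)
  expect_equal(nrow(tg$low), 430)
  expect_true(min(tg$low$rho) > max(tg$high$rho))  # disjoint extremes

  expect_equal(density_tail_groups(data.frame(rho = runif(100)))$n, 5)
  # round-half-up, not banker's rounding: 0.05 * 30 = 1.5 -> 2
  expect_equal(density_tail_groups(data.frame(rho = 1:30 / 30))$n, 2)
  expect_error(density_tail_groups(data.frame(rho = runif(30)),
                                   fraction = 0.6), "overlap")
  expect_error(density_tail_groups(data.frame(rho = c(NA, runif(99)))), "density")
})

test_that("group contrasts reproduce the published arithmetic", {
  mk <- function(rho, v, r, C_L) data.frame(rho = rho, v = v, r = r,
                                            bank = 0.4, C_L = C_L)
  low <- mk(1.099, 10.5, 28.3, 1.83)
  high <- mk(0.646, 13.5, 44.3, 1.74)
  gc <- compare_groups(low, high)
  expect_equal(gc$density_excess_pct, (1.099 / 0.646 - 1) * 100)
  expect_equal(gc$density_excess_pct, 70.05, tolerance = 0.002)
  expect_equal(gc$radius_increase_pct, (44.3 / 28.3 - 1) * 100)
  expect_equal(gc$radius_increase_pct, 56, tolerance = 0.01)
  expect_equal(gc$C_L_diff_pct, (1.83 - 1.74) / 1.83 * 100)
  expect_equal(gc$C_L_diff_pct, 4.87, tolerance = 0.02)
  expect_equal(gc$airspeed_increase_pct, (13.5 / 10.5 - 1) * 100)

  same <- compare_groups(low, low)
  expect_equal(same$density_excess_pct, 0)
  expect_equal(same$radius_increase_pct, 0)
  expect_equal(same$airspeed_increase_pct, 0)
  expect_equal(same$C_L_diff_pct, 0)
  expect_error(compare_groups(low[0, ], high), "empty")

  # scale invariance: rescaling all densities leaves the contrast unchanged
  low2 <- low; high2 <- high
  low2$rho <- low$rho * 3; high2$rho <- high$rho * 3
  expect_equal(compare_groups(low2, high2)$density_excess_pct,
               gc$density_excess_pct)
})

test_that("squared airspeed regresses on inverse density with the theoretical slope", {
  g <- soar_constants$g
  rho <- isa_density(seq(1000, 6200, length.out = 400))
  slope_true <- theoretical_speed_density_slope(10.54, 1.787)
  expect_equal(slope_true, 2 * g * 10.54 / 1.787)
  kin <- data.frame(rho = rho, v = sqrt(slope_true / rho))
  fit <- suppressWarnings(fit_speed_density_model(kin))  # perfect fit
  expect_equal(fit$slope, 115.7, tolerance = 1e-3)
  expect_equal(fit$intercept, 0, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_speed_density_model(data.frame(rho = rep(1.1, 10),
                                                  v = rnorm(10, 11))),
               "constant")

  set.seed(7)
  noisy <- kin
  noisy$v <- noisy$v + rnorm(nrow(noisy), sd = 1)
  nf <- fit_speed_density_model(noisy)
  expect_equal(nf$slope, 115.7, tolerance = 0.1)
  expect_lt(nf$r_squared, 1)
  expect_lt(nf$p_value, 1e-4)
})

test_that("radius-altitude trend recovers exact exponential growth", {
  h <- seq(500, 6500, length.out = 40)
  tr <- suppressWarnings(radius_altitude_trend(  # exact exponential input
    data.frame(r = 28.3 * 1.125^(h / 1000), altitude = h)))
  expect_equal(tr$trend_pct_per_km, 12.5, tolerance = 1e-6)

  expect_equal(suppressWarnings(radius_altitude_trend(
    data.frame(r = rep(30, 10), altitude = seq(0, 3000, length.out = 10))
  ))$trend_pct_per_km, 0, tolerance = 1e-9)

  expect_equal(suppressWarnings(radius_altitude_trend(
    data.frame(r = 30 * 2^(h / 1000), altitude = h)))$trend_pct_per_km,
    100, tolerance = 1e-9)

  expect_error(radius_altitude_trend(
    data.frame(r = runif(10, 20, 40),
               altitude = seq(100, 900, length.out = 10))), "span")
})

test_that("altitude bin summaries use interpolation quantiles per bin", {
  set.seed(9)
  kin <- data.frame(altitude = runif(90, 0, 6000), v = rnorm(90, 11))
  s <- altitude_bin_summary(kin, "v", k = 15)
  expect_equal(nrow(s), 15)
  expect_equal(sum(s$n), 90)
  expect_true(all(s$alt_min <= s$alt_max))
  expect_true(all(s$lo95 <= s$q25 & s$q25 <= s$q50 & s$q50 <= s$q75 &
                    s$q75 <= s$hi95))
  b <- equal_count_bins(kin$altitude, 15)
  expect_equal(s$q50[1], unname(stats::quantile(kin$v[b == 1], 0.5, type = 7)))
})
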