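#' Equal-count bins
#'
#' Partitions observations into `k` bins of (near) equal size after sorting
#' by `values`; ties are broken by the original order (time order for
#' segments). Bin sizes are floor(N/k) or ceil(N/k) and differ by at most
#' one; when N is not divisible by k the lower bins take the extra
#' observation.
#'
#' @param values numeric vector to bin (e.g. per-segment altitudes).
#' @param k number of bins (default 15).
#' @return integer bin index (1..k) per observation, in input order.
#' @export
equal_count_bins <- function(values, k = 15) {
  n <- length(values)
  if (n < k) stop("need at least k observations to form k equal-count bins")
  sizes <- rep(floor(n / k), k)
  extra <- n - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ord <- order(values, seq_len(n))
  bins <- integer(n)
  bins[ord] <- rep(seq_len(k), times = sizes)
  bins
}

# round-half-up (0.5 always rounds away from zero toward +Inf)
round_half_up <- function(x) floor(x + 0.5)

#' Density tail groups
#'
#' Splits segments into a low-flying and a high-flying subsample: the
#' `fraction` of segments with the highest air density form the low-flying
#' group and the same number with the lowest air density form the
#' high-flying group. Group size is round(fraction * N), rounding half up.
#'
#' @param kinematics data frame with one row per segment, including a `rho`
#'   column (kg m^-3) with no missing values.
#' @param fraction tail fraction (default 0.05).
#' @return list with data frames `low` (densest air) and `high` (thinnest
#'   air) and the common group size `n`.
#' @export
density_tail_groups <- function(kinematics, fraction = 0.05) {
  stopifnot(is.data.frame(kinematics), "rho" %in% names(kinematics))
  if (anyNA(kinematics$rho)) stop("every segment must carry an air density")
  N <- nrow(kinematics)
  n <- round_half_up(fraction * N)
  if (n < 1) stop("tail fraction selects no segments")
  if (N < 2 * n) stop("tail groups would overlap: too few segments")
  ord <- order(kinematics$rho, seq_len(N))
  list(high = kinematics[ord[seq_len(n)], , drop = FALSE],
       low = kinematics[ord[(N - n + 1):N], , drop = FALSE],
       n = n)
}

#' Contrast the low- and high-flying groups
#'
#' Group means of air density, airspeed, circle radius, bank angle and lift
#' coefficient, and the derived contrasts: the fractional density excess of
#' low over high (rho_l/rho_h - 1), the radius and airspeed increases of the
#' high-flying group relative to the low-flying one, and the lift-coefficient
#' difference relative to the low-flying value (C_L,low - C_L,high) /
#' C_L,low, all in percent.
#'
#' @param low,high data frames with columns `rho`, `v`, `r`, `bank`, `C_L`.
#' @return a `group_comparison` list.
#' @export
compare_groups <- function(low, high) {
  if (nrow(low) == 0 || nrow(high) == 0) stop("empty group")
  m <- function(g, col) mean(g[[col]])
  out <- list(
    rho_l = m(low, "rho"), rho_h = m(high, "rho"),
    v_l = m(low, "v"), v_h = m(high, "v"),
    r_l = m(low, "r"), r_h = m(high, "r"),
    theta_l = m(low, "bank"), theta_h = m(high, "bank"),
    C_L_low = m(low, "C_L"), C_L_high = m(high, "C_L"),
    n_low = nrow(low), n_high = nrow(high))
  if (out$rho_l < out$rho_h)
    stop("low-flying group must have the denser air")
  out$density_excess_pct <- (out$rho_l / out$rho_h - 1) * 100
  out$radius_increase_pct <- (out$r_h / out$r_l - 1) * 100
  out$airspeed_increase_pct <- (out$v_h / out$v_l - 1) * 100
  out$C_L_diff_pct <- (out$C_L_low - out$C_L_high) / out$C_L_low * 100
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("low vs high flying groups (n = %d / %d)\n", x$n_low, x$n_high))
  cat(sprintf("  air density  %.3f vs %.3f kg/m^3 (low %.2f%% denser)\n",
              x$rho_l, x$rho_h, x$density_excess_pct))
  cat(sprintf("  airspeed     %.2f vs %.2f m/s (+%.1f%% aloft)\n",
              x$v_l, x$v_h, x$airspeed_increase_pct))
  cat(sprintf("  radius       %.1f vs %.1f m (+%.1f%% aloft)\n",
              x$r_l, x$r_h, x$radius_increase_pct))
  cat(sprintf("  bank angle   %.1f vs %.1f deg\n",
              x$theta_l * 180 / pi, x$theta_h * 180 / pi))
  cat(sprintf("  lift coeff   %.3f vs %.3f (%.2f%% difference)\n",
              x$C_L_low, x$C_L_high, x$C_L_diff_pct))
  invisible(x)
}

#' Regression of squared airspeed on inverse air density
#'
#' At constant lift coefficient and wing loading the lift balance gives
#' v^2 = (2 l (m/S) / C_L) (1 / rho): squared airspeed is linear in inverse
#' density with slope 2 g (m/S) / C_L when lift just balances gravity.
#' Fits that line by ordinary least squares (with intercept, unweighted)
#' across segments.
#'
#' @param kinematics data frame with columns `v` and `rho`.
#' @return a `speed_density_fit`: slope (m^5 s^-2 kg^-1), intercept,
#'   r_squared, two-sided p-value of the slope, n, and the underlying `lm`.
#' @seealso [theoretical_speed_density_slope()]
#' @export
fit_speed_density_model <- function(kinematics) {
  stopifnot(all(c("v", "rho") %in% names(kinematics)))
  d <- data.frame(v2 = kinematics$v^2, inv_rho = 1 / kinematics$rho)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 segments with airspeed and density")
  if (stats::var(d$inv_rho) == 0)
    stop("air density is constant: inverse-density predictor is degenerate")
  fit <- stats::lm(v2 ~ inv_rho, data = d)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              p_value = sm$coefficients["inv_rho", "Pr(>|t|)"],
              n = nrow(d), lm = fit)
  class(out) <- "speed_density_fit"
  out
}

#' @export
print.speed_density_fit <- function(x, ...) {
  cat(sprintf(
    "v^2 ~ 1/rho: slope = %.1f, intercept = %.1f, R^2 = %.2f, n = %d\n",
    x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}

#' Theoretical squared-airspeed slope at constant lift coefficient
#'
#' @param wing_loading m/S (kg m^-2).
#' @param C_L lift coefficient held constant.
#' @param l lift acceleration (m s^-2), g for straight flight.
#' @return slope of v^2 against 1/rho: 2 l (m/S) / C_L.
#' @export
theoretical_speed_density_slope <- function(wing_loading, C_L,
                                            l = soar_constants$g) {
  2 * l * wing_loading / C_L
}

#' Circle-radius trend with altitude
#'
#' A constant percentage change per kilometre is a log-linear model: fits
#' OLS of log(radius) on altitude in km and reports
#' (exp(slope) - 1) * 100, the percent radius change per 1000 m climbed.
#'
#' @param kinematics data frame with columns `r` (m) and `altitude` (m),
#'   spanning at least 1000 m of altitude.
#' @return list with `trend_pct_per_km`, the log-slope, its p-value and n.
#' @export
radius_altitude_trend <- function(kinematics) {
  stopifnot(all(c("r", "altitude") %in% names(kinematics)))
  d <- data.frame(lr = log(kinematics$r), km = kinematics$altitude / 1000)
  d <- d[stats::complete.cases(d), , drop = FALSE]
  if (nrow(d) < 3) stop("need at least 3 segments")
  if (diff(range(d$km)) < 1)
    stop("altitude span below 1000 m: radius trend not identifiable")
  fit <- stats::lm(lr ~ km, data = d)
  sl <- unname(stats::coef(fit)[2])
  list(trend_pct_per_km = (exp(sl) - 1) * 100, log_slope = sl,
       p_value = summary(fit)$coefficients["km", "Pr(>|t|)"], n = nrow(d))
}

#' Per-bin summaries of a kinematic quantity across elevation
#'
#' Splits segments into equal-count altitude bins and summarises one
#' quantity per bin: mean, quartiles and the central 95% interval
#' (2.5--97.5 percentiles, linear-interpolation quantiles).
#'
#' @param kinematics data frame with an `altitude` column.
#' @param quantity name of the column to summarise (e.g. `"C_L"`, `"v"`).
#' @param k number of bins (default 15).
#' @return data frame, one row per bin: bin index, altitude range, n, mean,
#'   q25/q50/q75, lo95/hi95.
#' @export
altitude_bin_summary <- function(kinematics, quantity, k = 15) {
  stopifnot(quantity %in% names(kinematics),
            "altitude" %in% names(kinematics))
  bins <- equal_count_bins(kinematics$altitude, k = k)
  do.call(rbind, lapply(seq_len(k), function(b) {
    g <- kinematics[bins == b, , drop = FALSE]
    q <- stats::quantile(g[[quantity]],
                         c(0.025, 0.25, 0.5, 0.75, 0.975), type = 7)
    data.frame(bin = b, alt_min = min(g$altitude), alt_max = max(g$altitude),
               n = nrow(g), mean = mean(g[[quantity]]),
               q25 = q[[2]], q50 = q[[3]], q75 = q[[4]],
               lo95 = q[[1]], hi95 = q[[5]])
  }))
}
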