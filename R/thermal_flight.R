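#' Fit the thermalling-flight analysis to a GPS track
#'
#' The central fit of the package. From a 1 Hz track it
#' \enumerate{
#'   \item finds non-overlapping 30 s windows containing a full circle
#'     ([find_loop_segments()]),
#'   \item estimates the horizontal wind per loop from the circle drift and
#'     subtracts it to obtain airspeed ([fit_loop_wind()], [airspeed()]),
#'   \item derives circle radius r = v/omega, bank angle, lift acceleration
#'     and lift coefficient from banked-turn force balance, annotating each
#'     segment with air density (per-fix column when present, else the
#'     standard atmosphere at the segment altitude),
#'   \item fits the altitude statistics: equal-count elevation-bin summaries,
#'     the 5% density tail-group contrast, the OLS regression of squared
#'     airspeed on inverse density, and the radius-altitude trend.
#' }
#' Segments are dropped (with counts kept) when the wind fit does not
#' converge, when the wind dominates the airspeed, or when no density source
#' is available, mirroring the filtering of the field analysis.
#'
#' @param track a `soar_track` from [read_track()] or the simulator.
#' @param wing_loading population mass per wing area m/S (kg m^-2);
#'   default 10.54.
#' @param k_bins number of equal-count elevation bins (default 15).
#' @param tail_fraction density tail-group fraction (default 0.05).
#' @param min_speed per-fix ground-speed gate (m s^-1).
#' @param density_source priority of density sources: any ordering/subset of
#'   `"column"` (per-fix air-density values) and `"isa"` (standard
#'   atmosphere from altitude).
#' @return a `thermal_flight` object: per-segment kinematics (`kinematics`),
#'   wind table (`wind`), segment table (`segments`), filter `counts`,
#'   elevation-bin summaries (`bins`), tail-group contrast (`groups`), the
#'   squared-airspeed/inverse-density fit (`model`) and the radius trend
#'   (`trend`). Statistics that need more segments than available are NULL.
#' @examples
#' sim <- simulate_thermalling_track(simulation_config(seed = 1, burst_s = 120))
#' fit <- thermal_flight(sim$track)
#' print(fit)
#' @export
thermal_flight <- function(track, wing_loading = 10.54, k_bins = 15,
                           tail_fraction = 0.05, min_speed = 0.5,
                           density_source = c("column", "isa")) {
  stopifnot(wing_loading > 0, k_bins >= 1,
            tail_fraction > 0, tail_fraction < 0.5,
            all(density_source %in% c("column", "isa")))
  segs <- find_loop_segments(track, min_speed = min_speed)
  fits <- lapply(segs, fit_loop_wind)
  wind <- wind_table(segs, fits)

  rows <- Map(function(s, f) {
    if (!isTRUE(f$converged) ||
        wind_support_check(s, f) != "ok") return(NULL)
    v <- airspeed(s, f)
    omega <- angular_rate(s)
    r <- circle_radius(v, omega)
    rho <- NA_real_; src <- "none"
    for (ds in density_source) {
      if (ds == "column" && !is.na(s$air_density)) {
        rho <- s$air_density; src <- "column"; break
      }
      if (ds == "isa" && s$mean_altitude >= 0 && s$mean_altitude <= 11000) {
        rho <- isa_density(s$mean_altitude); src <- "isa"; break
      }
    }
    l <- lift_acceleration(v, r)
    data.frame(
      segment_id = s$segment_id, individual = s$individual,
      v = v, omega = omega, r = r, bank = bank_angle(v, r),
      lift_accel = l,
      C_L = if (is.na(rho)) NA_real_ else
        lift_coefficient(l, wing_loading, rho, v),
      rho = rho, rho_source = src, altitude = s$mean_altitude,
      vertical_speed = s$vertical_speed, stringsAsFactors = FALSE)
  }, segs, fits)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  kin_all <- if (length(rows)) do.call(rbind, rows) else
    data.frame(segment_id = integer(), individual = character(),
               v = numeric(), omega = numeric(), r = numeric(),
               bank = numeric(), lift_accel = numeric(), C_L = numeric(),
               rho = numeric(), rho_source = character(),
               altitude = numeric(), vertical_speed = numeric())
  kin <- kin_all[!is.na(kin_all$rho), , drop = FALSE]

  counts <- list(
    windows_scanned = attr(segs, "windows_scanned"),
    segments_accepted = length(segs),
    wind_converged = sum(wind$quality_flag != "not_converged"),
    wind_ok = sum(wind$quality_flag == "ok"),
    density_annotated = nrow(kin),
    dropped_no_density = nrow(kin_all) - nrow(kin))

  try_stat <- function(expr) tryCatch(expr, error = function(e) NULL)
  bins <- NULL
  if (nrow(kin) >= k_bins)
    bins <- lapply(stats::setNames(nm = c("C_L", "v", "r", "lift_accel",
                                          "vertical_speed")),
                   function(q) altitude_bin_summary(kin, q, k = k_bins))
  groups <- try_stat({
    tg <- density_tail_groups(kin, fraction = tail_fraction)
    compare_groups(tg$low, tg$high)
  })
  model <- try_stat(fit_speed_density_model(kin))
  trend <- try_stat(radius_altitude_trend(kin))

  structure(list(segments = segments_table(segs), wind = wind,
                 kinematics = kin, counts = counts, bins = bins,
                 groups = groups, model = model, trend = trend,
                 params = list(wing_loading = wing_loading, k_bins = k_bins,
                               tail_fraction = tail_fraction,
                               min_speed = min_speed,
                               density_source = density_source),
                 call = match.call()),
            class = "thermal_flight")
}

#' @export
print.thermal_flight <- function(x, ...) {
  ct <- x$counts
  cat("Thermalling-flight analysis\n")
  cat(sprintf(
    "  windows scanned %d | full circles %d | wind converged %d | usable %d\n",
    ct$windows_scanned, ct$segments_accepted, ct$wind_converged,
    ct$density_annotated))
  if (nrow(x$kinematics) > 0) {
    k <- x$kinematics
    cat(sprintf(
      "  airspeed %.1f m/s | radius %.1f m | bank %.1f deg | C_L %.2f (means)\n",
      mean(k$v), mean(k$r), mean(k$bank) * 180 / pi, mean(k$C_L, na.rm = TRUE)))
  }
  if (!is.null(x$model))
    cat(sprintf("  v^2 ~ 1/rho: slope %.1f, R^2 %.2f\n",
                x$model$slope, x$model$r_squared))
  invisible(x)
}

#' @export
summary.thermal_flight <- function(object, ...) {
  structure(list(counts = object$counts, groups = object$groups,
                 model = object$model, trend = object$trend,
                 params = object$params,
                 n = nrow(object$kinematics)),
            class = "summary.thermal_flight")
}

#' @export
print.summary.thermal_flight <- function(x, ...) {
  cat(sprintf("Usable full-circle segments: %d\n", x$n))
  if (!is.null(x$groups)) print(x$groups)
  if (!is.null(x$model)) print(x$model)
  if (!is.null(x$trend))
    cat(sprintf("circle radius trend: %+.1f%% per 1000 m (p = %.2g)\n",
                x$trend$trend_pct_per_km, x$trend$p_value))
  if (!is.null(x$groups))
    cat(sprintf(
      "required airspeed compensation over the density range: %.1f%% (observed %.1f%%)\n",
      100 * airspeed_compensation(x$groups$rho_l, x$groups$rho_h),
      x$groups$airspeed_increase_pct))
  invisible(x)
}

#' @export
coef.thermal_flight <- function(object, ...) {
  if (is.null(object$model)) stop("no squared-airspeed/inverse-density fit")
  c(intercept = object$model$intercept, slope = object$model$slope)
}

#' @export
residuals.thermal_flight <- function(object, ...) {
  if (is.null(object$model)) stop("no squared-airspeed/inverse-density fit")
  stats::residuals(object$model$lm)
}

#' Predict airspeed at a given air density
#'
#' Uses the fitted v^2 ~ 1/rho line: predicted airspeed is
#' sqrt(intercept + slope / rho).
#'
#' @param object a `thermal_flight` fit.
#' @param newdata data frame with a `rho` column (kg m^-3); when omitted,
#'   fitted values at the observed densities are returned.
#' @param ... unused.
#' @return predicted airspeed (m s^-1).
#' @export
predict.thermal_flight <- function(object, newdata = NULL, ...) {
  if (is.null(object$model)) stop("no squared-airspeed/inverse-density fit")
  rho <- if (is.null(newdata)) object$kinematics$rho else newdata$rho
  v2 <- object$model$intercept + object$model$slope / rho
  if (any(v2 < 0)) stop("negative predicted squared airspeed")
  sqrt(v2)
}

#' Diagnostic plots of a thermalling-flight fit
#'
#' Two base-graphics panels: squared airspeed against inverse air density
#' with the fitted line, and circle radius against altitude (log radius)
#' with the fitted percentage-per-km trend.
#'
#' @param x a `thermal_flight` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.thermal_flight <- function(x, ...) {
  k <- x$kinematics
  if (nrow(k) == 0) stop("no usable segments to plot")
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(1 / k$rho, k$v^2, xlab = expression(1 / rho ~ (m^3 / kg)),
                 ylab = expression(v^2 ~ (m^2 / s^2)), pch = 16,
                 col = "grey40", ...)
  if (!is.null(x$model))
    graphics::abline(x$model$intercept, x$model$slope, col = "red", lwd = 2)
  graphics::plot(k$altitude, k$r, log = "y", xlab = "altitude (m)",
                 ylab = "circle radius (m)", pch = 16, col = "grey40", ...)
  if (!is.null(x$trend)) {
    h <- seq(min(k$altitude), max(k$altitude), length.out = 50)
    b <- stats::coef(stats::lm(log(k$r) ~ I(k$altitude / 1000)))
    graphics::lines(h, exp(b[1] + b[2] * h / 1000), col = "red", lwd = 2)
  }
  invisible(x)
}
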