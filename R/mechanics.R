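#' Banked-turn flight mechanics
#'
#' Closed-form relations for a bird holding a balanced turn at constant
#' airspeed, circle radius and bank angle. The lift vector tilts by the bank
#' angle theta: its vertical component supports weight (l cos(theta) = g)
#' and its horizontal component supplies the centripetal acceleration
#' (l sin(theta) = v^2 / r). All functions are vectorised over their
#' numeric arguments.
#'
#' @param v airspeed (m s^-1), positive.
#' @param omega angular rate (rad s^-1), positive.
#' @param r circle radius (m), positive.
#' @return `circle_radius`: radius v/omega (m). `bank_angle`: bank angle
#'   (radians). `lift_acceleration`: lift force per unit mass (m s^-2),
#'   always >= g.
#' @examples
#' r <- circle_radius(10.5, 0.371)
#' lift_acceleration(10.5, r) * cos(bank_angle(10.5, r))  # = 9.81
#' @name banked_turn
NULL

#' @rdname banked_turn
#' @export
circle_radius <- function(v, omega) {
  stopifnot(all(v > 0), all(omega > 0))
  v / omega
}

#' @rdname banked_turn
#' @export
lift_acceleration <- function(v, r) {
  stopifnot(all(v > 0), all(r > 0))
  sqrt(soar_constants$g^2 + (v^2 / r)^2)
}

#' @rdname banked_turn
#' @export
bank_angle <- function(v, r) {
  stopifnot(all(v > 0), all(r > 0))
  atan(v^2 / (soar_constants$g * r))
}

#' Lift coefficient of a circling bird
#'
#' Inverts the lift equation L = 0.5 rho v^2 S C_L: with lift acceleration
#' l = L/m and wing loading m/S, C_L = 2 l (m/S) / (rho v^2). The lift
#' coefficient aggregates every lift-generating property of the bird (wing
#' posture, camber, angle of attack); a constant C_L across altitude means
#' the bird compensates for thin air behaviourally (speed, radius) rather
#' than by reconfiguring its wings.
#'
#' @param l lift acceleration (m s^-2).
#' @param wing_loading mass per unit wing area m/S (kg m^-2). The population
#'   default used throughout the package is 10.54 kg m^-2.
#' @param rho air density (kg m^-3).
#' @param v airspeed (m s^-1).
#' @return dimensionless lift coefficient.
#' @export
lift_coefficient <- function(l, wing_loading, rho, v) {
  stopifnot(all(l > 0), all(wing_loading > 0), all(rho > 0), all(v > 0))
  2 * l * wing_loading / (rho * v^2)
}

#' Airspeed compensation required by a drop in air density
#'
#' At fixed lift coefficient and wing loading, dynamic pressure
#' 0.5 rho v^2 must stay constant, so flying from density `rho_low` into
#' thinner air `rho_high` requires the airspeed ratio
#' sqrt(rho_low / rho_high). Returns that ratio minus one: the fractional
#' airspeed increase needed at altitude.
#'
#' @param rho_low air density of the denser (low altitude) air (kg m^-3).
#' @param rho_high air density of the thinner (high altitude) air (kg m^-3);
#'   must not exceed `rho_low`.
#' @return fractional required airspeed increase (0.304 means +30.4%).
#' @examples
#' airspeed_compensation(1.099, 0.646)  # 0.304
#' @export
airspeed_compensation <- function(rho_low, rho_high) {
  stopifnot(all(rho_low > 0), all(rho_high > 0))
  if (any(rho_low < rho_high))
    stop("rho_low < rho_high: arguments are (denser, thinner); swap the inputs")
  sqrt(rho_low / rho_high) - 1
}

#' Sink-rate penalty of turning flight
#'
#' In a banked turn the equilibrium sink rate exceeds the straight-line sink
#' rate by cos(theta)^(-3/2). `penalty_factor` is that multiplier;
#' `best_improvement` = 1 - cos(theta)^(3/2) is the fractional sink-rate
#' reduction attainable by rolling the wings level, i.e. the most a bird can
#' gain by widening its circle at fixed airspeed. The two are exact mutual
#' inverses: (1 - best_improvement) * penalty_factor = 1.
#'
#' @param theta bank angle in radians, in [0, pi/2).
#' @return list with `penalty_factor` and `best_improvement`.
#' @examples
#' sink_rate_turn_correction(42 * pi / 180)$best_improvement  # ~0.359
#' @export
sink_rate_turn_correction <- function(theta) {
  stopifnot(all(theta >= 0))
  if (any(theta >= pi / 2)) stop("bank angle must be below 90 degrees")
  f <- cos(theta)^(-3 / 2)
  list(penalty_factor = f, best_improvement = 1 - 1 / f)
}
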