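#' Air density from pressure and temperature
#'
#' Ideal-gas law for dry air: rho = p / (R T) with
#' R = 287.058 J kg^-1 K^-1.
#'
#' @param pressure static pressure (Pa).
#' @param temperature air temperature (K).
#' @return air density (kg m^-3).
#' @examples
#' air_density(101325, 288.15)  # 1.225
#' @export
air_density <- function(pressure, temperature) {
  stopifnot(all(pressure > 0), all(temperature > 0))
  pressure / (soar_constants$R_air * temperature)
}

#' International Standard Atmosphere density
#'
#' Troposphere segment of the ISA: sea-level temperature 288.15 K, lapse
#' rate 6.5 K km^-1, sea-level pressure 101325 Pa, so
#' T(h) = 288.15 - 0.0065 h and p(h) = 101325 (T/288.15)^5.25588. Used as
#' the fallback density source when tracks carry no per-fix density, and as
#' the altitude-density model of the flight simulator. Valid up to the
#' tropopause (11 km).
#'
#' @param altitude metres above mean sea level, in [0, 11000].
#' @return air density (kg m^-3), strictly decreasing in altitude.
#' @examples
#' isa_density(0)     # 1.225
#' isa_density(6500)  # ~0.624, roughly half of sea level
#' @export
isa_density <- function(altitude) {
  if (any(altitude < 0 | altitude > 11000))
    stop("ISA troposphere model valid for altitudes in [0, 11000] m")
  temp <- 288.15 - 0.0065 * altitude
  p <- 101325 * (temp / 288.15)^5.25588
  air_density(p, temp)
}

#' Altitude at which the ISA atmosphere reaches a given density
#'
#' Numerical inverse of [isa_density()], used by the population simulator to
#' place flight levels at prescribed air densities.
#'
#' @param rho target density (kg m^-3) within the ISA tropospheric range.
#' @return altitude (m).
#' @export
isa_altitude <- function(rho) {
  vapply(rho, function(r) {
    lo <- isa_density(11000); hi <- isa_density(0)
    if (r < lo || r > hi) stop("density outside ISA troposphere range")
    stats::uniroot(function(h) isa_density(h) - r, c(0, 11000),
                   tol = 1e-8)$root
  }, numeric(1))
}
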