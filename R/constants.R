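#' Physical constants used throughout the package
#'
#' Gravitational acceleration, the specific gas constant of dry air and the
#' spherical Earth radius used by the local tangent-plane projection.
#' Gravity is treated as altitude-independent and buoyancy is ignored: over
#' the 0--7 km band relevant to soaring flight both effects are far below
#' the measurement noise of 1 Hz GPS kinematics.
#'
#' @format A named list with elements `g` (m s^-2), `R_air`
#'   (J kg^-1 K^-1) and `R_earth` (m).
#' @export
soar_constants <- list(
  g       = 9.81,
  R_air   = 287.058,
  R_earth = 6371000
)
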