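# The extrusion die as a capillary rheometer: Hagen-Poiseuille wall stress
# and apparent shear rate, with the Weissenberg-Rabinowitsch correction for
# shear-thinning melts.

#' Wall shear stress in a cylindrical die
#'
#' Hagen-Poiseuille wall shear stress `tau = dp * r_die / (2 l_die)` for a
#' pressure drop `dp` across the die.
#'
#' @param pressure_drop pressure drop across the die, Pa (>= 0)
#' @param geom an [extruder_geometry()]
#' @return shear stress, Pa
#' @export
die_shear_stress <- function(pressure_drop, geom) {
  stopifnot(inherits(geom, "extruder_geometry"), all(pressure_drop >= 0))
  pressure_drop * geom$r_die / (2 * geom$l_die)
}

#' Apparent Newtonian wall shear rate in a cylindrical die
#'
#' `gammadot = 4 V / (pi r_die^3)` for a volume flow `V` through the die.
#'
#' @param volume_flow volume flow through the die, m^3/s (> 0)
#' @param geom an [extruder_geometry()]
#' @return shear rate, 1/s
#' @export
die_shear_rate <- function(volume_flow, geom) {
  stopifnot(inherits(geom, "extruder_geometry"))
  if (any(volume_flow <= 0)) stop("volume_flow must be positive")
  4 * volume_flow / (pi * geom$r_die^3)
}

#' Weissenberg-Rabinowitsch shear-rate correction
#'
#' Corrects the apparent Newtonian wall shear rate for the non-parabolic
#' velocity profile of a shear-thinning melt. With the Ostwald flow index
#' n = 1 - c the factor is `(3n + 1) / (4n) = (4 - 3c) / (4 - 4c)`; it is 1
#' for a Newtonian fluid (c = 0) and grows with shear thinning.
#'
#' @param shear_rate apparent wall shear rate, 1/s
#' @param c Carreau flow index, in \[0, 1)
#' @return corrected shear rate, 1/s
#' @export
wr_corrected_shear_rate <- function(shear_rate, c) {
  shear_rate * wr_factor(c)
}

#' @rdname wr_corrected_shear_rate
#' @export
wr_factor <- function(c) {
  if (any(c < 0) || any(c >= 1)) {
    stop("flow index c must lie in [0, 1); the correction diverges at c = 1")
  }
  (4 - 3 * c) / (4 - 4 * c)
}

#' Apparent die viscosity
#'
#' Wall shear stress over apparent wall shear rate,
#' `eta = [dp r/(2l)] / [4V/(pi r^3)]`, i.e. the die treated as a capillary
#' viscometer without shear-thinning correction.
#'
#' @inheritParams die_shear_stress
#' @inheritParams die_shear_rate
#' @return viscosity, Pa s
#' @export
apparent_viscosity <- function(pressure_drop, volume_flow, geom) {
  die_shear_stress(pressure_drop, geom) / die_shear_rate(volume_flow, geom)
}

#' Die viscosity with optional Weissenberg-Rabinowitsch correction
#'
#' The die viscosity used by the autogenic correlations: wall shear stress
#' divided by the WR-corrected shear rate (the correction applies to the
#' shear rate only, the stress is unchanged). Set `wr_correct = FALSE` for
#' the uncorrected apparent viscosity, e.g. for sensitivity analysis.
#'
#' @inheritParams apparent_viscosity
#' @param c Carreau flow index of the melt, in \[0, 1)
#' @param wr_correct apply the shear-rate correction? default TRUE
#' @return viscosity, Pa s
#' @export
die_viscosity <- function(pressure_drop, volume_flow, geom, c, wr_correct = TRUE) {
  rate <- die_shear_rate(volume_flow, geom)
  if (wr_correct) rate <- wr_corrected_shear_rate(rate, c)
  die_shear_stress(pressure_drop, geom) / rate
}
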