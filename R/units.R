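#' Unit conversions at the I/O boundary
#'
#' All computations in this package use SI units: screw speed in 1/s,
#' temperature in kelvin, pressure in pascal, mass flow in kg/s. Experiment
#' files and operator-facing tables use the units customary at the extruder
#' (rpm, degrees Celsius, bar, kg/h); these helpers convert between the two.
#'
#' @param rpm,hz screw speed in revolutions per minute / revolutions per second
#' @param celsius,kelvin temperature
#' @param bar,pascal pressure
#' @param kg_h,kg_s mass flow rate
#' @return numeric vector in the target unit
#' @examples
#' rpm_to_hz(200)        # 3.33 1/s
#' celsius_to_kelvin(200) # 473.15 K
#' @name units
NULL

#' @rdname units
#' @export
rpm_to_hz <- function(rpm) rpm / 60

#' @rdname units
#' @export
hz_to_rpm <- function(hz) hz * 60

#' @rdname units
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

#' @rdname units
#' @export
kelvin_to_celsius <- function(kelvin) kelvin - 273.15

#' @rdname units
#' @export
bar_to_pascal <- function(bar) bar * 1e5

#' @rdname units
#' @export
pascal_to_bar <- function(pascal) pascal / 1e5

#' @rdname units
#' @export
kg_h_to_kg_s <- function(kg_h) kg_h / 3600

#' @rdname units
#' @export
kg_s_to_kg_h <- function(kg_s) kg_s * 3600
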