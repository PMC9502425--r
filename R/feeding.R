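# Barrel-load model of the feeding section: specific feed load, slip, and
# maximum throughput.

#' Extruder geometry
#'
#' Dimensions of the screw, feeding section and die of a twin-screw extruder,
#' plus its nominal (maximum rated) screw speed.
#'
#' @param d screw diameter, m
#' @param A_free free cross-sectional area of the screw, m^2
#' @param l_pitch screw pitch in the feeding section, m
#' @param r_die die radius, m
#' @param l_die die length, m
#' @param n_max nominal screw speed, 1/s
#' @return an object of class `extruder_geometry`
#' @seealso [zse27_geometry()] for the bundled 27 mm reference machine
#' @export
extruder_geometry <- function(d, A_free, l_pitch, r_die, l_die, n_max) {
  vals <- c(d = d, A_free = A_free, l_pitch = l_pitch,
            r_die = r_die, l_die = l_die, n_max = n_max)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all geometry fields must be positive and finite")
  }
  structure(as.list(vals), class = "extruder_geometry")
}

#' @export
print.extruder_geometry <- function(x, ...) {
  cat("Twin-screw extruder geometry\n")
  cat(sprintf("  screw diameter d      : %.4g mm\n", x$d * 1e3))
  cat(sprintf("  free cross-section    : %.4g m^2\n", x$A_free))
  cat(sprintf("  feeding-section pitch : %.4g mm\n", x$l_pitch * 1e3))
  cat(sprintf("  die radius x length   : %.4g x %.4g mm\n",
              x$r_die * 1e3, x$l_die * 1e3))
  cat(sprintf("  nominal screw speed   : %.0f rpm\n", hz_to_rpm(x$n_max)))
  invisible(x)
}

#' Powder transport state
#'
#' Bulk and true density of the powder together with the slip fraction `s`:
#' the fraction of the feeding screw's geometric transport capacity that the
#' powder does not realize.
#'
#' @param rho_bulk bulk (untapped) density, kg/m^3
#' @param rho_true true (pycnometric) density, kg/m^3
#' @param slip slip fraction, in \[0, 1)
#' @return an object of class `powder_state`
#' @export
powder_state <- function(rho_bulk, rho_true, slip = 0) {
  stopifnot(
    "densities must satisfy 0 < rho_bulk <= rho_true" =
      is.numeric(rho_bulk) && is.numeric(rho_true) &&
      rho_bulk > 0 && rho_bulk <= rho_true,
    "slip must lie in [0, 1)" = is.numeric(slip) && slip >= 0 && slip < 1
  )
  structure(list(rho_bulk = rho_bulk, rho_true = rho_true, slip = slip),
            class = "powder_state")
}

#' @export
print.powder_state <- function(x, ...) {
  cat(sprintf("Powder: rho_bulk = %.4g kg/m^3, rho_true = %.4g kg/m^3, slip = %.4g\n",
              x$rho_bulk, x$rho_true, x$slip))
  invisible(x)
}

#' Specific feed load (SFL)
#'
#' Dimensionless barrel-load number: volumetric throughput (mass flow over
#' true density) normalized by screw speed times diameter cubed,
#' `SFL = (m / rho_true) / (n d^3)`.
#'
#' @param mass_flow mass flow rate, kg/s
#' @param rho_true true density, kg/m^3
#' @param n screw speed, 1/s (> 0)
#' @param d screw diameter, m
#' @return dimensionless specific feed load
#' @export
sfl <- function(mass_flow, rho_true, n, d) {
  if (any(n <= 0)) stop("screw speed n must be positive")
  stopifnot(rho_true > 0, d > 0, all(mass_flow >= 0))
  (mass_flow / rho_true) / (n * d^3)
}

#' Normalized specific feed load (SFL*)
#'
#' Feed load normalized by the slip-reduced transport capacity of the feeding
#' screw: `SFL* = (m / rho_bulk) / ((1 - s) l_pitch A_free n)`. SFL* = 0 is
#' an empty feeding section, SFL* = 1 a completely filled one.
#'
#' @param mass_flow mass flow rate, kg/s (>= 0)
#' @param powder a [powder_state()]
#' @param geom an [extruder_geometry()]
#' @param n screw speed, 1/s (> 0)
#' @return dimensionless normalized feed load
#' @export
sfl_star <- function(mass_flow, powder, geom, n) {
  stopifnot(inherits(powder, "powder_state"), inherits(geom, "extruder_geometry"))
  if (any(n <= 0)) stop("screw speed n must be positive")
  if (powder$slip >= 1) stop("slip = 1 means no transport capacity (degenerate)")
  if (any(mass_flow < 0)) stop("mass_flow must be non-negative")
  (mass_flow / powder$rho_bulk) /
    ((1 - powder$slip) * geom$l_pitch * geom$A_free * n)
}

#' Slip from a single filled-section operating point
#'
#' At the backlog point the feeding section is completely filled (SFL* = 1),
#' which determines the slip:
#' `s = 1 - (m / rho_bulk) / (l_pitch A_free n)`.
#' A computed slip >= 1 means the inputs are inconsistent with a filled
#' section and is an error; a negative slip (throughput exceeding the
#' geometric capacity) is returned unclamped with a warning.
#'
#' @param mass_flow mass flow rate at the filled point, kg/s
#' @param rho_bulk bulk density, kg/m^3
#' @param geom an [extruder_geometry()]
#' @param n screw speed at the filled point, 1/s
#' @return slip fraction
#' @export
slip_from_filled_point <- function(mass_flow, rho_bulk, geom, n) {
  stopifnot(inherits(geom, "extruder_geometry"),
            mass_flow > 0, rho_bulk > 0, n > 0)
  s <- 1 - (mass_flow / rho_bulk) / (geom$l_pitch * geom$A_free * n)
  if (s >= 1) {
    stop("computed slip >= 1: inputs are inconsistent with a filled feeding section")
  }
  if (s < 0) {
    warning(sprintf(
      "computed slip %.4g is negative (throughput exceeds geometric capacity); returned unclamped",
      s))
  }
  s
}

#' Fit slip from maximum-throughput measurements at several screw speeds
#'
#' The maximum mass flow transported through the feeding section is linear in
#' screw speed with no intercept (zero speed transports nothing):
#' `m_max = (1 - s) l_pitch A_free rho_bulk n`. Least-squares regression
#' through the origin of `m_max` on `n` yields
#' `s = 1 - slope / (l_pitch A_free rho_bulk)`.
#'
#' @param points data frame with columns `n` (1/s) and `max_mass_flow`
#'   (kg/s), e.g. from [read_feeding_csv()]; a single point reduces to
#'   [slip_from_filled_point()]
#' @param powder a [powder_state()] (bulk density is used)
#' @param geom an [extruder_geometry()]
#' @return slip fraction, with attribute `slope` (kg/s per 1/s)
#' @export
fit_slip <- function(points, powder, geom) {
  stopifnot(is.data.frame(points),
            all(c("n", "max_mass_flow") %in% names(points)),
            inherits(powder, "powder_state"),
            inherits(geom, "extruder_geometry"))
  if (nrow(points) == 0L) stop("no feeding measurements supplied")
  if (any(points$n <= 0) || any(points$max_mass_flow <= 0)) {
    stop("speeds and mass flows must be positive")
  }
  if (nrow(points) >= 2L && length(unique(points$n)) < 2L) {
    stop("feeding measurements must span at least two distinct screw speeds")
  }
  slope <- sum(points$max_mass_flow * points$n) / sum(points$n^2)
  one_minus_s <- slope / (geom$l_pitch * geom$A_free * powder$rho_bulk)
  if (one_minus_s <= 0) stop("fitted (1 - slip) is non-positive")
  s <- 1 - one_minus_s
  if (s < 0) {
    warning(sprintf("fitted slip %.4g is negative; returned unclamped", s))
  }
  structure(s, slope = slope)
}

#' Maximum specific feed load
#'
#' Predicted maximum barrel load from extruder geometry, powder densities and
#' slip: `SFLmax = (1 - s) (rho_bulk / rho_true) (A_free l_pitch) / d^3`.
#' Reaching it means the feeding section is completely filled.
#'
#' @inheritParams sfl_star
#' @return dimensionless maximum specific feed load
#' @export
sfl_max <- function(powder, geom) {
  stopifnot(inherits(powder, "powder_state"), inherits(geom, "extruder_geometry"))
  (1 - powder$slip) * (powder$rho_bulk / powder$rho_true) *
    (geom$A_free * geom$l_pitch) / geom$d^3
}

#' Maximum mass flow through the feeding section
#'
#' `m_max = (1 - s) l_pitch A_free rho_bulk n`: the throughput at which the
#' feeding section is completely filled (SFL* = 1) at screw speed `n`.
#'
#' @inheritParams sfl_star
#' @return mass flow rate, kg/s
#' @export
max_mass_flow <- function(powder, geom, n) {
  stopifnot(inherits(powder, "powder_state"), inherits(geom, "extruder_geometry"))
  if (any(n <= 0)) stop("screw speed n must be positive")
  (1 - powder$slip) * geom$l_pitch * geom$A_free * powder$rho_bulk * n
}
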