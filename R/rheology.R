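# Carreau melt viscosity with Arrhenius time-temperature superposition.

#' Universal gas constant, J/(mol K)
#' @keywords internal
R_GAS <- 8.314

#' Carreau-Arrhenius parameter set
#'
#' Bundles the three Carreau parameters of a polymer melt flow curve with the
#' Arrhenius activation energy and reference temperature used for
#' time-temperature superposition. The viscosity model is
#' \deqn{\eta(\dot\gamma, T) = \eta_0\, a_T\,
#'   \left(1 + a_T \dot\gamma / \dot\gamma_c\right)^{-c}}
#' with the shift factor
#' \deqn{a_T = \exp\!\left[\frac{E_A}{R}\Big(\frac{1}{T} -
#'   \frac{1}{T_{ref}}\Big)\right].}
#' The negative exponent is the shear-thinning convention consistent with the
#' Ostwald flow index relation n = 1 - c.
#'
#' @param eta0 zero-shear viscosity, Pa s (> 0)
#' @param gammadot_c critical shear rate, 1/s (> 0)
#' @param c Carreau flow index, dimensionless, in \[0, 1)
#' @param Ea activation energy, J/mol (> 0)
#' @param T_ref reference temperature, K (> 0)
#' @return an object of class `carreau_arrhenius`
#' @seealso [melt_viscosity()], [shift_factor()], [fit_carreau_arrhenius()]
#' @examples
#' pvpva <- carreau_arrhenius(eta0 = 169.7, gammadot_c = 133.1, c = 0.387,
#'                            Ea = 198292, T_ref = 473)
#' melt_viscosity(pvpva, shear_rate = 0, temperature = 473)  # returns eta0
#' @export
carreau_arrhenius <- function(eta0, gammadot_c, c, Ea, T_ref) {
  stopifnot(
    "eta0 must be a positive number" = is.numeric(eta0) && length(eta0) == 1L && eta0 > 0,
    "gammadot_c must be a positive number" = is.numeric(gammadot_c) && length(gammadot_c) == 1L && gammadot_c > 0,
    "c must lie in [0, 1)" = is.numeric(c) && length(c) == 1L && c >= 0 && c < 1,
    "Ea must be a positive number" = is.numeric(Ea) && length(Ea) == 1L && Ea > 0,
    "T_ref must be a positive temperature in K" = is.numeric(T_ref) && length(T_ref) == 1L && T_ref > 0
  )
  structure(
    list(eta0 = eta0, gammadot_c = gammadot_c, c = c, Ea = Ea, T_ref = T_ref),
    class = "carreau_arrhenius"
  )
}

#' @export
print.carreau_arrhenius <- function(x, ...) {
  cat("Carreau-Arrhenius melt viscosity model\n")
  cat(sprintf("  eta0       : %.4g Pa s (zero-shear viscosity)\n", x$eta0))
  cat(sprintf("  gammadot_c : %.4g 1/s  (critical shear rate)\n", x$gammadot_c))
  cat(sprintf("  c          : %.4g      (flow index; Ostwald n = %.4g)\n",
              x$c, 1 - x$c))
  cat(sprintf("  Ea         : %.4g J/mol\n", x$Ea))
  cat(sprintf("  T_ref      : %.4g K (%.1f degC)\n", x$T_ref,
              kelvin_to_celsius(x$T_ref)))
  invisible(x)
}

#' Arrhenius shift factor
#'
#' Time-temperature superposition factor
#' `a_T = exp((Ea/R) * (1/T - 1/T_ref))`; equal to 1 at the reference
#' temperature, below 1 above it. Strictly decreasing in temperature.
#'
#' @param params a [carreau_arrhenius()] object
#' @param temperature temperature, K (vectorized, all > 0)
#' @return dimensionless shift factor(s)
#' @export
shift_factor <- function(params, temperature) {
  stopifnot(inherits(params, "carreau_arrhenius"))
  if (any(!is.finite(temperature)) || any(temperature <= 0)) {
    stop("temperature must be positive (kelvin)")
  }
  exp(params$Ea / R_GAS * (1 / temperature - 1 / params$T_ref))
}

#' Melt viscosity from the Carreau-Arrhenius model
#'
#' Evaluates `eta = eta0 * a_T * (1 + a_T * shear_rate / gammadot_c)^(-c)`.
#' Strictly decreasing in shear rate (for c > 0) and in temperature.
#'
#' @inheritParams shift_factor
#' @param shear_rate shear rate, 1/s (vectorized, all >= 0)
#' @return viscosity, Pa s
#' @export
melt_viscosity <- function(params, shear_rate, temperature) {
  stopifnot(inherits(params, "carreau_arrhenius"))
  if (any(!is.finite(shear_rate)) || any(shear_rate < 0)) {
    stop("shear_rate must be non-negative")
  }
  aT <- shift_factor(params, temperature)
  params$eta0 * aT * (1 + aT * shear_rate / params$gammadot_c)^(-params$c)
}

#' Ostwald (power-law) flow index from the Carreau index
#'
#' The high-shear power-law slope of the Carreau model corresponds to the
#' Ostwald index `n = 1 - c` (Newtonian for c = 0).
#'
#' @inheritParams shift_factor
#' @return dimensionless flow index in (0, 1]
#' @export
ostwald_index <- function(params) {
  stopifnot(inherits(params, "carreau_arrhenius"))
  1 - params$c
}

#' Solve the Carreau-Arrhenius model for temperature
#'
#' Finds the temperature at which the melt reaches a target viscosity at a
#' given shear rate. The model has no closed-form inverse in temperature, but
#' viscosity is strictly monotone decreasing in T, so a bracketed root search
#' ([stats::uniroot()]) on `[T_ref - 150, T_ref + 150]` K converges to a
#' unique solution.
#'
#' @inheritParams shift_factor
#' @param shear_rate shear rate, 1/s (scalar, >= 0)
#' @param target_viscosity viscosity to match, Pa s (scalar, > 0)
#' @param bracket search interval in K, default `T_ref + c(-150, 150)`
#' @param tol absolute tolerance on temperature, K
#' @return temperature, K
#' @export
invert_temperature <- function(params, shear_rate, target_viscosity,
                               bracket = params$T_ref + c(-150, 150),
                               tol = 1e-6) {
  stopifnot(inherits(params, "carreau_arrhenius"),
            length(shear_rate) == 1L, shear_rate >= 0,
            length(target_viscosity) == 1L)
  if (!is.finite(target_viscosity) || target_viscosity <= 0) {
    stop("target_viscosity must be positive")
  }
  bracket <- sort(bracket)
  if (bracket[1] <= 0) bracket[1] <- 1e-3
  eta_hi <- melt_viscosity(params, shear_rate, bracket[1])  # cold end: high
  eta_lo <- melt_viscosity(params, shear_rate, bracket[2])  # hot end: low
  if (target_viscosity > eta_hi || target_viscosity < eta_lo) {
    stop(sprintf(
      paste0("target viscosity %.6g Pa s is outside the bracket range: ",
             "viscosity(%.1f K) = %.6g, viscosity(%.1f K) = %.6g Pa s"),
      target_viscosity, bracket[1], eta_hi, bracket[2], eta_lo
    ))
  }
  root <- stats::uniroot(
    function(T) melt_viscosity(params, shear_rate, T) - target_viscosity,
    interval = bracket, tol = tol
  )
  root$root
}

#' Fit the Carreau-Arrhenius model to flow-curve data
#'
#' Refits measured flow-curve points (shear rate, temperature, viscosity) to
#' the Carreau model coupled with the Arrhenius shift, by
#' Levenberg-Marquardt least squares on log10 viscosity (viscosity spans
#' decades, so residuals are taken in log space; unweighted). The reference
#' temperature is fixed by the caller, as is conventional when assembling a
#' master curve.
#'
#' @param points data frame with columns `shear_rate` (1/s), `temperature`
#'   (K) and `viscosity` (Pa s), e.g. from [read_flow_curve_csv()]
#' @param T_ref reference temperature to anchor the Arrhenius shift, K
#' @param start optional named list of start values
#'   (`eta0`, `gammadot_c`, `c`, `Ea`)
#' @return a [carreau_arrhenius()] object with attributes `rss` (residual sum
#'   of squares in log10 space) and `convergence` (optimizer status message)
#' @export
fit_carreau_arrhenius <- function(points, T_ref, start = NULL) {
  stopifnot(is.data.frame(points),
            all(c("shear_rate", "temperature", "viscosity") %in% names(points)))
  pts <- points[, c("shear_rate", "temperature", "viscosity")]
  if (any(pts$shear_rate < 0) || any(pts$viscosity <= 0) || any(pts$temperature <= 0)) {
    stop("flow-curve points must have shear_rate >= 0, viscosity > 0, temperature > 0")
  }
  if (nrow(pts) < 4L) {
    stop("at least 4 flow-curve points are required to fit 4 parameters")
  }
  if (length(unique(pts$temperature)) < 2L) {
    stop("flow-curve points span a single temperature: activation energy Ea is not identifiable")
  }

  # theta = (log eta0, log gammadot_c, c, log Ea); box bound keeps c in [0, 1)
  Ea0 <- if (!is.null(start$Ea)) start$Ea else 1.5e5
  c0 <- if (!is.null(start$c)) start$c else 0.4
  gdc0 <- if (!is.null(start$gammadot_c)) start$gammadot_c else {
    pos <- pts$shear_rate[pts$shear_rate > 0]
    if (length(pos)) stats::median(pos) else 100
  }
  eta00 <- if (!is.null(start$eta0)) start$eta0 else {
    aT0 <- exp(Ea0 / R_GAS * (1 / pts$temperature - 1 / T_ref))
    max(pts$viscosity / aT0)
  }

  resid_fn <- function(theta) {
    p <- carreau_arrhenius(exp(theta[1]), exp(theta[2]),
                           min(max(theta[3], 0), 1 - 1e-9),
                           exp(theta[4]), T_ref)
    log10(melt_viscosity(p, pts$shear_rate, pts$temperature)) - log10(pts$viscosity)
  }
  fit <- minpack.lm::nls.lm(
    par = c(log(eta00), log(gdc0), c0, log(Ea0)),
    lower = c(-Inf, -Inf, 0, log(1)),
    upper = c(Inf, Inf, 1 - 1e-6, log(1e7)),
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                         ptol = 1e-14)
  )
  if (!(fit$info %in% 1:4)) {
    stop("Carreau-Arrhenius fit did not converge: ", fit$message)
  }
  th <- fit$par
  out <- carreau_arrhenius(exp(th[1]), exp(th[2]), th[3], exp(th[4]), T_ref)
  attr(out, "rss") <- fit$deviance
  attr(out, "convergence") <- fit$message
  out
}
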