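# Autogenic extrusion correlations: in autogenic operation (barrel heating
# off) the melt temperature self-adjusts so that each screw speed produces a
# characteristic die viscosity, eta_die = tau_extruder / n. A second,
# log-log correlation maps the die viscosity onto the Carreau-Arrhenius
# (extruder-independent) viscosity, which closes the chain from screw speed
# to melt temperature.

#' Steady-state autogenic extrusion observations
#'
#' Validated table of autogenic steady-state records: screw speed, mass flow,
#' melt temperature at the die and die pressure.
#'
#' @param n screw speed, 1/s
#' @param mass_flow mass flow rate, kg/s
#' @param melt_temperature melt temperature at the die, K
#' @param die_pressure pressure drop across the die, Pa
#' @return a data frame of class `extrusion_observations`
#' @seealso [read_autogenic_csv()] for the rpm / kg/h / degC / bar file schema
#' @export
extrusion_observations <- function(n, mass_flow, melt_temperature, die_pressure) {
  df <- data.frame(n = n, mass_flow = mass_flow,
                   melt_temperature = melt_temperature,
                   die_pressure = die_pressure)
  if (nrow(df) == 0L) stop("no observations supplied")
  if (any(!is.finite(as.matrix(df))) || any(as.matrix(df) <= 0)) {
    stop("all observation fields must be positive and finite")
  }
  class(df) <- c("extrusion_observations", "data.frame")
  df
}

#' Extruder-specific autogenic fit
#'
#' Container for the fitted autogenic parameters: the characteristic shear
#' stress `tau_extruder` (with its dispersion over operating points), the
#' slope and intercept of the log-log die-to-calculated viscosity
#' correlation, and the Pearson correlation of that regression. These are
#' specific to one extruder in one setup (screw configuration and die), and
#' independent of material and process parameters.
#'
#' @param tau_extruder characteristic shear stress, Pa (> 0)
#' @param tau_sd standard deviation of tau over operating points, Pa
#' @param s_extruder slope of the log-log viscosity-ratio correlation
#' @param i_extruder intercept of that correlation
#' @param r_correlation Pearson correlation coefficient, in \[-1, 1\]
#' @param n_points_used number of observations that entered the fit
#' @param min_speed screw-speed threshold applied before fitting, 1/s
#' @return an object of class `autogenic_fit`
#' @export
autogenic_fit <- function(tau_extruder, tau_sd = NA_real_, s_extruder,
                          i_extruder, r_correlation = NA_real_,
                          n_points_used = NA_integer_,
                          min_speed = NA_real_) {
  stopifnot("tau_extruder must be positive" = tau_extruder > 0)
  if (!is.na(r_correlation) && abs(r_correlation) > 1 + 1e-12) {
    stop("r_correlation must lie in [-1, 1]")
  }
  structure(list(tau_extruder = tau_extruder, tau_sd = tau_sd,
                 s_extruder = s_extruder, i_extruder = i_extruder,
                 r_correlation = r_correlation,
                 n_points_used = n_points_used, min_speed = min_speed),
            class = "autogenic_fit")
}

#' @export
print.autogenic_fit <- function(x, ...) {
  cat("Autogenic extruder parameters\n")
  cat(sprintf("  tau_extruder : %.4g +/- %.3g Pa\n", x$tau_extruder, x$tau_sd))
  cat(sprintf("  s_extruder   : %.4g  (slope)\n", x$s_extruder))
  cat(sprintf("  i_extruder   : %.4g  (intercept)\n", x$i_extruder))
  cat(sprintf("  R            : %.4g  (Pearson, log-log regression)\n",
              x$r_correlation))
  if (!is.na(x$n_points_used)) {
    cat(sprintf("  fitted on %d observation(s)", x$n_points_used))
    if (!is.na(x$min_speed)) {
      cat(sprintf(" with n >= %.0f rpm", hz_to_rpm(x$min_speed)))
    }
    cat("\n")
  }
  invisible(x)
}

# Die viscosities of a set of observations, via the capillary treatment of
# the die; volume flow = mass flow / true density (melt density stand-in).
obs_die_viscosity <- function(obs, geom, material, wr_correct = TRUE) {
  volume_flow <- obs$mass_flow / material$rho_true
  die_viscosity(obs$die_pressure, volume_flow, geom,
                c = material$rheology$c, wr_correct = wr_correct)
}

qualifying_obs <- function(obs, min_speed) {
  keep <- obs$n >= min_speed
  if (!any(keep)) {
    stop(sprintf(
      "no observations at or above the %.0f rpm fitting threshold",
      hz_to_rpm(min_speed)))
  }
  obs[keep, , drop = FALSE]
}

#' Fit the characteristic extruder shear stress
#'
#' In autogenic operation the die viscosity follows the hyperbola
#' `eta_die = tau_extruder / n`, so `eta_die * n` is constant across
#' operating points. The fit is the mean of `eta_die * n` over all
#' observations at or above the speed threshold, reported with its standard
#' deviation (equal weighting across speeds). Points below the threshold are
#' excluded: at low throughput the equilibration to autogenic steady state
#' is incomplete and the hyperbola does not hold.
#'
#' @param obs an [extrusion_observations()] table
#' @param geom an [extruder_geometry()]
#' @param material a [material_properties()]
#' @param min_speed fitting threshold on screw speed, 1/s
#'   (default 100 rpm)
#' @param wr_correct apply the Weissenberg-Rabinowitsch correction when
#'   computing die viscosities? default TRUE
#' @return list with `tau` (Pa), `tau_sd` (Pa) and `n_points_used`
#' @export
fit_tau_extruder <- function(obs, geom, material,
                             min_speed = rpm_to_hz(100), wr_correct = TRUE) {
  stopifnot(inherits(obs, "extrusion_observations"))
  q <- qualifying_obs(obs, min_speed)
  tau_i <- obs_die_viscosity(q, geom, material, wr_correct) * q$n
  list(tau = mean(tau_i),
       tau_sd = if (length(tau_i) > 1L) stats::sd(tau_i) else 0,
       n_points_used = nrow(q))
}

#' Fit the log-log die-to-calculated viscosity correlation
#'
#' For each qualifying observation the die viscosity (capillary treatment of
#' the die) is compared with the viscosity the Carreau-Arrhenius model
#' assigns to the measured melt temperature at the WR-corrected die shear
#' rate. The ratio correlates with normalized screw speed on log-log axes:
#' `lg(eta_die / eta_calc) = s_extruder * lg(n / n_max) + i_extruder`
#' (lg = log10). Ordinary least squares gives slope, intercept and the
#' Pearson correlation of the regression.
#'
#' @inheritParams fit_tau_extruder
#' @return list with `s_extruder`, `i_extruder`, `r_correlation` and
#'   `n_points_used`
#' @export
fit_viscosity_ratio <- function(obs, geom, material,
                                min_speed = rpm_to_hz(100), wr_correct = TRUE) {
  stopifnot(inherits(obs, "extrusion_observations"))
  q <- qualifying_obs(obs, min_speed)
  if (nrow(q) < 2L) stop("at least 2 qualifying observations are required")
  eta_die <- obs_die_viscosity(q, geom, material, wr_correct)
  rate <- die_shear_rate(q$mass_flow / material$rho_true, geom)
  if (wr_correct) rate <- wr_corrected_shear_rate(rate, material$rheology$c)
  eta_calc <- melt_viscosity(material$rheology, rate, q$melt_temperature)
  x <- log10(q$n / geom$n_max)
  y <- log10(eta_die / eta_calc)
  if (stats::var(x) < .Machine$double.eps) {
    stop("screw speeds are degenerate: the slope is not identifiable")
  }
  co <- stats::coef(stats::lm(y ~ x))
  list(s_extruder = unname(co[2]), i_extruder = unname(co[1]),
       r_correlation = stats::cor(x, y), n_points_used = nrow(q))
}

#' Fit all autogenic extruder parameters
#'
#' Runs [fit_tau_extruder()] and [fit_viscosity_ratio()] on the same
#' observation table and combines the results.
#'
#' @inheritParams fit_tau_extruder
#' @return an [autogenic_fit()]
#' @export
fit_autogenic <- function(obs, geom, material,
                          min_speed = rpm_to_hz(100), wr_correct = TRUE) {
  tau <- fit_tau_extruder(obs, geom, material, min_speed, wr_correct)
  vr <- fit_viscosity_ratio(obs, geom, material, min_speed, wr_correct)
  autogenic_fit(tau_extruder = tau$tau, tau_sd = tau$tau_sd,
                s_extruder = vr$s_extruder, i_extruder = vr$i_extruder,
                r_correlation = vr$r_correlation,
                n_points_used = vr$n_points_used, min_speed = min_speed)
}

#' Predict the autogenic operating point for a screw speed
#'
#' Chains the fitted correlations into a full operating-point prediction.
#' For each requested speed `n`: the mass flow at maximum barrel load is
#' `SFLmax * rho_true * n * d^3`; the die shear rate follows from the volume
#' flow (WR-corrected); the die viscosity is `tau_extruder / n`; the log-log
#' correlation converts it to the extruder-independent (Carreau) viscosity;
#' and numerically inverting the Carreau-Arrhenius model at the corrected
#' die shear rate yields the melt temperature.
#'
#' @param n screw speed(s), 1/s
#' @param fit an [autogenic_fit()]
#' @param material a [material_properties()]
#' @param geom an [extruder_geometry()]
#' @param sfl_max maximum specific feed load to operate at, e.g. from
#'   [sfl_max()]
#' @param wr_correct apply the WR correction to the die shear rate?
#'   default TRUE
#' @return a data frame of class `prediction_result` with columns `n`,
#'   `mass_flow` (kg/s), `die_shear_rate_corr` (1/s), `eta_die` (Pa s),
#'   `eta_calculated` (Pa s) and `melt_temperature` (K)
#' @export
predict_operating_point <- function(n, fit, material, geom, sfl_max,
                                    wr_correct = TRUE) {
  stopifnot(inherits(fit, "autogenic_fit"),
            inherits(material, "material_properties"),
            inherits(geom, "extruder_geometry"),
            sfl_max > 0)
  if (any(n <= 0)) stop("screw speed n must be positive")
  mass_flow <- sfl_max * material$rho_true * n * geom$d^3
  rate <- die_shear_rate(mass_flow / material$rho_true, geom)
  if (wr_correct) rate <- wr_corrected_shear_rate(rate, material$rheology$c)
  eta_die <- fit$tau_extruder / n
  eta_calc <- eta_die *
    10^(-(fit$s_extruder * log10(n / geom$n_max) + fit$i_extruder))
  melt_T <- vapply(seq_along(n), function(i) {
    invert_temperature(material$rheology, rate[i], eta_calc[i])
  }, numeric(1))
  out <- data.frame(n = n, mass_flow = mass_flow,
                    die_shear_rate_corr = rate, eta_die = eta_die,
                    eta_calculated = eta_calc, melt_temperature = melt_T)
  class(out) <- c("prediction_result", "data.frame")
  out
}

#' Combine autogenic fits from donor materials (crossover)
#'
#' Transfers extruder parameters to a material not used in fitting: the
#' donors' `tau_extruder`, `s_extruder` and `i_extruder` are combined by
#' arithmetic mean (a single donor passes through unchanged). The dispersion
#' reported is the mean of the donor dispersions; the correlation
#' coefficient does not transfer and is NA.
#'
#' @param fits list of [autogenic_fit()] objects (at least one)
#' @return an [autogenic_fit()]
#' @export
crossover_parameters <- function(fits) {
  if (length(fits) == 0L) stop("at least one donor fit is required")
  stopifnot(all(vapply(fits, inherits, logical(1), "autogenic_fit")))
  if (length(fits) == 1L) return(fits[[1]])
  pick <- function(f) vapply(fits, `[[`, numeric(1), f)
  autogenic_fit(
    tau_extruder = mean(pick("tau_extruder")),
    tau_sd = mean(pick("tau_sd")),
    s_extruder = mean(pick("s_extruder")),
    i_extruder = mean(pick("i_extruder")),
    r_correlation = NA_real_,
    n_points_used = as.integer(sum(vapply(
      fits, function(f) as.numeric(f$n_points_used), numeric(1)))),
    min_speed = fits[[1]]$min_speed
  )
}
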