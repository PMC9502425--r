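# Virtual autogenic extruder: forward-generates steady-state observation
# tables from ground-truth parameters by inverting the prediction chain, so
# every fitting and prediction stage can be exercised without hardware.

#' Simulation scenario for a virtual autogenic campaign
#'
#' Ground truth for a virtual extrusion campaign run at maximum barrel load
#' (SFL* = 1 at every speed, emulating a ramp in which mass flow and screw
#' speed are raised together at constant specific feed load). Measurement
#' noise is Gaussian: additive on the melt temperature (IR-camera-like) and
#' multiplicative on the die pressure (gauge-like); both default to
#' realistic magnitudes of 1 K and 1%.
#'
#' @param material a [material_properties()]
#' @param geometry an [extruder_geometry()]
#' @param true_slip ground-truth slip fraction in \[0, 1)
#' @param true_tau ground-truth characteristic shear stress, Pa
#' @param true_slope,true_intercept ground-truth parameters of the log-log
#'   viscosity-ratio correlation
#' @param speeds screw speeds of the campaign, 1/s (positive, distinct);
#'   default an 8-point ramp from 100 to 500 rpm
#' @param noise_T temperature noise standard deviation, K (>= 0)
#' @param noise_p_rel relative pressure noise standard deviation (>= 0)
#' @param seed integer RNG seed
#' @return an object of class `simulation_scenario`
#' @export
simulation_scenario <- function(material, geometry, true_slip,
                                true_tau = 400, true_slope = 0.3,
                                true_intercept = 0.1,
                                speeds = rpm_to_hz(seq(100, 500, length.out = 8)),
                                noise_T = 1, noise_p_rel = 0.01, seed = 1L) {
  stopifnot(inherits(material, "material_properties"),
            inherits(geometry, "extruder_geometry"),
            true_slip >= 0, true_slip < 1, true_tau > 0,
            noise_T >= 0, noise_p_rel >= 0)
  if (any(speeds <= 0) || anyDuplicated(speeds)) {
    stop("speeds must be positive and distinct")
  }
  structure(list(material = material, geometry = geometry,
                 true_slip = true_slip, true_tau = true_tau,
                 true_slope = true_slope, true_intercept = true_intercept,
                 speeds = speeds, noise_T = noise_T,
                 noise_p_rel = noise_p_rel, seed = as.integer(seed)),
            class = "simulation_scenario")
}

#' Simulate an autogenic extrusion campaign
#'
#' Forward-generates one steady-state observation per scenario speed. For
#' each speed `n`: the mass flow fills the feeding section exactly
#' (SFL* = 1); the die viscosity is `true_tau / n`; the log-log correlation
#' gives the extruder-independent viscosity; inverting the
#' Carreau-Arrhenius model at the WR-corrected die shear rate yields the
#' melt temperature; and inverting the capillary die equations yields the
#' die pressure. Seeded Gaussian noise is then added (additive on
#' temperature, multiplicative on pressure). Deterministic for a fixed
#' scenario seed.
#'
#' @param scenario a [simulation_scenario()]
#' @return an [extrusion_observations()] table; attribute `truth` holds the
#'   noiseless melt temperatures and die pressures
#' @export
simulate_autogenic_campaign <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  mat <- scenario$material
  geom <- scenario$geometry
  powder <- powder_from_material(mat, scenario$true_slip)
  n <- scenario$speeds

  mass_flow <- max_mass_flow(powder, geom, n)
  rate <- wr_corrected_shear_rate(
    die_shear_rate(mass_flow / mat$rho_true, geom), mat$rheology$c)
  eta_die <- scenario$true_tau / n
  eta_calc <- eta_die *
    10^(-(scenario$true_slope * log10(n / geom$n_max) + scenario$true_intercept))
  melt_T <- vapply(seq_along(n), function(i) {
    tryCatch(
      invert_temperature(mat$rheology, rate[i], eta_calc[i]),
      error = function(e) stop(sprintf(
        "temperature inversion failed at screw speed %.0f rpm: %s",
        hz_to_rpm(n[i]), conditionMessage(e)), call. = FALSE)
    )
  }, numeric(1))
  # invert eta_die = tau_wall / rate_corr with tau_wall = dp r / (2 l)
  die_pressure <- eta_die * rate * 2 * geom$l_die / geom$r_die

  noisy <- withr::with_seed(scenario$seed, {
    list(T = melt_T + stats::rnorm(length(n), 0, scenario$noise_T),
         p = die_pressure * (1 + stats::rnorm(length(n), 0, scenario$noise_p_rel)))
  })
  obs <- extrusion_observations(n, mass_flow, noisy$T, noisy$p)
  attr(obs, "truth") <- data.frame(n = n, melt_temperature = melt_T,
                                   die_pressure = die_pressure)
  obs
}

#' Simulate feeding (maximum-throughput) experiments
#'
#' Generates maximum mass-flow measurements at several screw speeds from a
#' ground-truth slip, with optional multiplicative Gaussian noise; input for
#' [fit_slip()].
#'
#' @param powder a [powder_state()] carrying the ground-truth slip
#' @param geom an [extruder_geometry()]
#' @param speeds screw speeds, 1/s
#' @param noise_rel relative noise standard deviation (default 0: noiseless)
#' @param seed integer RNG seed
#' @return data frame with columns `n` and `max_mass_flow`
#' @export
simulate_feeding_experiments <- function(powder, geom, speeds,
                                         noise_rel = 0, seed = 1L) {
  m <- max_mass_flow(powder, geom, speeds)
  if (noise_rel > 0) {
    m <- withr::with_seed(as.integer(seed),
                          m * (1 + stats::rnorm(length(m), 0, noise_rel)))
  }
  data.frame(n = speeds, max_mass_flow = m)
}
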