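# Shared fixtures: the three reference polymers, the 27 mm machine, and a
# scenario builder with paper-plausible extruder truth.

ref_mats <- reference_polymers()
ref_geom <- zse27_geometry()
ref_slip <- reference_slips()

# Ground-truth extruder parameters per material (characteristic shear
# stress, log-log slope/intercept) used by the simulation scenarios.
truth_for <- function(key) {
  switch(key,
    pvpva = list(tau = 399, slope = 0.409, intercept = 0.131),
    sol   = list(tau = 361, slope = 0.318, intercept = 0.036),
    bbma  = list(tau = 361, slope = 0.126, intercept = 0.045))
}

make_scenario <- function(key = "pvpva", noise_T = 0, noise_p_rel = 0,
                          seed = 1L, speeds = NULL, slip = NULL) {
  tr <- truth_for(key)
  args <- list(material = ref_mats[[key]], geometry = ref_geom,
               true_slip = if (is.null(slip)) ref_slip[[key]] else slip,
               true_tau = tr$tau, true_slope = tr$slope,
               true_intercept = tr$intercept,
               noise_T = noise_T, noise_p_rel = noise_p_rel, seed = seed)
  if (!is.null(speeds)) args$speeds <- speeds
  do.call(simulation_scenario, args)
}

# Independent scalar oracle for the viscosity model: a literal one-line
# transcription kept separate from the package implementation.
oracle_viscosity <- function(eta0, gdc, cc, Ea, Tref, gd, Tk) {
  aT <- exp(Ea / 8.314 * (1 / Tk - 1 / Tref))
  eta0 * aT * (1 + aT * gd / gdc)^(-cc)
}

# Grid-search oracle for the temperature inverse: exhaustive 0.01 K scan.
oracle_invert_T <- function(params, shear_rate, target, lo, hi) {
  grid <- seq(lo, hi, by = 0.01)
  eta <- melt_viscosity(params, shear_rate, grid)
  grid[which.min(abs(eta - target))]
}
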