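# SIOS 2.0 orchestration: plan the minimal experimental campaign, fit the
# feed-load and autogenic models, sweep predictions, and validate across
# materials.

#' Plan the autogenic characterization experiments
#'
#' Emits the minimal experiment protocol with concrete set-points. The first
#' condition runs at a chosen start speed with the mass flow set so the
#' feeding section is exactly filled (SFL* = 1). Follow-up conditions scale
#' screw speed and mass flow by the same ratio — down (default two-thirds)
#' if the relative power consumption is low, up (default four-thirds) if it
#' is high — which preserves SFL* = 1, so every condition stays at maximum
#' barrel load.
#'
#' @param powder a [powder_state()] with slip known or assumed
#' @param geom an [extruder_geometry()]
#' @param start_speed first screw speed, 1/s (e.g. 200 rpm)
#' @param ratio_down,ratio_up scaling for the low-/high-power branch
#' @param n_follow_up number of follow-up conditions per branch
#' @return a data frame of class `sios2_plan` with columns `step`, `branch`,
#'   `screw_speed_rpm` and `mass_flow_kg_h`
#' @export
plan_experiments <- function(powder, geom, start_speed,
                             ratio_down = 2 / 3, ratio_up = 4 / 3,
                             n_follow_up = 2L) {
  stopifnot(start_speed > 0, ratio_down > 0, ratio_down < 1, ratio_up > 1)
  speed <- function(branch_ratio, k) start_speed * branch_ratio^k
  rows <- list(data.frame(step = 1L, branch = "start",
                          n = start_speed))
  for (k in seq_len(n_follow_up)) {
    rows <- c(rows, list(
      data.frame(step = k + 1L, branch = "low_power",
                 n = speed(ratio_down, k)),
      data.frame(step = k + 1L, branch = "high_power",
                 n = speed(ratio_up, k))
    ))
  }
  df <- do.call(rbind, rows)
  df$mass_flow <- max_mass_flow(powder, geom, df$n)  # SFL* = 1 set-point
  out <- data.frame(step = df$step, branch = df$branch,
                    screw_speed_rpm = hz_to_rpm(df$n),
                    mass_flow_kg_h = kg_s_to_kg_h(df$mass_flow))
  class(out) <- c("sios2_plan", "data.frame")
  out
}

#' @export
print.sios2_plan <- function(x, ...) {
  cat("Autogenic characterization plan (all set-points at SFL* = 1)\n")
  cat("  1. Set barrel temperatures to the recommended process temperature;\n")
  cat("     cool the feeding section.\n")
  cat("  2. Run the start condition below; wait for coherent extrudate,\n")
  cat("     then switch off barrel temperature control (keep feeding-section\n")
  cat("     cooling and die heating).\n")
  cat("  3. At steady state record screw speed, mass flow, melt temperature\n")
  cat("     and die pressure; move along the low-power branch if relative\n")
  cat("     power consumption is below ~50%, else along the high-power branch.\n\n")
  print.data.frame(as.data.frame(x), row.names = FALSE, digits = 4)
  invisible(x)
}

#' Run the full SIOS 2.0 workflow
#'
#' Executes the pipeline on one material: fit the slip from feeding
#' experiments, derive the maximum specific feed load, fit the autogenic
#' extruder parameters, and sweep operating-point predictions over the
#' requested screw speeds. Inputs may be in-memory tables or CSV paths in
#' the schemas of [read_feeding_csv()] and [read_autogenic_csv()].
#'
#' @param slip_data data frame (`n`, `max_mass_flow`) or CSV path
#' @param autogenic_data [extrusion_observations()] or CSV path
#' @param material a [material_properties()] or YAML path
#' @param geom an [extruder_geometry()] or YAML path
#' @param prediction_speeds screw speeds to predict, 1/s (strictly
#'   increasing)
#' @param min_speed autogenic fitting threshold, 1/s (default 100 rpm)
#' @param wr_correct apply the Weissenberg-Rabinowitsch correction?
#' @return an object of class `sios2_report`: a list with elements
#'   `material`, `slip`, `slip_slope`, `sfl_max`, `fit` (an
#'   [autogenic_fit()]), `predictions` (a `prediction_result` data frame)
#'   and `settings`
#' @export
run_sios2 <- function(slip_data, autogenic_data, material, geom,
                      prediction_speeds, min_speed = rpm_to_hz(100),
                      wr_correct = TRUE) {
  if (is.character(slip_data)) slip_data <- read_feeding_csv(slip_data)
  if (is.character(autogenic_data)) autogenic_data <- read_autogenic_csv(autogenic_data)
  if (is.character(material)) material <- read_material_yaml(material)
  if (is.character(geom)) geom <- read_geometry_yaml(geom)
  stopifnot(inherits(material, "material_properties"),
            inherits(geom, "extruder_geometry"))
  if (is.unsorted(prediction_speeds, strictly = TRUE)) {
    stop("prediction_speeds must be strictly increasing")
  }

  powder0 <- powder_from_material(material, slip = 0)
  slip <- tryCatch(fit_slip(slip_data, powder0, geom),
                   error = function(e) stop("slip fitting failed: ",
                                            conditionMessage(e), call. = FALSE))
  powder <- powder_from_material(material, slip = as.numeric(slip))
  sflmax <- sfl_max(powder, geom)

  n_low <- sum(autogenic_data$n < min_speed)
  if (n_low > 0) {
    message(sprintf("excluding %d observation(s) below the %.0f rpm threshold",
                    n_low, hz_to_rpm(min_speed)))
  }
  fit <- tryCatch(
    fit_autogenic(autogenic_data, geom, material, min_speed, wr_correct),
    error = function(e) stop("autogenic fitting failed: ",
                             conditionMessage(e), call. = FALSE))
  pred <- predict_operating_point(prediction_speeds, fit, material, geom,
                                  sflmax, wr_correct)

  structure(list(
    material = material$name,
    slip = as.numeric(slip),
    slip_slope = attr(slip, "slope"),
    sfl_max = sflmax,
    fit = fit,
    predictions = pred,
    settings = list(min_speed = min_speed, wr_correct = wr_correct,
                    n_slip_points = nrow(slip_data),
                    n_autogenic_points = nrow(autogenic_data),
                    n_excluded_low_speed = n_low)
  ), class = "sios2_report")
}

#' @export
print.sios2_report <- function(x, ...) {
  cat(sprintf("SIOS 2.0 report for %s\n", x$material))
  cat(sprintf("  slip    : %.4g   (from %d feeding point(s))\n",
              x$slip, x$settings$n_slip_points))
  cat(sprintf("  SFLmax  : %.4g\n", x$sfl_max))
  print(x$fit)
  cat("Predicted operating points:\n")
  tab <- data.frame(
    screw_speed_rpm = hz_to_rpm(x$predictions$n),
    mass_flow_kg_h = kg_s_to_kg_h(x$predictions$mass_flow),
    melt_temp_C = kelvin_to_celsius(x$predictions$melt_temperature))
  print(tab, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Serialize / restore a SIOS 2.0 report
#'
#' Writes the report to JSON (numbers at full precision) and reads it back
#' into an equivalent `sios2_report` object; `write_prediction_csv()` writes
#' the prediction table in operator units.
#'
#' @param report a `sios2_report` from [run_sios2()]
#' @param path file path
#' @return `write_sios2_report()` / `write_prediction_csv()`: the path,
#'   invisibly; `read_sios2_report()`: a `sios2_report`
#' @export
write_sios2_report <- function(report, path) {
  stopifnot(inherits(report, "sios2_report"))
  x <- unclass(report)
  x$fit <- unclass(x$fit)
  x$predictions <- as.data.frame(x$predictions)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_sios2_report
#' @export
read_sios2_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit <- x$fit
  x$fit <- autogenic_fit(fit$tau_extruder, fit$tau_sd, fit$s_extruder,
                         fit$i_extruder,
                         if (is.null(fit$r_correlation)) NA_real_ else fit$r_correlation,
                         as.integer(fit$n_points_used), fit$min_speed)
  x$predictions <- as.data.frame(x$predictions)
  class(x$predictions) <- c("prediction_result", "data.frame")
  structure(x, class = "sios2_report")
}

#' @rdname write_sios2_report
#' @export
write_prediction_csv <- function(report, path) {
  stopifnot(inherits(report, "sios2_report"))
  p <- report$predictions
  utils::write.csv(
    data.frame(screw_speed_rpm = hz_to_rpm(p$n),
               mass_flow_kg_h = kg_s_to_kg_h(p$mass_flow),
               eta_die_Pa_s = p$eta_die,
               eta_calculated_Pa_s = p$eta_calculated,
               melt_temp_C = kelvin_to_celsius(p$melt_temperature)),
    path, row.names = FALSE)
  invisible(path)
}

#' Crossover validation: predict one material from the others' fits
#'
#' Transfers extruder parameters fitted on donor materials to a target
#' material (arithmetic mean via [crossover_parameters()]) and compares the
#' predictions against the target's own measured table, point by point. The
#' mass-flow comparison uses the target's bulk density with the donor slip.
#'
#' @param donor_fits list of [autogenic_fit()] objects from other materials
#' @param donor_slip slip transferred from the donors (e.g. their mean)
#' @param target_obs measured [extrusion_observations()] of the target
#' @param target_material the target's [material_properties()]
#' @param geom an [extruder_geometry()]
#' @param wr_correct apply the WR correction? default TRUE
#' @return data frame with one row per target observation: screw speed,
#'   predicted and measured melt temperature (K), `delta_T` (predicted -
#'   measured, K), predicted and measured mass flow (kg/s) and
#'   `rel_delta_mass_flow`
#' @export
crossover_validation <- function(donor_fits, donor_slip, target_obs,
                                 target_material, geom, wr_correct = TRUE) {
  stopifnot(inherits(target_obs, "extrusion_observations"))
  fit <- crossover_parameters(donor_fits)
  powder <- powder_from_material(target_material, donor_slip)
  sflmax <- sfl_max(powder, geom)
  pred <- predict_operating_point(target_obs$n, fit, target_material, geom,
                                  sflmax, wr_correct)
  data.frame(
    n = target_obs$n,
    melt_temperature_pred = pred$melt_temperature,
    melt_temperature_meas = target_obs$melt_temperature,
    delta_T = pred$melt_temperature - target_obs$melt_temperature,
    mass_flow_pred = pred$mass_flow,
    mass_flow_meas = target_obs$mass_flow,
    rel_delta_mass_flow = (pred$mass_flow - target_obs$mass_flow) /
      target_obs$mass_flow
  )
}
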