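# Readers and writers for the package's file formats. Files carry the units
# customary at the extruder (rpm, degC, bar, kg/h); everything is converted
# to SI on the way in and back on the way out.

#' Read a material parameter file
#'
#' YAML file with keys `name` (optional), `eta0_Pa_s`, `gammadot_c_per_s`,
#' `c`, `Ea_J_per_mol`, `T_ref_K`, `rho_bulk_kg_m3`, `rho_true_kg_m3`.
#'
#' @param path file path
#' @return a [material_properties()]
#' @export
read_material_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("eta0_Pa_s", "gammadot_c_per_s", "c", "Ea_J_per_mol", "T_ref_K",
            "rho_bulk_kg_m3", "rho_true_kg_m3")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop("material file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "))
  }
  material_properties(
    name = if (!is.null(y$name)) y$name else tools::file_path_sans_ext(basename(path)),
    rho_bulk = y$rho_bulk_kg_m3, rho_true = y$rho_true_kg_m3,
    rheology = carreau_arrhenius(y$eta0_Pa_s, y$gammadot_c_per_s, y$c,
                                 y$Ea_J_per_mol, y$T_ref_K)
  )
}

#' Read an extruder geometry file
#'
#' YAML file with keys `d_m`, `A_free_m2`, `l_pitch_m`, `r_die_m`, `l_die_m`,
#' `n_max_rpm`.
#'
#' @param path file path
#' @return an [extruder_geometry()]
#' @export
read_geometry_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("d_m", "A_free_m2", "l_pitch_m", "r_die_m", "l_die_m", "n_max_rpm")
  missing <- setdiff(need, names(y))
  if (length(missing)) {
    stop("geometry file ", path, " is missing key(s): ",
         paste(missing, collapse = ", "))
  }
  extruder_geometry(d = y$d_m, A_free = y$A_free_m2, l_pitch = y$l_pitch_m,
                    r_die = y$r_die_m, l_die = y$l_die_m,
                    n_max = rpm_to_hz(y$n_max_rpm))
}

check_columns <- function(df, need, path) {
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  }
}

#' Read a flow-curve CSV
#'
#' Columns `shear_rate_per_s`, `temperature_C`, `viscosity_Pa_s`; returns SI
#' columns `shear_rate` (1/s), `temperature` (K), `viscosity` (Pa s) for
#' [fit_carreau_arrhenius()].
#'
#' @param path file path
#' @return data frame
#' @export
read_flow_curve_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("shear_rate_per_s", "temperature_C", "viscosity_Pa_s"), path)
  data.frame(shear_rate = df$shear_rate_per_s,
             temperature = celsius_to_kelvin(df$temperature_C),
             viscosity = df$viscosity_Pa_s)
}

#' Read a feeding-experiment CSV
#'
#' Columns `screw_speed_rpm`, `max_mass_flow_kg_h`; returns SI columns `n`
#' (1/s) and `max_mass_flow` (kg/s) for [fit_slip()].
#'
#' @param path file path
#' @return data frame
#' @export
read_feeding_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("screw_speed_rpm", "max_mass_flow_kg_h"), path)
  data.frame(n = rpm_to_hz(df$screw_speed_rpm),
             max_mass_flow = kg_h_to_kg_s(df$max_mass_flow_kg_h))
}

#' Read or write an autogenic-experiment CSV
#'
#' Columns `screw_speed_rpm`, `mass_flow_kg_h`, `melt_temp_C`,
#' `die_pressure_bar`. Simulated and measured tables share this schema, so
#' they are interchangeable downstream.
#'
#' @param path file path
#' @param obs an [extrusion_observations()] table (for writing)
#' @return `read_autogenic_csv()`: an [extrusion_observations()] table;
#'   `write_autogenic_csv()`: the path, invisibly
#' @export
read_autogenic_csv <- function(path) {
  df <- utils::read.csv(path)
  check_columns(df, c("screw_speed_rpm", "mass_flow_kg_h", "melt_temp_C",
                      "die_pressure_bar"), path)
  bad <- which(!stats::complete.cases(df))
  if (length(bad)) {
    stop("file ", path, " has incomplete row(s): ",
         paste(bad, collapse = ", "))
  }
  extrusion_observations(
    n = rpm_to_hz(df$screw_speed_rpm),
    mass_flow = kg_h_to_kg_s(df$mass_flow_kg_h),
    melt_temperature = celsius_to_kelvin(df$melt_temp_C),
    die_pressure = bar_to_pascal(df$die_pressure_bar)
  )
}

#' @rdname read_autogenic_csv
#' @export
write_autogenic_csv <- function(obs, path) {
  stopifnot(inherits(obs, "extrusion_observations"))
  utils::write.csv(
    data.frame(screw_speed_rpm = hz_to_rpm(obs$n),
               mass_flow_kg_h = kg_s_to_kg_h(obs$mass_flow),
               melt_temp_C = kelvin_to_celsius(obs$melt_temperature),
               die_pressure_bar = pascal_to_bar(obs$die_pressure)),
    path, row.names = FALSE)
  invisible(path)
}
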