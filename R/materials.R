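# Material parameter sets and the bundled reference extruder.

#' Material properties of a polymer powder and its melt
#'
#' Bundles the bulk and true density of the powder with the
#' Carreau-Arrhenius parameters of the melt.
#'
#' @param name material identifier
#' @param rho_bulk bulk (untapped) density, kg/m^3
#' @param rho_true true (pycnometric) density, kg/m^3
#' @param rheology a [carreau_arrhenius()] parameter set
#' @return an object of class `material_properties`
#' @export
material_properties <- function(name, rho_bulk, rho_true, rheology) {
  stopifnot(is.character(name), length(name) == 1L,
            inherits(rheology, "carreau_arrhenius"),
            rho_bulk > 0, rho_bulk <= rho_true)
  structure(list(name = name, rho_bulk = rho_bulk, rho_true = rho_true,
                 rheology = rheology),
            class = "material_properties")
}

#' @export
print.material_properties <- function(x, ...) {
  cat(sprintf("Material '%s': rho_bulk = %.4g kg/m^3, rho_true = %.4g kg/m^3\n",
              x$name, x$rho_bulk, x$rho_true))
  print(x$rheology)
  invisible(x)
}

#' Reference pharmaceutical extrusion polymers
#'
#' Material parameter sets for three polymers widely used as carriers for
#' amorphous solid dispersions: polyvinylpyrrolidone-vinyl acetate copolymer
#' (PVPVA, Plasdone S-630), polyvinyl caprolactam-polyvinyl
#' acetate-polyethylene glycol graft copolymer (SOL, Soluplus) and basic
#' butylated methacrylate copolymer (bBMA, Eudragit EPO). The
#' Carreau-Arrhenius parameters come from refits of published oscillatory
#' rheometry, all anchored at a 473 K reference temperature; densities are
#' pycnometric and untapped-bulk measurements.
#'
#' @return named list of [material_properties()] objects
#'   (`pvpva`, `sol`, `bbma`)
#' @examples
#' mats <- reference_polymers()
#' melt_viscosity(mats$pvpva$rheology, 0, 473)  # zero-shear viscosity
#' @export
reference_polymers <- function() {
  list(
    pvpva = material_properties(
      "PVPVA", rho_bulk = 315, rho_true = 1190,
      carreau_arrhenius(eta0 = 169.7, gammadot_c = 133.1, c = 0.387,
                        Ea = 198292, T_ref = 473)),
    sol = material_properties(
      "SOL", rho_bulk = 597, rho_true = 1080,
      carreau_arrhenius(eta0 = 147.3, gammadot_c = 136.7, c = 0.411,
                        Ea = 150773, T_ref = 473)),
    bbma = material_properties(
      "bBMA", rho_bulk = 339, rho_true = 1092,
      carreau_arrhenius(eta0 = 25.58, gammadot_c = 1688, c = 0.561,
                        Ea = 140336, T_ref = 473))
  )
}

#' Reference slip fractions of the bundled polymers
#'
#' Slip values determined from the filled-feeding-section condition
#' (SFL* = 1) at the backlog point on the 27 mm reference extruder. The
#' values are similar across the three polymers, indicating comparable
#' powder flow in the barrel.
#'
#' @return named numeric vector of slip fractions
#' @export
reference_slips <- function() {
  c(pvpva = 0.865, sol = 0.858, bbma = 0.850)
}

#' Bundled 27 mm corotating twin-screw reference geometry
#'
#' Geometry of a ZSE 27 class corotating twin-screw extruder: 28.3 mm screw
#' diameter, 4.91e-4 m^2 free cross-sectional area and a cylindrical die of
#' 3 mm diameter and 11.7 mm length. The feeding-section pitch defaults to
#' one screw diameter (square-pitched conveying elements) and the nominal
#' screw speed to 1200 rpm, both overridable.
#'
#' @param l_pitch feeding-section pitch, m
#' @param n_max nominal screw speed, 1/s
#' @return an [extruder_geometry()]
#' @export
zse27_geometry <- function(l_pitch = 0.0283, n_max = rpm_to_hz(1200)) {
  extruder_geometry(d = 0.0283, A_free = 4.91e-4, l_pitch = l_pitch,
                    r_die = 0.0015, l_die = 0.0117, n_max = n_max)
}

#' Powder state of a material at a given slip
#'
#' Convenience constructor combining a material's densities with a slip
#' fraction.
#'
#' @param material a [material_properties()]
#' @param slip slip fraction in \[0, 1)
#' @return a [powder_state()]
#' @export
powder_from_material <- function(material, slip) {
  stopifnot(inherits(material, "material_properties"))
  powder_state(material$rho_bulk, material$rho_true, slip)
}
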