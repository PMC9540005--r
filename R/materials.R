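# Material tables and per-element poroelastic property assignment.
#
# All tissues are treated as saturated biphasic (solid + fluid) continua.
# Elastic moduli are in MPa, permeability is stored in the source units of
# m^4/(N s) and converted once to mm^4/(N s) for the solver.  Tissue types
# whose modulus is a range (soft tissues maturing as their cell population
# matures) carry E_min/E_max; the mechano-regulation module interpolates
# within the range using the matching normalized cell density.

#' Default tissue/material property table
#'
#' @return a data.frame keyed by tissue name with elastic modulus range
#'   (MPa), permeability (m^4/Ns), Poisson ratio, initial porosity, solid
#'   and fluid bulk moduli (MPa) and a representative apparent density
#'   (g/cm^3) used for the strain-energy-density stimulus.
#' @export
default_material_table <- function() {
  data.frame(
    tissue = c("cortical", "marrow", "granulation", "fibrous", "cartilage",
               "immature", "intermediate", "mature", "titanium"),
    E_min = c(17000, 0.0247, 0.001, 0.2, 5, 500, 1000, 2000, 110000),
    E_max = c(17000, 0.0247, 2, 5, 500, 1000, 2000, 6000, 110000),
    permeability = c(1e-17, 1e-14, 1e-14, 1e-14, 5e-15, 1e-13, 3.7e-13,
                     3.7e-13, 1e-18),
    nu = c(0.37, 0.167, 0.167, 0.167, 0.167, 0.3, 0.3, 0.3, 0.3),
    porosity = c(0.04, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.01),
    Ks = c(2300, 2300, 2300, 2300, 2300, 2300, 2300, 2300, 1e5),
    Kf = c(2300, 2300, 2300, 2300, 13920, 13920, 13920, 13920, 1e5),
    rho = c(1.649, 1.0, 1.0, 1.0, 1.0, 1.0, 1.2, 1.4, 4.5),
    stringsAsFactors = FALSE
  )
}

# mesh region -> tissue row used at t = 0 (callus starts as granulation)
REGION_TISSUE <- c(cortex = "cortical", marrow = "marrow",
                   inner_callus = "granulation", callus_focus = "granulation",
                   outer_callus = "granulation", plate = "titanium")

#' Construct per-element poroelastic materials
#'
#' @param E,nu,permeability,porosity,Ks,Kf,rho vectors (recycled) of
#'   elastic modulus (MPa), Poisson ratio, permeability in mm^4/(N s),
#'   porosity, solid/fluid bulk moduli (MPa) and apparent density (g/cm^3).
#' @param n number of elements.
#' @return object of class `poro_materials` (a data.frame).
#' @export
poro_materials <- function(E, nu, permeability, porosity, Ks, Kf, rho,
                           n = length(E)) {
  out <- data.frame(E = rep_len(E, n), nu = rep_len(nu, n),
                    permeability = rep_len(permeability, n),
                    porosity = rep_len(porosity, n), Ks = rep_len(Ks, n),
                    Kf = rep_len(Kf, n), rho = rep_len(rho, n))
  if (any(out$E <= 0)) stopf("elastic modulus must be positive")
  if (any(out$nu <= -1 | out$nu >= 0.5)) {
    stopf("Poisson ratio must lie in (-1, 0.5)")
  }
  if (any(out$porosity < 0 | out$porosity > 1)) {
    stopf("porosity (fluid volume fraction) must lie in [0, 1]")
  }
  if (any(out$permeability <= 0 & out$nu >= 0.499)) {
    stopf("non-physical material: incompressible with zero permeability")
  }
  class(out) <- c("poro_materials", "data.frame")
  out
}

#' Assign region materials to every element of a mesh
#'
#' Every element receives the properties of the tissue its region carries
#' at the start of a simulation (callus zones start as granulation tissue;
#' range-valued moduli start at their minimum, i.e. zero cell maturation,
#' except granulation tissue which uses the fixed early-callus modulus
#' `E_gran`).
#'
#' @param mesh a `mesh_model`.
#' @param material_table defaults to [default_material_table()].
#' @param E_gran granulation-tissue modulus (MPa) used for fresh callus;
#'   must lie within the tabulated granulation range.
#' @return a `poro_materials` data.frame with one row per element.
#' @export
assign_region_materials <- function(mesh, material_table = default_material_table(),
                                    E_gran = 0.3) {
  tis <- REGION_TISSUE[mesh$region]
  if (anyNA(tis)) {
    bad <- unique(mesh$region[is.na(tis)])
    stopf("no material entry for region '%s'", bad[1L])
  }
  idx <- match(tis, material_table$tissue)
  if (anyNA(idx)) {
    stopf("material table is missing tissue '%s'", tis[which(is.na(idx))[1L]])
  }
  tab <- material_table[idx, ]
  E <- tab$E_min
  E[tis == "granulation"] <- E_gran
  E[mesh$region == "plate"] <- mesh$spec$plate_modulus %||% tab$E_max[1L]
  poro_materials(E = E, nu = tab$nu,
                 permeability = tab$permeability * PERM_M4NS_TO_MM4NS,
                 porosity = tab$porosity, Ks = tab$Ks, Kf = tab$Kf,
                 rho = tab$rho)
}
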