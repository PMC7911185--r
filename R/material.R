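#' HU-density-elasticity-strength material mapping
#'
#' Vertebral bone is modelled as a continuum whose local mechanical
#' properties follow the CT attenuation (HU) through a chain of published
#' empirical relations: apparent density from HU, ash density as a fixed
#' fraction of apparent density, a transversely isotropic elastic card from
#' apparent density (the stiff axis being the cranio-caudal z direction),
#' and strength limits plus a post-yield plastic strain capacity from ash
#' density.
#'
#' Units: densities are computed in kg/m^3; the strength and plastic-strain
#' laws consume ash density in g/cm^3 (the regression coefficients and the
#' 0.317 branch point are only dimensionally sensible in that unit, which is
#' the convention of the source cadaver literature), so [material_cards()]
#' divides by 1000 when bridging. Moduli and strengths are in MPa; with
#' lengths in mm this makes finite-element reaction forces come out in N.
#'
#' The affine density and modulus laws go negative for very low HU (air or
#' fat inside coarse elements), so they are clamped below: apparent density
#' at a tiny positive `rho_app_min` (1 kg/m^3, keeping the strength power
#' laws defined), the axial modulus at `e_floor` (0.01 MPa) and the plastic
#' strain at 0. Clamping keeps every element stiffness positive definite
#' while leaving the printed relations exact over the whole physiological
#' range (the density law itself only goes negative below -42 HU).
#'
#' @param hu Hounsfield units (numeric vector).
#' @param rho_app Apparent density in kg/m^3.
#' @param rho_ash Ash density in g/cm^3 (note the unit).
#' @param rho_app_min,e_floor,eps_floor Lower clamps (kg/m^3, MPa, unitless).
#' @name material_mapping
NULL

# fixed anisotropy constants (transverse isotropy about z)
.nu_xy <- 0.381
.nu_xz <- 0.104
.ex_ratio <- 0.333
.gxy_ratio <- 0.121
.gxz_ratio <- 0.157
.sigma_branch <- 0.317  # g/cm^3

#' @rdname material_mapping
#' @return `apparent_density()`: apparent density in kg/m^3.
#' @export
#' @examples
#' apparent_density(0)     # 47 kg/m^3
#' apparent_density(1000)  # 1169 kg/m^3
apparent_density <- function(hu, rho_app_min = 1) {
  if (any(!is.finite(hu))) abort("HU must be finite", class = "vertefail_material_error")
  pmax(47 + 1.122 * hu, rho_app_min)
}

#' @rdname material_mapping
#' @return `ash_density()`: ash density in kg/m^3 (60% of apparent density).
#' @export
ash_density <- function(rho_app) {
  if (any(rho_app < 0)) abort("apparent density must be >= 0",
                              class = "vertefail_material_error")
  0.6 * rho_app
}

#' @rdname material_mapping
#' @return `elastic_card()`: a tibble with axial modulus `E_z` (MPa, affine in
#'   apparent density, clamped at `e_floor`), transverse moduli
#'   `E_x = E_y = 0.333 E_z`, shear moduli `G_xy = 0.121 E_z`,
#'   `G_xz = G_yz = 0.157 E_z`, and Poisson ratios `nu_xy = 0.381`,
#'   `nu_xz = nu_yz = 0.104`.
#' @export
elastic_card <- function(rho_app, e_floor = 0.01) {
  if (any(rho_app < 0)) abort("apparent density must be >= 0",
                              class = "vertefail_material_error")
  E_z <- pmax(-349 + 5.82 * rho_app, e_floor)
  tibble(
    E_z = E_z, E_x = .ex_ratio * E_z, E_y = .ex_ratio * E_z,
    G_xy = .gxy_ratio * E_z, G_xz = .gxz_ratio * E_z, G_yz = .gxz_ratio * E_z,
    nu_xy = .nu_xy, nu_xz = .nu_xz, nu_yz = .nu_xz
  )
}

#' @rdname material_mapping
#' @return `strength_limits()`: a tibble with the maximum principal stress
#'   limit `sigma` (tension, piecewise power law switching branch at
#'   0.317 g/cm^3), the minimum principal stress limit `sigma_min`
#'   (compression) and the post-yield plastic strain capacity `eps_ab`
#'   (clamped below at `eps_floor`).
#' @export
strength_limits <- function(rho_ash, eps_floor = 0) {
  if (any(!is.finite(rho_ash)) || any(rho_ash <= 0)) {
    abort("ash density must be positive (in g/cm^3)",
          class = "vertefail_material_error")
  }
  sigma <- ifelse(rho_ash < .sigma_branch,
                  137 * rho_ash^1.88,
                  114 * rho_ash^1.72)
  tibble(
    sigma = sigma,
    sigma_min = 65.1 * rho_ash^1.93,
    eps_ab = pmax(-0.00315 + 0.0728 * rho_ash, eps_floor)
  )
}

#' Gap between the two tension-strength branches at the switch point
#'
#' The two power-law branches are independent fits that nearly meet at
#' 0.317 g/cm^3; this reports the discontinuity there.
#'
#' @return A list with the low- and high-branch values (MPa), their absolute
#'   gap and the gap relative to the branch mean.
#' @export
sigma_branch_gap <- function() {
  low <- 137 * .sigma_branch^1.88
  high <- 114 * .sigma_branch^1.72
  list(low = low, high = high, gap = abs(high - low),
       relative = abs(high - low) / mean(c(low, high)))
}

#' Per-element material cards for a mesh
#'
#' Chains the HU-density-elasticity-strength relations for every element of
#' a finite-element mesh, using the element mean HU assigned during meshing.
#' The cortical shell is treated with the same relations as trabecular bone
#' (it is modelled as denser trabecular bone, not as a separate phase).
#'
#' @param mesh A [build_mesh()] result.
#' @param rho_app_min,e_floor,eps_floor Clamps, see [material_mapping].
#' @return A tibble with one row per element: `element`, `hu`, `rho_app`
#'   (kg/m^3), `rho_ash` (g/cm^3), the elastic card and the strength limits.
#' @export
material_cards <- function(mesh, rho_app_min = 1, e_floor = 0.01, eps_floor = 0) {
  stopifnot(inherits(mesh, "vertefail_mesh"))
  hu <- mesh$element_hu
  rho_app <- apparent_density(hu, rho_app_min = rho_app_min)
  rho_ash_gcc <- ash_density(rho_app) / 1000  # kg/m^3 -> g/cm^3
  dplyr::bind_cols(
    tibble(element = seq_along(hu), hu = hu, rho_app = rho_app,
           rho_ash = rho_ash_gcc),
    elastic_card(rho_app, e_floor = e_floor),
    strength_limits(rho_ash_gcc, eps_floor = eps_floor)
  )
}

#' Elasticity (stiffness) matrix of a material card
#'
#' Builds the 6x6 elasticity matrix in Voigt order
#' (xx, yy, zz, yz, xz, xy; engineering shear strains) by inverting the
#' orthotropic compliance assembled from the card's moduli and Poisson
#' ratios.
#'
#' @param card A one-row data frame (or list) with `E_x`, `E_y`, `E_z`,
#'   `G_xy`, `G_xz`, `G_yz`, `nu_xy`, `nu_xz`, `nu_yz`.
#' @return A 6x6 symmetric positive-definite matrix (MPa).
#' @export
elasticity_matrix <- function(card) {
  S <- matrix(0, 6, 6)
  S[1, 1] <- 1 / card$E_x
  S[2, 2] <- 1 / card$E_y
  S[3, 3] <- 1 / card$E_z
  S[1, 2] <- S[2, 1] <- -card$nu_xy / card$E_x
  S[1, 3] <- S[3, 1] <- -card$nu_xz / card$E_x
  S[2, 3] <- S[3, 2] <- -card$nu_yz / card$E_y
  S[4, 4] <- 1 / card$G_yz
  S[5, 5] <- 1 / card$G_xz
  S[6, 6] <- 1 / card$G_xy
  solve(S)
}

# Unit elasticity matrix: elasticity_matrix for E_z = 1 with the fixed
# anisotropy ratios. Every pipeline card's matrix is E_z times this, which
# lets the solver assemble all elements from one reference stiffness.
unit_elasticity_matrix <- function() {
  elasticity_matrix(elastic_card(rho_app = (1 + 349) / 5.82)[1, ])
}
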