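#' Physical constants for 15N relaxation calculations
#'
#' Returns the constant set used throughout the relaxation module: SI
#' gyromagnetic ratios, the N-H bond length, the axially symmetric 15N
#' chemical-shift anisotropy, and vacuum permeability / Planck constants.
#' The defaults are fixed at the values used for the mBS analysis:
#' `r_NH = 1.02` angstrom and `delta_sigma = -160` ppm.  `gamma_N` is
#' negative; the sign is kept explicit so that heteronuclear NOE values
#' below 1 are representable.
#'
#' @param r_NH_A N-H bond length in angstrom.
#' @param delta_sigma_ppm 15N CSA in ppm (axially symmetric tensor).
#' @param theta_deg angle between the N-H dipole vector and the unique CSA
#'   axis, used only for the cross-correlated rates eta_xy / eta_zz.
#' @return A list of class `"nmr_constants"` with elements `gamma_H`,
#'   `gamma_N` (rad s^-1 T^-1), `r_NH` (m), `delta_sigma` (dimensionless),
#'   `theta` (rad), `mu0`, `hbar`, and the gas constant `R_kcal`
#'   (kcal mol^-1 K^-1).
#' @export
nmr_constants <- function(r_NH_A = 1.02, delta_sigma_ppm = -160,
                          theta_deg = 17) {
  structure(list(
    gamma_H = 2.6752218744e8,
    gamma_N = -2.7126180800e7,
    r_NH = r_NH_A * 1e-10,
    delta_sigma = delta_sigma_ppm * 1e-6,
    theta = theta_deg * pi / 180,
    mu0 = 4 * pi * 1e-7,
    hbar = 1.054571817e-34,
    R_kcal = 1.987e-3
  ), class = "nmr_constants")
}

# gas constant in kcal/(mol K); used by hx_kinetics and denaturation
.RGAS <- 1.987e-3

#' Dipolar and CSA interaction constants
#'
#' `d` is the N-H dipolar coupling constant
#' \eqn{d = \mu_0 \hbar \gamma_H \gamma_N / (4 \pi r_{NH}^3)} and
#' `c` the CSA constant \eqn{c = \omega_N \Delta\sigma / \sqrt{3}}, both in
#' rad/s, for a spectrometer with the given proton Larmor frequency.
#'
#' @param field_MHz proton Larmor frequency in MHz.
#' @param constants an [nmr_constants()] list.
#' @return list with `d`, `c`, `omega_H`, `omega_N` (rad/s; `omega_N < 0`
#'   because `gamma_N < 0`; spectral densities are evaluated at `|omega|`).
#' @keywords internal
interaction_constants <- function(field_MHz, constants = nmr_constants()) {
  omega_H <- 2 * pi * field_MHz * 1e6
  omega_N <- omega_H * constants$gamma_N / constants$gamma_H
  d <- constants$mu0 * constants$hbar * constants$gamma_H * constants$gamma_N /
    (4 * pi * constants$r_NH^3)
  cc <- abs(omega_N) * constants$delta_sigma / sqrt(3)
  list(d = d, c = cc, omega_H = omega_H, omega_N = omega_N)
}

# van der Waals radii (angstrom) for surface and depth calculations;
# Bondi-style values, hydrogens explicit
.VDW_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)

#' Look up van der Waals radii by element
#'
#' @param element character vector of element symbols.
#' @param default radius used for elements not in the shipped table.
#' @return numeric vector of radii in angstrom.
#' @export
vdw_radius <- function(element, default = 1.7) {
  r <- .VDW_RADII[toupper(element)]
  r[is.na(r)] <- default
  unname(r)
}
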