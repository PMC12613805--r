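## ---- Interfacial distribution of adsorbed NOM and adsorption volume ------

#' Excess (d-plane) fraction of adsorbed NOM
#'
#' Fraction of adsorbed particles residing beyond the Stern layers:
#' `f_d = (Gamma_tot - Gamma_MST) / Gamma_tot` when the total loading exceeds
#' the attainable Stern-layer maximum, and 0 otherwise. Continuous at
#' `Gamma_tot = Gamma_MST` and non-decreasing in `Gamma_tot`.
#'
#' @param Gamma_tot Total adsorbed amount, mg/m2 (vectorized).
#' @param Gamma_MST Attainable Stern-layer maximum, mg/m2.
#' @return `f_d` in `[0, 1]`.
#' @export
excess_fraction <- function(Gamma_tot, Gamma_MST) {
  if (any(Gamma_tot < 0) || any(Gamma_MST < 0)) {
    stop_validation("adsorbed amounts must be non-negative")
  }
  ifelse(Gamma_tot > Gamma_MST & Gamma_tot > 0,
         (Gamma_tot - Gamma_MST) / Gamma_tot, 0)
}

#' Adsorption volume of a mixed HA/FA layer
#'
#' Volume of the adsorbed phase under the variable-volume scenario: the
#' weighted sum `V = sum(omega_i * V_i)` of the single-component limiting
#' volumes, with weights equal to the relative presence of each component in
#' the adsorbed phase.
#'
#' @param omega Relative adsorbed fractions per component (must sum to 1).
#' @param V_i Single-component limiting volumes, m3/m2.
#' @return The mixture adsorption volume, m3/m2.
#' @export
#' @examples
#' mixing_volume(c(0.5, 0.5), c(3e-9, 0.8e-9))
mixing_volume <- function(omega, V_i) {
  if (length(omega) != length(V_i)) {
    stop_validation("omega and V_i must have equal length")
  }
  if (any(omega < -1e-12) || abs(sum(omega) - 1) > 1e-8) {
    stop_validation("omega must be non-negative and sum to 1")
  }
  sum(omega * V_i)
}

#' Volume fraction of an adsorbed component
#'
#' `phi_ads = Gamma / (V * rho_p)`; reaches 1 when the component completely
#' fills the adsorbed phase.
#'
#' @param Gamma_p Adsorbed mass, kg/m2.
#' @param V Adsorption volume, m3/m2.
#' @param rho_p Particle mass density, kg/m3.
#' @param tolerance Infeasibility slack on `phi > 1`.
#' @return Volume fraction in `[0, 1]`.
#' @export
volume_fraction_adsorbed <- function(Gamma_p, V, rho_p, tolerance = 1e-9) {
  if (any(V <= 0) || any(rho_p <= 0)) {
    stop_validation("V and rho_p must be positive")
  }
  if (any(Gamma_p < 0)) stop_validation("Gamma_p must be non-negative")
  phi <- Gamma_p / (V * rho_p)
  if (any(phi > 1 + tolerance)) {
    stop_validation("adsorbed mass exceeds the available adsorption volume")
  }
  pmin(phi, 1)
}

#' Volume fraction of a dissolved component
#'
#' `phi_sol = C_p / rho_p`.
#'
#' @param C_p Mass concentration in solution, kg/m3.
#' @param rho_p Particle mass density, kg/m3.
#' @return Volume fraction (m3/m3).
#' @export
volume_fraction_solution <- function(C_p, rho_p) {
  if (any(rho_p <= 0)) stop_validation("rho_p must be positive")
  if (any(C_p < 0)) stop_validation("C_p must be non-negative")
  C_p / rho_p
}

#' Regulate the interfacial distribution from the potential profile
#'
#' The attainable Stern occupation `theta_s` and the first-Stern fraction `R`
#' of adsorbed NOM respond to the electrostatic potential gradients within
#' the compact part of the double layer. The default regulator is a pair of
#' logistic functions of the two Stern potential drops (scaled by RT/F): at a
#' flat profile it returns the neutral point `(theta_s, R) = (1, 0.5)`; `R`
#' increases monotonically with the inner-layer drop `psi0 - psi1` (which
#' attracts the negatively charged functional groups toward the surface) and
#' `theta_s` decreases below 1 only when the outer-layer gradient turns
#' repulsive. A custom regulator `function(psi_planes) -> list(theta_s, R)`
#' can be plugged in via the `regulator` argument.
#'
#' @param plane_potentials Potentials at planes 0, 1, 2, d (V).
#' @param steepness_R,steepness_theta Dimensionless steepness of the two
#'   logistic responses.
#' @param temperature_K Temperature, K.
#' @param regulator Optional replacement function.
#' @return A list with `theta_s` and `R`, both in `[0, 1]`.
#' @export
#' @examples
#' regulate_distribution(c(0, 0, 0, 0)) # neutral point: theta_s 1, R 0.5
regulate_distribution <- function(plane_potentials, steepness_R = 1,
                                  steepness_theta = 1, temperature_K = 295.15,
                                  regulator = NULL) {
  if (length(plane_potentials) < 3 || any(!is.finite(plane_potentials))) {
    stop_validation("plane_potentials must be a finite potential profile")
  }
  if (is.function(regulator)) {
    out <- regulator(plane_potentials)
    out$theta_s <- min(max(out$theta_s, 0), 1)
    out$R <- min(max(out$R, 0), 1)
    return(out)
  }
  f_rt <- .FARADAY / (.RGAS * temperature_K)
  x_R <- steepness_R * f_rt * (plane_potentials[1] - plane_potentials[2])
  x_t <- steepness_theta * f_rt * (plane_potentials[2] - plane_potentials[3])
  list(
    theta_s = min(1, 2 * plogis(x_t)),
    R = plogis(x_R)
  )
}

#' Assemble an interfacial distribution
#'
#' Splits a component's adsorbed amount over the Stern layers and the
#' d-plane: the d-plane takes the excess over the attainable Stern maximum
#' `theta_s * Gamma_MST_max` ([excess_fraction()]), and the Stern-resident
#' remainder is divided between the first (0+1) and second (1+2) plane pair
#' by the first-Stern fraction `R`.
#'
#' @param Gamma_tot Total adsorbed amount, mg/m2.
#' @param Gamma_MST_max Physical Stern maximum, mg/m2.
#' @param theta_s Relative attainable Stern occupation in `[0, 1]`.
#' @param R First-Stern fraction in `[0, 1]`.
#' @return A list of class `interfacial_distribution` with fields `f_0plus1`,
#'   `f_1plus2`, `f_d` (summing to 1), `Gamma_tot`, `Gamma_MST`,
#'   `Gamma_MST_max`, `theta_s`, `R`.
#' @export
interfacial_distribution <- function(Gamma_tot, Gamma_MST_max, theta_s, R) {
  if (theta_s < 0 || theta_s > 1 || R < 0 || R > 1) {
    stop_validation("theta_s and R must lie in [0, 1]")
  }
  Gamma_MST <- theta_s * Gamma_MST_max
  f_d <- excess_fraction(Gamma_tot, Gamma_MST)
  structure(list(
    f_0plus1 = R * (1 - f_d),
    f_1plus2 = (1 - R) * (1 - f_d),
    f_d = f_d,
    Gamma_tot = Gamma_tot,
    Gamma_MST = Gamma_MST,
    Gamma_MST_max = Gamma_MST_max,
    theta_s = theta_s,
    R = R
  ), class = "interfacial_distribution")
}
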