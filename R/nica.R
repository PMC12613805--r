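#' NICA proton occupancy of a heterogeneous ligand distribution
#'
#' Monocomponent NICA isotherm for proton binding to one affinity
#' distribution: `theta = (K a)^m / (1 + (K a)^m)`, with `K = 10^logK_tilde_H`
#' the median affinity and `m` in (0, 1] the width of the affinity
#' distribution (`m = 1` is the homogeneous Langmuir limit).
#'
#' @param a_H_local Local proton activity (bulk activity times the Boltzmann
#'   factor of the plane where the group resides). Vectorized.
#' @param logK_tilde_H log10 median proton affinity.
#' @param m Width exponent in (0, 1].
#' @return Occupancy in `[0, 1]`, strictly increasing in `a_H_local`.
#' @export
#' @examples
#' proton_occupancy(10^-4, logK_tilde_H = 4, m = 1) # midpoint: 0.5
proton_occupancy <- function(a_H_local, logK_tilde_H, m) {
  if (any(!is.finite(a_H_local)) || any(a_H_local <= 0)) {
    stop_validation("proton activity must be positive and finite")
  }
  if (m <= 0 || m > 1) stop_validation("NICA width exponent m must be in (0, 1]")
  ## log-space for numerical range safety
  t <- exp(m * (logK_tilde_H * log(10) + log(a_H_local)))
  t / (1 + t)
}

## Net charge (mol_c per kg, negative) of one NOM component's bimodal ligand
## distribution at a given local proton activity.
nica_charge_at <- function(a_H_local, nica) {
  th1 <- proton_occupancy(a_H_local, nica$logK1, nica$m1)
  th2 <- proton_occupancy(a_H_local, nica$logK2, nica$m2)
  -(nica$Qmax1_mol_kg * (1 - th1) + nica$Qmax2_mol_kg * (1 - th2))
}

## Plane weights (0, 1, 2, d) implied by an interfacial distribution.
## Groups in f_0+1 split their charge between the 0- and 1-plane, f_1+2
## between the 1- and 2-plane (split fraction to the first plane of the pair
## is configurable), f_d sits wholly at the d-plane.
plane_weights <- function(distribution, split = 0.5) {
  f <- c(distribution$f_0plus1, distribution$f_1plus2, distribution$f_d)
  if (any(f < -1e-12) || abs(sum(f) - 1) > 1e-8) {
    stop_validation("interfacial fractions must be non-negative and sum to 1")
  }
  c(f[1] * split, f[1] * (1 - split) + f[2] * split, f[2] * (1 - split), f[3])
}

## Per-plane NOM charge densities (mol_c per kg at planes 0,1,2,d) for one
## component, given the potential at each plane.
nom_plane_charge <- function(pH, psi_planes, distribution, nica,
                             temperature_K, split = 0.5) {
  w <- plane_weights(distribution, split)
  a_bulk <- 10^(-pH)
  f_rt <- .FARADAY / (.RGAS * temperature_K)
  a_local <- a_bulk * exp(-f_rt * psi_planes)
  vapply(seq_along(w), function(i) {
    if (w[i] == 0) 0 else w[i] * nica_charge_at(a_local[i], nica)
  }, numeric(1))
}

#' Net proton charge of a NOM component
#'
#' Total net charge (mol_c per kg, negative above the fully protonated limit)
#' of the bimodal carboxylic/phenolic NICA site distribution of an HA or FA
#' component. For adsorbed particles the functional groups experience the
#' local proton activity `a_H * exp(-F psi / RT)` of the electrostatic plane
#' they occupy, weighted by the interfacial distribution; for particles in
#' solution the bulk activity applies.
#'
#' @param pH Solution pH.
#' @param plane_potentials Potentials (V) at planes 0, 1, 2 and d. Ignored
#'   when `distribution = "solution"`.
#' @param distribution Either the string `"solution"` or a list with fields
#'   `f_0plus1`, `f_1plus2`, `f_d` summing to 1 (see
#'   [interfacial_distribution()]).
#' @param component A NOM component configuration (e.g. `lcd_config()$nom$FA`).
#' @param temperature_K Temperature, K.
#' @param split Fraction of a plane pair's charge assigned to its first plane.
#' @return Net charge in mol_c per kg.
#' @export
#' @examples
#' nom_charge_density(4, distribution = "solution",
#'                    component = lcd_config()$nom$FA)
nom_charge_density <- function(pH, plane_potentials = c(0, 0, 0, 0),
                               distribution = "solution", component,
                               temperature_K = 295.15, split = 0.5) {
  if (identical(distribution, "solution")) {
    return(nica_charge_at(10^(-pH), component$nica))
  }
  sum(nom_plane_charge(pH, plane_potentials, distribution, component$nica,
                       temperature_K, split))
}
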