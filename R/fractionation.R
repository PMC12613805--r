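## ---- Adsorptive molecular-mass fractionation ------------------------------
##
## HA is polydisperse; particles of lower molar mass are preferentially
## adsorbed, so the mean molar mass of the adsorbed pool rises from M_o (the
## most preferred particles) toward the original-material mean as the
## adsorbed fraction grows. FA shows no significant fractionation
## (k ~ 0), so its adsorbed molar mass stays at the original 1.8 kDa.

#' Mean molar mass of adsorbed HA
#'
#' Empirical fractionation relation
#' `M_w = M_o + k * (1 - ssr * C_HA / HA_tot)`, where `ssr * C_HA / HA_tot`
#' is the fraction of added HA remaining in solution. At zero adsorption the
#' relation returns `M_o` (1.6 kDa by default); when everything is adsorbed
#' it returns `M_o + k`, the original-material mean (17 kDa under the default
#' closure `k = 15.4`). The result is clamped to `[M_o, M_o + k]`.
#'
#' @param C_HA HA concentration left in solution, mg/L (vectorized).
#' @param HA_tot Total HA added per unit solid, mg/g.
#' @param ssr Solution-to-solid ratio, L/g.
#' @param M_o Molar mass of the most preferred particles, kDa.
#' @param k Fractionation factor, kDa.
#' @return Mean molar mass of the adsorbed HA, kDa.
#' @export
#' @examples
#' mw_adsorbed_ha(C_HA = 0, HA_tot = 160) # fully adsorbed: 17 kDa
mw_adsorbed_ha <- function(C_HA, HA_tot, ssr = 1.0, M_o = 1.6, k = 15.4) {
  if (any(C_HA < 0) || any(HA_tot <= 0) || ssr <= 0) {
    stop_validation("C_HA must be non-negative, HA_tot and ssr positive")
  }
  frac_sol <- ssr * C_HA / HA_tot
  if (any(frac_sol > 1 + 1e-9)) {
    stop_validation("ssr * C_HA exceeds HA_tot (negative adsorption)")
  }
  pmin(pmax(M_o + k * (1 - frac_sol), M_o), M_o + k)
}

#' Mean molar mass of an adsorbed HA/FA mixture
#'
#' Mass-fraction weighted mean
#' `M_w_mix = M_w_HA * phi_HA + M_w_FA * (1 - phi_HA)`.
#'
#' @param M_w_HA,M_w_FA Mean molar masses of the adsorbed components, kDa.
#' @param phi_frac_HA Adsorbed HA mass fraction of the total adsorbed NOM.
#' @return Mixture mean molar mass, kDa.
#' @export
mw_mixture <- function(M_w_HA, M_w_FA, phi_frac_HA) {
  if (any(phi_frac_HA < 0) || any(phi_frac_HA > 1)) {
    stop_validation("phi_frac_HA must lie in [0, 1]")
  }
  M_w_HA * phi_frac_HA + M_w_FA * (1 - phi_frac_HA)
}

#' Invert the mixture molar mass for the adsorbed HA
#'
#' Exact algebraic inverse of [mw_mixture()]: given a measured mixture mean
#' molar mass and the adsorbed HA mass fraction, recovers the mean molar mass
#' of the adsorbed HA, with the adsorbed-FA molar mass held at the
#' original-FA value.
#'
#' @param M_w_mix Mixture mean molar mass, kDa.
#' @param phi_frac_HA Adsorbed HA mass fraction (> 0).
#' @param M_w_FA Adsorbed FA molar mass, kDa.
#' @return Mean molar mass of adsorbed HA, kDa.
#' @export
invert_mw_ha <- function(M_w_mix, phi_frac_HA, M_w_FA = 1.8) {
  if (any(phi_frac_HA <= 0)) {
    stop_validation("phi_frac_HA must be positive (HA molar mass undetermined)")
  }
  if (any(phi_frac_HA > 1)) stop_validation("phi_frac_HA must lie in (0, 1]")
  (M_w_mix - M_w_FA * (1 - phi_frac_HA)) / phi_frac_HA
}
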