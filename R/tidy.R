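## ---- broom-style accessors --------------------------------------------------

#' Tidy a coupled LCD state into a per-component tibble
#'
#' @param x An `lcd_state` from [lcd_solve()].
#' @param ... Unused.
#' @return One row per NOM component: adsorbed and dissolved amounts, volume
#'   fractions, interfacial fractions, molar mass and log affinity.
#' @method tidy lcd_state
#' @export
tidy.lcd_state <- function(x, ...) {
  purrr::map_dfr(c("HA", "FA"), function(cc) {
    d <- x$distribution[[cc]]
    tibble::tibble(
      component = cc,
      added_mg_L = if (cc == "HA") x$system$HA_tot_mg_L else x$system$FA_tot_mg_L,
      Gamma_ads_mg_m2 = x$partition$Gamma_mg_m2[[cc]],
      C_sol_mg_L = x$partition$C_mg_L[[cc]],
      phi_ads = x$partition$phi_ads[[cc]],
      phi_sol = x$partition$phi_sol[[cc]],
      f_0plus1 = d$f_0plus1, f_1plus2 = d$f_1plus2, f_d = d$f_d,
      M_w_kDa = x$M_w_kDa[[cc]],
      ln_K_tilde = x$affinity[[cc]]$ln_K_tilde
    )
  })
}

#' One-row summary of a coupled LCD state
#'
#' @inheritParams tidy.lcd_state
#' @return A one-row tibble with the solution conditions, adsorption volume,
#'   regulator outputs, plane potentials and solver diagnostics.
#' @method glance lcd_state
#' @export
glance.lcd_state <- function(x, ...) {
  tibble::tibble(
    pH = x$system$pH,
    ionic_strength_M = x$system$ionic_strength_M,
    scenario = x$scenario,
    mode = x$mode,
    V_m3_m2 = x$V_m3_m2,
    theta_s = x$theta_s,
    R = x$R,
    psi0_V = unname(x$surface$psi["psi0"]),
    psi1_V = unname(x$surface$psi["psi1"]),
    psi2_V = unname(x$surface$psi["psi2"]),
    net_surface_charge_C_m2 = x$surface$net_surface_charge,
    max_residual = max(abs(x$residuals)),
    iterations = x$iterations,
    converged = x$converged
  )
}
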