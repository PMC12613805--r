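## ---- Competitive Langmuir-Freundlich partition and the coupled solve ------
##
## Units are strictly SI internally (kg, m, mol); mg/L and mg/m2 appear only
## at the I/O boundary. Volume fractions: phi_sol = C_p / rho_p (C_p in
## kg/m3), phi_ads = Gamma_p / (V rho_p) (Gamma_p in kg/m2, V in m3/m2).

planes_from_psi <- function(psi, topology) {
  if (topology == "extended") c(psi[1], psi[2], psi[3], psi[3])
  else c(psi[1], psi[2], psi[2], psi[2])
}

#' System composition of a batch adsorption experiment
#'
#' @param HA_tot_mg_L,FA_tot_mg_L Total added concentrations, mg/L.
#' @param pH Suspension pH.
#' @param solid_g_L Goethite concentration, g/L.
#' @param ionic_strength_M Background 1:1 electrolyte, mol/L.
#' @param area_m2_g Specific surface area, m2/g.
#' @return A `system_composition` list with the derived surface area per
#'   litre (`A_m2_L`) and solution-to-solid ratio (`ssr_L_g`).
#' @export
system_composition <- function(HA_tot_mg_L = 0, FA_tot_mg_L = 0, pH = 4,
                               solid_g_L = 1, ionic_strength_M = 0.01,
                               area_m2_g = 96) {
  if (HA_tot_mg_L < 0 || FA_tot_mg_L < 0 || solid_g_L <= 0 ||
      ionic_strength_M <= 0 || area_m2_g <= 0) {
    stop_validation("system composition values must be non-negative (solid, I, area positive)")
  }
  structure(list(
    HA_tot_mg_L = HA_tot_mg_L, FA_tot_mg_L = FA_tot_mg_L, pH = pH,
    solid_g_L = solid_g_L, ionic_strength_M = ionic_strength_M,
    area_m2_g = area_m2_g,
    A_m2_L = area_m2_g * solid_g_L,
    ssr_L_g = 1 / solid_g_L
  ), class = "system_composition")
}

#' Single-component Langmuir-Freundlich isotherm
#'
#' Solves `phi_ads / (1 - phi_ads) = (K_tilde * phi_sol)^q` for the adsorbed
#' volume fraction. `q = 1` is the homogeneous Langmuir limit; `0 < q < 1`
#' expresses particle-level heterogeneity.
#'
#' @param K_tilde Median affinity (dimensionless), > 0.
#' @param q Heterogeneity exponent in (0, 1].
#' @param phi_sol Solution volume fraction in `[0, 1)`. Vectorized.
#' @param ln_K_tilde Optional `log(K_tilde)`, for affinities beyond double
#'   range.
#' @return `phi_ads` in `[0, 1)`.
#' @export
#' @examples
#' lf_isotherm(1, 1, 1)            # Langmuir midpoint: 0.5
#' lf_isotherm(4, 0.5, 1)          # x/(1-x) = 2: 2/3
lf_isotherm <- function(K_tilde, q, phi_sol, ln_K_tilde = log(K_tilde)) {
  if (!is.finite(ln_K_tilde)) stop_validation("K_tilde must be positive and finite on log scale")
  if (q <= 0 || q > 1) stop_validation("q must be in (0, 1]")
  if (any(phi_sol < 0) || any(phi_sol >= 1 + 1e-12)) {
    stop_validation("phi_sol must lie in [0, 1)")
  }
  out <- numeric(length(phi_sol))
  pos <- phi_sol > 0
  out[pos] <- plogis(q * (ln_K_tilde + log(phi_sol[pos])))
  out
}

## Partition context: fixed-affinity quantities per component.
## Gamma in mg/m2 throughout these internal helpers.
partition_phi <- function(Gamma_mg, T_mg_L, A_m2_L, V, rho) {
  C_mg_L <- T_mg_L - Gamma_mg * A_m2_L
  list(C_mg_L = C_mg_L,
       phi_sol = C_mg_L * 1e-3 / rho,
       phi_ads = Gamma_mg * 1e-6 / (V * rho))
}

## ln-residual of the competitive LF equation for one component:
## q (lnK + ln phi_sol) - ln phi_ads + ln(1 - sum phi_ads)
lf_residual <- function(ln_K, q, phi_sol, phi_ads, S) {
  if (phi_sol <= 0 || phi_ads <= 0 || S >= 1) return(NaN)
  q * (ln_K + log(phi_sol)) - log(phi_ads) + log1p(-S)
}

#' Simultaneous binary Langmuir-Freundlich partition at fixed affinities
#'
#' Solves the coupled pair of competitive LF equations (shared
#' unoccupied-space denominator `1 - phi_HA,ads - phi_FA,ads`) together with
#' the two component mass balances, at fixed median affinities and a fixed
#' adsorption volume. Root finding is nested Brent iteration in
#' log-transformed adsorbed amounts, which is monotone in each variable.
#'
#' @param K_HA,K_FA Median affinities (dimensionless).
#' @param q_HA,q_FA Heterogeneity exponents in (0, 1].
#' @param system A [system_composition()].
#' @param V Adsorption volume, m3/m2.
#' @param rho_p Named mass densities `c(HA = , FA = )`, kg/m3.
#' @param ln_K_HA,ln_K_FA Optional log affinities.
#' @param tol Residual tolerance (ln units).
#' @return A `partition_state` list: per-component adsorbed amounts (kg/m2
#'   and mg/m2), solution concentrations (mg/L), volume fractions, the shared
#'   volume, residuals, and mass-balance diagnostics.
#' @export
solve_binary_partition <- function(K_HA, K_FA, q_HA, q_FA, system, V,
                                   rho_p = c(HA = 1250, FA = 1250),
                                   ln_K_HA = log(K_HA), ln_K_FA = log(K_FA),
                                   tol = 1e-10) {
  if (!is.finite(ln_K_HA) || !is.finite(ln_K_FA)) {
    stop_validation("affinities must be positive (finite on log scale)")
  }
  if (q_HA <= 0 || q_HA > 1 || q_FA <= 0 || q_FA > 1) {
    stop_validation("q exponents must be in (0, 1]")
  }
  if (V <= 0) stop_validation("V must be positive")
  A <- system$A_m2_L
  T_ <- c(HA = system$HA_tot_mg_L, FA = system$FA_tot_mg_L)
  lnK <- c(HA = ln_K_HA, FA = ln_K_FA)
  qq <- c(HA = q_HA, FA = q_FA)

  cap <- function(comp, other_phi) {
    ## upper bound on Gamma (mg/m2): mass balance and remaining volume
    min(T_[comp] / A, (1 - other_phi - 1e-12) * V * rho_p[comp] * 1e6)
  }
  resid_comp <- function(comp, Gamma_mg, other_phi) {
    p <- partition_phi(Gamma_mg, T_[comp], A, V, rho_p[comp])
    lf_residual(lnK[comp], qq[comp], p$phi_sol, p$phi_ads, p$phi_ads + other_phi)
  }
  solve_comp <- function(comp, other_phi) {
    if (T_[comp] <= 0) return(0)
    up <- cap(comp, other_phi)
    if (up <= 0) return(0)
    f <- function(u) resid_comp(comp, exp(u) * up, other_phi)
    lo_u <- log(1e-14)
    hi_u <- log(1 - 1e-13)
    f_lo <- f(lo_u)
    if (!is.finite(f_lo) || f_lo < 0) return(0)       # nothing adsorbs
    f_hi <- f(hi_u)
    if (is.finite(f_hi) && f_hi > 0) return(up * (1 - 1e-13))  # cap-limited
    exp(uniroot(f, c(lo_u, hi_u), f.lower = f_lo, f.upper = f_hi,
                tol = 1e-13, maxiter = 300)$root) * up
  }

  if (T_["FA"] <= 0) {
    G <- c(HA = solve_comp("HA", 0), FA = 0)
  } else if (T_["HA"] <= 0) {
    G <- c(HA = 0, FA = solve_comp("FA", 0))
  } else {
    outer_res <- function(G_FA) {
      phi_F <- G_FA * 1e-6 / (V * rho_p["FA"])
      G_HA <- solve_comp("HA", phi_F)
      phi_H <- G_HA * 1e-6 / (V * rho_p["HA"])
      resid_comp("FA", G_FA, phi_H)
    }
    up_F <- cap("FA", 0)
    f <- function(u) outer_res(exp(u) * up_F)
    f_lo <- f(log(1e-14))
    f_hi <- f(log(1 - 1e-13))
    G_FA <- if (!is.finite(f_lo) || f_lo < 0) {
      0
    } else if (is.finite(f_hi) && f_hi > 0) {
      up_F * (1 - 1e-13)
    } else {
      exp(uniroot(f, c(log(1e-14), log(1 - 1e-13)), f.lower = f_lo,
                  f.upper = f_hi, tol = 1e-13, maxiter = 300)$root) * up_F
    }
    G_HA <- solve_comp("HA", G_FA * 1e-6 / (V * rho_p["FA"]))
    G <- c(HA = G_HA, FA = G_FA)
  }

  pH_ <- partition_phi(G["HA"], T_["HA"], A, V, rho_p["HA"])
  pF_ <- partition_phi(G["FA"], T_["FA"], A, V, rho_p["FA"])
  S <- pH_$phi_ads + pF_$phi_ads
  res <- c(
    HA = if (T_["HA"] > 0) lf_residual(lnK["HA"], qq["HA"], pH_$phi_sol, pH_$phi_ads, S) else 0,
    FA = if (T_["FA"] > 0) lf_residual(lnK["FA"], qq["FA"], pF_$phi_sol, pF_$phi_ads, S) else 0
  )
  structure(list(
    Gamma_mg_m2 = as.list(G),
    Gamma_kg_m2 = as.list(G * 1e-6),
    C_mg_L = list(HA = unname(pH_$C_mg_L), FA = unname(pF_$C_mg_L)),
    phi_sol = list(HA = unname(pH_$phi_sol), FA = unname(pF_$phi_sol)),
    phi_ads = list(HA = unname(pH_$phi_ads), FA = unname(pF_$phi_ads)),
    V_m3_m2 = V,
    residuals = res,
    mass_balance_rel = vapply(c("HA", "FA"), function(cc) {
      Tt <- T_[cc]
      if (Tt <= 0) return(0)
      Cc <- if (cc == "HA") pH_$C_mg_L else pF_$C_mg_L
      abs(Tt - Cc - G[cc] * A) / Tt
    }, numeric(1)),
    converged = all(abs(res) < max(tol, 1e-9))
  ), class = "partition_state")
}

## ---------------------------------------------------------------------------
## Full self-consistent coupled solve
## ---------------------------------------------------------------------------

build_model_context <- function(config) {
  config <- validate_config(config)
  e <- config$edl
  comps <- lapply(config$nom, function(n) {
    n$Gamma_MST_max_mg_m2 <- min(n$V_limit_m3_m2, e$d_ST_m) * n$rho_p_kg_m3 * 1e6
    n$d_ST_m <- e$d_ST_m
    n
  })
  list(
    config = config,
    sctx = surface_context(config),
    comps = comps,
    T_K = e$temperature_K,
    RT = .RGAS * e$temperature_K,
    steep_R = config$regulator$steepness_R,
    steep_t = config$regulator$steepness_theta,
    reg_fn = config$regulator$override,
    E_LX = config$affinity$ligand_exchange_kJ_mol,
    omega_basis = config$volume$omega_basis,
    V_const = config$volume$V_constant_m3_m2,
    tol_charge = config$solver$tol_charge_C_m2,
    tol_partition = config$solver$tol_partition,
    max_iter = config$solver$max_iter
  )
}

## Fast internal regulator (mirrors regulate_distribution defaults).
fast_regulator <- function(planes, ctx) {
  if (is.function(ctx$reg_fn)) {
    out <- ctx$reg_fn(planes)
    return(list(theta_s = min(max(out$theta_s, 0), 1),
                R = min(max(out$R, 0), 1)))
  }
  f_rt <- ctx$sctx$f_rt
  list(
    theta_s = min(1, 2 * plogis(ctx$steep_t * f_rt * (planes[2] - planes[3]))),
    R = plogis(ctx$steep_R * f_rt * (planes[1] - planes[2]))
  )
}

fast_distribution <- function(Gamma_mg, Gamma_MST_max, theta_s, R) {
  G_MST <- theta_s * Gamma_MST_max
  f_d <- if (Gamma_mg > G_MST && Gamma_mg > 0) (Gamma_mg - G_MST) / Gamma_mg else 0
  list(f_0plus1 = R * (1 - f_d), f_1plus2 = (1 - R) * (1 - f_d), f_d = f_d,
       Gamma_tot = Gamma_mg, Gamma_MST = G_MST, Gamma_MST_max = Gamma_MST_max,
       theta_s = theta_s, R = R)
}

## Evaluate the whole coupled model at unknowns x = c(psi, u_free) and
## return residuals plus (optionally) the assembled auxiliary state.
lcd_eval <- function(x, ctx, sys, free, fixed_Gamma, scenario, full = FALSE) {
  np <- if (ctx$sctx$topology == "extended") 3L else 2L
  psi <- x[seq_len(np)]
  if (max(abs(psi)) > 2) return(NULL)
  planes <- planes_from_psi(psi, ctx$sctx$topology)
  T_ <- c(HA = sys$HA_tot_mg_L, FA = sys$FA_tot_mg_L)
  A <- sys$A_m2_L

  Gamma_mg <- c(HA = 0, FA = 0)
  C_mg_L <- T_
  u <- x[-seq_len(np)]
  for (i in seq_along(free)) {
    ui <- min(max(u[i], -600), 600)
    Gamma_mg[free[i]] <- plogis(ui) * T_[free[i]] / A
    C_mg_L[free[i]] <- plogis(-ui) * T_[free[i]]   # exact 1 - z, no cancellation
  }
  for (comp in names(fixed_Gamma)) {
    Gamma_mg[comp] <- fixed_Gamma[[comp]]
    C_mg_L[comp] <- T_[comp] - Gamma_mg[comp] * A
  }

  rho <- c(HA = ctx$comps$HA$rho_p_kg_m3, FA = ctx$comps$FA$rho_p_kg_m3)
  V_lim <- c(HA = ctx$comps$HA$V_limit_m3_m2, FA = ctx$comps$FA$V_limit_m3_m2)
  if (any(C_mg_L < -1e-9)) return(NULL)
  C_mg_L <- pmax(C_mg_L, 0)
  phi_sol <- C_mg_L * 1e-3 / rho

  ## adsorption volume
  share <- if (ctx$omega_basis == "volume") Gamma_mg / rho else Gamma_mg
  if (sum(share) > 0) {
    omega <- share / sum(share)
  } else {
    share0 <- if (ctx$omega_basis == "volume") T_ / rho else T_
    omega <- if (sum(share0) > 0) share0 / sum(share0) else c(HA = 0.5, FA = 0.5)
  }
  V <- if (scenario == "constant") ctx$V_const else sum(omega * V_lim)
  phi_ads <- Gamma_mg * 1e-6 / (V * rho)
  S <- sum(phi_ads)
  if (S >= 1 - 1e-12) return(NULL)

  free_space <- 1 - S
  reg <- fast_regulator(planes, ctx)
  dist <- lapply(c(HA = "HA", FA = "FA"), function(cc) {
    fast_distribution(Gamma_mg[[cc]], ctx$comps[[cc]]$Gamma_MST_max_mg_m2,
                      reg$theta_s, reg$R)
  })

  ## fractionation-updated molar masses
  Mw <- vapply(c(HA = "HA", FA = "FA"), function(cc) {
    n <- ctx$comps[[cc]]
    if (T_[cc] <= 0) return(n$M_w_original_kDa)
    frac_sol <- min(C_mg_L[cc] / T_[cc], 1)
    min(max(n$M_o_kDa + n$k_fractionation_kDa * (1 - frac_sol), n$M_o_kDa),
        n$M_o_kDa + n$k_fractionation_kDa)
  }, numeric(1))

  ## affinities and NOM plane charges
  ln_K <- c(HA = NA_real_, FA = NA_real_)
  sigma_nom <- numeric(4)
  q_planes <- list()
  for (cc in c("HA", "FA")) {
    n <- ctx$comps[[cc]]
    ## Stern-contact fraction: layer thickness scales with the cube root of
    ## the current adsorbed-pool molar mass (slab contact geometry); only the
    ## contacting part of a particle interacts energetically with the surface.
    h_layer <- n$V_limit_m3_m2 * (Mw[cc] / n$M_w_original_kDa)^(1 / 3)
    contact <- min(1, n$d_ST_m / h_layer)
    qp <- nom_plane_charge(sys$pH, planes, dist[[cc]], n$nica, ctx$T_K,
                           n$charge_split_first_plane)
    q_planes[[cc]] <- qp
    w_elec <- .FARADAY * sum(qp * planes)
    w_chem <- -ctx$E_LX * 1000 * n$nica$Qmax1_mol_kg * dist[[cc]]$f_0plus1
    ln_K[cc] <- -(Mw[cc] * contact *
                    (w_elec + w_chem + n$affinity_offset_J_kg) +
                    n$affinity_offset_J_mol) / ctx$RT
    sigma_nom <- sigma_nom + .FARADAY * Gamma_mg[cc] * 1e-6 * qp
  }

  r_surf <- surface_residuals(psi, ctx$sctx, sys$pH, sys$ionic_strength_M,
                              sigma_nom)
  if (any(!is.finite(r_surf))) return(NULL)
  r_part <- vapply(free, function(cc) {
    lf_residual(ln_K[cc], ctx$comps[[cc]]$q, phi_sol[cc], phi_ads[cc], S)
  }, numeric(1))
  if (length(r_part) && any(!is.finite(r_part))) return(NULL)

  out <- list(residuals = c(r_surf, r_part), r_surf = r_surf, r_part = r_part,
              free_space = free_space)
  if (full) {
    out <- c(out, list(
      psi = psi, planes = planes, Gamma_mg = Gamma_mg, C_mg_L = C_mg_L,
      phi_sol = phi_sol, phi_ads = phi_ads, V = V, omega = omega,
      reg = reg, dist = dist, Mw = Mw, ln_K = ln_K, sigma_nom = sigma_nom,
      q_planes = q_planes))
  }
  out
}

#' Self-consistent competitive LCD solve
#'
#' Solves the fully coupled system for one batch point: CD-MUSIC surface
#' speciation and electrostatics with the adsorbed NOM charge at its planes,
#' the potential-regulated interfacial distributions, the
#' fractionation-updated molar masses, the resulting median affinities, and
#' the competitive Langmuir-Freundlich partition with mass balance. Under
#' `scenario = "constant"` the adsorption volume is fixed (default 3e-9
#' m3/m2, the single-component HA value); under `scenario = "variable"` it
#' follows the mixing rule `V = sum(omega_i V_i)`.
#'
#' All equations are solved simultaneously by a damped Newton iteration on
#' the plane potentials and logit-transformed adsorbed fractions, with a
#' robust nested-bisection fallback; results are therefore independent of any
#' module update ordering. In `mode = "conditional"` the adsorbed amount of
#' one component is clamped to a supplied (measured) value and only the other
#' component's partition equation is solved, mirroring how measured
#' competitor adsorption can be imposed during data interpretation.
#'
#' @param system A [system_composition()].
#' @param config An [lcd_config()] configuration.
#' @param scenario `"variable"` or `"constant"` adsorption volume.
#' @param mode `"predictive"` or `"conditional"`.
#' @param conditional_fixed For conditional mode: `list(component = "FA",
#'   Gamma_mg_m2 = <value>)`.
#' @param init Optional warm start from a previous `lcd_state` (continuation
#'   along an isotherm series).
#' @return An `lcd_state` object bundling the `surface_state`, partition
#'   (amounts, concentrations, volume fractions, mass balance), per-component
#'   interfacial distributions and affinities, molar masses, the adsorption
#'   volume and mixing weights, and solver diagnostics.
#' @export
lcd_solve <- function(system, config = lcd_config(),
                      scenario = c("variable", "constant"),
                      mode = c("predictive", "conditional"),
                      conditional_fixed = NULL, init = NULL) {
  mode <- match.arg(mode)
  ctx <- if (inherits(config, "lcd_model_context")) config else
    structure(build_model_context(config), class = "lcd_model_context")
  scenario <- if (missing(scenario)) ctx$config$scenario else match.arg(scenario)
  sys <- system
  np <- if (ctx$sctx$topology == "extended") 3L else 2L

  fixed_Gamma <- list()
  if (mode == "conditional") {
    if (is.null(conditional_fixed) ||
        !all(c("component", "Gamma_mg_m2") %in% names(conditional_fixed))) {
      stop_validation("conditional mode requires conditional_fixed = list(component, Gamma_mg_m2)")
    }
    comp <- match.arg(conditional_fixed$component, c("HA", "FA"))
    fixed_Gamma[[comp]] <- conditional_fixed$Gamma_mg_m2
  }
  T_ <- c(HA = sys$HA_tot_mg_L, FA = sys$FA_tot_mg_L)
  free <- setdiff(names(T_)[T_ > 0], names(fixed_Gamma))

  ## The ln-residual of the partition equation carries a log1p(-S) term whose
  ## double-precision floor is eps / (1 - S); near complete filling the
  ## attainable tolerance is therefore state-dependent.
  last_free_space <- 1
  fn <- function(x) {
    ev <- lcd_eval(x, ctx, sys, free, fixed_Gamma, scenario)
    if (is.null(ev)) return(rep(NaN, np + length(free)))
    last_free_space <<- ev$free_space
    ev$residuals
  }
  tol_fun <- function(r) {
    tol_part <- max(ctx$tol_partition,
                    4 * .Machine$double.eps / max(last_free_space, 1e-15))
    max(abs(r[seq_len(np)])) < ctx$tol_charge &&
      (length(r) == np || max(abs(r[-seq_len(np)])) < tol_part)
  }

  ## starting points: warm start, then a ladder of adsorbed fractions
  bare <- solve_surface_state(sys$pH, sys$ionic_strength_M,
                              config = ctx$config)
  psi0 <- unname(bare$psi[seq_len(np)])
  z_ladder <- c(0.9, 0.5, 0.99, 0.1, 0.7, 0.999, 0.01)
  starts <- list()
  if (!is.null(init) && inherits(init, "lcd_state")) {
    u_init <- vapply(free, function(cc) {
      z <- init$partition$Gamma_mg_m2[[cc]] * sys$A_m2_L / T_[cc]
      qlogis(min(max(z, 1e-6), 1 - 1e-6))
    }, numeric(1))
    starts <- list(c(unname(init$surface$psi)[seq_len(np)], u_init))
  }
  for (z in z_ladder) {
    starts <- c(starts, list(c(psi0, rep(qlogis(z), length(free)))))
  }
  if (length(free) == 2) {
    starts <- c(starts,
                list(c(psi0, qlogis(0.9), qlogis(0.4)),
                     c(psi0, qlogis(0.4), qlogis(0.9))))
  }

  sol <- NULL
  for (x0 in starts) {
    cand <- newton_solve(fn, x0, tol_fun, max_iter = ctx$max_iter)
    if (cand$converged) {
      sol <- cand
      break
    }
    if (is.null(sol) ||
        (all(is.finite(cand$residuals)) &&
         (!all(is.finite(sol$residuals)) ||
          sum(cand$residuals^2) < sum(sol$residuals^2)))) sol <- cand
  }
  if (is.null(sol) || !sol$converged) {
    sol <- lcd_solve_bisect(ctx, sys, free, fixed_Gamma, scenario, np,
                            fn, tol_fun)
  }
  if (!sol$converged) {
    stop_convergence(
      paste0("coupled solver did not converge (HA ", T_["HA"], ", FA ",
             T_["FA"], " mg/L, pH ", sys$pH, "); residuals: ",
             paste(format(sol$residuals, digits = 3), collapse = ", ")),
      residuals = sol$residuals)
  }
  ev <- lcd_eval(sol$x, ctx, sys, free, fixed_Gamma, scenario, full = TRUE)
  assemble_lcd_state(ev, sol, ctx, sys, free, scenario,
                     if (mode == "conditional") "conditional" else "predictive")
}

## Robust fallback: nested Brent iteration over logit adsorbed fractions,
## with an inner full surface solve (NOM charge as a function of the
## potentials) at each trial loading.
lcd_solve_bisect <- function(ctx, sys, free, fixed_Gamma, scenario, np,
                             fn, tol_fun) {
  T_ <- c(HA = sys$HA_tot_mg_L, FA = sys$FA_tot_mg_L)
  A <- sys$A_m2_L
  psi_last <- NULL

  eval_at <- function(u_free) {
    ## inner surface solve at this loading
    inner <- function(psi) {
      ev <- lcd_eval(c(psi, u_free), ctx, sys, free, fixed_Gamma, scenario)
      if (is.null(ev)) rep(NaN, np) else ev$r_surf
    }
    start <- psi_last %||% unname(solve_surface_state(
      sys$pH, sys$ionic_strength_M, config = ctx$config)$psi[seq_len(np)])
    s <- newton_solve(inner, start, function(r) max(abs(r)) < ctx$tol_charge,
                      max_iter = ctx$max_iter)
    if (!s$converged) return(NULL)
    psi_last <<- s$x
    lcd_eval(c(s$x, u_free), ctx, sys, free, fixed_Gamma, scenario)
  }
  ## infeasible loadings (adsorbed volume cap exceeded, or no surface
  ## convergence there) lie past the root: surrogate large negative residual
  part_res <- function(u_free, i) {
    ev <- eval_at(u_free)
    if (is.null(ev) || !is.finite(ev$r_part[i])) return(-1e6)
    ev$r_part[i]
  }
  ## The residual decreases from + (nothing adsorbed) to - (too much) along
  ## u; infeasible loadings count as "past the root". Bisection keeps the
  ## last feasible positive-side point, so boundary equilibria (complete
  ## adsorption, or a completely filled layer, both beyond double precision)
  ## are returned as the feasible edge state.
  lim <- 650
  solve_u <- function(f) {
    r_lo <- f(-lim)
    if (!is.finite(r_lo) || r_lo < 0) return(-lim)  # nothing adsorbs
    r_hi <- f(lim)
    if (is.finite(r_hi) && r_hi > 0) return(lim)    # complete adsorption
    lo <- -lim
    hi <- lim
    for (k in seq_len(80)) {
      mid <- (lo + hi) / 2
      rm <- f(mid)
      if (is.finite(rm) && rm > 0) lo <- mid else hi <- mid
      if (abs(rm) < 1e-13 || (hi - lo) < 4e-14 * max(1, abs(lo))) break
    }
    lo
  }
  uu <- setNames(rep(NA_real_, length(free)), free)
  if (length(free) == 0) {
    ev <- eval_at(numeric(0))
  } else if (length(free) == 1) {
    uu[1] <- solve_u(function(u) part_res(u, 1))
    ev <- eval_at(uu)
  } else {
    outer <- function(u2) {
      u1 <- solve_u(function(u) part_res(c(u, u2), 1))
      part_res(c(u1, u2), 2)
    }
    uu[2] <- solve_u(outer)
    uu[1] <- solve_u(function(u) part_res(c(u, uu[2]), 1))
    ev <- eval_at(uu)
  }
  if (is.null(ev)) {
    return(list(x = NA, residuals = Inf, converged = FALSE, iterations = NA))
  }
  x <- c(psi_last, unname(uu))
  r <- fn(x)
  part_ok <- function(rr) {
    all(vapply(seq_along(free), function(i) {
      ri <- rr[np + i]
      abs(ri) < max(ctx$tol_partition,
                    4 * .Machine$double.eps / max(ev$free_space, 1e-15)) ||
        (uu[i] >= lim && ri > 0) ||     # complete adsorption of the addition
        (uu[i] <= -lim && ri < 0) ||    # complete non-adsorption
        (ri > 0 && ev$free_space < 1e-10)  # volume-saturated layer
    }, logical(1)))
  }
  if (all(is.finite(r)) &&
      max(abs(r[seq_len(np)])) < ctx$tol_charge && part_ok(r)) {
    return(list(x = x, residuals = r, converged = TRUE, iterations = NA))
  }
  ## polish with Newton from the bisection solution
  newton_solve(fn, x, tol_fun, max_iter = 40)
}

assemble_lcd_state <- function(ev, sol, ctx, sys, free, scenario, mode) {
  surf <- build_surface_state(
    list(x = ev$psi, residuals = ev$r_surf, iterations = sol$iterations,
         converged = TRUE),
    ctx$sctx, sys$pH, sys$ionic_strength_M, ev$sigma_nom, ctx$config)
  T_ <- c(HA = sys$HA_tot_mg_L, FA = sys$FA_tot_mg_L)
  A <- sys$A_m2_L
  mass_bal <- vapply(c("HA", "FA"), function(cc) {
    if (T_[cc] <= 0) return(0)
    abs(T_[cc] - ev$C_mg_L[cc] - ev$Gamma_mg[cc] * A) / T_[cc]
  }, numeric(1))
  affinity <- lapply(c(HA = "HA", FA = "FA"), function(cc) {
    n <- ctx$comps[[cc]]
    structure(list(
      ln_K_tilde = unname(ev$ln_K[cc]),
      K_tilde = exp(min(ev$ln_K[cc], 700)),
      dG_ads_J_mol = -unname(ev$ln_K[cc]) * ctx$RT,
      offset_J_kg = n$affinity_offset_J_kg,
      offset_J_mol = n$affinity_offset_J_mol,
      M_w_kDa = unname(ev$Mw[cc])
    ), class = "affinity_result")
  })
  partition <- structure(list(
    Gamma_mg_m2 = as.list(ev$Gamma_mg),
    Gamma_kg_m2 = as.list(ev$Gamma_mg * 1e-6),
    C_mg_L = as.list(unname(ev$C_mg_L)) |> setNames(c("HA", "FA")),
    phi_sol = as.list(unname(ev$phi_sol)) |> setNames(c("HA", "FA")),
    phi_ads = as.list(unname(ev$phi_ads)) |> setNames(c("HA", "FA")),
    V_m3_m2 = ev$V,
    residuals = ev$r_part,
    mass_balance_rel = mass_bal,
    converged = TRUE
  ), class = "partition_state")
  structure(list(
    surface = surf,
    partition = partition,
    distribution = ev$dist,
    affinity = affinity,
    M_w_kDa = as.list(ev$Mw),
    V_m3_m2 = ev$V,
    omega = ev$omega,
    theta_s = ev$reg$theta_s,
    R = ev$reg$R,
    scenario = scenario,
    mode = mode,
    system = sys,
    residuals = sol$residuals,
    iterations = sol$iterations,
    converged = TRUE
  ), class = "lcd_state")
}

#' @export
print.lcd_state <- function(x, ...) {
  cat("<lcd_state> pH", x$system$pH, "| HA", x$system$HA_tot_mg_L,
      "FA", x$system$FA_tot_mg_L, "mg/L |", x$scenario, "volume |", x$mode, "\n")
  cat(sprintf("  adsorbed: HA %.4f, FA %.4f mg/m2 | V %.3g m3/m2\n",
              x$partition$Gamma_mg_m2$HA, x$partition$Gamma_mg_m2$FA,
              x$V_m3_m2))
  cat(sprintf("  psi0 %.4f V | ln K~: HA %.1f, FA %.1f | Mw(HA ads) %.2f kDa\n",
              x$surface$psi[["psi0"]], x$affinity$HA$ln_K_tilde,
              x$affinity$FA$ln_K_tilde, x$M_w_kDa$HA))
  invisible(x)
}
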