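## ---- CD-MUSIC surface speciation and multi-plane electrostatics ----------
##
## 1-pK MUSIC description of goethite: singly (FeOH^-1/2) and triply
## (Fe3O^-1/2) coordinated groups protonate with the same intrinsic logK
## (equal to the pristine point of zero charge for a symmetric electrolyte),
## placing the proton charge at the 0-plane. Na+ and Cl- form outer-sphere
## pairs whose charge resides at the 2-plane (extended Stern) or at the head
## of the diffuse layer (basic Stern). NOM charge can be imposed at any of
## the planes 0, 1, 2 and d; the d-plane sits at the Stern/diffuse boundary
## and also collects the electrolyte charge of the NOM-occupied diffuse
## region.

surface_context <- function(config) {
  e <- config$edl
  s <- config$surface
  T_K <- e$temperature_K
  list(
    topology = e$topology,
    C1 = e$C1_F_m2, C2 = e$C2_F_m2,
    T_K = T_K,
    f_rt = .FARADAY / (.RGAS * T_K),
    gc_pref = function(I) sqrt(8 * e$relative_permittivity * .EPS0 *
                                 .RGAS * T_K * 1000 * I),
    Nse = vapply(s$sites, function(x) x$density_nm2 * 1e18 * .ECHARGE, 0),
    K_H = vapply(s$sites, function(x) 10^x$logK_H, 0),
    site_names = vapply(s$sites, function(x) x$name, ""),
    K_Na = 10^s$logK_Na,
    K_Cl = 10^s$logK_Cl
  )
}

## Surface speciation at given 0- and 2-plane potentials. Species per site:
## reference (deprotonated), protonated, Na-pair, protonated-Cl-pair.
surf_speciation <- function(sctx, pH, I, psi0, psi2) {
  aH <- 10^(-pH)
  g <- davies_gamma(I)
  aNa <- g * I
  aCl <- g * I
  y0 <- sctx$f_rt * psi0
  y2 <- sctx$f_rt * psi2
  sigma0 <- 0
  sigma2 <- 0
  frac <- vector("list", length(sctx$Nse))
  for (i in seq_along(sctx$Nse)) {
    s1 <- sctx$K_H[i] * aH * exp(-y0)
    s2 <- sctx$K_Na * aNa * exp(-y2)
    s3 <- sctx$K_H[i] * sctx$K_Cl * aH * aCl * exp(-y0 + y2)
    den <- 1 + s1 + s2 + s3
    sigma0 <- sigma0 + sctx$Nse[i] * (0.5 * (s1 + s3) - 0.5 * (1 + s2)) / den
    sigma2 <- sigma2 + sctx$Nse[i] * (s2 - s3) / den
    frac[[i]] <- c(ref = 1, protonated = s1, Na_pair = s2, Cl_pair = s3) / den
  }
  names(frac) <- sctx$site_names
  list(sigma0 = sigma0, sigma2 = sigma2, fractions = frac)
}

## Diffuse-layer (Gouy-Chapman, 1:1 electrolyte) charge at potential psi_d.
gouy_chapman_charge <- function(sctx, I, psi_d) {
  -sctx$gc_pref(I) * sinh(sctx$f_rt * psi_d / 2)
}

## Residual system. `nom_sigma` is either a length-4 numeric (C/m2 at planes
## 0,1,2,d) or a function(psi_planes) returning that vector.
surface_residuals <- function(psi, sctx, pH, I, nom_sigma) {
  if (sctx$topology == "extended") {
    psi0 <- psi[1]; psi1 <- psi[2]; psi2 <- psi[3]
    planes <- c(psi0, psi1, psi2, psi2)
  } else {
    psi0 <- psi[1]; psi1 <- psi[2]; psi2 <- psi1
    planes <- c(psi0, psi1, psi1, psi1)
  }
  if (max(abs(planes)) > 2) return(rep(NaN, length(psi)))
  nom <- if (is.function(nom_sigma)) nom_sigma(planes) else nom_sigma
  sp <- surf_speciation(sctx, pH, I, psi0, psi2)
  sig0 <- sp$sigma0 + nom[1]
  sig1 <- nom[2]
  sig2 <- sp$sigma2 + nom[3]
  sigd <- nom[4]
  if (sctx$topology == "extended") {
    c(sig0 - sctx$C1 * (psi0 - psi1),
      sctx$C1 * (psi0 - psi1) + sig1 - sctx$C2 * (psi1 - psi2),
      sig0 + sig1 + sig2 + sigd + gouy_chapman_charge(sctx, I, psi2))
  } else {
    c(sig0 - sctx$C1 * (psi0 - psi1),
      sig0 + sig1 + sig2 + sigd + gouy_chapman_charge(sctx, I, psi1))
  }
}

#' Solve the goethite surface state
#'
#' Finds the electrostatic plane potentials and surface speciation of
#' goethite at a given pH and ionic strength, optionally with externally
#' imposed NOM charge at the 0-, 1-, 2- and d-planes. The converged state
#' satisfies mass action with Boltzmann factors, the charge-potential
#' relations across the Stern capacitors, a Gouy-Chapman diffuse layer, and
#' global electroneutrality.
#'
#' @param pH Solution pH in `[2, 12]`.
#' @param ionic_strength Ionic strength of the 1:1 electrolyte, mol/L.
#' @param nom_plane_charges Numeric length 4: NOM charge (C/m2) at planes
#'   0, 1, 2, d; or a function of the length-4 plane-potential vector
#'   returning such charges (used by the coupled solver).
#' @param config An [lcd_config()] configuration.
#' @param init Optional initial potentials (length 3 for the extended Stern
#'   topology, 2 for basic).
#' @return A `surface_state` object: plane potentials `psi` (V), plane charge
#'   densities `sigma` (C/m2, including the diffuse layer), per-site species
#'   fractions, residuals and solver diagnostics.
#' @export
#' @examples
#' st <- solve_surface_state(4, 0.01)
#' sum(st$sigma) # electroneutrality
solve_surface_state <- function(pH, ionic_strength,
                                nom_plane_charges = c(0, 0, 0, 0),
                                config = lcd_config(), init = NULL) {
  if (!is.finite(pH) || pH < 2 || pH > 12) {
    stop_validation("pH must lie in [2, 12]")
  }
  if (!is.finite(ionic_strength) || ionic_strength <= 0) {
    stop_validation("ionic_strength must be positive")
  }
  config <- validate_config(config)
  sctx <- surface_context(config)
  tol <- config$solver$tol_charge_C_m2
  np <- if (sctx$topology == "extended") 3L else 2L

  nernst <- log(10) / sctx$f_rt * (mean(log10(sctx$K_H)) - pH)
  psi0_guess <- max(min(0.9 * nernst, 0.45), -0.45)
  starts <- list()
  if (!is.null(init)) starts <- c(starts, list(init[seq_len(np)]))
  starts <- c(starts,
              list(psi0_guess * c(1, 0.6, 0.3)[seq_len(np)],
                   rep(0, np),
                   psi0_guess * c(1, 0.9, 0.8)[seq_len(np)],
                   -psi0_guess * c(1, 0.6, 0.3)[seq_len(np)]))

  fn <- function(psi) surface_residuals(psi, sctx, pH, ionic_strength,
                                        nom_plane_charges)
  tol_fun <- function(r) max(abs(r)) < tol
  sol <- NULL
  for (x0 in starts) {
    cand <- newton_solve(fn, x0, tol_fun, max_iter = config$solver$max_iter)
    if (cand$converged) {
      sol <- cand
      break
    }
    if (is.null(sol) || sum(cand$residuals^2) < sum(sol$residuals^2)) sol <- cand
  }
  if (!sol$converged) {
    stop_convergence(
      paste0("surface solver did not converge at pH ", pH,
             " (max residual ", format(max(abs(sol$residuals))), " C/m2)"),
      residuals = sol$residuals)
  }
  build_surface_state(sol, sctx, pH, ionic_strength, nom_plane_charges, config)
}

build_surface_state <- function(sol, sctx, pH, I, nom_sigma, config) {
  psi <- sol$x
  if (sctx$topology == "extended") {
    planes <- c(psi[1], psi[2], psi[3], psi[3])
  } else {
    planes <- c(psi[1], psi[2], psi[2], psi[2])
  }
  nom <- if (is.function(nom_sigma)) nom_sigma(planes) else nom_sigma
  sp <- surf_speciation(sctx, pH, I, planes[1], planes[3])
  sigma <- c(sigma0 = sp$sigma0 + nom[1],
             sigma1 = nom[2],
             sigma2 = sp$sigma2 + nom[3],
             sigmad = nom[4],
             sigma_diffuse = gouy_chapman_charge(sctx, I, planes[4]))
  structure(list(
    psi = setNames(planes, c("psi0", "psi1", "psi2", "psid")),
    sigma = sigma,
    net_surface_charge = unname(sum(sigma[1:4])),
    species_fractions = sp$fractions,
    pH = pH,
    ionic_strength = I,
    nom_plane_charges = nom,
    topology = sctx$topology,
    residuals = sol$residuals,
    iterations = sol$iterations,
    converged = sol$converged
  ), class = "surface_state")
}

#' @export
print.surface_state <- function(x, ...) {
  cat("<surface_state> pH", x$pH, " I", x$ionic_strength, "M (",
      x$topology, "Stern )\n")
  cat("  psi  (V):   ", paste(sprintf("%+.4f", x$psi), collapse = "  "), "\n")
  cat("  sigma(C/m2):", paste(sprintf("%+.4f", x$sigma), collapse = "  "), "\n")
  cat("  net surface charge:", format(x$net_surface_charge, digits = 4), "C/m2\n")
  invisible(x)
}

#' Tidy a surface state into a per-plane tibble
#' @param x A `surface_state`.
#' @param ... Unused.
#' @method tidy surface_state
#' @export
tidy.surface_state <- function(x, ...) {
  tibble::tibble(
    plane = c("0", "1", "2", "d", "diffuse"),
    sigma_C_m2 = unname(x$sigma),
    psi_V = c(unname(x$psi), unname(x$psi[4]))
  )
}

#' Point of zero charge of the bare surface
#'
#' Locates the pH at which the net surface charge of the bare goethite
#' crosses zero, by bracketed root finding on the charging curve in a
#' symmetric 1:1 electrolyte. With the default 1-pK parameterization this is
#' set by the intrinsic protonation constants, independent of the Stern
#' capacitances.
#'
#' @param config An [lcd_config()] configuration.
#' @param ionic_strength Ionic strength, mol/L.
#' @param interval pH search interval.
#' @return The point of zero charge (pH units).
#' @export
#' @examples
#' compute_pzc() # 9.3 under defaults
compute_pzc <- function(config = lcd_config(), ionic_strength = 0.01,
                        interval = c(3, 11.5)) {
  f <- function(pH) {
    solve_surface_state(pH, ionic_strength, config = config)$net_surface_charge
  }
  lo <- f(interval[1])
  hi <- f(interval[2])
  if (sign(lo) == sign(hi)) {
    stop_validation("net surface charge does not change sign over the scanned pH range")
  }
  uniroot(f, interval, f.lower = lo, f.upper = hi, tol = 1e-10)$root
}

#' Charging curve of the (possibly NOM-loaded) surface
#'
#' Solves the surface state on a monotone pH grid and returns plane charges
#' and potentials as a tibble (one converged state per row).
#'
#' @param pH_grid Monotone numeric vector of pH values.
#' @param ionic_strength Ionic strength, mol/L.
#' @param config An [lcd_config()] configuration.
#' @param nom_plane_charges NOM charge at planes 0, 1, 2, d (C/m2).
#' @return A tibble with columns `pH`, `sigma0`, `sigma1`, `sigma2`, `sigmad`,
#'   `sigma_diffuse`, `net_charge`, `psi0`, `psi1`, `psi2`, `psid`.
#' @export
charging_curve <- function(pH_grid, ionic_strength = 0.01,
                           config = lcd_config(),
                           nom_plane_charges = c(0, 0, 0, 0)) {
  if (length(pH_grid) > 1 && !(all(diff(pH_grid) > 0) || all(diff(pH_grid) < 0))) {
    stop_validation("pH_grid must be monotone")
  }
  init <- NULL
  rows <- purrr::map(pH_grid, function(p) {
    st <- tryCatch(
      solve_surface_state(p, ionic_strength, nom_plane_charges, config,
                          init = init),
      lcdcc_convergence_error = function(e) {
        stop_convergence(paste0("charging_curve failed at pH ", p, ": ",
                                conditionMessage(e)))
      })
    init <<- unname(st$psi[seq_len(if (st$topology == "extended") 3 else 2)])
    tibble::tibble(
      pH = p,
      sigma0 = unname(st$sigma["sigma0"]), sigma1 = unname(st$sigma["sigma1"]),
      sigma2 = unname(st$sigma["sigma2"]), sigmad = unname(st$sigma["sigmad"]),
      sigma_diffuse = unname(st$sigma["sigma_diffuse"]),
      net_charge = st$net_surface_charge,
      psi0 = unname(st$psi["psi0"]), psi1 = unname(st$psi["psi1"]),
      psi2 = unname(st$psi["psi2"]), psid = unname(st$psi["psid"])
    )
  })
  dplyr::bind_rows(rows)
}
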