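## Independent oracles, written from the defining equations without reusing
## the package's solvers.

.F <- 96485.33212
.R <- 8.314462618
.E <- 1.602176634e-19
.EPS0o <- 8.8541878128e-12

## Surface speciation written out from the mass-action laws (1-pK MUSIC with
## symmetric ion pairing), independent of the package internals.
oracle_speciation <- function(cfg, pH, I, psi0, psi2) {
  TK <- cfg$edl$temperature_K
  frt <- .F / (.R * TK)
  gam <- 10^(-0.509 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I))
  aH <- 10^(-pH)
  aNa <- gam * I
  aCl <- gam * I
  sig0 <- 0
  sig2 <- 0
  for (site in cfg$surface$sites) {
    Nse <- site$density_nm2 * 1e18 * .E
    KH <- 10^site$logK_H
    s1 <- KH * aH * exp(-frt * psi0)
    s2 <- 10^cfg$surface$logK_Na * aNa * exp(-frt * psi2)
    s3 <- KH * 10^cfg$surface$logK_Cl * aH * aCl * exp(-frt * (psi0 - psi2))
    den <- 1 + s1 + s2 + s3
    sig0 <- sig0 + Nse * (0.5 * (s1 + s3) - 0.5 * (1 + s2)) / den
    sig2 <- sig2 + Nse * (s2 - s3) / den
  }
  list(sig0 = sig0, sig2 = sig2)
}

## Nested-bisection solution of the extended-Stern system: outer bisection on
## psi0 (electroneutrality), inner bisection on psi2 (consistency of the
## outer capacitor relation).
oracle_surface_bisect <- function(cfg, pH, I, nom = c(0, 0, 0, 0)) {
  TK <- cfg$edl$temperature_K
  frt <- .F / (.R * TK)
  C1 <- cfg$edl$C1_F_m2
  C2 <- cfg$edl$C2_F_m2
  gc <- function(psi) {
    -sqrt(8 * cfg$edl$relative_permittivity * .EPS0o * .R * TK * 1000 * I) *
      sinh(frt * psi / 2)
  }
  psi2_of <- function(psi0) {
    f <- function(psi2) {
      sp <- oracle_speciation(cfg, pH, I, psi0, psi2)
      psi1 <- psi0 - (sp$sig0 + nom[1]) / C1
      (psi1 - (sp$sig0 + nom[1] + nom[2]) / C2) - psi2
    }
    lo <- -1; hi <- 1
    for (k in 1:100) {
      mid <- (lo + hi) / 2
      if (f(mid) > 0) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  net <- function(psi0) {
    psi2 <- psi2_of(psi0)
    sp <- oracle_speciation(cfg, pH, I, psi0, psi2)
    sp$sig0 + nom[1] + nom[2] + sp$sig2 + nom[3] + nom[4] + gc(psi2)
  }
  lo <- -1; hi <- 1
  for (k in 1:100) {
    mid <- (lo + hi) / 2
    if (net(mid) > 0) lo <- mid else hi <- mid
  }
  psi0 <- (lo + hi) / 2
  psi2 <- psi2_of(psi0)
  sp <- oracle_speciation(cfg, pH, I, psi0, psi2)
  psi1 <- psi0 - (sp$sig0 + nom[1]) / C1
  list(psi = c(psi0, psi1, psi2),
       net_charge = sp$sig0 + nom[1] + nom[2] + sp$sig2 + nom[3] + nom[4])
}

## 2-D grid-refinement oracle for the binary competitive LF partition at
## fixed affinities: minimizes the summed squared ln-residuals over
## (phi_HA, phi_FA), shrinking the window around the argmin.
oracle_grid_binary <- function(ln_K, q, T_mg_L, A, V, rho, rounds = 16,
                               n_grid = 41) {
  resid2 <- function(x, y) {
    gx <- x * V * rho[1] * 1e6
    gy <- y * V * rho[2] * 1e6
    cx <- T_mg_L[1] - gx * A
    cy <- T_mg_L[2] - gy * A
    sx <- cx * 1e-3 / rho[1]
    sy <- cy * 1e-3 / rho[2]
    bad <- cx <= 0 | cy <= 0 | x <= 0 | y <= 0 | (x + y) >= 1
    sx[bad] <- 1; sy[bad] <- 1   # placeholder, masked below
    xb <- ifelse(bad, 0.5, x); yb <- ifelse(bad, 0.25, y)
    r1 <- q[1] * (ln_K[1] + log(sx)) - log(xb) + log1p(-(xb + yb))
    r2 <- q[2] * (ln_K[2] + log(sy)) - log(yb) + log1p(-(xb + yb))
    out <- r1^2 + r2^2
    out[bad] <- Inf
    out
  }
  lo <- c(1e-12, 1e-12)
  hi <- pmin(1 - 1e-12, T_mg_L / (A * V * rho * 1e6))
  for (r in seq_len(rounds)) {
    xs <- seq(lo[1], hi[1], length.out = n_grid)
    ys <- seq(lo[2], hi[2], length.out = n_grid)
    g <- outer(xs, ys, resid2)
    ij <- arrayInd(which.min(g), dim(g))
    dx <- (hi[1] - lo[1]) / (n_grid - 1)
    dy <- (hi[2] - lo[2]) / (n_grid - 1)
    ## conservative window shrink (+-5 cells) so a narrow diagonal valley
    ## cannot escape the refinement window
    lo <- c(max(1e-12, xs[ij[1]] - 5 * dx), max(1e-12, ys[ij[2]] - 5 * dy))
    hi <- c(xs[ij[1]] + 5 * dx, ys[ij[2]] + 5 * dy)
  }
  c(HA = xs[ij[1]], FA = ys[ij[2]])
}

## Classical competitive Langmuir (q = 1) with mass balance, reduced to a
## scalar root in the free-space fraction D = 1 - x - y.
oracle_competitive_langmuir <- function(K, T_mg_L, A, V, rho) {
  x_of <- function(D, i) {
    ## x = K_i phi_sol,i D with phi_sol linear in x:
    ## phi_sol,i = (T_i - x V rho_i 1e6 A) 1e-3 / rho_i
    a <- K[i] * T_mg_L[i] * 1e-3 / rho[i]
    b <- K[i] * V * 1e6 * A * 1e-3
    a * D / (1 + b * D)
  }
  f <- function(D) D + x_of(D, 1) + x_of(D, 2) - 1
  D <- uniroot(f, c(1e-15, 1), tol = 1e-15)$root
  c(HA = x_of(D, 1), FA = x_of(D, 2))
}
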