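---
title: "Competitive adsorption of humic and fulvic acid on goethite: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Competitive adsorption of humic and fulvic acid on goethite: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Natural organic matter (NOM) in soils and waters is a mixture of
operationally defined fractions — here humic acid (HA, large particles,
mean molar mass 17 kDa, layer thickness about 3 nm) and fulvic acid (FA,
small, 1.8 kDa, about 1 nm) — that bind to iron (hydr)oxide surfaces.
When both are present they compete: small, highly charged FA particles
form inner-sphere complexes close to the surface and confiscate
interfacial space, while the larger HA particles are pushed out of the
compact double layer. `lcdcc` implements a consistent competitive
ligand-and-charge-distribution (LCD) model of this system for goethite
(96 m²/g, pristine point of zero charge 9.3) in NaCl, and the batch
designs used to probe it: HA series (20–240 mg/L) at fixed FA (0 or
100 mg/L), and FA series (25–200 mg/L) at fixed HA (0 or 160 mg/L), at
1 g/L goethite, 0.01 M NaCl, pH 4 and 6.

## Model structure

The model couples five pieces, solved simultaneously for each batch
point.

### Goethite surface: CD-MUSIC with a multi-plane Stern layer

The surface is described with a 1-pK MUSIC site pair — singly
(3.45 nm⁻²) and triply (2.7 nm⁻²) coordinated oxygens, both protonating
with log K_H = 9.3, which fixes the point of zero charge at 9.3 for a
symmetric electrolyte — plus outer-sphere Na⁺/Cl⁻ pairs (log K = −1)
whose charge sits at the 2-plane. The electrical double layer is an
extended Stern stack (capacitances C1 = 0.9, C2 = 0.74 F/m²; a basic
Stern variant is available via `edl.topology`), a d-plane at the
Stern/diffuse boundary that hosts NOM residing beyond the compact layer,
and a Gouy–Chapman diffuse layer. A converged `solve_surface_state()`
satisfies all mass-action laws with Boltzmann factors, the
charge–potential relations across the Stern capacitors, and global
electroneutrality to better than 1e−10 C/m².

### NOM proton chemistry: bimodal NICA

Each component carries a bimodal NICA distribution (carboxylic- and
phenolic-type) with generic humic/fulvic proton parameters as defaults;
occupancy of a group at an interfacial plane is evaluated at the local
proton activity `a_H exp(-F psi / RT)`. FA carries more charge per mass
than HA at pH 4–6, as its higher carboxylic density dictates.

### Interfacial distribution of adsorbed NOM

Adsorbed particles first fill the Stern layers up to an attainable
maximum `Gamma_MST = theta_s * Gamma_MST_max`; the excess fraction

    f_d = (Gamma_tot - Gamma_MST) / Gamma_tot   (0 below Gamma_MST)

resides at the d-plane, and the Stern-resident remainder is split
between the (0+1) and (1+2) plane pairs by the first-Stern fraction `R`,
with `f_0+1 + f_1+2 + f_d = 1`. `Gamma_MST_max` is the component's
limiting volume truncated at the Stern thickness times the particle
density — for FA, `0.8e-9 m³/m² × 1250 kg/m³ = 1 mg/m²`, the
completely filled FA layer. The exact functional regulating
`(theta_s, R)` from the potential profile is not published; the default
regulator is a pair of logistic functions of the two Stern potential
drops with the neutral point `(1, 0.5)` at a flat profile, `R`
increasing with the inner drop `psi0 - psi1` (which pulls the negative
functional groups toward the surface). Any replacement can be plugged in
through `regulator.override` or the `regulator` argument of
`regulate_distribution()`; the package's headline outputs were chosen to
be insensitive to its exact shape.

The charge of the (0+1) pair is split per component:
`charge_split_first_plane` defaults to 0.8 for FA — its carboxylates
ligand-exchange into inner-sphere complexes, and in CD-MUSIC terms an
inner-sphere complex places the dominant charge fraction at the surface
plane — and 0.5 for HA, whose larger particles have a weaker
inner-sphere character. This species-specific charge distribution is
what makes FA's binding robust against the potential swing caused by
accumulating NOM charge, and with it the pH-insensitive asymmetry of the
competition.

### Median affinity (ADAPT-style)

The Langmuir–Freundlich equations need a median affinity per component,

    ln K~ = -dG_ads / RT,
    dG_ads = M_int (w_elec + w_chem + w_cal) + offset,

where `w_elec` is the electrostatic work (J/kg) of transferring the
plane-assigned NICA charges from the bulk to the local plane potentials,
`w_chem = -E_LX * Qmax1 * f_0+1` a ligand-exchange term for the
first-Stern carboxylic groups (`E_LX` default 10 kJ/mol), `w_cal` a
per-mass compensation energy calibrated per component, and `offset` an
optional fixed per-particle term (J/mol, default 0). `M_int` is the
interacting mass: the current mean molar mass of the adsorbed pool times
a Stern-contact fraction `min(1, d_ST / h)`, with the layer thickness
`h = V_limit (M_w / M_w_original)^(1/3)` (slab contact geometry). FA
fits entirely inside the 0.8 nm Stern layer (contact 1); a full-size HA
layer of 3 nm has contact ≈ 0.27. Two consequences are intended: the
affinity of HA responds more weakly than linearly to its molar mass
(damping the fractionation feedback), and large particles do not earn
electrostatic energy for the part of them that never touches the compact
layer. The published energy bookkeeping lives in supporting material
that is not reproduced here; this decomposition is the package's
documented reference implementation, kept behind `median_affinity()` so
a different bookkeeping can replace it without touching the other
modules.

Calibration (`calibrate_components()`) sets `w_cal` per component from
single-component reference isotherms at pH 4: near-complete removal of
the added material at low additions and the filled-layer plateau
`0.95 * V_limit * rho_p` at high additions, reflecting that residual
solution concentrations in such systems are low (tens of mg/L). The
estimator brackets the monotone mean-deviation root and then refines by
least squares.

### Competitive partition, fractionation, and the adsorption volume

The binary Langmuir–Freundlich system shares one unoccupied-space
denominator,

    phi_p,ads / (1 - sum_p phi_p,ads) = (K~_p phi_p,sol)^(q_p),

with particle-level heterogeneity exponents `q_HA = 0.1`,
`q_FA = 0.3`, and volume fractions `phi_ads = Gamma / (V rho_p)`,
`phi_sol = C / rho_p` (`rho_p = 1250 kg/m³` for both, the midpoint of
the hydrated-to-dry range 700–1700). The mean molar mass of adsorbed HA
follows the empirical fractionation relation
`M_w = M_o + k (1 - ssr C_HA / HA_tot)` with `M_o = 1.6 kDa` and
`k = 15.4 kDa` chosen so that a fully adsorbed pool carries the original
mean of 17 kDa; adsorbed FA stays at 1.8 kDa (k = 0).

The adsorption volume `V` distinguishes the two scenarios: constant
(`V = 3e-9 m³/m²`, the single-component HA value) or variable,
`V = sum(omega_i V_i)` with `omega` the relative adsorbed volume shares
(`volume.omega_basis` switches to mass shares; at equal densities the
two coincide). Under the variable scenario, adsorbed FA shrinks the
space available to HA — the interfacial space limitation that produces
the measured asymmetry: roughly two units of HA mass leave the surface
per unit of FA mass adsorbed, while added HA barely displaces FA.

## Numerical approach

All couplings are solved simultaneously: the unknowns are the Stern
plane potentials plus one logit-transformed adsorbed fraction per
dissolved component, and the residual vector stacks the surface charge
balances (C/m²) with the log-form partition equations. A damped Newton
iteration with a step-halving line search solves the stack from a ladder
of starting loadings, warm-started along addition series (deterministic
continuation is also the tie-break if several fixed points exist); a
nested Brent/bisection fallback in the logit variables guarantees
robustness. Because everything is solved at once, the converged state
does not depend on any module update ordering.

Tolerances: charge residuals < 1e−11 C/m², partition residuals
< 1e−10 in ln units. Two boundary regimes are accepted as exact limit
solutions: complete adsorption (the equilibrium residual concentration
falls below double precision; the state is reported with the addition
fully adsorbed) and a volume-saturated layer (free space
`1 - sum(phi_ads)` below 1e−10, where the log-form residual hits its
double-precision floor `eps / (1 - S)`). Mass balance is exact by
construction in both regimes.

Problem sizes in the shipped tests were chosen to keep the full suite
in the minutes range on a single core: design series of 3–8 additions
per pH, 24-point recovery datasets, 20-seed recovery replicates, and
50-instance oracle comparisons.

## The synthetic-data generator

`generate_dataset()` replays a batch design through the model under
ground-truth parameters and applies multiplicative Gaussian noise
(default 2% relative standard deviation, truncated at zero) to the
adsorbed amounts, because duplicate-measurement scatter in batch
adsorption data scales with the signal; solution concentrations are then
recomputed so each row still closes its mass balance. It emulates the
study conditions (1 g/L goethite, 0.01 M NaCl, pH 4 and 6, the HA/FA
addition series above). It does not emulate filtration losses, pH drift
and readjustment, the error structure of spectroscopic HA/FA
quantification in mixtures, particle aggregation, or kinetics — passing
recovery tests therefore demonstrate statistical identifiability under
ideal sampling, not robustness to those real-world artifacts.
`recover_parameters()` is the matching harness: bounded least squares
over up to three configuration parameters with Gauss–Newton standard
errors.

## Design choices where the design was open

* **Volume shares in the mixing rule.** The weights `omega` are
  interpreted as shares of occupied volume (dimensionally consistent
  with a volume-weighted mean); mass shares are available as a
  configuration switch and coincide at equal densities.
* **Per-component Stern maxima.** `Gamma_MST_max` is derived per
  component from its limiting volume truncated at the Stern thickness,
  rather than shared across components.
* **Exchange-ratio regression.** Desorbed amounts are computed against
  the zero-competitor baseline at the same pH and the same own-addition;
  ordinary least squares with a free intercept is the default, an
  origin-constrained variant is available.
* **Recovery designs.** Identifiability drives the choice: the HA
  heterogeneity exponent is estimated from single-HA isotherms at pH 6,
  where adsorption is affinity-limited (at pH 4 low additions adsorb
  quantitatively and carry no information about `q`).

## Known limitations

* Absolute adsorbed amounts depend on the per-component calibration;
  only the structure (plateaus, asymmetry, scenario contrast) is
  parameter-free. The published site-specific parameter tables for this
  goethite and these NOM extracts are not available, so generic values
  stand in and are fully overridable.
* Coupling the median affinity to the fractionation-updated molar mass
  makes the high-loading end of HA isotherms flatten and, in mixtures,
  decline by a few percent past the plateau onset — within the
  measurement scatter the model is meant to describe, but visible in
  noise-free simulations.
* The offset calibration inherits a soft direction from the plateau:
  2% amplitude noise on a plateau-dominated reference corresponds to
  several ln-units of affinity, so calibrated offsets carry a
  few-percent uncertainty.
* Proton-only NICA: no metal-cation competition, no Donnan phase for
  dissolved NOM, at most two NOM components, no oxyanion ternary
  systems.
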