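test_that("point of zero charge sits at the intrinsic protonation constant", {
  expect_equal(compute_pzc(), 9.3, tolerance = 1e-6)

  ## PZC is set by intrinsic constants, not by the Stern capacitances
  cfg <- config_set(lcd_config(), "edl.C1_F_m2", 1.8)
  cfg <- config_set(cfg, "edl.C2_F_m2", 1.48)
  expect_equal(compute_pzc(cfg), 9.3, tolerance = 1e-6)

  ## root finder agrees with a dense grid scan
  grid <- seq(9.0, 9.6, by = 0.001)
  net <- vapply(grid, function(p) {
    solve_surface_state(p, 0.01)$net_surface_charge
  }, numeric(1))
  i <- which(diff(sign(net)) != 0)[1]
  expect_lt(abs(compute_pzc() - grid[i]), 0.002)

  ## bare surface: positive below PZC, negative above
  expect_gt(solve_surface_state(5, 0.01)$net_surface_charge, 0)
  expect_lt(solve_surface_state(11, 0.01)$net_surface_charge, 0)
})

test_that("surface solver matches the independent nested-bisection oracle", {
  cfg <- lcd_config()
  st <- solve_surface_state(4, 0.01, config = cfg)
  orc <- oracle_surface_bisect(cfg, 4, 0.01)
  expect_lt(abs(st$net_surface_charge - orc$net_charge), 1e-10)
  expect_lt(max(abs(unname(st$psi[1:3]) - orc$psi)), 1e-9)

  ## equivalence over random (pH, I) instances, with and without NOM charge
  set.seed(11)
  for (k in 1:20) {
    pH <- runif(1, 3, 11)
    I <- 10^runif(1, -3, -0.5)
    nom <- if (k %% 2) c(0, 0, 0, 0) else
      -runif(4, 0, 0.05) * c(1, 1, 0.5, 0.5)
    st <- solve_surface_state(pH, I, nom, cfg)
    orc <- oracle_surface_bisect(cfg, pH, I, nom)
    expect_lt(abs(st$net_surface_charge - orc$net_charge), 1e-10)
  }
})

test_that("every converged state is electroneutral below 1e-10 C/m2", {
  for (pH in c(3, 4.7, 6, 9.3, 10.5)) {
    st <- solve_surface_state(pH, 0.01)
    expect_lt(abs(sum(st$sigma)), 1e-10)
    fr <- st$species_fractions
    for (f in fr) expect_equal(sum(f), 1, tolerance = 1e-12)
  }
  st <- solve_surface_state(4, 0.01, c(-0.1, -0.05, -0.02, -0.03))
  expect_lt(abs(sum(st$sigma)), 1e-10)
})

test_that("solution is independent of the initial guess", {
  inits <- list(c(0.4, 0.3, 0.2), c(0, 0, 0), c(-0.3, -0.2, -0.1))
  states <- lapply(inits, function(i) {
    solve_surface_state(5.5, 0.01, init = i)
  })
  for (s in states[-1]) {
    expect_equal(unname(s$psi), unname(states[[1]]$psi), tolerance = 1e-9)
  }
})

test_that("zero potentials reduce speciation to the intrinsic prediction", {
  cfg <- lcd_config()
  sctx <- lcdcc:::surface_context(cfg)
  sp <- lcdcc:::surf_speciation(sctx, 4, 0.01, 0, 0)
  ## Boltzmann factors all 1: fractions follow directly from K and activities
  gam <- 10^(-0.509 * (sqrt(0.01) / (1 + sqrt(0.01)) - 0.3 * 0.01))
  s1 <- 10^9.3 * 1e-4
  s2 <- 10^-1 * gam * 0.01
  s3 <- s1 * 10^-1 * gam * 0.01
  den <- 1 + s1 + s2 + s3
  expect_equal(unname(sp$fractions$FeOH["protonated"]), s1 / den,
               tolerance = 1e-12)
  expect_equal(unname(sp$fractions$FeOH["Na_pair"]), s2 / den,
               tolerance = 1e-12)
})

test_that("charging curve is tabulated per grid point and monotone", {
  one <- charging_curve(9.3, 0.01)
  expect_equal(nrow(one), 1L)
  expect_lt(abs(one$net_charge), 1e-10)

  cc <- charging_curve(seq(3, 11, by = 0.5), 0.01)
  expect_equal(nrow(cc), 17L)
  expect_true(all(diff(cc$net_charge) < 0))
  expect_error(charging_curve(c(4, 3, 5)), class = "lcdcc_validation_error")
})

test_that("basic Stern topology solves and stays electroneutral", {
  cfg <- config_set(lcd_config(), "edl.topology", "basic")
  st <- solve_surface_state(4, 0.01, config = cfg)
  expect_lt(abs(sum(st$sigma)), 1e-10)
  expect_equal(unname(st$psi["psi2"]), unname(st$psi["psi1"]))
  ## PZC unchanged by topology
  expect_equal(compute_pzc(cfg), 9.3, tolerance = 1e-6)
})

test_that("inputs outside the model domain are rejected", {
  expect_error(solve_surface_state(1, 0.01), class = "lcdcc_validation_error")
  expect_error(solve_surface_state(7, -1), class = "lcdcc_validation_error")
  cfg <- lcd_config()
  cfg$edl$C1_F_m2 <- -1
  expect_error(solve_surface_state(7, 0.01, config = cfg),
               class = "lcdcc_config_error")
})
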