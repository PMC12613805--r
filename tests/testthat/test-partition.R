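test_that("single-component LF isotherm has the known closed-form values", {
  expect_equal(lf_isotherm(1, 1, 1), 0.5)           # Langmuir midpoint
  expect_equal(lf_isotherm(10, 0.5, 0), 0)
  expect_equal(lf_isotherm(4, 0.5, 1), 2 / 3, tolerance = 1e-12)
  expect_error(lf_isotherm(-1, 0.5, 0.1), class = "lcdcc_validation_error")
  expect_error(lf_isotherm(1, 2, 0.1), class = "lcdcc_validation_error")
})

test_that("binary partition degenerates to the single-component solution", {
  sys <- system_composition(160, 0, pH = 4)
  ps <- solve_binary_partition(K_HA = exp(12), K_FA = exp(10),
                               q_HA = 0.4, q_FA = 0.6, sys, V = 3e-9)
  ## independent single-component root in Gamma
  f <- function(G) {
    C <- 160 - G * 96
    phis <- C * 1e-3 / 1250
    phia <- G * 1e-6 / (3e-9 * 1250)
    0.4 * (12 + log(phis)) - log(phia) + log1p(-phia)
  }
  G1 <- uniroot(f, c(1e-10, 160 / 96 - 1e-10), tol = 1e-14)$root
  expect_equal(ps$Gamma_mg_m2$HA, G1, tolerance = 1e-8)
  expect_equal(ps$Gamma_mg_m2$FA, 0)
})

test_that("fully symmetric binary inputs give identical adsorbed amounts", {
  sys <- system_composition(120, 120, pH = 4)
  ps <- solve_binary_partition(K_HA = exp(11), K_FA = exp(11),
                               q_HA = 0.5, q_FA = 0.5, sys, V = 2e-9)
  expect_equal(ps$Gamma_mg_m2$HA, ps$Gamma_mg_m2$FA, tolerance = 1e-9)
})

test_that("binary partition matches the 2-D grid-refinement oracle", {
  set.seed(7)
  for (k in 1:10) {
    lnK <- runif(2, 6, 14)
    qq <- runif(2, 0.3, 1)
    T_ <- c(runif(1, 20, 240), runif(1, 25, 200))
    V <- runif(1, 0.8e-9, 3e-9)
    sys <- system_composition(T_[1], T_[2], pH = 4)
    ps <- solve_binary_partition(NA, NA, qq[1], qq[2], sys, V,
                                 ln_K_HA = lnK[1], ln_K_FA = lnK[2])
    orc <- oracle_grid_binary(lnK, qq, T_, 96, V, c(1250, 1250))
    expect_lt(abs(ps$phi_ads$HA - orc["HA"]), 1e-6)
    expect_lt(abs(ps$phi_ads$FA - orc["FA"]), 1e-6)
    expect_true(all(ps$mass_balance_rel < 1e-10))
  }
})

test_that("q = 1 with equal volumes reduces to classical competitive Langmuir", {
  V <- 2e-9
  K <- exp(c(10, 11))
  sys <- system_composition(150, 100, pH = 4)
  ps <- solve_binary_partition(K[1], K[2], 1, 1, sys, V)
  orc <- oracle_competitive_langmuir(K, c(150, 100), 96, V, c(1250, 1250))
  expect_equal(ps$phi_ads$HA, unname(orc["HA"]), tolerance = 1e-8)
  expect_equal(ps$phi_ads$FA, unname(orc["FA"]), tolerance = 1e-8)
})

test_that("adsorption responds monotonically to own and competing additions", {
  base <- function(T_HA, T_FA) {
    sys <- system_composition(T_HA, T_FA, pH = 4)
    solve_binary_partition(NA, NA, 0.5, 0.5, sys, 2e-9,
                           ln_K_HA = 10, ln_K_FA = 10)$Gamma_mg_m2
  }
  own <- vapply(c(40, 80, 160, 240), function(t) base(t, 100)$HA, numeric(1))
  expect_true(all(diff(own) > 0))
  comp <- vapply(c(0, 50, 100, 200), function(t) base(160, t)$HA, numeric(1))
  expect_true(all(diff(comp) < 0))
})

test_that("the coupled solve reduces to the bare surface without NOM", {
  st <- lcd_solve(system_composition(0, 0, pH = 4), lcd_config())
  bare <- solve_surface_state(4, 0.01)
  expect_equal(unname(st$surface$psi), unname(bare$psi), tolerance = 1e-9)
  expect_equal(st$partition$Gamma_mg_m2$HA, 0)
  expect_equal(st$partition$Gamma_mg_m2$FA, 0)
})

test_that("single-FA systems make the volume scenarios coincide", {
  cal <- calibrated_config()
  cal2 <- config_set(cal, "volume.V_constant_m3_m2", 0.8e-9)
  a <- lcd_solve(system_composition(0, 100, pH = 4), cal2, scenario = "constant")
  b <- lcd_solve(system_composition(0, 100, pH = 4), cal2, scenario = "variable")
  expect_equal(a$partition$Gamma_mg_m2$FA, b$partition$Gamma_mg_m2$FA,
               tolerance = 1e-8)
  expect_equal(a$V_m3_m2, b$V_m3_m2)
})

test_that("space limitation lowers HA adsorption under the variable volume", {
  cal <- calibrated_config()
  v <- lcd_solve(system_composition(160, 200, pH = 4), cal, scenario = "variable")
  c <- lcd_solve(system_composition(160, 200, pH = 4), cal, scenario = "constant")
  expect_lt(v$partition$Gamma_mg_m2$HA, c$partition$Gamma_mg_m2$HA)
  ## mixture volume lies between the single-component limits
  expect_gte(v$V_m3_m2, 0.8e-9)
  expect_lte(v$V_m3_m2, 3e-9)
})

test_that("converged coupled states close their mass balance and charge balance", {
  cal <- calibrated_config()
  for (case in list(c(100, 50, 4), c(160, 100, 6), c(20, 200, 4))) {
    st <- lcd_solve(system_composition(case[1], case[2], pH = case[3]), cal)
    expect_true(all(st$partition$mass_balance_rel < 1e-10))
    expect_lt(abs(sum(st$surface$sigma)), 1e-10)
    S <- st$partition$phi_ads$HA + st$partition$phi_ads$FA
    expect_lt(S, 1 + 1e-9)
  }
})

test_that("conditional mode reproduces the predictive solution when fed it", {
  cal <- calibrated_config()
  pred <- lcd_solve(system_composition(160, 100, pH = 4), cal)
  cond <- lcd_solve(system_composition(160, 100, pH = 4), cal,
                    mode = "conditional",
                    conditional_fixed = list(
                      component = "FA",
                      Gamma_mg_m2 = pred$partition$Gamma_mg_m2$FA))
  expect_equal(cond$partition$Gamma_mg_m2$HA, pred$partition$Gamma_mg_m2$HA,
               tolerance = 1e-6)
  expect_error(lcd_solve(system_composition(160, 100, pH = 4), cal,
                         mode = "conditional"),
               class = "lcdcc_validation_error")
})
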