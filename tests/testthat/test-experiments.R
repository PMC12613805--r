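test_that("run_design tabulates every design point including baselines", {
  d <- experiment_design("custom", fixed_component = "FA", fixed_mg_L = 50,
                         varied_component = "HA",
                         varied_series_mg_L = c(40, 120), pH_values = 4)
  tb <- run_design(d, calibrated_config())
  ## fixed in {0, 50} x varied in {0, 40, 120}
  expect_equal(nrow(tb), 6L)
  blank <- tb[tb$HA_added_mg_L == 0 & tb$FA_added_mg_L == 0, ]
  expect_equal(blank$HA_ads_mg_m2, 0)
  expect_equal(blank$FA_ads_mg_m2, 0)
  expect_true(all(tb$converged))
  ## per-row mass balance
  ok <- abs(tb$HA_added_mg_L - tb$HA_sol_mg_L - tb$HA_ads_mg_m2 * 96) <
    1e-8 * pmax(tb$HA_added_mg_L, 1)
  expect_true(all(ok))
})

test_that("competitive trends along the HA series have the expected direction", {
  cal <- calibrated_config()
  d <- experiment_design("ExpI", cal, pH_values = 4,
                         varied_series_mg_L = c(20, 80, 145, 240))
  tb <- run_design(d, cal)
  mix <- tb[tb$FA_added_mg_L > 0 & tb$HA_added_mg_L > 0, ]
  mix <- mix[order(mix$HA_added_mg_L), ]
  ## HA adsorption rises along its addition series and FA falls; on the HA
  ## plateau the molar-mass feedback allows a small (<6%) wiggle
  ha <- mix$HA_ads_mg_m2
  fa <- mix$FA_ads_mg_m2
  expect_gt(ha[length(ha)], 3 * ha[1])
  expect_true(all(diff(ha) > -0.06 * max(ha)))
  expect_lt(fa[length(fa)], 0.75 * fa[1])
  expect_true(all(diff(fa) < 0.03 * max(fa)))
  ## variable-scenario mixture volume stays inside the component limits
  expect_true(all(mix$V_m3_m2 >= 0.8e-9 & mix$V_m3_m2 <= 3e-9))
})

test_that("exchange ratio equals the closed-form least-squares slope", {
  mk <- function(fa_ads, ha_ads) {
    ## first row is the zero-FA baseline
    n <- length(fa_ads)
    tibble::tibble(
      design_id = "ExpII", pH = 4,
      HA_added_mg_L = 160, FA_added_mg_L = c(0, seq_len(n - 1) * 25),
      HA_ads_mg_m2 = ha_ads,
      FA_ads_mg_m2 = fa_ads,
      HA_sol_mg_L = 0, FA_sol_mg_L = 0, V_m3_m2 = 3e-9,
      M_w_HA_ads_kDa = 17, M_w_mix_kDa = 17,
      scenario = "variable", mode = "predictive", converged = TRUE)
  }
  ## exact synthetic line with slope 2
  x <- c(0, 0.1, 0.2, 0.3, 0.4)
  tb <- mk(fa_ads = x, ha_ads = 1.5 - 2 * x)
  er <- exchange_ratio(tb, "HA")
  expect_equal(er$slope, 2, tolerance = 1e-12)
  expect_equal(er$se, 0, tolerance = 1e-10)
  ## no desorption: slope 0
  tb0 <- mk(fa_ads = x, ha_ads = rep(1.5, 5))
  expect_equal(exchange_ratio(tb0, "HA")$slope, 0, tolerance = 1e-12)
  ## random scatter against the normal equations
  set.seed(9)
  y <- 1.5 - 2 * x + c(0, rnorm(4, 0, 0.05))
  tb2 <- mk(fa_ads = x, ha_ads = y)
  er2 <- exchange_ratio(tb2, "HA")
  des <- x[-1]
  dep <- y[1] - y[-1]
  beta <- sum((des - mean(des)) * (dep - mean(dep))) /
    sum((des - mean(des))^2)
  expect_lt(abs(er2$slope - beta), 1e-12)
  ## intercept-free option
  er3 <- exchange_ratio(tb2, "HA", intercept = FALSE)
  expect_lt(abs(er3$slope - sum(des * dep) / sum(des^2)), 1e-12)
  ## too few points
  expect_error(exchange_ratio(mk(x, 1.5 - 2 * x)[1:3, ], "HA"),
               class = "lcdcc_validation_error")
})

test_that("rmse matches an independent two-pass computation", {
  tb <- expII_table_pH4()
  expect_equal(rmse(tb, tb, "HA"), 0)
  shifted <- tb
  shifted$HA_ads_mg_m2 <- shifted$HA_ads_mg_m2 + 0.25
  expect_equal(rmse(shifted, tb, "HA"), 0.25, tolerance = 1e-12)
  set.seed(13)
  noisy <- tb
  noisy$FA_ads_mg_m2 <- noisy$FA_ads_mg_m2 + rnorm(nrow(tb), 0, 0.1)
  d <- noisy$FA_ads_mg_m2 - tb$FA_ads_mg_m2
  expect_lt(abs(rmse(noisy, tb, "FA") - sqrt(sum(d^2) / length(d))), 1e-12)
  expect_error(rmse(tb[-1, ], tb, "HA"), class = "lcdcc_validation_error")
})

test_that("variable volume fits space-limited data better than constant volume", {
  cal <- calibrated_config()
  d <- small_design("ExpII", 4, cal)
  obs <- generate_dataset(d, cal, scenario = "variable", noise_sd = 0.02,
                          seed = 101)
  pred_var <- run_design(d, cal, scenario = "variable")
  pred_con <- run_design(d, cal, scenario = "constant")
  obs$scenario <- "x"; pred_var$scenario <- "x"; pred_con$scenario <- "x"
  expect_lt(rmse(pred_var, obs, "HA"), rmse(pred_con, obs, "HA"))
})

test_that("sensitivity sweeps vary one parameter at a time", {
  cal <- calibrated_config()
  d <- experiment_design("custom", fixed_component = "HA", fixed_mg_L = 0,
                         varied_component = "FA",
                         varied_series_mg_L = c(50, 150), pH_values = 4)
  ## single-value sweep equals a plain run
  sw <- sensitivity_sweep("q_FA", 0.3, d, cal,
                          output_metric = "max_FA_ads_mg_m2")
  plain <- run_design(d, cal)
  expect_equal(sw$metric_value, max(plain$FA_ads_mg_m2), tolerance = 1e-9)
  ## three densities, three rows
  sw2 <- sensitivity_sweep("rho_p", c(700, 1250, 1700), d, cal,
                           output_metric = "max_FA_ads_mg_m2")
  expect_equal(nrow(sw2), 3L)
  expect_true(all(is.finite(sw2$metric_value)))
  expect_error(sensitivity_sweep("nom.FA.nope", 1, d, cal),
               class = "lcdcc_config_error")
})
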