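test_that("the generator is exact at zero noise and seed-reproducible", {
  cal <- calibrated_config()
  d <- small_design("ExpII", 4, cal)
  clean <- run_design(d, cal)
  g0 <- generate_dataset(d, cal, noise_sd = 0, seed = 1)
  expect_identical(g0, clean)

  g1 <- generate_dataset(d, cal, noise_sd = 0.02, seed = 7, clean = clean)
  g2 <- generate_dataset(d, cal, noise_sd = 0.02, seed = 7, clean = clean)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_isotherm(g1, f1)
  write_isotherm(g2, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  ## different seed, different data
  g3 <- generate_dataset(d, cal, noise_sd = 0.02, seed = 8, clean = clean)
  expect_false(identical(g1$HA_ads_mg_m2, g3$HA_ads_mg_m2))
  ## noisy rows still close their mass balance
  ok <- abs(g1$HA_added_mg_L - g1$HA_sol_mg_L - g1$HA_ads_mg_m2 * 96) <
    1e-8 * pmax(g1$HA_added_mg_L, 1)
  expect_true(all(ok))
})

test_that("the applied relative noise has the requested magnitude", {
  cal <- calibrated_config()
  d <- experiment_design("custom", cal, fixed_component = "FA", fixed_mg_L = 0,
                         varied_component = "HA",
                         varied_series_mg_L = seq(20, 240, length.out = 24),
                         pH_values = 6)
  clean <- run_design(d, cal)
  noisy <- generate_dataset(d, cal, noise_sd = 0.02, seed = 3, clean = clean)
  pos <- clean$HA_ads_mg_m2 > 0
  rel <- noisy$HA_ads_mg_m2[pos] / clean$HA_ads_mg_m2[pos] - 1
  expect_gt(sd(rel), 0.01)
  expect_lt(sd(rel), 0.03)
})

test_that("parameter recovery is exact on noise-free data", {
  cal <- calibrated_config()
  d <- experiment_design("custom", cal, fixed_component = "FA", fixed_mg_L = 0,
                         varied_component = "HA",
                         varied_series_mg_L = seq(40, 240, length.out = 8),
                         pH_values = 6)
  data <- run_design(d, cal)
  est <- recover_parameters(data, "q_HA", cal, bounds = list(q_HA = c(0.02, 0.6)),
                            tol = 1e-6)
  expect_lt(abs(est$estimate - 0.1), 1e-4)
  expect_lt(attr(est, "sse"), 1e-8)
})

test_that("the FA limiting volume is identifiable from its own isotherm", {
  cal <- calibrated_config()
  d <- experiment_design("custom", cal, fixed_component = "HA", fixed_mg_L = 0,
                         varied_component = "FA",
                         varied_series_mg_L = seq(25, 200, length.out = 6),
                         pH_values = 4)
  data <- run_design(d, cal)
  est <- recover_parameters(data, "V_FA", cal,
                            bounds = list(V_FA = c(2e-10, 3e-9)), tol = 1e-13)
  expect_lt(abs(est$estimate - 0.8e-9) / 0.8e-9, 0.01)
})

test_that("estimates are invariant to the row order of the data", {
  cal <- calibrated_config()
  d <- experiment_design("custom", cal, fixed_component = "FA", fixed_mg_L = 0,
                         varied_component = "HA",
                         varied_series_mg_L = c(60, 120, 180, 240),
                         pH_values = 6)
  data <- generate_dataset(d, cal, noise_sd = 0.02, seed = 5)
  perm <- withr::with_seed(6, sample(nrow(data)))
  e1 <- recover_parameters(data, "q_HA", cal,
                           bounds = list(q_HA = c(0.02, 0.6)), tol = 1e-4)
  e2 <- recover_parameters(data[perm, ], "q_HA", cal,
                           bounds = list(q_HA = c(0.02, 0.6)), tol = 1e-4)
  expect_equal(e1$estimate, e2$estimate, tolerance = 1e-8)
})

test_that("invalid recovery requests are refused", {
  cal <- calibrated_config()
  d <- small_design("ExpII", 4, cal)
  data <- run_design(d, cal)
  expect_error(recover_parameters(data, c("q_HA", "q_FA", "V_HA", "V_FA"), cal),
               class = "lcdcc_validation_error")
  expect_error(recover_parameters(data[1, ], "q_HA", cal),
               class = "lcdcc_validation_error")
})
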