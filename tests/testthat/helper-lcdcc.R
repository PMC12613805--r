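## Shared test state: single-component plateau calibration is deterministic
## but costs a few seconds, so it is computed once per session.
.lcdcc_cache <- new.env(parent = emptyenv())

calibrated_config <- function() {
  if (is.null(.lcdcc_cache$cal)) {
    .lcdcc_cache$cal <- calibrate_components(lcd_config(), pH = 4)
  }
  .lcdcc_cache$cal
}

## Small design used by several tests: both canonical designs thinned to
## 3 varied additions at one pH.
small_design <- function(id = "ExpII", pH = 4, cfg = lcd_config()) {
  if (id == "ExpII") {
    experiment_design("ExpII", cfg, pH_values = pH,
                      varied_series_mg_L = c(50, 125, 200))
  } else {
    experiment_design("ExpI", cfg, pH_values = pH,
                      varied_series_mg_L = c(50, 145, 240))
  }
}

expII_table_pH4 <- function() {
  if (is.null(.lcdcc_cache$expII4)) {
    cfg <- calibrated_config()
    .lcdcc_cache$expII4 <- run_design(experiment_design("ExpII", cfg,
                                                        pH_values = 4),
                                      cfg, scenario = "variable")
  }
  .lcdcc_cache$expII4
}
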