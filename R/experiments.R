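## ---- In-silico batch experiment designs and evaluation ---------------------

#' Define a batch competition experiment design
#'
#' The two canonical designs mirror the measured series: `"ExpI"` varies HA
#' (20-240 mg/L) at fixed FA (0 or 100 mg/L), `"ExpII"` varies FA
#' (25-200 mg/L) at fixed HA (0 or 160 mg/L); both at 1 g/L goethite in
#' 0.01 M NaCl, pH 4 and 6. Zero-competitor and zero-addition baselines are
#' generated automatically by [run_design()].
#'
#' @param design_id `"ExpI"`, `"ExpII"` or `"custom"`.
#' @param config Configuration supplying the default series.
#' @param fixed_component,fixed_mg_L Fixed component and its addition (used
#'   for `"custom"`, defaulted for the canonical designs).
#' @param varied_component,varied_series_mg_L Varied component and its
#'   addition series.
#' @param pH_values Suspension pH values.
#' @param solid_g_L Goethite concentration, g/L.
#' @param ionic_strength_M Background electrolyte, mol/L.
#' @return An `experiment_design` list.
#' @export
experiment_design <- function(design_id = c("ExpI", "ExpII", "custom"),
                              config = lcd_config(),
                              fixed_component = NULL, fixed_mg_L = NULL,
                              varied_component = NULL,
                              varied_series_mg_L = NULL,
                              pH_values = config$experiment$pH_values,
                              solid_g_L = config$experiment$solid_g_L,
                              ionic_strength_M = config$experiment$ionic_strength_M) {
  design_id <- match.arg(design_id)
  ex <- config$experiment
  if (design_id == "ExpI") {
    fixed_component <- fixed_component %||% "FA"
    fixed_mg_L <- fixed_mg_L %||% ex$ExpI_fixed_FA_mg_L
    varied_component <- varied_component %||% "HA"
    varied_series_mg_L <- varied_series_mg_L %||% ex$ExpI_HA_series_mg_L
  } else if (design_id == "ExpII") {
    fixed_component <- fixed_component %||% "HA"
    fixed_mg_L <- fixed_mg_L %||% ex$ExpII_fixed_HA_mg_L
    varied_component <- varied_component %||% "FA"
    varied_series_mg_L <- varied_series_mg_L %||% ex$ExpII_FA_series_mg_L
  }
  if (is.null(fixed_component) || is.null(varied_component) ||
      is.null(fixed_mg_L) || is.null(varied_series_mg_L)) {
    stop_validation("custom designs need fixed/varied components and concentrations")
  }
  if (fixed_component == varied_component) {
    stop_validation("fixed and varied components must differ")
  }
  if (any(varied_series_mg_L < 0) || fixed_mg_L < 0) {
    stop_validation("concentrations must be non-negative")
  }
  structure(list(
    design_id = design_id,
    fixed_component = fixed_component, fixed_mg_L = fixed_mg_L,
    varied_component = varied_component,
    varied_series_mg_L = sort(unique(varied_series_mg_L)),
    pH_values = pH_values, solid_g_L = solid_g_L,
    ionic_strength_M = ionic_strength_M
  ), class = "experiment_design")
}

#' Run an experimental design through the model
#'
#' Simulates every (pH, fixed-addition, varied-addition) combination of the
#' design -- including the zero-competitor baselines and the blank -- with
#' [lcd_solve()], warm-starting each point from its predecessor along the
#' addition series. Failed points are kept as rows with `converged = FALSE`
#' and missing adsorbed amounts.
#'
#' @param design An [experiment_design()].
#' @param config An [lcd_config()] configuration.
#' @param scenario `"variable"` or `"constant"` adsorption volume.
#' @param mode `"predictive"` or `"conditional"`.
#' @param observed For conditional mode: an isotherm table supplying the
#'   measured adsorption of the fixed component, matched by pH and additions.
#' @return An isotherm tibble (class `lcd_isotherm`): one row per design
#'   point with additions (mg/L), adsorbed amounts (mg/m2), solution
#'   concentrations (mg/L), the adsorption volume, the adsorbed-HA and
#'   mixture molar masses (kDa), and diagnostics.
#' @export
run_design <- function(design, config = lcd_config(),
                       scenario = c("variable", "constant"),
                       mode = c("predictive", "conditional"),
                       observed = NULL) {
  ctx <- if (inherits(config, "lcd_model_context")) config else
    structure(build_model_context(config), class = "lcd_model_context")
  scenario <- if (missing(scenario)) ctx$config$scenario else match.arg(scenario)
  mode <- match.arg(mode)
  fixed_levels <- unique(c(0, design$fixed_mg_L))
  varied_levels <- unique(c(0, design$varied_series_mg_L))
  rows <- list()
  for (pH in design$pH_values) {
    for (fx in fixed_levels) {
      prev <- NULL
      for (vx in varied_levels) {
        adds <- setNames(c(fx, vx), c(design$fixed_component,
                                      design$varied_component))
        sys <- system_composition(
          HA_tot_mg_L = adds[["HA"]], FA_tot_mg_L = adds[["FA"]], pH = pH,
          solid_g_L = design$solid_g_L,
          ionic_strength_M = design$ionic_strength_M,
          area_m2_g = ctx$config$surface$specific_surface_area_m2_g)
        cond <- NULL
        if (mode == "conditional" && adds[[design$fixed_component]] > 0) {
          if (is.null(observed)) {
            stop_validation("conditional mode requires an observed table")
          }
          obs_row <- observed[observed$pH == pH &
                                observed$HA_added_mg_L == adds[["HA"]] &
                                observed$FA_added_mg_L == adds[["FA"]], ]
          if (nrow(obs_row) != 1) {
            stop_validation("observed table must match each conditional design point exactly once")
          }
          cond <- list(component = design$fixed_component,
                       Gamma_mg_m2 = obs_row[[paste0(design$fixed_component,
                                                     "_ads_mg_m2")]])
        }
        st <- tryCatch(
          lcd_solve(sys, ctx, scenario = scenario,
                    mode = if (is.null(cond)) "predictive" else "conditional",
                    conditional_fixed = cond, init = prev),
          lcdcc_convergence_error = function(e) NULL)
        rows[[length(rows) + 1L]] <- isotherm_row(design$design_id, sys, st,
                                                  scenario, mode)
        if (!is.null(st)) prev <- st
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("lcd_isotherm", class(out))
  out
}

isotherm_row <- function(design_id, sys, st, scenario, mode) {
  if (is.null(st)) {
    return(tibble::tibble(
      design_id = design_id, pH = sys$pH,
      HA_added_mg_L = sys$HA_tot_mg_L, FA_added_mg_L = sys$FA_tot_mg_L,
      HA_ads_mg_m2 = NA_real_, FA_ads_mg_m2 = NA_real_,
      HA_sol_mg_L = NA_real_, FA_sol_mg_L = NA_real_,
      V_m3_m2 = NA_real_, M_w_HA_ads_kDa = NA_real_, M_w_mix_kDa = NA_real_,
      scenario = scenario, mode = mode, converged = FALSE))
  }
  G <- st$partition$Gamma_mg_m2
  tot <- G$HA + G$FA
  tibble::tibble(
    design_id = design_id, pH = sys$pH,
    HA_added_mg_L = sys$HA_tot_mg_L, FA_added_mg_L = sys$FA_tot_mg_L,
    HA_ads_mg_m2 = G$HA, FA_ads_mg_m2 = G$FA,
    HA_sol_mg_L = st$partition$C_mg_L$HA, FA_sol_mg_L = st$partition$C_mg_L$FA,
    V_m3_m2 = st$V_m3_m2,
    M_w_HA_ads_kDa = st$M_w_kDa$HA,
    M_w_mix_kDa = if (tot > 0) mw_mixture(st$M_w_kDa$HA, st$M_w_kDa$FA,
                                          G$HA / tot) else NA_real_,
    scenario = scenario, mode = mode, converged = TRUE)
}

#' Exchange ratio: mass desorbed per unit mass of competitor adsorbed
#'
#' For each point of an isotherm table where the competitor is present, the
#' desorbed amount of the displaced component is computed relative to its
#' zero-competitor baseline at the same pH and the same own addition, and
#' regressed against the competitor's adsorbed amount (ordinary least
#' squares; intercept optional). The slope is the exchange ratio (mg
#' desorbed per mg adsorbed).
#'
#' @param table An isotherm tibble from [run_design()] (must contain the
#'   zero-competitor baseline rows).
#' @param displaced `"HA"` or `"FA"`: the component being displaced.
#' @param pH Optional pH filter (default: all pH values pooled).
#' @param intercept Fit with a free intercept (default) or through the
#'   origin.
#' @return A one-row tibble: `displaced`, `slope`, `se`, `intercept`,
#'   `n`, `r_squared`.
#' @export
exchange_ratio <- function(table, displaced = c("HA", "FA"), pH = NULL,
                           intercept = TRUE) {
  displaced <- match.arg(displaced)
  competitor <- setdiff(c("HA", "FA"), displaced)
  d_add <- paste0(displaced, "_added_mg_L")
  c_add <- paste0(competitor, "_added_mg_L")
  d_ads <- paste0(displaced, "_ads_mg_m2")
  c_ads <- paste0(competitor, "_ads_mg_m2")
  tb <- table[table$converged %in% TRUE, ]
  if (!is.null(pH)) tb <- tb[tb$pH %in% pH, ]
  pts <- tb[tb[[c_add]] > 0 & tb[[d_add]] > 0, ]
  base <- tb[tb[[c_add]] == 0, ]
  if (nrow(pts) == 0) stop_validation("no points with positive competitor addition")
  desorbed <- vapply(seq_len(nrow(pts)), function(i) {
    b <- base[base$pH == pts$pH[i] & base[[d_add]] == pts[[d_add]][i], ]
    if (nrow(b) != 1) return(NA_real_)
    b[[d_ads]] - pts[[d_ads]][i]
  }, numeric(1))
  x <- pts[[c_ads]]
  keep <- is.finite(desorbed) & is.finite(x) & x > 0
  if (sum(keep) < 3) {
    stop_validation("need at least 3 valid points with positive competitor adsorption")
  }
  df <- data.frame(y = desorbed[keep], x = x[keep])
  fit <- if (intercept) lm(y ~ x, data = df) else lm(y ~ 0 + x, data = df)
  sm <- summary(fit)
  co <- sm$coefficients
  tibble::tibble(
    displaced = displaced,
    slope = unname(co["x", "Estimate"]),
    se = unname(co["x", "Std. Error"]),
    intercept = if (intercept) unname(co["(Intercept)", "Estimate"]) else 0,
    n = nrow(df),
    r_squared = sm$r.squared
  )
}

#' Root mean square error between two isotherm tables
#'
#' Matches rows on design point (pH and both additions) and returns the RMSE
#' of the adsorbed amounts of one component, in mg/m2.
#'
#' @param predicted,observed Isotherm tibbles with matching design points.
#' @param component `"HA"` or `"FA"`.
#' @return RMSE in mg/m2.
#' @export
rmse <- function(predicted, observed, component = c("HA", "FA")) {
  component <- match.arg(component)
  col <- paste0(component, "_ads_mg_m2")
  keys <- c("pH", "HA_added_mg_L", "FA_added_mg_L")
  for (k in c(keys, col)) {
    if (!k %in% names(predicted) || !k %in% names(observed)) {
      stop_validation(paste0("both tables must carry column ", k))
    }
  }
  j <- dplyr::inner_join(
    predicted[, c(keys, col)], observed[, c(keys, col)],
    by = keys, suffix = c("_pred", "_obs"))
  if (nrow(j) != nrow(predicted) || nrow(j) != nrow(observed)) {
    stop_validation("predicted and observed tables do not match row for row")
  }
  pr <- j[[paste0(col, "_pred")]]
  ob <- j[[paste0(col, "_obs")]]
  ok <- is.finite(pr) & is.finite(ob)
  sqrt(mean((pr[ok] - ob[ok])^2))
}

param_alias <- function(name) {
  map <- list(
    q_HA = "nom.HA.q", q_FA = "nom.FA.q",
    V_HA = "nom.HA.V_limit_m3_m2", V_FA = "nom.FA.V_limit_m3_m2",
    rho_HA = "nom.HA.rho_p_kg_m3", rho_FA = "nom.FA.rho_p_kg_m3",
    rho_p = c("nom.HA.rho_p_kg_m3", "nom.FA.rho_p_kg_m3"),
    offset_HA = "nom.HA.affinity_offset_J_mol",
    offset_FA = "nom.FA.affinity_offset_J_mol"
  )
  if (name %in% names(map)) return(map[[name]])
  name
}

default_bounds <- function(alias) {
  if (grepl("^q_", alias)) return(c(0.02, 1))
  if (grepl("^V_", alias)) return(c(1e-10, 8e-9))
  if (grepl("rho", alias)) return(c(700, 1700))
  if (grepl("offset", alias)) return(c(-2e6, 2e6))
  stop_validation(paste0("no default bounds for parameter ", alias,
                         "; supply bounds explicitly"))
}

builtin_metric <- function(name) {
  switch(name,
    max_HA_ads_mg_m2 = function(tb) max(tb$HA_ads_mg_m2, na.rm = TRUE),
    max_FA_ads_mg_m2 = function(tb) max(tb$FA_ads_mg_m2, na.rm = TRUE),
    max_total_ads_mg_m2 = function(tb) {
      max(tb$HA_ads_mg_m2 + tb$FA_ads_mg_m2, na.rm = TRUE)
    },
    stop_validation(paste0("unknown output metric: ", name))
  )
}

#' Sensitivity sweep over one model parameter
#'
#' Re-runs a design for each value of one configuration parameter (all else
#' fixed) and evaluates a scalar output metric.
#'
#' @param parameter A dotted configuration path (`"nom.FA.q"`) or an alias
#'   (`"q_FA"`, `"V_HA"`, `"rho_p"` -- the latter sets both densities).
#' @param values Parameter values to sweep.
#' @param design An [experiment_design()].
#' @param config Base configuration.
#' @param output_metric A builtin metric name (`"max_HA_ads_mg_m2"`,
#'   `"max_FA_ads_mg_m2"`, `"max_total_ads_mg_m2"`) or a
#'   `function(isotherm) -> numeric`.
#' @param scenario Volume scenario.
#' @return A tibble with one row per swept value.
#' @export
sensitivity_sweep <- function(parameter, values, design, config = lcd_config(),
                              output_metric = "max_total_ads_mg_m2",
                              scenario = c("variable", "constant")) {
  scenario <- if (missing(scenario)) config$scenario else match.arg(scenario)
  paths <- param_alias(parameter)
  metric <- if (is.function(output_metric)) output_metric else
    builtin_metric(output_metric)
  metric_name <- if (is.function(output_metric)) "metric" else output_metric
  rows <- purrr::map(values, function(v) {
    cfg <- config
    for (p in paths) cfg <- config_set(cfg, p, v)
    tb <- run_design(design, cfg, scenario = scenario)
    tibble::tibble(parameter = parameter, value = v,
                   metric = metric_name, metric_value = metric(tb))
  })
  dplyr::bind_rows(rows)
}
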