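## ---- Synthetic isotherms with known ground truth ---------------------------

#' Generate a synthetic isotherm dataset
#'
#' Runs a design through the model under ground-truth parameters and applies
#' multiplicative Gaussian noise to the adsorbed amounts (relative standard
#' deviation `noise_sd`, truncated at zero -- duplicate-measurement scatter
#' on adsorption data is relative, so the noise model is multiplicative).
#' Solution concentrations are recomputed from the noisy adsorbed amounts so
#' every row still closes its mass balance. Identical seed and spec give
#' byte-identical output.
#'
#' @param design An [experiment_design()].
#' @param config Ground-truth configuration.
#' @param scenario Volume scenario.
#' @param noise_sd Relative standard deviation of the multiplicative noise
#'   (0 reproduces the clean [run_design()] output exactly).
#' @param seed Integer seed.
#' @param clean Optional precomputed clean table (to re-noise without
#'   re-solving).
#' @return An isotherm tibble.
#' @export
generate_dataset <- function(design, config = lcd_config(),
                             scenario = c("variable", "constant"),
                             noise_sd = 0.02, seed = 1L, clean = NULL) {
  scenario <- if (missing(scenario)) config$scenario else match.arg(scenario)
  if (noise_sd < 0) stop_validation("noise_sd must be non-negative")
  tb <- clean %||% run_design(design, config, scenario = scenario)
  if (noise_sd == 0) return(tb)
  area_L <- (if (inherits(config, "lcd_model_context")) config$config else
               config)$surface$specific_surface_area_m2_g * design$solid_g_L
  withr::with_seed(seed, {
    for (comp in c("HA", "FA")) {
      ads <- paste0(comp, "_ads_mg_m2")
      sol <- paste0(comp, "_sol_mg_L")
      add <- paste0(comp, "_added_mg_L")
      eps <- rnorm(nrow(tb), 0, noise_sd)
      g <- pmax(0, tb[[ads]] * (1 + eps))
      g <- pmin(g, tb[[add]] / area_L)       # keep mass balance feasible
      g[is.na(tb[[ads]])] <- NA_real_
      tb[[ads]] <- g
      tb[[sol]] <- tb[[add]] - g * area_L
    }
  })
  tb
}

#' Recover model parameters from an isotherm table
#'
#' Bounded least-squares estimation of up to three configuration parameters
#' from an isotherm dataset: predictions are full self-consistent solves at
#' each row's additions and pH, and the objective is the summed squared
#' deviation of the adsorbed amounts of both components. Standard errors are
#' Gauss-Newton approximations from the numerical Hessian at the optimum.
#'
#' @param data An isotherm tibble (e.g. from [generate_dataset()]).
#' @param free_parameters Character vector of aliases or dotted paths
#'   (`"q_HA"`, `"V_FA"`, `"nom.HA.rho_p_kg_m3"`, ...), at most 3.
#' @param config Configuration holding all non-free parameters at truth.
#' @param scenario Volume scenario.
#' @param bounds Optional list of `c(lower, upper)` per parameter.
#' @param tol Optimizer tolerance on the parameter scale.
#' @return A tibble with `parameter`, `estimate`, `se`, plus the achieved
#'   `sse` as attribute.
#' @export
recover_parameters <- function(data, free_parameters, config = lcd_config(),
                               scenario = c("variable", "constant"),
                               bounds = NULL, tol = 1e-6) {
  scenario <- if (missing(scenario)) config$scenario else match.arg(scenario)
  if (length(free_parameters) < 1 || length(free_parameters) > 3) {
    stop_validation("between 1 and 3 parameters can be freed simultaneously")
  }
  paths <- lapply(free_parameters, param_alias)
  bnds <- lapply(seq_along(free_parameters), function(i) {
    bounds[[free_parameters[i]]] %||% default_bounds(free_parameters[i])
  })
  rows <- data[data$converged %in% TRUE &
                 (data$HA_added_mg_L > 0 | data$FA_added_mg_L > 0), ]
  if (nrow(rows) < 2 * length(free_parameters)) {
    stop_validation("not enough data rows to identify the requested parameters")
  }
  sse_fn <- function(theta) {
    cfg <- config
    for (i in seq_along(theta)) {
      for (p in paths[[i]]) cfg <- config_set(cfg, p, theta[i])
    }
    ctx <- structure(build_model_context(cfg), class = "lcd_model_context")
    prev <- NULL
    sse <- 0
    for (r in seq_len(nrow(rows))) {
      sys <- system_composition(
        HA_tot_mg_L = rows$HA_added_mg_L[r], FA_tot_mg_L = rows$FA_added_mg_L[r],
        pH = rows$pH[r], solid_g_L = ctx$config$experiment$solid_g_L,
        ionic_strength_M = ctx$config$experiment$ionic_strength_M,
        area_m2_g = ctx$config$surface$specific_surface_area_m2_g)
      st <- tryCatch(lcd_solve(sys, ctx, scenario = scenario, init = prev),
                     lcdcc_convergence_error = function(e) NULL)
      if (is.null(st)) return(1e6)
      prev <- st
      if (rows$HA_added_mg_L[r] > 0 && is.finite(rows$HA_ads_mg_m2[r])) {
        sse <- sse + (st$partition$Gamma_mg_m2$HA - rows$HA_ads_mg_m2[r])^2
      }
      if (rows$FA_added_mg_L[r] > 0 && is.finite(rows$FA_ads_mg_m2[r])) {
        sse <- sse + (st$partition$Gamma_mg_m2$FA - rows$FA_ads_mg_m2[r])^2
      }
    }
    sse
  }
  if (length(free_parameters) == 1) {
    opt <- optimize(sse_fn, interval = bnds[[1]], tol = tol)
    est <- opt$minimum
    sse <- opt$objective
  } else {
    start <- vapply(bnds, mean, numeric(1))
    opt <- optim(start, sse_fn, method = "L-BFGS-B",
                 lower = vapply(bnds, `[`, numeric(1), 1),
                 upper = vapply(bnds, `[`, numeric(1), 2),
                 control = list(factr = 1e10))
    est <- opt$par
    sse <- opt$value
  }
  n_obs <- sum(rows$HA_added_mg_L > 0 & is.finite(rows$HA_ads_mg_m2)) +
    sum(rows$FA_added_mg_L > 0 & is.finite(rows$FA_ads_mg_m2))
  p <- length(est)
  se <- rep(NA_real_, p)
  if (n_obs > p) {
    H <- tryCatch(optimHess(est, sse_fn,
                            control = list(ndeps = rep(1e-4, p) *
                                             pmax(abs(est), 1e-3))),
                  error = function(e) NULL)
    if (!is.null(H)) {
      cv <- tryCatch(2 * (sse / (n_obs - p)) * solve(H),
                     error = function(e) NULL)
      if (!is.null(cv)) {
        dg <- diag(as.matrix(cv))
        se <- ifelse(dg > 0, sqrt(dg), NA_real_)
      }
    }
  }
  structure(tibble::tibble(parameter = free_parameters, estimate = est, se = se),
            sse = sse)
}
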