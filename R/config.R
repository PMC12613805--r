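#' Default model configuration
#'
#' Builds the full hierarchical configuration of the competitive ligand and
#' charge distribution model with its documented defaults: a goethite surface
#' of 96 m2/g with a pristine point of zero charge of 9.3 described by a 1-pK
#' CD-MUSIC site pair (singly and triply coordinated surface groups), an
#' extended Stern double layer (C1 = 0.9 F/m2, C2 = 0.74 F/m2, Stern
#' thickness 0.8 nm), bimodal NICA proton binding for humic (HA) and fulvic
#' (FA) acid, particle-level heterogeneity exponents q = 0.1 (HA) and 0.3
#' (FA), a particle mass density of 1250 kg/m3, limiting adsorption volumes
#' of 3e-9 (HA) and 0.8e-9 (FA) m3/m2, and the molar-mass fractionation
#' parameters of the HA (M_o = 1.6 kDa, original mean mass 17 kDa).
#'
#' Every physical quantity carries its unit in the key name. All values can
#' be overridden from a YAML file via [load_config()] or programmatically
#' with [config_set()].
#'
#' @return A nested list of class `lcd_config`.
#' @export
#' @examples
#' cfg <- lcd_config()
#' cfg$nom$FA$q
lcd_config <- function() {
  cfg <- list(
    surface = list(
      specific_surface_area_m2_g = 96,
      sites = list(
        list(name = "FeOH", density_nm2 = 3.45, logK_H = 9.3),
        list(name = "Fe3O", density_nm2 = 2.70, logK_H = 9.3)
      ),
      logK_Na = -1,
      logK_Cl = -1
    ),
    edl = list(
      topology = "extended",      # "extended" (planes 0,1,2) or "basic" (0,1)
      C1_F_m2 = 0.9,
      C2_F_m2 = 0.74,
      d_ST_m = 0.8e-9,
      temperature_K = 295.15,
      relative_permittivity = 78.5
    ),
    nom = list(
      HA = list(
        nica = list(
          Qmax1_mol_kg = 3.15, logK1 = 2.93, m1 = 0.50,
          Qmax2_mol_kg = 2.55, logK2 = 8.00, m2 = 0.26
        ),
        q = 0.1,
        M_w_original_kDa = 17,
        M_o_kDa = 1.6,
        k_fractionation_kDa = 15.4,
        rho_p_kg_m3 = 1250,
        V_limit_m3_m2 = 3e-9,
        charge_split_first_plane = 0.5,
        affinity_offset_J_kg = 0,
        affinity_offset_J_mol = 0
      ),
      FA = list(
        nica = list(
          Qmax1_mol_kg = 5.88, logK1 = 2.34, m1 = 0.38,
          Qmax2_mol_kg = 1.86, logK2 = 8.60, m2 = 0.53
        ),
        q = 0.3,
        M_w_original_kDa = 1.8,
        M_o_kDa = 1.8,
        k_fractionation_kDa = 0,
        rho_p_kg_m3 = 1250,
        V_limit_m3_m2 = 0.8e-9,
        charge_split_first_plane = 0.8,
        affinity_offset_J_kg = 0,
        affinity_offset_J_mol = 0
      )
    ),
    affinity = list(
      ligand_exchange_kJ_mol = 10
    ),
    regulator = list(
      steepness_R = 1,
      steepness_theta = 1,
      override = NULL   # optional function(psi_planes) -> list(theta_s, R)
    ),
    volume = list(
      omega_basis = "volume",     # "volume" or "mass" share in the mixing rule
      V_constant_m3_m2 = 3e-9     # scenario = "constant"
    ),
    scenario = "variable",
    solver = list(
      tol_charge_C_m2 = 1e-11,
      tol_partition = 1e-10,
      max_iter = 120,
      damping = 0.5
    ),
    experiment = list(
      solid_g_L = 1.0,
      ionic_strength_M = 0.01,
      pH_values = c(4, 6),
      ExpI_fixed_FA_mg_L = 100,
      ExpI_HA_series_mg_L = c(20, 50, 80, 110, 145, 180, 210, 240),
      ExpII_fixed_HA_mg_L = 160,
      ExpII_FA_series_mg_L = c(25, 50, 75, 100, 125, 150, 175, 200)
    )
  )
  structure(cfg, class = "lcd_config")
}

#' Load a model configuration from a YAML file
#'
#' Reads a hierarchical YAML file, merges it onto the package defaults
#' ([lcd_config()]), rejects unknown keys, and range-validates every value.
#' An empty file yields the full default configuration.
#'
#' @param path Path to a YAML configuration file.
#' @return A validated `lcd_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop_io(paste0("configuration file not found: ", path))
  }
  user <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) stop_config(paste0("malformed YAML in ", path, ": ",
                                           conditionMessage(e)))
  )
  if (is.null(user)) user <- list()
  if (!is.list(user)) stop_config("configuration root must be a mapping")
  cfg <- merge_config(lcd_config(), user, path = character())
  validate_config(cfg)
}

#' Set a configuration value by dotted path
#'
#' @param config An `lcd_config` object.
#' @param path Dotted key path, e.g. `"nom.FA.q"`.
#' @param value Replacement value.
#' @return The modified, re-validated configuration.
#' @export
#' @examples
#' cfg <- config_set(lcd_config(), "nom.HA.q", 0.15)
config_set <- function(config, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- config
  for (k in keys) {
    if (!is.list(node) || !k %in% names(node)) {
      stop_config(paste0("unknown configuration key: ", path))
    }
    node <- node[[k]]
  }
  config[[keys]] <- value
  validate_config(config)
}

#' Read a configuration value by dotted path
#' @inheritParams config_set
#' @return The stored value.
#' @export
config_get <- function(config, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  config[[keys]]
}

## Recursive merge of user values onto defaults, rejecting keys that do not
## exist in the default skeleton. `surface.sites` is replaced wholesale (it is
## a list of records, not a mapping).
merge_config <- function(default, user, path) {
  for (key in names(user)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(default)) {
      stop_config(paste0("unknown configuration key: ", here))
    }
    dval <- default[[key]]
    uval <- user[[key]]
    wholesale <- identical(here, "surface.sites") ||
      identical(here, "experiment.pH_values") ||
      grepl("series_mg_L$", here)
    if (is.list(dval) && !wholesale) {
      if (!is.list(uval)) {
        stop_config(paste0("key ", here, " must be a mapping"))
      }
      default[[key]] <- merge_config(dval, uval, c(path, key))
    } else {
      default[[key]] <- uval
    }
  }
  default
}

check_range <- function(value, key, min = -Inf, max = Inf,
                        open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(value) && all(is.finite(value)) &&
    all(if (open_min) value > min else value >= min) &&
    all(if (open_max) value < max else value <= max)
  if (!ok) {
    stop_config(paste0("configuration value out of range: ", key, " = ",
                       paste(format(value), collapse = ", "),
                       " (allowed ", if (open_min) "(" else "[", min, ", ",
                       max, if (open_max) ")" else "]", ")"))
  }
  invisible(value)
}

#' Validate a configuration
#'
#' Checks ranges of every physical parameter (e.g. particle mass density must
#' lie within the hydrated-to-dry span 700-1700 kg/m3, heterogeneity and NICA
#' width exponents within (0, 1]). Called automatically by [load_config()]
#' and [config_set()].
#'
#' @param config A configuration list.
#' @return The configuration, invisibly classed as `lcd_config`.
#' @export
validate_config <- function(config) {
  s <- config$surface
  check_range(s$specific_surface_area_m2_g, "surface.specific_surface_area_m2_g",
              min = 0, open_min = TRUE)
  if (!is.list(s$sites) || length(s$sites) == 0) {
    stop_config("surface.sites must be a non-empty list of site records")
  }
  for (site in s$sites) {
    if (is.null(site$name) || is.null(site$density_nm2) || is.null(site$logK_H)) {
      stop_config("each surface site needs fields name, density_nm2, logK_H")
    }
    check_range(site$density_nm2, "surface.sites.density_nm2",
                min = 0, open_min = TRUE)
  }
  e <- config$edl
  if (!e$topology %in% c("extended", "basic")) {
    stop_config("edl.topology must be 'extended' or 'basic'")
  }
  check_range(e$C1_F_m2, "edl.C1_F_m2", min = 0, open_min = TRUE)
  check_range(e$C2_F_m2, "edl.C2_F_m2", min = 0, open_min = TRUE)
  check_range(e$d_ST_m, "edl.d_ST_m", min = 0, open_min = TRUE)
  check_range(e$temperature_K, "edl.temperature_K", min = 250, max = 350)
  for (comp in c("HA", "FA")) {
    n <- config$nom[[comp]]
    pre <- paste0("nom.", comp, ".")
    check_range(n$q, paste0(pre, "q"), min = 0, max = 1, open_min = TRUE)
    check_range(n$rho_p_kg_m3, paste0(pre, "rho_p_kg_m3"), min = 700, max = 1700)
    check_range(n$V_limit_m3_m2, paste0(pre, "V_limit_m3_m2"),
                min = 0, open_min = TRUE)
    check_range(n$M_o_kDa, paste0(pre, "M_o_kDa"), min = 0, open_min = TRUE)
    check_range(n$k_fractionation_kDa, paste0(pre, "k_fractionation_kDa"), min = 0)
    for (f in c("Qmax1_mol_kg", "Qmax2_mol_kg")) {
      check_range(n$nica[[f]], paste0(pre, "nica.", f), min = 0, open_min = TRUE)
    }
    for (f in c("m1", "m2")) {
      check_range(n$nica[[f]], paste0(pre, "nica.", f),
                  min = 0, max = 1, open_min = TRUE)
    }
  }
  if (!config$volume$omega_basis %in% c("volume", "mass")) {
    stop_config("volume.omega_basis must be 'volume' or 'mass'")
  }
  check_range(config$volume$V_constant_m3_m2, "volume.V_constant_m3_m2",
              min = 0, open_min = TRUE)
  if (!config$scenario %in% c("variable", "constant")) {
    stop_config("scenario must be 'variable' or 'constant'")
  }
  for (comp in c("HA", "FA")) {
    check_range(config$nom[[comp]]$charge_split_first_plane,
                paste0("nom.", comp, ".charge_split_first_plane"),
                min = 0, max = 1)
  }
  if (!is.null(config$regulator$override) &&
      !is.function(config$regulator$override)) {
    stop_config("regulator.override must be NULL or a function(psi_planes)")
  }
  check_range(config$experiment$solid_g_L, "experiment.solid_g_L",
              min = 0, open_min = TRUE)
  check_range(config$experiment$ionic_strength_M, "experiment.ionic_strength_M",
              min = 0, open_min = TRUE)
  structure(config, class = "lcd_config")
}

#' Write a configuration to YAML
#' @param config An `lcd_config` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @export
print.lcd_config <- function(x, ...) {
  cat("<lcd_config>\n")
  cat(yaml::as.yaml(unclass(x)))
  invisible(x)
}
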