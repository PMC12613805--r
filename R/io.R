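## ---- Tabular I/O -----------------------------------------------------------

isotherm_columns <- c(
  "design_id", "pH", "HA_added_mg_L", "FA_added_mg_L",
  "HA_ads_mg_m2", "FA_ads_mg_m2", "HA_sol_mg_L", "FA_sol_mg_L",
  "V_m3_m2", "M_w_HA_ads_kDa", "M_w_mix_kDa", "scenario", "mode", "converged"
)

#' Write an isotherm table to CSV
#'
#' UTF-8, '.' decimal separator, ',' field separator, mandatory header;
#' numeric values survive a write/read round trip at better than 12
#' significant digits.
#'
#' @param table An isotherm tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_isotherm <- function(table, path) {
  missing_cols <- setdiff(isotherm_columns, names(table))
  if (length(missing_cols)) {
    stop_io(paste0("isotherm table lacks columns: ",
                   paste(missing_cols, collapse = ", ")))
  }
  readr::write_csv(table[, isotherm_columns], path, progress = FALSE)
  invisible(path)
}

#' Read an isotherm table from CSV
#'
#' @param path CSV file written by [write_isotherm()] (or matching its
#'   documented header).
#' @return An isotherm tibble (class `lcd_isotherm`).
#' @export
read_isotherm <- function(path) {
  if (!file.exists(path)) stop_io(paste0("file not found: ", path))
  hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                               progress = FALSE))
  missing_cols <- setdiff(isotherm_columns, hdr)
  if (length(missing_cols)) {
    stop_io(paste0("isotherm CSV lacks columns: ",
                   paste(missing_cols, collapse = ", ")))
  }
  tb <- readr::read_csv(
    path, progress = FALSE,
    col_types = readr::cols(
      design_id = readr::col_character(),
      scenario = readr::col_character(),
      mode = readr::col_character(),
      converged = readr::col_logical(),
      .default = readr::col_double()
    ))
  class(tb) <- c("lcd_isotherm", class(tb))
  tb
}
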