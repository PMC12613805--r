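## ---- Plotting ---------------------------------------------------------------

#' Plot an isotherm table
#'
#' Adsorbed amount of each component against its own addition, one panel per
#' pH, line type distinguishing the competitor addition level.
#'
#' @param object An `lcd_isotherm` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot lcd_isotherm
#' @export
autoplot.lcd_isotherm <- function(object, ...) {
  long <- dplyr::bind_rows(
    dplyr::transmute(object, pH = .data$pH, component = "HA",
                     added_mg_L = .data$HA_added_mg_L,
                     ads_mg_m2 = .data$HA_ads_mg_m2,
                     competitor_mg_L = .data$FA_added_mg_L),
    dplyr::transmute(object, pH = .data$pH, component = "FA",
                     added_mg_L = .data$FA_added_mg_L,
                     ads_mg_m2 = .data$FA_ads_mg_m2,
                     competitor_mg_L = .data$HA_added_mg_L)
  )
  long <- dplyr::filter(long, .data$added_mg_L > 0, is.finite(.data$ads_mg_m2))
  ggplot2::ggplot(long, ggplot2::aes(.data$added_mg_L, .data$ads_mg_m2,
                                     colour = .data$component,
                                     linetype = factor(.data$competitor_mg_L))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.6) +
    ggplot2::facet_wrap(~pH, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "added (mg/L)", y = "adsorbed (mg/m2)",
                  colour = "component", linetype = "competitor (mg/L)") +
    ggplot2::theme_minimal()
}

#' Plot a charging curve
#'
#' @param curve A tibble from [charging_curve()].
#' @param planes Which charge columns to draw.
#' @return A ggplot object.
#' @export
plot_charging_curve <- function(curve,
                                planes = c("sigma0", "sigma2", "net_charge")) {
  long <- tidyr::pivot_longer(curve[, c("pH", planes)],
                              dplyr::all_of(planes),
                              names_to = "plane", values_to = "sigma_C_m2")
  ggplot2::ggplot(long, ggplot2::aes(.data$pH, .data$sigma_C_m2,
                                     colour = .data$plane)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, linewidth = 0.3) +
    ggplot2::labs(x = "pH", y = "charge density (C/m2)") +
    ggplot2::theme_minimal()
}
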