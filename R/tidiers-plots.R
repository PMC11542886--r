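# broom-style accessors and ggplot2 diagnostics for the result types

#' @export
tidy.steady_state_result <- function(x, ...) {
  reg <- adm1_components()
  tibble::tibble(component = reg$name, phase = reg$phase, unit = reg$unit,
                 effluent = as.numeric(x$effluent))
}

#' @export
glance.steady_state_result <- function(x, ...) {
  tibble::tibble(rcod = x$rcod,
                 effluent_cod_kg_m3 = x$cod_out_kg_m3,
                 biogas_ch4_kg_d = x$biogas_ch4_kg_d,
                 biogas_h2_kg_d = x$biogas_h2_kg_d,
                 dissolved_ch4_kg_d = x$dissolved_ch4_kg_d,
                 fugitive_ch4_kg_d = x$fugitive_ch4_kg_d,
                 cod_closure = x$cod_closure,
                 converged = x$converged, t_days = x$t_days)
}

#' @export
tidy.cash_flow_schedule <- function(x, ...) x$flows

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Density plot of pairwise relative impacts
#'
#' @param delta A [pairwise_delta()] tibble (several variables may be bound
#'   together).
#' @return A ggplot object.
#' @export
plot_delta_density <- function(delta) {
  .need_ggplot()
  ggplot2::ggplot(delta, ggplot2::aes(x = .data$delta,
                                      fill = .data$alternative)) +
    ggplot2::geom_density(alpha = 0.4) +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(x = "relative impact (indicator range = 1)",
                  y = "density") +
    ggplot2::theme_minimal()
}

#' Bubble chart of Monte Carlo filtering KS results
#'
#' @param ks Bound rows of [monte_carlo_filter()] outputs with an
#'   `indicator` column added.
#' @param alpha Significance threshold highlighted in the plot.
#' @return A ggplot object.
#' @export
plot_ks_bubble <- function(ks, alpha = 0.05) {
  .need_ggplot()
  ks$significant <- ks$p_value < alpha
  ggplot2::ggplot(ks, ggplot2::aes(x = .data$indicator, y = .data$parameter,
                                   size = .data$statistic,
                                   colour = .data$significant)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_size_area(max_size = 10) +
    ggplot2::labs(size = "KS D", colour = paste0("p < ", alpha)) +
    ggplot2::theme_minimal()
}

#' Heat map of a stage-III design map
#'
#' @param object A [stage3_map()] tibble.
#' @param fill Column to map to fill (default minimized `ci`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.stage3_map <- function(object, fill = "ci", ...) {
  .need_ggplot()
  nms <- names(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data[[nms[1]]],
                                       y = .data[[nms[2]]],
                                       fill = .data[[fill]])) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(fill = fill) +
    ggplot2::theme_minimal()
}

#' Stacked contribution chart for indicator breakdowns
#'
#' @param ind A [compute_indicators()] row (or several bound together).
#' @param which `"lc"` or `"ci"`.
#' @return A ggplot object.
#' @export
plot_breakdown <- function(ind, which = c("lc", "ci")) {
  .need_ggplot()
  which <- match.arg(which)
  pre <- paste0(which, "_")
  keep <- setdiff(grep(pre, names(ind), value = TRUE),
                  paste0(which, c("_usd_t", "_kgco2_t")))
  long <- tidyr::pivot_longer(
    dplyr::mutate(ind, scenario = dplyr::row_number()),
    dplyr::all_of(keep), names_to = "group", values_to = "contribution")
  long$group <- sub(pre, "", long$group)
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$scenario),
                                     y = .data$contribution,
                                     fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "scenario",
                  y = if (which == "lc") "USD per tonne COD removed"
                      else "kg CO2eq per tonne COD removed") +
    ggplot2::theme_minimal()
}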