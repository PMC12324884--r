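#' Plot an eco-evolutionary trajectory
#'
#' Faceted time series of the recorded metrics along the substitution axis.
#'
#' @param object an `ecoevo_trajectory` from [run_trajectory()].
#' @param metrics which record columns to show.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ecoevo_trajectory <- function(object,
                                       metrics = c("richness",
                                                   "effective_diversity",
                                                   "total_biomass",
                                                   "connectance",
                                                   "rho_eff_p", "rho_c_p"),
                                       ...) {
  long <- tibble::as_tibble(object) |>
    dplyr::select(dplyr::all_of(c("substitution", metrics))) |>
    tidyr::pivot_longer(-"substitution", names_to = "metric")
  ggplot2::ggplot(long, ggplot2::aes(.data$substitution, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "substitutions (accepted events)", y = NULL)
}

#' Plot an extinction-fraction curve
#'
#' Fraction of perturbation draws causing at least one extinction against the
#' perturbation amplitude, on a log amplitude axis.
#'
#' @param curve tibble from [extinction_fraction_curve()] (or the `curve`
#'   attribute of [estimate_delta_c_numeric()]).
#' @param threshold optional horizontal reference (e.g. the detection
#'   threshold used for the numerical critical perturbation).
#' @return a ggplot object.
#' @export
plot_extinction_curve <- function(curve, threshold = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(.data$delta, .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "perturbation amplitude", y = "fraction with extinction")
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Plot a grid summary of final diversity
#'
#' Boxplots of final richness by competition, faceted by perturbation
#' amplitude, coloured by selection regime.
#'
#' @param grid_table output of [run_grid()].
#' @return a ggplot object.
#' @export
plot_grid_diversity <- function(grid_table) {
  fin <- final_records(grid_table)
  ggplot2::ggplot(fin, ggplot2::aes(factor(.data$rho), .data$richness,
                                    fill = .data$selection)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~delta, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "interspecific competition", y = "final richness",
                  fill = "selection")
}
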