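#' Spaghetti plot of per-animal tumor-volume series
#'
#' One line per animal, colored by arm, on a log10 volume scale (zero
#' volumes are shown at the plot floor of 1 mm^3).
#'
#' @param data A measurement table.
#' @param floor Plot floor in mm^3 for zero/near-zero volumes. Default 1.
#' @return A ggplot object.
#' @export
plot_growth_curves <- function(data, floor = 1) {
  tbl <- dplyr::mutate(as_tibble(data),
                       vol_plot = pmax(.data$volume, floor))
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$day, y = .data$vol_plot,
                                    group = .data$animal_id,
                                    color = .data$group)) +
    ggplot2::geom_line(alpha = 0.6) +
    ggplot2::geom_point(size = 0.8, alpha = 0.6) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Study day", y = "Tumor volume (mm³, log scale)",
                  color = "Arm") +
    ggplot2::theme_minimal()
}

#' Step plot of Kaplan-Meier curves
#'
#' @param object A `km_curve` from [km_estimate()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.km_curve <- function(object, ...) {
  start <- object %>%
    dplyr::distinct(.data$group) %>%
    dplyr::mutate(time = 0, survival = 1)
  curve <- dplyr::bind_rows(
    start,
    dplyr::select(as_tibble(object), "group", "time", "survival")
  ) %>%
    dplyr::arrange(.data$group, .data$time)
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$time, y = .data$survival,
                                      color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Study day", y = "Surrogate survival", color = "Arm") +
    ggplot2::theme_minimal()
}
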