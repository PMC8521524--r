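# ggplot2 visualisations for the main result types.

#' @describeIn fit_pressure_coefficients Plot per-residue first-order
#'   pressure coefficients (corrected where available), coloured by
#'   response class when present.
#' @param object An `absalt_pressure_fit` tibble.
#' @param ... Unused.
#' @method autoplot absalt_pressure_fit
#' @export
autoplot.absalt_pressure_fit <- function(object, ...) {
  b1 <- if ("B1_corrected" %in% names(object)) "B1_corrected" else "B1"
  p <- ggplot2::ggplot(object, ggplot2::aes(
    x = .data$residue_index, y = .data[[b1]]
  )) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::labs(
      x = "Residue", y = expression(B[1] ~ "(ppm/kbar)"),
      title = "First-order pressure coefficients"
    ) +
    ggplot2::theme_minimal()
  if ("response" %in% names(object)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$response)) +
      ggplot2::scale_fill_manual(values = c(
        negative = "#2166ac", near_zero = "grey70", positive = "#b2182b"
      ), drop = FALSE)
  } else {
    p <- p + ggplot2::geom_col(fill = "grey40")
  }
  if (dplyr::n_distinct(object$nucleus) > 1) {
    p <- p + ggplot2::facet_wrap(~nucleus, scales = "free_y")
  }
  p
}

#' @describeIn fit_cest_profile Plot the measured profile and the fitted
#'   two-site exchange curve.
#' @param object A `cest_fit` object.
#' @param ... Unused.
#' @method autoplot cest_fit
#' @export
autoplot.cest_fit <- function(object, ...) {
  ggplot2::ggplot(object$profile, ggplot2::aes(x = .data$offset_ppm)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$intensity), size = 1,
                        colour = "grey30") +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "#b2182b") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(
      x = "Saturation offset (ppm)", y = "Normalised intensity",
      title = sprintf("CEST fit: k_ex = %.0f 1/s, delta_omega = %.0f rad/s",
                      object$estimates$estimate[1],
                      object$estimates$estimate[2])
    ) +
    ggplot2::theme_minimal()
}

#' Plot salt-bridge occupancies with mode breakdown
#'
#' Stacked bar chart of per-pair occupancy split into side-on, end-on and
#' backside fractions.
#'
#' @param occupancy Tibble from [bridge_occupancy()].
#' @return A ggplot object.
#' @export
plot_bridge_occupancy <- function(occupancy) {
  long <- occupancy |>
    dplyr::mutate(pair = paste0("Arg", .data$donor, "-",
                                .data$acceptor_name, .data$acceptor)) |>
    tidyr::pivot_longer(dplyr::all_of(c("f_side_on", "f_end_on", "f_backside")),
                        names_to = "mode", values_to = "fraction") |>
    dplyr::mutate(mode = factor(sub("^f_", "", .data$mode),
                                levels = c("side_on", "end_on", "backside")))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pair, y = .data$fraction,
                                     fill = .data$mode)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_brewer(palette = "Set2") +
    ggplot2::labs(x = NULL, y = "Fraction of conformers",
                  title = "Salt-bridge occupancy by interaction mode") +
    ggplot2::theme_minimal()
}
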