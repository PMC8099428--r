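#' Plot methods for pipeline result objects
#'
#' `autoplot()` methods give the standard visual summaries: the free-energy
#' surface in tIC space, the schematic 1D profile with state levels and TST
#' barriers, the state-by-residue contact grid, implied-timescale
#' convergence, Chapman-Kolmogorov curves, and I-V data with the fitted
#' activation curve.
#'
#' @param object The result object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name vsdk-autoplot
NULL

#' @rdname vsdk-autoplot
#' @export
autoplot.fes <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tic1, y = .data$tic2,
                                   fill = .data$free_energy)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "white",
                                  name = sprintf("F (kT)")) +
    ggplot2::labs(x = "tIC 1", y = "tIC 2") +
    ggplot2::theme_minimal()
}

#' @rdname vsdk-autoplot
#' @export
autoplot.free_energy_profile <- function(object, ...) {
  st <- object$states
  st$xmin <- st$position - 0.3
  st$xmax <- st$position + 0.3
  fw <- object$barriers[object$barriers$direction == "forward", ]
  fw$x <- match(fw$from, st$state) + 0.5
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = st,
                          ggplot2::aes(x = .data$xmin, xend = .data$xmax,
                                       y = .data$free_energy,
                                       yend = .data$free_energy),
                          linewidth = 1.4) +
    ggplot2::geom_point(data = fw,
                        ggplot2::aes(x = .data$x, y = .data$peak_level),
                        shape = 24, size = 2.5, fill = "grey60") +
    ggplot2::scale_x_continuous(breaks = st$position, labels = st$name) +
    ggplot2::labs(x = NULL, y = "free energy (kJ/mol)") +
    ggplot2::theme_minimal()
}

#' @rdname vsdk-autoplot
#' @export
autoplot.contact_table <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$state),
                                   y = paste(.data$charge, "-", .data$partner),
                                   fill = .data$occupancy)) +
    ggplot2::geom_tile(color = "white") +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "state", y = NULL,
                  title = sprintf("contacts (cutoff %.1f Å)",
                                  attr(object, "cutoff"))) +
    ggplot2::theme_minimal()
}

#' @rdname vsdk-autoplot
#' @export
autoplot.implied_timescales <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag_time,
                                       y = .data$timescale,
                                       colour = factor(.data$index))) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "lag time", y = "implied timescale",
                  colour = "process") +
    ggplot2::theme_minimal()
}

#' @rdname vsdk-autoplot
#' @export
autoplot.ck_test <- function(object, ...) {
  df <- object$results
  ggplot2::ggplot(df, ggplot2::aes(x = .data$factor)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower,
                                      ymax = .data$upper),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$estimated),
                       colour = "black") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~ .data$set, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "lag factor", y = "staying probability",
                  title = sprintf("Chapman-Kolmogorov: %s",
                                  if (object$pass) "pass" else "fail")) +
    ggplot2::theme_minimal()
}

#' @rdname vsdk-autoplot
#' @param fit Optional [fit_iv()] result to overlay.
#' @export
autoplot.iv_dataset <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$voltage, y = .data$current)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "voltage (mV)", y = "current") +
    ggplot2::theme_minimal()
  if (!is.null(fit)) {
    cf <- as.list(coef(fit))
    vv <- seq(min(object$voltage), max(object$voltage), length.out = 200)
    curve <- tibble(voltage = vv,
                    current = iv_current(vv, cf$Gmax, cf$Vrev, cf$Vhalf,
                                         cf$slope_k))
    p <- p + ggplot2::geom_line(data = curve, colour = "red")
  }
  p
}
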