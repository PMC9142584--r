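#' Plot a calibration family with optional measured curves
#'
#' Dephasing curves (S/S0 against mixing time) for a calibration set,
#' coloured by 13C fraction, with measured scheme curves overlaid as
#' points with error bars when supplied.
#'
#' @param cal Calibration tibble (`fraction`, `time_ms`, `ratio`,
#'   optionally `sigma`).
#' @param measured Optional measured tibble (`scheme`, `time_ms`,
#'   `ratio`, optionally `sigma`).
#' @return A ggplot object.
#' @export
plot_redor_curves <- function(cal, measured = NULL) {
  p <- ggplot2::ggplot(cal, ggplot2::aes(x = .data$time_ms, y = .data$ratio)) +
    ggplot2::geom_line(ggplot2::aes(group = factor(.data$fraction),
                                    colour = factor(.data$fraction))) +
    ggplot2::scale_colour_viridis_d(name = "13C fraction") +
    ggplot2::labs(x = "mixing time (ms)", y = expression(S / S[0])) +
    ggplot2::theme_minimal()
  if (!is.null(measured)) {
    p <- p + ggplot2::geom_point(
      data = measured,
      ggplot2::aes(shape = factor(.data$scheme)), size = 1.6) +
      ggplot2::labs(shape = "scheme")
    if (!is.null(measured$sigma)) {
      p <- p + ggplot2::geom_errorbar(
        data = measured,
        ggplot2::aes(ymin = .data$ratio - .data$sigma,
                     ymax = .data$ratio + .data$sigma),
        width = 0)
    }
  }
  p
}

#' Plot an isoform chain as a coloured strip
#'
#' One tile per monomer along the fibril axis, coloured by isoform, the
#' standard rendering of simulated isoform succession.
#'
#' @param chain An `isoform_chain`, or a named list of chains (one strip
#'   per protofilament).
#' @return A ggplot object.
#' @export
plot_chain <- function(chain) {
  if (inherits(chain, "isoform_chain")) chain <- list(chain = chain)
  df <- purrr::imap_dfr(chain, function(ch, nm) {
    tibble(proto = nm, position = seq_along(ch), isoform = as.character(ch))
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$position, y = .data$proto,
                                   fill = .data$isoform)) +
    ggplot2::geom_tile(height = 0.8) +
    ggplot2::scale_fill_manual(values = c("4R" = "#E69F00", "3R" = "#0072B2")) +
    ggplot2::labs(x = "monomer position along fibril axis", y = NULL) +
    ggplot2::theme_minimal()
}

#' Autoplot a mixing fit
#'
#' Point-and-error-bar display of the fitted quantities (p43, p34, chi4,
#' Q) from a `mixing_fit`.
#'
#' @param object A `mixing_fit`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot mixing_fit
#' @export
autoplot.mixing_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$term, y = .data$estimate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$estimate - .data$std.error,
                                        ymax = .data$estimate + .data$std.error),
                           width = 0.15, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "estimate") +
    ggplot2::theme_minimal()
}

#' @export
ggplot2::autoplot
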