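#' Plot a power spectrum on log-log axes
#'
#' @param object a [fes_spectrum()].
#' @param ... further spectra to overlay (named arguments become legend
#'   labels).
#' @return a ggplot.
#' @method autoplot fes_spectrum
#' @export
autoplot.fes_spectrum <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, is.data.frame, logical(1))]
  specs <- c(list(object), extra)
  labels <- c(fes_label(object),
              if (length(extra)) {
                nm <- names(extra) %||% rep("", length(extra))
                ifelse(nzchar(nm), nm, vapply(extra, fes_label, character(1)))
              })
  df <- purrr::map2_dfr(specs, labels, function(s, lab) {
    tibble(frequency = s$frequency, density = s$density, spectrum = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$frequency, .data$density,
                                   colour = .data$spectrum)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density (1/Hz units)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fingerprint as a symbol bar chart
#'
#' Draws one bar per sub-band at height -1, 0 or +1, the customary display
#' for slope-code fingerprints.
#'
#' @param object a `fes_fingerprint`.
#' @param ... further fingerprints to show side by side (for example the two
#'   measurements of a pair).
#' @return a ggplot.
#' @method autoplot fes_fingerprint
#' @export
autoplot.fes_fingerprint <- function(object, ...) {
  extra <- list(...)
  extra <- extra[vapply(extra, function(x) inherits(x, "fes_fingerprint"),
                        logical(1))]
  fps <- c(list(object), extra)
  nm <- names(extra) %||% rep("", length(extra))
  labels <- c(fes_label(object),
              if (length(extra)) ifelse(nzchar(nm),
                                        nm, vapply(extra, fes_label, character(1))))
  labels <- make.unique(as.character(labels))
  df <- purrr::map2_dfr(fps, labels, function(fp, lab) {
    tibble(band = fp$band, bit = fp$bit, fingerprint = lab)
  })
  ggplot2::ggplot(df, ggplot2::aes(factor(.data$band), .data$bit,
                                   fill = .data$fingerprint)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.7),
                      width = 0.6) +
    ggplot2::scale_y_continuous(breaks = c(-1, 0, 1), limits = c(-1.1, 1.1)) +
    ggplot2::labs(x = "sub-band", y = "symbol", fill = NULL,
                  title = sprintf("%s fingerprint", fingerprint_scheme(object))) +
    ggplot2::theme_minimal()
}

#' Plot a noise record
#'
#' @param object a [fes_timeseries()].
#' @param max_points thin the trace to at most this many points for display.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot fes_timeseries
#' @export
autoplot.fes_timeseries <- function(object, max_points = 5000, ...) {
  idx <- if (nrow(object) > max_points) {
    unique(round(seq(1L, nrow(object), length.out = max_points)))
  } else {
    seq_len(nrow(object))
  }
  ggplot2::ggplot(object[idx, ], ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::labs(x = "time (s)", y = "noise voltage (a.u.)",
                  title = fes_label(object)) +
    ggplot2::theme_minimal()
}
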