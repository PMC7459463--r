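#' Construct a one-sided power density spectrum
#'
#' A power spectrum is a tibble with columns `frequency` (Hz, strictly
#' ascending, all positive -- the DC bin is never part of a spectrum) and
#' `density` (power per Hz, strictly positive). The number of averaged
#' periodogram segments and a label travel as attributes.
#'
#' Non-positive densities are rejected rather than floored: a proper Welch
#' estimate of a noise record is positive everywhere, so a zero or negative
#' value in user-supplied data signals a corrupt file, and silently flooring
#' it would distort the log-log slopes downstream.
#'
#' @param frequency numeric vector of frequencies in Hz; strictly ascending,
#'   all positive, length >= 2.
#' @param density numeric vector of spectral densities (power/Hz); strictly
#'   positive, same length as `frequency`.
#' @param n_averages number of averaged segments behind the estimate
#'   (`NA` for analytic or file-loaded spectra).
#' @param label free-text label.
#'
#' @return a tibble of class `fes_spectrum`.
#' @examples
#' ps <- fes_spectrum(c(1, 10, 100), c(1, 0.1, 0.01))
#' @export
fes_spectrum <- function(frequency, density, n_averages = NA_integer_,
                         label = "spectrum") {
  frequency <- as.numeric(frequency)
  density <- as.numeric(density)
  if (length(frequency) != length(density)) {
    abort("`frequency` and `density` must have the same length.",
          class = "fes_validation_error")
  }
  if (length(frequency) < 2L) {
    abort("a spectrum needs at least 2 points.", class = "fes_validation_error")
  }
  if (!all(is.finite(frequency)) || any(frequency <= 0)) {
    abort("`frequency` must be finite and strictly positive (no DC bin).",
          class = "fes_validation_error")
  }
  if (any(diff(frequency) <= 0)) {
    abort("`frequency` must be strictly ascending.", class = "fes_validation_error")
  }
  if (!all(is.finite(density)) || any(density <= 0)) {
    bad <- which(!is.finite(density) | density <= 0)[1L]
    abort(
      sprintf("`density` must be finite and strictly positive; offending row %d (density = %g).",
              bad, density[bad]),
      class = "fes_validation_error"
    )
  }
  out <- tibble(frequency = frequency, density = density)
  new_fes_tbl(out, "fes_spectrum",
              n_averages = n_averages, label = as.character(label))
}

#' Welch estimate of the power density spectrum of a noise record
#'
#' Estimates the one-sided power density spectrum of a sensor-noise voltage
#' trace by the averaged-periodogram (Welch) method: the record is cut into
#' overlapping segments, each segment is mean-removed, windowed and Fourier
#' transformed, and the squared magnitudes are averaged. The DC bin is dropped
#' (log-log slope analysis is undefined at f = 0) and the estimate is
#' normalised so that `sum(density) * df` equals the input variance for white
#' noise (Parseval consistency).
#'
#' @param ts a [fes_timeseries()] record (or a data frame with `time`/`value`
#'   columns, or a `value` column plus `sampling_rate`).
#' @param segment_length samples per Welch segment (>= 16, <= record length).
#' @param overlap fractional overlap between consecutive segments in `[0, 1)`.
#' @param window taper applied to each segment: `"hann"` (default),
#'   `"hamming"` or `"rectangular"`.
#' @param sampling_rate sampling rate in Hz, only needed when `ts` does not
#'   carry one.
#'
#' @return a [fes_spectrum()] tibble with `floor(segment_length / 2)` rows;
#'   the `n_averages` attribute records how many segments were averaged.
#' @examples
#' ts <- fes_timeseries(rnorm(2^14), sampling_rate = 1000)
#' ps <- estimate_psd(ts, segment_length = 1024)
#' # Parseval: integrated density matches the sample variance
#' sum(ps$density) * diff(ps$frequency)[1]
#' var(ts$value)
#' @export
estimate_psd <- function(ts, segment_length = 4096, overlap = 0.5,
                         window = c("hann", "hamming", "rectangular"),
                         sampling_rate = NULL) {
  ts <- as_fes_timeseries(ts, sampling_rate = sampling_rate)
  window <- match.arg(window)
  x <- ts$value
  n <- length(x)
  fs <- sampling_rate(ts)
  segment_length <- as.integer(segment_length)
  if (segment_length < 16L) {
    abort("`segment_length` must be at least 16 samples.",
          class = "fes_sizing_error")
  }
  if (segment_length > n) {
    abort(
      sprintf("series too short: %d samples cannot hold one segment of %d.",
              n, segment_length),
      class = "fes_sizing_error"
    )
  }
  if (!is.numeric(overlap) || length(overlap) != 1L || overlap < 0 || overlap >= 1) {
    abort("`overlap` must be a fraction in [0, 1).", class = "fes_validation_error")
  }

  w <- switch(window,
    hann        = as.numeric(signal::hanning(segment_length)),
    hamming     = as.numeric(signal::hamming(segment_length)),
    rectangular = rep(1, segment_length)
  )
  step <- max(1L, as.integer(round(segment_length * (1 - overlap))))
  starts <- seq.int(1L, n - segment_length + 1L, by = step)
  n_avg <- length(starts)

  # segments as columns; per-segment mean removal, then taper
  seg <- vapply(starts, function(s) {
    xi <- x[s:(s + segment_length - 1L)]
    (xi - mean(xi)) * w
  }, numeric(segment_length))
  X <- stats::mvfft(seg)

  half <- segment_length %/% 2L
  idx <- 2:(half + 1L)                       # drop DC; keep up to Nyquist
  p <- rowMeans(Mod(X[idx, , drop = FALSE])^2)
  scale <- fs * sum(w^2)
  density <- 2 * p / scale
  if (segment_length %% 2L == 0L) {
    density[half] <- density[half] / 2      # Nyquist bin is not doubled
  }
  freq <- (1:half) * fs / segment_length

  fes_spectrum(freq, density, n_averages = n_avg, label = fes_label(ts))
}

#' Smooth a spectrum onto a logarithmic frequency grid
#'
#' Averages the spectrum within contiguous bins of equal width in
#' `log10(frequency)`: each output point is the geometric mean frequency and
#' arithmetic mean density of the input points falling in its bin. Empty bins
#' are dropped. Log binning evens out the single-bin scatter of the raw Welch
#' estimate so that local chord slopes are stable, and it preserves power-law
#' slopes.
#'
#' @param ps a [fes_spectrum()].
#' @param bins_per_decade number of bins per decade of frequency (>= 1;
#'   default 12).
#'
#' @return a [fes_spectrum()] on the coarser grid; `n_averages` is carried
#'   over from the input.
#' @examples
#' ps <- fes_spectrum(seq(1, 100, by = 0.5), 1 / seq(1, 100, by = 0.5))
#' log_bin_spectrum(ps, bins_per_decade = 10)
#' @export
log_bin_spectrum <- function(ps, bins_per_decade = 12) {
  ps <- as_fes_spectrum(ps)
  if (!is.numeric(bins_per_decade) || length(bins_per_decade) != 1L ||
      bins_per_decade < 1) {
    abort("`bins_per_decade` must be a single number >= 1.",
          class = "fes_validation_error")
  }
  lf <- log10(ps$frequency)
  # bins anchored at the lowest frequency; the top band edge belongs to the
  # last bin, so a span of d decades yields at most ceiling(d * bpd) points
  bin <- floor((lf - lf[1L]) * bins_per_decade + 1e-9)
  bin <- pmin(bin, ceiling((lf[length(lf)] - lf[1L]) * bins_per_decade - 1e-9) - 1)
  bin <- pmax(bin, 0)
  out <- ps |>
    as_tibble() |>
    dplyr::mutate(.bin = bin) |>
    dplyr::summarise(
      frequency = 10^mean(log10(.data$frequency)),
      density = mean(.data$density),
      .by = ".bin"
    ) |>
    dplyr::arrange(.data$frequency)
  if (nrow(out) < 2L) {
    abort("log binning left fewer than 2 points; use more `bins_per_decade` or a wider spectrum.",
          class = "fes_degenerate_error")
  }
  fes_spectrum(out$frequency, out$density,
               n_averages = attr(ps, "n_averages", exact = TRUE),
               label = fes_label(ps))
}

#' Restrict a spectrum to an analysis band
#'
#' Keeps the points with `f_low <= frequency <= f_high` (closed interval).
#' This is the "meaningful part" of the spectrum on which slopes and
#' fingerprints are computed; the band is an operator choice, and
#' [default_band()] supplies a conservative default.
#'
#' @param ps a [fes_spectrum()].
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#'
#' @return the restricted [fes_spectrum()].
#' @examples
#' ps <- fes_spectrum(10^seq(-1, 2, by = 0.1), 10^-seq(-1, 2, by = 0.1))
#' select_band(ps, 1, 10)
#' @export
select_band <- function(ps, f_low, f_high) {
  ps <- as_fes_spectrum(ps)
  check_band(f_low, f_high)
  keep <- ps$frequency >= f_low & ps$frequency <= f_high
  if (sum(keep) < 2L) {
    abort(
      sprintf("band [%g, %g] Hz leaves %d spectrum point(s); need at least 2.",
              f_low, f_high, sum(keep)),
      class = "fes_band_error"
    )
  }
  fes_spectrum(ps$frequency[keep], ps$density[keep],
               n_averages = attr(ps, "n_averages", exact = TRUE),
               label = fes_label(ps))
}

#' Resample a spectrum onto a target frequency grid
#'
#' Interpolates `log10(density)` linearly against `log10(frequency)` at the
#' target frequencies. On a pure power law the interpolation is exact, since a
#' power law is a straight line in log-log coordinates. Extrapolation outside
#' the source support is refused.
#'
#' @param ps a [fes_spectrum()].
#' @param frequencies target frequencies in Hz; strictly ascending, all inside
#'   the source support.
#'
#' @return a [fes_spectrum()] on the target grid.
#' @examples
#' ps <- fes_spectrum(c(1, 100), c(1, 0.01))
#' resample_spectrum(ps, c(1, 10, 100))  # density 0.1 at 10 Hz
#' @export
resample_spectrum <- function(ps, frequencies) {
  ps <- as_fes_spectrum(ps)
  frequencies <- as.numeric(frequencies)
  if (length(frequencies) < 2L || any(diff(frequencies) <= 0) ||
      any(frequencies <= 0) || !all(is.finite(frequencies))) {
    abort("`frequencies` must be >= 2 finite positive strictly ascending values.",
          class = "fes_validation_error")
  }
  support <- range(ps$frequency)
  if (any(frequencies < support[1] | frequencies > support[2])) {
    bad <- frequencies[frequencies < support[1] | frequencies > support[2]][1L]
    abort(
      sprintf("target frequency %g Hz lies outside the spectrum support [%g, %g]; extrapolation is refused.",
              bad, support[1], support[2]),
      class = "fes_extrapolation_error"
    )
  }
  logd <- approx(log10(ps$frequency), log10(ps$density),
                 xout = log10(frequencies), ties = "ordered")$y
  fes_spectrum(frequencies, 10^logd,
               n_averages = attr(ps, "n_averages", exact = TRUE),
               label = fes_label(ps))
}

#' Default analysis band of a spectrum
#'
#' Returns `c(2 * min(frequency), 0.8 * max(frequency))`: the lowest retained
#' frequencies carry the largest estimator scatter and the top of the band may
#' be shaped by anti-aliasing roll-off, so both ends are trimmed. The band is
#' only a fallback; pass an explicit band where the instrument's meaningful
#' range is known.
#'
#' @param ps a [fes_spectrum()].
#' @return length-2 numeric vector `c(f_low, f_high)` in Hz.
#' @export
default_band <- function(ps) {
  ps <- as_fes_spectrum(ps)
  c(2 * ps$frequency[1L], 0.8 * ps$frequency[nrow(ps)])
}

as_fes_spectrum <- function(x) {
  if (inherits(x, "fes_spectrum")) return(x)
  if (is.data.frame(x) && all(c("frequency", "density") %in% names(x))) {
    return(fes_spectrum(x$frequency, x$density,
                        n_averages = attr(x, "n_averages", exact = TRUE) %||% NA_integer_,
                        label = attr(x, "label", exact = TRUE) %||% "spectrum"))
  }
  abort("expected a `fes_spectrum` or a data frame with `frequency` and `density` columns.",
        class = "fes_validation_error")
}

check_band <- function(f_low, f_high) {
  if (!is.numeric(f_low) || !is.numeric(f_high) ||
      length(f_low) != 1L || length(f_high) != 1L ||
      !is.finite(f_low) || !is.finite(f_high) ||
      f_low <= 0 || f_low >= f_high) {
    abort("band edges must satisfy 0 < f_low < f_high.",
          class = "fes_validation_error")
  }
  invisible(TRUE)
}
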