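#' Construct a sensor-noise time series record
#'
#' A time series record holds a uniformly sampled noise voltage trace together
#' with its sampling rate and a free-text label (agent, sensor or measurement
#' id). It is an ordinary tibble with columns `time` (seconds) and `value`
#' (voltage, arbitrary units); the sampling rate and label travel as
#' attributes so the record survives piping into [estimate_psd()].
#'
#' @param value numeric vector of sampled values; all finite, length >= 2.
#' @param sampling_rate sampling rate in Hz; strictly positive and finite.
#' @param label free-text label for provenance (default `"timeseries"`).
#'
#' @return a tibble of class `fes_timeseries` with columns `time` and `value`.
#' @examples
#' ts <- fes_timeseries(rnorm(1024), sampling_rate = 1000)
#' sampling_rate(ts)
#' @export
fes_timeseries <- function(value, sampling_rate, label = "timeseries") {
  value <- as.numeric(value)
  if (length(value) < 2L) {
    abort("`value` must contain at least 2 samples.", class = "fes_validation_error")
  }
  if (!all(is.finite(value))) {
    bad <- which(!is.finite(value))[1L]
    abort(
      sprintf("`value` must be finite everywhere; first non-finite sample at index %d.", bad),
      class = "fes_validation_error"
    )
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single finite positive number (Hz).",
          class = "fes_validation_error")
  }
  out <- tibble(time = (seq_along(value) - 1) / sampling_rate, value = value)
  new_fes_tbl(out, "fes_timeseries",
              sampling_rate = as.numeric(sampling_rate),
              label = as.character(label))
}

#' Sampling rate of a time series record
#'
#' @param ts a [fes_timeseries()] object.
#' @return the sampling rate in Hz.
#' @export
sampling_rate <- function(ts) {
  attr(ts, "sampling_rate", exact = TRUE)
}

#' Label attached to a fesprint object
#'
#' @param x a time series, spectrum, fingerprint or model object.
#' @return the label string, or `NA` if none is attached.
#' @export
fes_label <- function(x) {
  attr(x, "label", exact = TRUE) %||% NA_character_
}

# shared constructor: a tibble subclass carrying named attributes
new_fes_tbl <- function(data, subclass, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(data, nm) <- attrs[[nm]]
  class(data) <- c(subclass, class(tibble()))
  data
}

as_fes_timeseries <- function(x, sampling_rate = NULL) {
  if (inherits(x, "fes_timeseries")) return(x)
  if (is.data.frame(x)) {
    if (all(c("time", "value") %in% names(x))) {
      dt <- diff(x$time)
      check_uniform_dt(dt)
      return(fes_timeseries(x$value, sampling_rate = 1 / mean(dt)))
    }
    if ("value" %in% names(x)) {
      if (is.null(sampling_rate)) {
        abort("a `value`-only data frame needs `sampling_rate`.",
              class = "fes_validation_error")
      }
      return(fes_timeseries(x$value, sampling_rate = sampling_rate))
    }
  }
  if (is.numeric(x)) {
    if (is.null(sampling_rate)) {
      abort("a bare numeric vector needs `sampling_rate`.",
            class = "fes_validation_error")
    }
    return(fes_timeseries(x, sampling_rate = sampling_rate))
  }
  abort("cannot interpret input as a time series record.",
        class = "fes_validation_error")
}

check_uniform_dt <- function(dt, rel_tol = 1e-6, what = "time") {
  if (any(dt <= 0)) {
    abort(sprintf("`%s` column must be strictly increasing.", what),
          class = "fes_parse_error")
  }
  dt0 <- mean(dt)
  if (any(abs(dt - dt0) > rel_tol * dt0)) {
    bad <- which(abs(dt - dt0) > rel_tol * dt0)[1L]
    abort(
      sprintf("non-uniform %s grid: step %d deviates from the mean step by more than %g relative.",
              what, bad, rel_tol),
      class = "fes_parse_error"
    )
  }
  invisible(dt0)
}
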