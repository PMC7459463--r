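#' Analysis configuration for the end-to-end pipeline
#'
#' Bundles and validates every tunable of the sensing chain. Each constraint
#' is checked at construction with a field-specific message, so a bad
#' configuration fails before any data are touched. `f_low`/`f_high` may be
#' left `NULL` to fall back on [default_band()] of each estimated spectrum.
#'
#' @param segment_length Welch segment length in samples (>= 16).
#' @param overlap Welch overlap fraction in `[0, 1)`.
#' @param window `"hann"`, `"hamming"` or `"rectangular"`.
#' @param log_bins_per_decade log-binning resolution (>= 1).
#' @param f_low,f_high analysis band in Hz (`NULL` = automatic).
#' @param n_subbands number of fingerprint sub-bands (>= 1).
#' @param tie_tolerance ternary tie tolerance in slope units (>= 0).
#' @param seed integer seed for any simulation step.
#' @param verbose log the resolved settings and each stage?
#' @return a list of class `fes_config`.
#' @examples
#' cfg <- fes_config(f_low = 10, f_high = 400)
#' @export
fes_config <- function(segment_length = 4096, overlap = 0.5,
                       window = c("hann", "hamming", "rectangular"),
                       log_bins_per_decade = 12,
                       f_low = NULL, f_high = NULL,
                       n_subbands = 5, tie_tolerance = 0.05,
                       seed = 1L, verbose = TRUE) {
  window <- match.arg(window)
  check_scalar <- function(x, name, lo, hi = Inf, int = FALSE,
                           lo_open = FALSE, hi_open = FALSE) {
    ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
      (if (lo_open) x > lo else x >= lo) &&
      (if (hi_open) x < hi else x <= hi) &&
      (!int || x == round(x))
    if (!ok) {
      abort(sprintf("`%s` must be a %s in %s%g, %g%s.",
                    name, if (int) "whole number" else "number",
                    if (lo_open) "(" else "[", lo, hi,
                    if (hi_open) ")" else "]"),
            class = "fes_validation_error")
    }
    x
  }
  check_scalar(segment_length, "segment_length", 16, int = TRUE)
  check_scalar(overlap, "overlap", 0, 1, hi_open = TRUE)
  check_scalar(log_bins_per_decade, "log_bins_per_decade", 1)
  check_scalar(n_subbands, "n_subbands", 1, int = TRUE)
  check_scalar(tie_tolerance, "tie_tolerance", 0)
  check_scalar(seed, "seed", -2^31, 2^31, int = TRUE)
  if (!is.null(f_low) || !is.null(f_high)) {
    if (is.null(f_low) || is.null(f_high)) {
      abort("give both `f_low` and `f_high`, or neither.",
            class = "fes_validation_error")
    }
    check_band(f_low, f_high)
  }
  structure(
    list(segment_length = as.integer(segment_length), overlap = overlap,
         window = window, log_bins_per_decade = log_bins_per_decade,
         f_low = f_low, f_high = f_high,
         n_subbands = as.integer(n_subbands), tie_tolerance = tie_tolerance,
         seed = as.integer(seed), verbose = isTRUE(verbose)),
    class = "fes_config"
  )
}

#' Run the full sensing chain on one or two measurements
#'
#' Executes spectrum estimation, smoothing, band selection and fingerprinting
#' end to end, with optional classification against a library: the software
#' analogue of the sensor / pattern-extractor / classifier chain. Inputs may
#' be time series records, file paths, or spectrum models (which are simulated
#' under `config$seed` first). When `agent` is a list of two records (a
#' measurement pair), both are fingerprinted and their bit agreement is
#' reported. A `reference` turns the fingerprints ternary; without one they
#' are binary.
#'
#' Every parameter actually used is logged (when `config$verbose`), so no
#' analysis setting stays implicit. When `out_dir` is given, the spectra
#' (CSV) and fingerprints (JSON) are written there with deterministic
#' content.
#'
#' @param agent a [fes_timeseries()], a file path, a [spectrum_model()], or a
#'   list of two of these (a measurement pair).
#' @param reference optional reference odor: time series, path, model, or a
#'   ready [fes_spectrum()].
#' @param library optional [fingerprint_library()] for classification.
#' @param config a [fes_config()].
#' @param out_dir optional directory for artifacts.
#' @param sampling_rate fallback sampling rate for value-only inputs, and the
#'   rate used when simulating from models (default from
#'   [default_conditions()]).
#' @param n_samples samples to draw when simulating from models.
#'
#' @return a list of class `fes_run`: `spectra` (list of [fes_spectrum()]),
#'   `fingerprints` (list of `fes_fingerprint`), `agreement` (fraction or
#'   `NULL`), `classification` (tibble or `NULL`), `config`.
#' @examples
#' mods <- example_models()
#' run <- run_pipeline(mods$agent, reference = mods$reference,
#'                     config = fes_config(f_low = 10, f_high = 400,
#'                                         verbose = FALSE),
#'                     n_samples = 2^15)
#' fingerprint_bits(run$fingerprints[[1]])
#' @export
run_pipeline <- function(agent, reference = NULL, library = NULL,
                         config = fes_config(), out_dir = NULL,
                         sampling_rate = default_conditions()$sampling_rate,
                         n_samples = default_conditions()$n_samples) {
  stopifnot(inherits(config, "fes_config"))
  say <- function(...) if (config$verbose) message(sprintf(...))
  say("pipeline settings: segment=%d overlap=%g window=%s log_bins=%g band=%s subbands=%d tie_tol=%g seed=%d",
      config$segment_length, config$overlap, config$window,
      config$log_bins_per_decade,
      if (is.null(config$f_low)) "auto"
      else sprintf("[%g, %g] Hz", config$f_low, config$f_high),
      config$n_subbands, config$tie_tolerance, config$seed)

  is_pair <- is.list(agent) && !is.data.frame(agent) &&
    !inherits(agent, "fes_spectrum_model") && length(agent) == 2L
  inputs <- if (is_pair) agent else list(agent)

  to_spectrum <- function(x, seed, stage) {
    ts <- if (inherits(x, "fes_spectrum_model")) {
      say("[%s] simulating %d samples at %g Hz (seed %d)", stage, n_samples,
          sampling_rate, seed)
      simulate_noise(x, n_samples, sampling_rate, seed)
    } else if (is.character(x)) {
      say("[%s] reading %s", stage, x)
      read_timeseries(x, sampling_rate = sampling_rate)
    } else {
      as_fes_timeseries(x, sampling_rate = sampling_rate)
    }
    ps <- estimate_psd(ts, segment_length = config$segment_length,
                       overlap = config$overlap, window = config$window) |>
      log_bin_spectrum(bins_per_decade = config$log_bins_per_decade)
    band <- if (is.null(config$f_low)) default_band(ps)
            else c(config$f_low, config$f_high)
    say("[%s] %d averaged segments; analysis band [%g, %g] Hz", stage,
        attr(ps, "n_averages", exact = TRUE), band[1], band[2])
    # keep one log bin of margin on each side so the binned grid (whose
    # points sit at in-bin geometric means) still covers the plan edges
    pad <- 10^(1 / config$log_bins_per_decade)
    sel <- select_band(ps,
                       max(ps$frequency[1L], band[1L] / pad),
                       min(ps$frequency[nrow(ps)], band[2L] * pad))
    list(spectrum = sel, band = band)
  }

  stages <- purrr::imap(inputs, function(x, i) {
    to_spectrum(x, config$seed + (i - 1L) * 2L, paste0("psd-", i))
  })
  spectra <- purrr::map(stages, "spectrum")
  band <- stages[[1L]]$band
  plan <- band_plan(band[1L], band[2L], config$n_subbands)

  ref_spectrum <- NULL
  if (!is.null(reference)) {
    ref_spectrum <- if (inherits(reference, "fes_spectrum")) reference
      else if (is.data.frame(reference) &&
               all(c("frequency", "density") %in% names(reference))) {
        as_fes_spectrum(reference)
      } else {
        to_spectrum(reference, config$seed + 101L, "psd-reference")$spectrum
      }
  }

  fingerprints <- purrr::map(spectra, function(ps) {
    if (is.null(ref_spectrum)) {
      binary_fingerprint(ps, plan)
    } else {
      ternary_fingerprint(ps, ref_spectrum, plan,
                          tie_tolerance = config$tie_tolerance)
    }
  })
  scheme <- fingerprint_scheme(fingerprints[[1L]])
  say("[fingerprint] %s bits: %s", scheme,
      paste(purrr::map_chr(fingerprints,
                           ~ paste(fingerprint_bits(.x), collapse = " ")),
            collapse = " | "))

  agreement <- NULL
  if (is_pair) {
    agreement <- bit_agreement(fingerprints[[1L]], fingerprints[[2L]])
    say("[compare] bit agreement between the pair: %.3f", agreement)
  }

  classification <- NULL
  if (!is.null(library)) {
    classification <- classify_fingerprint(fingerprints[[1L]], library)
    say("[classify] nearest: %s (distance %g%s)",
        paste(classification$label, collapse = ", "),
        classification$distance[1L],
        if (classification$ambiguous[1L]) ", ambiguous" else "")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (i in seq_along(spectra)) {
      write_spectrum(spectra[[i]], file.path(out_dir, sprintf("spectrum-%d.csv", i)))
      write_fingerprint(fingerprints[[i]],
                        file.path(out_dir, sprintf("fingerprint-%d.json", i)))
    }
    if (!is.null(ref_spectrum)) {
      write_spectrum(ref_spectrum, file.path(out_dir, "reference-spectrum.csv"))
    }
    say("[write] artifacts in %s", out_dir)
  }

  structure(
    list(spectra = spectra, fingerprints = fingerprints,
         reference_spectrum = ref_spectrum,
         agreement = agreement, classification = classification,
         config = config),
    class = "fes_run"
  )
}
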