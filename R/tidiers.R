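#' Tidy a fingerprint into a plain tibble
#'
#' @param x a `fes_fingerprint`.
#' @param ... unused.
#' @return a tibble with one row per sub-band (`band`, `f_lo`, `f_hi`,
#'   `local_slope`, `reference_slope`, `delta`, `bit`).
#' @method tidy fes_fingerprint
#' @export
tidy.fes_fingerprint <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' One-row summary of a fingerprint
#'
#' @param x a `fes_fingerprint`.
#' @param ... unused.
#' @return a one-row tibble: scheme, band, sub-band count, symbol counts,
#'   global slope, tie tolerance, reference label, and the per-symbol and
#'   total information entropy of the alphabet.
#' @method glance fes_fingerprint
#' @export
glance.fes_fingerprint <- function(x, ...) {
  bits <- fingerprint_bits(x)
  scheme <- fingerprint_scheme(x)
  tibble(
    scheme = scheme,
    f_low = x$f_lo[1L],
    f_high = x$f_hi[nrow(x)],
    n_subbands = nrow(x),
    n_negative = sum(bits == -1L),
    n_zero = sum(bits == 0L),
    n_positive = sum(bits == 1L),
    global_slope = attr(x, "global_slope", exact = TRUE),
    tie_tolerance = attr(x, "tie_tolerance", exact = TRUE),
    reference_label = attr(x, "reference_label", exact = TRUE),
    entropy_per_symbol = alphabet_entropy(scheme),
    entropy_total = nrow(x) * alphabet_entropy(scheme)
  )
}

#' Tidy a fingerprint library into a long tibble
#'
#' @param x a [fingerprint_library()].
#' @param ... unused.
#' @return a tibble with columns `label`, `band`, `bit`.
#' @method tidy fes_library
#' @export
tidy.fes_library <- function(x, ...) {
  purrr::map2_dfr(x$label, x$fingerprint, function(lab, fp) {
    tibble(label = lab, band = fp$band, bit = fp$bit)
  })
}

#' One-row summary of a spectrum
#'
#' @param x a [fes_spectrum()].
#' @param ... unused.
#' @return a one-row tibble: point count, support, averaged-segment count,
#'   integrated power over the support (trapezoidal), and the global chord
#'   slope over the full support.
#' @method glance fes_spectrum
#' @export
glance.fes_spectrum <- function(x, ...) {
  f <- x$frequency
  s <- x$density
  tibble(
    n_points = length(f),
    f_min = f[1L],
    f_max = f[length(f)],
    n_averages = attr(x, "n_averages", exact = TRUE),
    total_power = sum(diff(f) * (s[-1L] + s[-length(s)]) / 2),
    global_slope = endpoint_slope(x, f[1L], f[length(f)])
  )
}

#' One-row summary of a pipeline run
#'
#' @param x a `fes_run` from [run_pipeline()].
#' @param ... unused.
#' @return a one-row tibble: scheme, number of measurements, fingerprint
#'   string(s), pair agreement and classification outcome where present.
#' @method glance fes_run
#' @export
glance.fes_run <- function(x, ...) {
  fp_string <- function(fp) paste(fingerprint_bits(fp), collapse = ",")
  tibble(
    scheme = fingerprint_scheme(x$fingerprints[[1L]]),
    n_measurements = length(x$fingerprints),
    fingerprints = paste(vapply(x$fingerprints, fp_string, character(1)),
                         collapse = " | "),
    agreement = x$agreement %||% NA_real_,
    nearest_label = if (is.null(x$classification)) NA_character_
                    else paste(x$classification$label, collapse = ", "),
    nearest_distance = if (is.null(x$classification)) NA_real_
                       else x$classification$distance[1L]
  )
}
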