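#' Chord slope of a log-log spectrum between two frequencies
#'
#' The slope is obtained by connecting the two endpoints of the band on
#' log-log axes:
#' `(log10 S(f_hi) - log10 S(f_lo)) / (log10 f_hi - log10 f_lo)`.
#' Interior points are deliberately ignored -- the fingerprinting scheme is
#' defined on chord (endpoint) slopes, not least-squares fits. Endpoint
#' densities are taken from the spectrum by log-log interpolation when the
#' endpoints do not fall on grid points.
#'
#' Chord slopes are invariant under scaling the density by any positive
#' constant, so fingerprints do not depend on gain or amplification.
#'
#' @param ps a [fes_spectrum()].
#' @param f_lo,f_hi chord endpoints in Hz, `0 < f_lo < f_hi`, both inside the
#'   spectrum support.
#'
#' @return a single dimensionless slope (d log10 S / d log10 f).
#' @examples
#' ps <- fes_spectrum(c(1, 10, 100), c(1, 5, 0.01))
#' endpoint_slope(ps, 1, 100)  # -1: the interior bump is ignored
#' @export
endpoint_slope <- function(ps, f_lo, f_hi) {
  ps <- as_fes_spectrum(ps)
  check_band(f_lo, f_hi)
  s <- resample_at(ps, c(f_lo, f_hi))
  (log10(s[2L]) - log10(s[1L])) / (log10(f_hi) - log10(f_lo))
}

# density at arbitrary frequencies via log-log interpolation (no extrapolation)
resample_at <- function(ps, frequencies) {
  support <- range(ps$frequency)
  out_of <- frequencies < support[1] | frequencies > support[2]
  if (any(out_of)) {
    abort(
      sprintf("frequency %g Hz lies outside the spectrum support [%g, %g].",
              frequencies[out_of][1L], support[1], support[2]),
      class = "fes_extrapolation_error"
    )
  }
  10^approx(log10(ps$frequency), log10(ps$density),
            xout = log10(frequencies), ties = "ordered")$y
}

#' Tile an analysis band into log-equal sub-bands
#'
#' Splits `[f_low, f_high]` into `n_subbands` contiguous sub-bands whose edges
#' are equally spaced in `log10(frequency)`:
#' `edges[k] = f_low * (f_high / f_low)^(k / n)`. Equal log width matters: it
#' makes the mean of the local chord slopes equal the global chord slope
#' (the chords telescope), which anchors the binary coding rule.
#'
#' @param f_low,f_high band edges in Hz, `0 < f_low < f_high`.
#' @param n_subbands number of sub-bands (>= 1; default 5, matching the
#'   five-bit displays customary in FES work).
#'
#' @return a tibble of class `fes_band_plan` with columns `band`, `f_lo`,
#'   `f_hi`; the full edge vector is in the `edges` attribute.
#' @examples
#' band_plan(1, 100, 2)  # edges 1, 10, 100
#' @export
band_plan <- function(f_low, f_high, n_subbands = 5) {
  check_band(f_low, f_high)
  n_subbands <- as.integer(n_subbands)
  if (is.na(n_subbands) || n_subbands < 1L) {
    abort("`n_subbands` must be a positive integer.", class = "fes_validation_error")
  }
  edges <- f_low * (f_high / f_low)^(seq(0, n_subbands) / n_subbands)
  edges[1L] <- f_low
  edges[n_subbands + 1L] <- f_high
  out <- tibble(
    band = seq_len(n_subbands),
    f_lo = edges[-(n_subbands + 1L)],
    f_hi = edges[-1L]
  )
  new_fes_tbl(out, "fes_band_plan", edges = edges)
}

#' Global and local chord slopes of a spectrum over a band plan
#'
#' Computes the global chord slope over the plan's full band and the local
#' chord slope over each sub-band, all by [endpoint_slope()].
#'
#' @param ps a [fes_spectrum()] whose support covers the plan's band.
#' @param plan a [band_plan()].
#'
#' @return a tibble of class `fes_slopes` with columns `band`, `f_lo`, `f_hi`,
#'   `local_slope`; the global slope is in the `global_slope` attribute.
#' @examples
#' f <- 10^seq(0, 2, by = 0.05)
#' ps <- fes_spectrum(f, f^-1.5)
#' slope_profile(ps, band_plan(1, 100, 5))
#' @export
slope_profile <- function(ps, plan) {
  ps <- as_fes_spectrum(ps)
  plan <- as_band_plan(plan)
  edges <- attr(plan, "edges", exact = TRUE)
  global <- endpoint_slope(ps, edges[1L], edges[length(edges)])
  local <- purrr::map2_dbl(plan$f_lo, plan$f_hi, ~ endpoint_slope(ps, .x, .y))
  out <- tibble(band = plan$band, f_lo = plan$f_lo, f_hi = plan$f_hi,
                local_slope = local)
  new_fes_tbl(out, "fes_slopes",
              global_slope = global, edges = edges, label = fes_label(ps))
}

as_band_plan <- function(plan) {
  if (inherits(plan, "fes_band_plan")) return(plan)
  if (is.data.frame(plan) && all(c("f_lo", "f_hi") %in% names(plan))) {
    edges <- c(plan$f_lo, plan$f_hi[nrow(plan)])
    if (any(abs(plan$f_hi[-nrow(plan)] - plan$f_lo[-1L]) >
            1e-9 * plan$f_hi[-nrow(plan)])) {
      abort("sub-bands must tile the band contiguously (each f_hi = next f_lo).",
            class = "fes_validation_error")
    }
    out <- tibble(band = seq_len(nrow(plan)), f_lo = plan$f_lo, f_hi = plan$f_hi)
    return(new_fes_tbl(out, "fes_band_plan", edges = edges))
  }
  abort("expected a `fes_band_plan` (see `band_plan()`).",
        class = "fes_validation_error")
}
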