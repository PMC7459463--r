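#' Binary fingerprint of a spectrum
#'
#' Codes the slope structure of a log-log power density spectrum into symbols
#' from `{-1, +1}`: the analysis band is tiled into log-equal sub-bands, and
#' each sub-band's local chord slope is compared with the global chord slope
#' over the whole band. A local slope below the global slope gives -1,
#' otherwise +1 -- ties go to +1 by the coding rule, so a pure power law
#' (where every local slope equals the global slope) codes as all +1.
#'
#' Because the local chords of a log-equal tiling telescope, their mean equals
#' the global chord slope; consequently a binary fingerprint always contains
#' at least one +1.
#'
#' @param ps a [fes_spectrum()].
#' @param plan a [band_plan()]; when `NULL`, [default_band()] with
#'   `n_subbands` sub-bands is used.
#' @param n_subbands sub-band count for the default plan (ignored when `plan`
#'   is given).
#'
#' @return a tibble of class `fes_fingerprint` with one row per sub-band:
#'   columns `band`, `f_lo`, `f_hi`, `local_slope`, `reference_slope` (`NA`
#'   for the binary scheme), `delta` (`NA`), `bit`. Attributes: `scheme`
#'   (`"binary"`), `global_slope`, `tie_tolerance` (`NA`), `reference_label`
#'   (`NA`), `label`.
#' @examples
#' f <- 10^seq(0, 2, by = 0.02)
#' ps <- fes_spectrum(f, ifelse(f < 10, f^-1, 0.1 * (f / 10)^-2))
#' binary_fingerprint(ps, band_plan(1, 100, 2))
#' @export
binary_fingerprint <- function(ps, plan = NULL, n_subbands = 5) {
  ps <- as_fes_spectrum(ps)
  if (is.null(plan)) {
    b <- default_band(ps)
    plan <- band_plan(b[1L], b[2L], n_subbands)
  }
  prof <- slope_profile(ps, plan)
  global <- attr(prof, "global_slope", exact = TRUE)
  bit <- ifelse(prof$local_slope < global, -1L, 1L)
  new_fingerprint(prof, bit,
                  scheme = "binary",
                  global_slope = global,
                  tie_tolerance = NA_real_,
                  reference_label = NA_character_,
                  label = fes_label(ps))
}

#' Ternary fingerprint of a spectrum relative to a reference odor
#'
#' Codes the slope structure of an agent spectrum relative to a reference
#' spectrum into symbols from `{-1, 0, +1}`: in each sub-band, the agent's
#' local chord slope is compared with the reference's local chord slope over
#' the same sub-band. A smaller agent slope gives -1, a greater one +1, and
#' slopes equal within `tie_tolerance` give 0. The 0 symbol is what makes the
#' alphabet ternary; with it, each symbol carries `log2(3)` bits instead of 1,
#' and different reference odors produce different fingerprints of the same
#' agent, so the code is relative to the chosen reference.
#'
#' On floating-point slopes exact equality is a null event, so the tie is
#' declared within an explicit tolerance (default 0.05 slope units -- the
#' "resolution" of the slope comparison). Increasing the tolerance can only
#' turn -1/+1 symbols into 0, never flip a sign.
#'
#' The reference is resampled onto the agent's frequency grid (log-log
#' interpolation) before slope extraction so that both slopes are measured
#' between identical endpoints.
#'
#' @param agent a [fes_spectrum()] of the chemical environment being coded.
#' @param reference a [fes_spectrum()] of the reference odor; its support must
#'   cover the plan's band.
#' @param plan a [band_plan()]; when `NULL`, [default_band()] of the agent
#'   with `n_subbands` sub-bands.
#' @param tie_tolerance slope difference magnitude (dimensionless) at or below
#'   which the two slopes are declared equal; >= 0.
#' @param n_subbands sub-band count for the default plan.
#'
#' @return a tibble of class `fes_fingerprint` (columns as in
#'   [binary_fingerprint()], with `reference_slope` and
#'   `delta = local_slope - reference_slope` filled); attributes `scheme`
#'   (`"ternary"`), `global_slope`, `reference_global_slope`, `tie_tolerance`,
#'   `reference_label`, `label`.
#' @examples
#' f <- 10^seq(0, 2, by = 0.02)
#' agent <- fes_spectrum(f, f^-1, label = "agent")
#' ref <- fes_spectrum(f, f^-2, label = "lab air")
#' ternary_fingerprint(agent, ref, band_plan(1, 100, 5))  # all +1
#' @export
ternary_fingerprint <- function(agent, reference, plan = NULL,
                                tie_tolerance = 0.05, n_subbands = 5) {
  agent <- as_fes_spectrum(agent)
  reference <- as_fes_spectrum(reference)
  if (!is.numeric(tie_tolerance) || length(tie_tolerance) != 1L ||
      is.na(tie_tolerance) || tie_tolerance < 0) {
    abort("`tie_tolerance` must be a single number >= 0.",
          class = "fes_validation_error")
  }
  if (is.null(plan)) {
    b <- default_band(agent)
    plan <- band_plan(b[1L], b[2L], n_subbands)
  }
  plan <- as_band_plan(plan)
  edges <- attr(plan, "edges", exact = TRUE)
  band <- range(edges)
  rsup <- range(reference$frequency)
  asup <- range(agent$frequency)
  if (rsup[1] > band[1] || rsup[2] < band[2] ||
      asup[1] > band[1] || asup[2] < band[2]) {
    abort(
      sprintf("both spectra must cover the plan band [%g, %g] Hz (agent support [%g, %g], reference [%g, %g]).",
              band[1], band[2], asup[1], asup[2], rsup[1], rsup[2]),
      class = "fes_alignment_error"
    )
  }
  # put the reference on the agent's grid so chords share endpoints exactly;
  # the plan edges are added to the grid so each chord endpoint is taken from
  # the reference's own sampling rather than re-interpolated across it
  grid <- agent$frequency[agent$frequency >= rsup[1] & agent$frequency <= rsup[2]]
  grid <- sort(unique(c(grid, edges)))
  ref_aligned <- resample_spectrum(reference, grid)

  prof_a <- slope_profile(agent, plan)
  prof_r <- slope_profile(ref_aligned, plan)
  delta <- prof_a$local_slope - prof_r$local_slope
  bit <- as.integer(sign(delta))
  bit[abs(delta) <= tie_tolerance] <- 0L

  out <- new_fingerprint(prof_a, bit,
                         scheme = "ternary",
                         global_slope = attr(prof_a, "global_slope", exact = TRUE),
                         tie_tolerance = tie_tolerance,
                         reference_label = fes_label(reference),
                         label = fes_label(agent))
  out$reference_slope <- prof_r$local_slope
  out$delta <- delta
  attr(out, "reference_global_slope") <- attr(prof_r, "global_slope", exact = TRUE)
  out
}

new_fingerprint <- function(prof, bit, scheme, global_slope, tie_tolerance,
                            reference_label, label) {
  out <- tibble(
    band = prof$band,
    f_lo = prof$f_lo,
    f_hi = prof$f_hi,
    local_slope = prof$local_slope,
    reference_slope = NA_real_,
    delta = NA_real_,
    bit = as.integer(bit)
  )
  new_fes_tbl(out, "fes_fingerprint",
              scheme = scheme,
              global_slope = global_slope,
              tie_tolerance = tie_tolerance,
              reference_label = reference_label,
              edges = c(prof$f_lo, prof$f_hi[nrow(prof)]),
              label = label)
}

#' Construct a fingerprint from its symbols
#'
#' Builds a fingerprint object directly from a symbol vector and band edges,
#' for example to enter a published fingerprint by hand or to assemble a
#' classification library from recorded codes. The scheme invariants are
#' enforced: a binary fingerprint may not contain 0 symbols and carries no
#' reference, a ternary fingerprint must name its reference odor.
#'
#' @param bits integer vector over `{-1, 0, +1}` (over `{-1, +1}` for the
#'   binary scheme), one symbol per sub-band.
#' @param edges sub-band edges in Hz, strictly ascending, length
#'   `length(bits) + 1`.
#' @param scheme `"binary"` or `"ternary"`.
#' @param tie_tolerance the tie tolerance the code was produced with
#'   (ternary; `NA` when unknown).
#' @param reference_label reference odor label (required for ternary).
#' @param label fingerprint label.
#' @return a `fes_fingerprint` tibble (slope columns are `NA`).
#' @examples
#' fes_fingerprint(c(1, -1, 0, 1, 1), edges = 10 * 40^(0:5 / 5),
#'                 scheme = "ternary", reference_label = "lab air")
#' @export
fes_fingerprint <- function(bits, edges, scheme = c("binary", "ternary"),
                            tie_tolerance = NA_real_,
                            reference_label = NA_character_,
                            label = "fingerprint") {
  scheme <- match.arg(scheme)
  bits <- as.integer(bits)
  edges <- as.numeric(edges)
  if (!all(bits %in% c(-1L, 0L, 1L))) {
    abort("`bits` must take values -1, 0 or +1.", class = "fes_validation_error")
  }
  if (scheme == "binary" && any(bits == 0L)) {
    abort("a binary fingerprint cannot contain 0 symbols.",
          class = "fes_validation_error")
  }
  if (scheme == "binary" && !is.na(reference_label)) {
    abort("a binary fingerprint carries no reference label.",
          class = "fes_validation_error")
  }
  if (scheme == "ternary" && is.na(reference_label)) {
    abort("a ternary fingerprint must name its `reference_label`.",
          class = "fes_validation_error")
  }
  if (length(edges) != length(bits) + 1L || any(!is.finite(edges)) ||
      any(edges <= 0) || any(diff(edges) <= 0)) {
    abort("`edges` must be positive, strictly ascending, length(bits) + 1.",
          class = "fes_validation_error")
  }
  if (!is.na(tie_tolerance) && tie_tolerance < 0) {
    abort("`tie_tolerance` must be >= 0.", class = "fes_validation_error")
  }
  n <- length(bits)
  out <- tibble(
    band = seq_len(n),
    f_lo = edges[-(n + 1L)],
    f_hi = edges[-1L],
    local_slope = NA_real_,
    reference_slope = NA_real_,
    delta = NA_real_,
    bit = bits
  )
  new_fes_tbl(out, "fes_fingerprint",
              scheme = scheme, global_slope = NA_real_,
              tie_tolerance = as.numeric(tie_tolerance),
              reference_label = as.character(reference_label),
              edges = edges, label = as.character(label))
}

#' Fingerprint symbols as a plain vector
#'
#' @param fp a `fes_fingerprint`.
#' @return integer vector over `{-1, 0, +1}`.
#' @export
fingerprint_bits <- function(fp) {
  stopifnot(inherits(fp, "fes_fingerprint") ||
              (is.data.frame(fp) && "bit" %in% names(fp)))
  as.integer(fp$bit)
}

#' Coding scheme of a fingerprint
#'
#' @param fp a `fes_fingerprint`.
#' @return `"binary"` or `"ternary"`.
#' @export
fingerprint_scheme <- function(fp) {
  attr(fp, "scheme", exact = TRUE)
}

#' Information entropy of a fingerprint symbol
#'
#' Under a uniform symbol model, one symbol of an alphabet of size `m`
#' carries `log2(m)` bits. A ternary symbol therefore carries
#' `log2(3) = ln(3)/ln(2)` times the information of a binary one.
#'
#' @param scheme `"binary"` or `"ternary"`.
#' @return entropy in bits per symbol.
#' @examples
#' alphabet_entropy("binary")   # 1
#' alphabet_entropy("ternary")  # log2(3) ~ 1.585
#' @export
alphabet_entropy <- function(scheme = c("binary", "ternary")) {
  scheme <- match.arg(scheme)
  switch(scheme, binary = 1, ternary = log2(3))
}

#' Per-symbol entropy gain of the ternary over the binary alphabet
#'
#' @return the percentage increase, `100 * (log2(3) - 1)` (about 58.5%).
#' @examples
#' entropy_increase()
#' @export
entropy_increase <- function() {
  100 * (log2(3) - 1)
}
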