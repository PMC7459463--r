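#' Hamming distance between two fingerprints
#'
#' Counts the positions at which the two symbol strings differ. The plain
#' count treats a sign flip (+1 vs -1) and a zero transition (0 vs +-1)
#' equally; the weighted variant charges a sign flip 2 and a zero transition
#' 1 (`sum(|a_i - b_i|)`), for callers who consider a full sign reversal a
#' larger disagreement. The unweighted count is the default and the metric
#' used by [classify_fingerprint()].
#'
#' Both fingerprints must come from the same scheme, sub-band count and band
#' edges; comparing incompatible codes is refused with a message naming the
#' mismatched attribute.
#'
#' @param a,b `fes_fingerprint` objects.
#' @param weighted use the weighted count?
#' @return a non-negative count (integer-valued numeric).
#' @examples
#' f <- 10^seq(0, 2, by = 0.02)
#' plan <- band_plan(1, 100, 5)
#' ref <- fes_spectrum(f, f^-1.5)
#' a <- ternary_fingerprint(fes_spectrum(f, f^-1), ref, plan)
#' b <- ternary_fingerprint(fes_spectrum(f, f^-2), ref, plan)
#' fingerprint_distance(a, b)
#' @export
fingerprint_distance <- function(a, b, weighted = FALSE) {
  check_compatible(a, b)
  if (weighted) {
    as.integer(sum(abs(fingerprint_bits(a) - fingerprint_bits(b))))
  } else {
    as.integer(sum(fingerprint_bits(a) != fingerprint_bits(b)))
  }
}

#' Fraction of agreeing fingerprint positions
#'
#' `1 - distance / length`: the reproducibility statistic for repeated
#' measurements of the same sample -- two measurements whose fingerprints
#' agree in every position score 1.
#'
#' @inheritParams fingerprint_distance
#' @return a fraction in `[0, 1]`.
#' @export
bit_agreement <- function(a, b) {
  1 - fingerprint_distance(a, b) / nrow(a)
}

#' Build a labelled fingerprint library
#'
#' Collects fingerprints of known chemical environments so an unknown can be
#' identified by nearest fingerprint. All entries must share the scheme, the
#' sub-band count, the band edges and (for ternary codes) the reference
#' label; labels must be unique. Labels default to each fingerprint's own
#' `label` attribute and can be overridden with a named list.
#'
#' @param fingerprints a list of `fes_fingerprint` objects, optionally named
#'   (names become entry labels).
#'
#' @return a tibble of class `fes_library` with columns `label` and
#'   `fingerprint` (a list-column).
#' @examples
#' f <- 10^seq(0, 2, by = 0.02)
#' plan <- band_plan(1, 100, 3)
#' lib <- fingerprint_library(list(
#'   shallow = binary_fingerprint(fes_spectrum(f, f^-0.5 + f^-2), plan),
#'   steep = binary_fingerprint(fes_spectrum(f, f^-2 + f^-0.2), plan)
#' ))
#' @export
fingerprint_library <- function(fingerprints) {
  if (!is.list(fingerprints) || length(fingerprints) == 0L ||
      inherits(fingerprints, "fes_fingerprint")) {
    abort("`fingerprints` must be a non-empty list of fingerprints.",
          class = "fes_validation_error")
  }
  labels <- names(fingerprints) %||% rep(NA_character_, length(fingerprints))
  labels <- ifelse(is.na(labels) | labels == "",
                   vapply(fingerprints, fes_label, character(1)), labels)
  if (anyDuplicated(labels)) {
    abort(sprintf("library labels must be unique; duplicated: %s.",
                  paste(unique(labels[duplicated(labels)]), collapse = ", ")),
          class = "fes_validation_error")
  }
  ref <- fingerprints[[1L]]
  for (i in seq_along(fingerprints)) {
    check_compatible(ref, fingerprints[[i]])
    ra <- attr(ref, "reference_label", exact = TRUE)
    rb <- attr(fingerprints[[i]], "reference_label", exact = TRUE)
    if (!identical(is.na(ra), is.na(rb)) || (!is.na(ra) && !identical(ra, rb))) {
      abort(
        sprintf("library entries mix reference labels ('%s' vs '%s' in entry '%s').",
                ra, rb, labels[i]),
        class = "fes_compatibility_error"
      )
    }
  }
  out <- tibble(label = labels, fingerprint = unname(fingerprints))
  new_fes_tbl(out, "fes_library",
              scheme = fingerprint_scheme(ref),
              edges = attr(ref, "edges", exact = TRUE),
              tie_tolerance = attr(ref, "tie_tolerance", exact = TRUE),
              reference_label = attr(ref, "reference_label", exact = TRUE))
}

#' Identify an unknown fingerprint against a library
#'
#' Returns the library entry (or entries) at minimum Hamming distance from
#' the query -- the "address lookup" that turns a fingerprint into the name of
#' a chemical environment, generalised to nearest match. Ties are surfaced,
#' never broken silently: when several entries are equidistant the result has
#' one row per tied label and `ambiguous = TRUE`.
#'
#' @param query a `fes_fingerprint` compatible with the library.
#' @param library a [fingerprint_library()].
#' @return a tibble with columns `label`, `distance`, `agreement`,
#'   `ambiguous`; one row when the minimiser is unique.
#' @examples
#' f <- 10^seq(0, 2, by = 0.02)
#' plan <- band_plan(1, 100, 3)
#' lib <- fingerprint_library(list(
#'   shallow = binary_fingerprint(fes_spectrum(f, f^-0.5 + f^-2), plan),
#'   steep = binary_fingerprint(fes_spectrum(f, f^-2 + f^-0.2), plan)
#' ))
#' classify_fingerprint(lib$fingerprint[[1]], lib)
#' @export
classify_fingerprint <- function(query, library) {
  if (!inherits(library, "fes_library") || nrow(library) == 0L) {
    abort("`library` must be a non-empty fingerprint library.",
          class = "fes_validation_error")
  }
  d <- vapply(library$fingerprint,
              function(fp) fingerprint_distance(query, fp), integer(1))
  best <- which(d == min(d))
  n_bits <- nrow(query)
  tibble(
    label = library$label[best],
    distance = d[best],
    agreement = 1 - d[best] / n_bits,
    ambiguous = length(best) > 1L
  )
}

check_compatible <- function(a, b) {
  for (x in list(a, b)) {
    if (!inherits(x, "fes_fingerprint")) {
      abort("both arguments must be `fes_fingerprint` objects.",
            class = "fes_compatibility_error")
    }
  }
  if (!identical(fingerprint_scheme(a), fingerprint_scheme(b))) {
    abort(sprintf("incompatible fingerprints: scheme '%s' vs '%s'.",
                  fingerprint_scheme(a), fingerprint_scheme(b)),
          class = "fes_compatibility_error")
  }
  if (nrow(a) != nrow(b)) {
    abort(sprintf("incompatible fingerprints: %d vs %d sub-bands.",
                  nrow(a), nrow(b)),
          class = "fes_compatibility_error")
  }
  ea <- attr(a, "edges", exact = TRUE)
  eb <- attr(b, "edges", exact = TRUE)
  if (any(abs(ea - eb) > 1e-9 * pmax(ea, eb))) {
    abort("incompatible fingerprints: band edges differ.",
          class = "fes_compatibility_error")
  }
  invisible(TRUE)
}
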