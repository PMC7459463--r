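#' Read a noise time series from delimited text
#'
#' Accepts either a two-column file (`time_s`, `value`) from which the
#' sampling rate is inferred (the time grid must be uniform to 1e-6 relative),
#' or a one-column file of values with the sampling rate supplied by the
#' caller. Comma, tab and whitespace delimiters are accepted; a header row is
#' auto-detected. Non-numeric rows are reported with their line number.
#'
#' @param path path to the file.
#' @param sampling_rate sampling rate in Hz; required for one-column files,
#'   ignored (with a warning on conflict) for two-column files.
#' @param label label for the record (defaults to the file name).
#' @return a [fes_timeseries()].
#' @export
read_timeseries <- function(path, sampling_rate = NULL, label = basename(path)) {
  m <- read_numeric_table(path, max_cols = 2L)
  if (ncol(m) == 2L) {
    dt <- check_uniform_dt(diff(m[, 1L]))
    fs <- 1 / dt
    if (!is.null(sampling_rate) && abs(fs - sampling_rate) > 1e-6 * fs) {
      warn(sprintf("file time column implies %g Hz; ignoring sampling_rate = %g.",
                   fs, sampling_rate))
    }
    fes_timeseries(m[, 2L], sampling_rate = fs, label = label)
  } else {
    if (is.null(sampling_rate)) {
      abort(sprintf("'%s' has a single column; `sampling_rate` is required.", path),
            class = "fes_parse_error")
    }
    fes_timeseries(m[, 1L], sampling_rate = sampling_rate, label = label)
  }
}

#' Write a time series as CSV
#'
#' Writes columns `time_s,value` with 12 significant digits, enough for an
#' exact read/write round trip at double precision for these data.
#'
#' @param ts a [fes_timeseries()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_timeseries <- function(ts, path) {
  ts <- as_fes_timeseries(ts)
  lines <- c("time_s,value",
             sprintf("%.12g,%.12g", ts$time, ts$value))
  writeLines(lines, path)
  invisible(path)
}

#' Read a power spectrum from CSV
#'
#' Expects columns `frequency_hz,psd`. Rows violating the spectrum invariants
#' (non-positive density, non-ascending frequency) are reported by row.
#'
#' @param path path to the file.
#' @param label label (defaults to the file name).
#' @return a [fes_spectrum()].
#' @export
read_spectrum <- function(path, label = basename(path)) {
  m <- read_numeric_table(path, max_cols = 2L)
  if (ncol(m) != 2L) {
    abort(sprintf("'%s' must have two columns (frequency_hz, psd).", path),
          class = "fes_parse_error")
  }
  fes_spectrum(m[, 1L], m[, 2L], n_averages = NA_integer_, label = label)
}

#' Write a power spectrum as CSV
#'
#' Writes columns `frequency_hz,psd` with 12 significant digits; the writer is
#' deterministic, so identical spectra give byte-identical files.
#'
#' @param ps a [fes_spectrum()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(ps, path) {
  ps <- as_fes_spectrum(ps)
  lines <- c("frequency_hz,psd",
             sprintf("%.12g,%.12g", ps$frequency, ps$density))
  writeLines(lines, path)
  invisible(path)
}

#' Write a fingerprint as JSON
#'
#' Stable field order (`scheme`, `bits`, `band_edges`, `tie_tolerance`,
#' `reference_label`, `label`, then the slope detail), full numeric precision;
#' round-trip safe via [read_fingerprint()].
#'
#' @param fp a `fes_fingerprint`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  stopifnot(inherits(fp, "fes_fingerprint"))
  obj <- list(
    scheme = fingerprint_scheme(fp),
    bits = fingerprint_bits(fp),
    band_edges = attr(fp, "edges", exact = TRUE),
    tie_tolerance = attr(fp, "tie_tolerance", exact = TRUE),
    reference_label = attr(fp, "reference_label", exact = TRUE),
    label = fes_label(fp),
    global_slope = attr(fp, "global_slope", exact = TRUE),
    local_slopes = fp$local_slope,
    reference_slopes = fp$reference_slope
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fingerprint from JSON
#'
#' @param path path to a file written by [write_fingerprint()].
#' @return a `fes_fingerprint`.
#' @export
read_fingerprint <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  fingerprint_from_list(obj, where = path)
}

fingerprint_from_list <- function(obj, where = "fingerprint") {
  required <- c("scheme", "bits", "band_edges")
  missing <- setdiff(required, names(obj))
  if (length(missing)) {
    abort(sprintf("%s: missing field(s) %s.", where,
                  paste(missing, collapse = ", ")),
          class = "fes_parse_error")
  }
  scheme <- obj$scheme
  bits <- as.integer(obj$bits)
  edges <- as.numeric(obj$band_edges)
  n <- length(bits)
  if (length(edges) != n + 1L) {
    abort(sprintf("%s: band_edges must have length(bits) + 1 entries.", where),
          class = "fes_parse_error")
  }
  if (!scheme %in% c("binary", "ternary")) {
    abort(sprintf("%s: unknown scheme '%s'.", where, scheme),
          class = "fes_parse_error")
  }
  if (!all(bits %in% c(-1L, 0L, 1L))) {
    abort(sprintf("%s: bits must be -1, 0 or +1.", where),
          class = "fes_parse_error")
  }
  if (scheme == "binary" && any(bits == 0L)) {
    abort(sprintf("%s: binary fingerprints cannot contain 0 bits.", where),
          class = "fes_parse_error")
  }
  ref_label <- obj$reference_label
  if (is.null(ref_label)) ref_label <- NA_character_
  if (scheme == "ternary" && is.na(ref_label)) {
    abort(sprintf("%s: ternary fingerprints need a reference_label.", where),
          class = "fes_parse_error")
  }
  nnum <- function(x, field) {
    if (is.null(x) || length(x) == 0L) return(rep(NA_real_, n))
    v <- as.numeric(x)
    if (length(v) != n) {
      abort(sprintf("%s: field '%s' has %d value(s), expected %d.",
                    where, field, length(v), n),
            class = "fes_parse_error")
    }
    v
  }
  local <- nnum(obj$local_slopes, "local_slopes")
  refsl <- nnum(obj$reference_slopes, "reference_slopes")
  out <- tibble(
    band = seq_len(n),
    f_lo = edges[-(n + 1L)],
    f_hi = edges[-1L],
    local_slope = local,
    reference_slope = refsl,
    delta = local - refsl,
    bit = bits
  )
  new_fes_tbl(out, "fes_fingerprint",
              scheme = scheme,
              global_slope = if (is.null(obj$global_slope)) NA_real_ else as.numeric(obj$global_slope),
              tie_tolerance = if (is.null(obj$tie_tolerance)) NA_real_ else as.numeric(obj$tie_tolerance),
              reference_label = ref_label,
              edges = edges,
              label = if (is.null(obj$label)) NA_character_ else obj$label)
}

#' Write a spectrum model as JSON
#'
#' @param model a [spectrum_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  model <- as_spectrum_model(model)
  obj <- list(
    edges = attr(model, "edges", exact = TRUE),
    exponents = model$exponent,
    level = attr(model, "level", exact = TRUE),
    label = fes_label(model)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read a spectrum model from JSON
#'
#' @param path path to a file written by [write_model()].
#' @return a [spectrum_model()].
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("edges", "exponents", "level")) {
    if (is.null(obj[[f]])) {
      abort(sprintf("'%s': missing field '%s'.", path, f),
            class = "fes_parse_error")
    }
  }
  spectrum_model(as.numeric(obj$edges), as.numeric(obj$exponents),
                 level = as.numeric(obj$level),
                 label = obj$label %||% basename(path))
}

#' Write a fingerprint library as JSON
#'
#' @param library a [fingerprint_library()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "fes_library"))
  entries <- purrr::map2(library$label, library$fingerprint, function(lab, fp) {
    list(label = lab,
         bits = fingerprint_bits(fp),
         global_slope = attr(fp, "global_slope", exact = TRUE),
         local_slopes = fp$local_slope,
         reference_slopes = fp$reference_slope)
  })
  obj <- list(
    scheme = attr(library, "scheme", exact = TRUE),
    band_edges = attr(library, "edges", exact = TRUE),
    tie_tolerance = attr(library, "tie_tolerance", exact = TRUE),
    reference_label = attr(library, "reference_label", exact = TRUE),
    entries = entries
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' Read a fingerprint library from JSON
#'
#' All entries must share the library's scheme, band edges and reference; a
#' violated invariant is reported with the offending entry.
#'
#' @param path path to a file written by [write_library()].
#' @return a [fingerprint_library()].
#' @export
read_library <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (f in c("scheme", "band_edges", "entries")) {
    if (is.null(obj[[f]])) {
      abort(sprintf("'%s': missing field '%s'.", path, f),
            class = "fes_parse_error")
    }
  }
  shared <- list(
    scheme = obj$scheme,
    band_edges = as.numeric(unlist(obj$band_edges)),
    tie_tolerance = obj$tie_tolerance,
    reference_label = obj$reference_label
  )
  json_num_vec <- function(x) {
    if (is.null(x)) return(NULL)
    vapply(x,
           function(v) if (is.null(v) || length(v) == 0L) NA_real_
                       else as.numeric(v[[1L]]),
           numeric(1))
  }
  fps <- lapply(obj$entries, function(e) {
    fingerprint_from_list(
      list(scheme = shared$scheme,
           bits = as.integer(unlist(e$bits)),
           band_edges = shared$band_edges,
           tie_tolerance = shared$tie_tolerance,
           reference_label = shared$reference_label,
           label = e$label,
           global_slope = e$global_slope,
           local_slopes = json_num_vec(e$local_slopes),
           reference_slopes = json_num_vec(e$reference_slopes)),
      where = sprintf("'%s' entry '%s'", path, e$label %||% "?")
    )
  })
  names(fps) <- vapply(obj$entries, function(e) e$label %||% NA_character_,
                       character(1))
  fingerprint_library(fps)
}

# ---- shared low-level reader -------------------------------------------------

# delimited numeric table with delimiter + header auto-detection; errors
# carry 1-based file line numbers
read_numeric_table <- function(path, max_cols = 2L) {
  if (!file.exists(path)) {
    abort(sprintf("file '%s' does not exist.", path), class = "fes_parse_error")
  }
  raw <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(raw)))
  if (length(keep) < 2L) {
    abort(sprintf("'%s' holds fewer than 2 data lines.", path),
          class = "fes_parse_error")
  }
  first <- raw[keep[1L]]
  delim <- if (grepl(",", first, fixed = TRUE)) "," else
    if (grepl("\t", first, fixed = TRUE)) "\t" else "[[:space:]]+"
  split_line <- function(line) {
    parts <- strsplit(trimws(line), delim)[[1L]]
    parts[nzchar(parts)]
  }
  tok1 <- split_line(first)
  has_header <- anyNA(suppressWarnings(as.numeric(tok1)))
  data_idx <- if (has_header) keep[-1L] else keep
  rows <- lapply(raw[data_idx], split_line)
  ncols <- lengths(rows)
  if (length(unique(ncols)) != 1L) {
    bad <- data_idx[which(ncols != ncols[1L])[1L]]
    abort(sprintf("'%s': line %d has %d field(s), expected %d.",
                  path, bad, ncols[ncols != ncols[1L]][1L], ncols[1L]),
          class = "fes_parse_error")
  }
  if (ncols[1L] > max_cols) {
    abort(sprintf("'%s': expected at most %d columns, found %d.",
                  path, max_cols, ncols[1L]),
          class = "fes_parse_error")
  }
  m <- matrix(suppressWarnings(as.numeric(unlist(rows))),
              ncol = ncols[1L], byrow = TRUE)
  if (anyNA(m)) {
    bad <- data_idx[which(rowSums(is.na(m)) > 0)[1L]]
    abort(sprintf("'%s': non-numeric value at line %d.", path, bad),
          class = "fes_parse_error")
  }
  m
}
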