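# shared fixture builders: everything is generated in code at test time

# dense log-spaced grid
log_grid <- function(f_min, f_max, per_decade = 50) {
  10^seq(log10(f_min), log10(f_max), by = 1 / per_decade)
}

# exact power law S(f) = c * f^-gamma on a log grid
power_law_spectrum <- function(gamma, c = 1, f_min = 1, f_max = 100,
                               per_decade = 50, label = "power law") {
  f <- log_grid(f_min, f_max, per_decade)
  fes_spectrum(f, c * f^(-gamma), label = label)
}

# smooth random spectrum: random log-log polynomial, positive by construction
random_spectrum <- function(seed, f_min = 1, f_max = 100, per_decade = 40) {
  withr::with_seed(seed, {
    f <- log_grid(f_min, f_max, per_decade)
    lf <- log10(f) - mean(log10(f))
    coef <- rnorm(4, sd = c(1, 1, 0.5, 0.25))
    logS <- coef[1] + coef[2] * lf + coef[3] * lf^2 + coef[4] * lf^3
    fes_spectrum(f, 10^logS, label = paste0("random-", seed))
  })
}

# spectrum whose local chord slope in sub-band i of `plan` is -exponents[i]
piecewise_spectrum <- function(exponents, plan, level = 1, per_decade = 60,
                               label = "piecewise") {
  edges <- attr(plan, "edges", exact = TRUE)
  model <- spectrum_model(edges, exponents, level = level, label = label)
  model_psd(model, log_grid(edges[1], edges[length(edges)], per_decade))
}

# random ternary fingerprint on a fixed plan, for metric/classification tests
random_ternary_fp <- function(seed, n_bits = 5, edges = 10 * 40^(0:n_bits / n_bits),
                              label = paste0("fp-", seed)) {
  withr::with_seed(seed, {
    fes_fingerprint(sample(c(-1L, 0L, 1L), n_bits, replace = TRUE),
                    edges = edges, scheme = "ternary",
                    tie_tolerance = 0.05, reference_label = "ref",
                    label = label)
  })
}
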