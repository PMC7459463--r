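plan5 <- band_plan(1, 100, 5)

test_that("binary coding follows the below/otherwise rule against the global slope", {
  # sub-band exponents engineered so locals sit (below, above, below, above,
  # above) the global chord slope: the classic five-bit A-E pattern
  ps <- piecewise_spectrum(c(2, 0.5, 2, 0.5, 0.5), plan5)
  fp <- binary_fingerprint(ps, plan5)
  expect_identical(fingerprint_bits(fp), c(-1L, 1L, -1L, 1L, 1L))
  expect_identical(fingerprint_scheme(fp), "binary")
  expect_equal(attr(fp, "global_slope", exact = TRUE), -1.1, tolerance = 1e-9)

  # pure power law: every local equals the global; ties code as +1
  pl <- power_law_spectrum(1)
  expect_identical(fingerprint_bits(binary_fingerprint(pl, plan5)),
                   rep(1L, 5))
})

test_that("two-exponent spectrum codes (+1, -1) over a two-band plan", {
  plan2 <- band_plan(1, 100, 2)
  ps <- piecewise_spectrum(c(1, 2), plan2)
  fp <- binary_fingerprint(ps, plan2)
  # oracle by chord arithmetic: locals -1 and -2, global (-1 + -2)/2 = -1.5
  expect_identical(fingerprint_bits(fp), c(1L, -1L))
  expect_equal(fp$local_slope, c(-1, -2), tolerance = 1e-9)
  expect_equal(attr(fp, "global_slope", exact = TRUE), -1.5, tolerance = 1e-9)
})

test_that("ternary coding compares local slopes against the reference odor", {
  # agent-minus-reference slope orderings (greater, less, equal, greater,
  # greater): the five-bit F-J pattern
  agent <- piecewise_spectrum(c(2, 0.5, 1, 0.5, 0.5), plan5, label = "agent")
  ref <- piecewise_spectrum(c(2.5, 0.2, 1, 1, 1), plan5, label = "lab air")
  fp <- ternary_fingerprint(agent, ref, plan5, tie_tolerance = 0.05)
  expect_identical(fingerprint_bits(fp), c(1L, -1L, 0L, 1L, 1L))
  expect_identical(fingerprint_scheme(fp), "ternary")
  expect_identical(attr(fp, "reference_label", exact = TRUE), "lab air")

  # analytic slopes: f^-1 agent over f^-2 reference is +1 everywhere
  fp2 <- ternary_fingerprint(power_law_spectrum(1), power_law_spectrum(2),
                             plan5, tie_tolerance = 0.05)
  expect_identical(fingerprint_bits(fp2), rep(1L, 5))
})

test_that("a spectrum fingerprinted against itself is all zeros", {
  for (seed in 1:25) {
    ps <- random_spectrum(seed)
    tol <- withr::with_seed(seed, runif(1, 0, 0.2))
    fp <- ternary_fingerprint(ps, ps, band_plan(1.5, 80, 5),
                              tie_tolerance = tol)
    expect_identical(fingerprint_bits(fp), rep(0L, 5))
  }
})

test_that("swapping agent and reference negates every symbol", {
  plan <- band_plan(1.5, 80, 6)
  for (seed in 1:15) {
    a <- random_spectrum(seed)
    b <- random_spectrum(seed + 1000)
    ab <- ternary_fingerprint(a, b, plan, tie_tolerance = 0.03)
    ba <- ternary_fingerprint(b, a, plan, tie_tolerance = 0.03)
    expect_identical(fingerprint_bits(ab), -fingerprint_bits(ba))
  }
})

test_that("fingerprints are invariant under density rescaling", {
  plan <- band_plan(1.5, 80, 5)
  for (seed in 1:10) {
    a <- random_spectrum(seed)
    b <- random_spectrum(seed + 500)
    scale_a <- withr::with_seed(seed, 10^runif(1, -3, 3))
    a2 <- fes_spectrum(a$frequency, scale_a * a$density)
    expect_identical(fingerprint_bits(binary_fingerprint(a2, plan)),
                     fingerprint_bits(binary_fingerprint(a, plan)))
    expect_identical(
      fingerprint_bits(ternary_fingerprint(a2, b, plan, 0.05)),
      fingerprint_bits(ternary_fingerprint(a, b, plan, 0.05))
    )
  }
})

test_that("raising the tie tolerance only zeroes symbols, never flips them", {
  plan <- band_plan(1.5, 80, 5)
  for (seed in 1:10) {
    a <- random_spectrum(seed)
    b <- random_spectrum(seed + 2000)
    tols <- sort(withr::with_seed(seed, runif(4, 0, 0.6)))
    fps <- lapply(tols, function(t) {
      fingerprint_bits(ternary_fingerprint(a, b, plan, tie_tolerance = t))
    })
    for (i in seq_len(length(tols) - 1)) {
      lo <- fps[[i]]
      hi <- fps[[i + 1]]
      changed <- lo != hi
      expect_true(all(hi[changed] == 0L))
    }
  }
})

test_that("every binary fingerprint contains a positive symbol", {
  for (seed in 1:25) {
    ps <- random_spectrum(seed)
    fp <- binary_fingerprint(ps, band_plan(1.5, 80, 5))
    expect_gte(sum(fingerprint_bits(fp) == 1L), 1)
  }
})

test_that("ternary fingerprints need coverage, a reference and a valid tolerance", {
  narrow <- power_law_spectrum(1, f_min = 5, f_max = 50)
  wide <- power_law_spectrum(1)
  expect_error(ternary_fingerprint(wide, narrow, plan5, 0.05),
               class = "fes_alignment_error")
  expect_error(ternary_fingerprint(narrow, wide, plan5, 0.05),
               class = "fes_alignment_error")
  expect_error(ternary_fingerprint(wide, wide, plan5, tie_tolerance = -0.1),
               class = "fes_validation_error")
})

test_that("alphabet entropies match the information-theoretic values", {
  expect_identical(alphabet_entropy("binary"), 1)
  expect_equal(alphabet_entropy("ternary"), log(3) / log(2))
  expect_equal(alphabet_entropy("ternary") / alphabet_entropy("binary"),
               log2(3))
  expect_equal(entropy_increase(), 100 * (log2(3) - 1))
  expect_gte(entropy_increase(), 50)
  expect_error(alphabet_entropy("quaternary"))
})

test_that("hand-built fingerprints enforce the scheme invariants", {
  edges <- 10 * 40^(0:5 / 5)
  fp <- fes_fingerprint(c(1, -1, 0, 1, 1), edges, scheme = "ternary",
                        reference_label = "lab air")
  expect_identical(fingerprint_bits(fp), c(1L, -1L, 0L, 1L, 1L))
  expect_error(fes_fingerprint(c(1, 0, 1), 10 * 40^(0:3 / 3), scheme = "binary"),
               class = "fes_validation_error")
  expect_error(fes_fingerprint(c(1, -1), c(1, 10, 100), scheme = "ternary"),
               class = "fes_validation_error")
  expect_error(fes_fingerprint(c(1, 2), c(1, 10, 100), scheme = "binary"),
               class = "fes_validation_error")
})
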