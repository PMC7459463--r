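edges5 <- 10 * 40^(0:5 / 5)

fp_of <- function(bits, label = "fp") {
  fes_fingerprint(bits, edges5, scheme = "ternary", tie_tolerance = 0.05,
                  reference_label = "ref", label = label)
}

test_that("fingerprint distance counts differing positions", {
  a <- fp_of(c(1, -1, 0, 1, 1))
  expect_identical(fingerprint_distance(a, a), 0L)
  b <- fp_of(c(1, 1, 0, 1, 1))
  expect_identical(fingerprint_distance(a, b), 1L)
  expect_equal(bit_agreement(a, b), 0.8)
  expect_equal(bit_agreement(a, a), 1)

  no_zeros <- fp_of(c(1, -1, -1, 1, 1))
  negated <- fp_of(-c(1, -1, -1, 1, 1))
  expect_identical(fingerprint_distance(no_zeros, negated), 5L)
  expect_equal(bit_agreement(no_zeros, negated), 0)

  # weighted variant: sign flip costs 2, zero transition 1
  expect_identical(fingerprint_distance(no_zeros, negated, weighted = TRUE), 10L)
  expect_identical(fingerprint_distance(a, b, weighted = TRUE), 2L)
  expect_identical(fingerprint_distance(a, fp_of(c(1, 0, 0, 1, 1)),
                                        weighted = TRUE), 1L)
})

test_that("incompatible fingerprints are refused with the mismatch named", {
  a <- fp_of(c(1, -1, 0, 1, 1))
  bin <- fes_fingerprint(c(1, -1, -1, 1, 1), edges5, scheme = "binary")
  expect_error(fingerprint_distance(a, bin), regexp = "scheme",
               class = "fes_compatibility_error")
  short <- fes_fingerprint(c(1, -1), edges5[1:3], scheme = "ternary",
                           reference_label = "ref")
  expect_error(fingerprint_distance(a, short), regexp = "sub-bands",
               class = "fes_compatibility_error")
  shifted <- fes_fingerprint(c(1, -1, 0, 1, 1), 2 * edges5, scheme = "ternary",
                             reference_label = "ref")
  expect_error(fingerprint_distance(a, shifted), regexp = "edges",
               class = "fes_compatibility_error")
})

test_that("the unweighted distance is a metric over ternary strings", {
  fps <- lapply(1:40, random_ternary_fp)
  for (i in 1:40) {
    expect_identical(fingerprint_distance(fps[[i]], fps[[i]]), 0L)
  }
  idx <- withr::with_seed(99, matrix(sample(40, 3 * 60, replace = TRUE), ncol = 3))
  for (r in seq_len(nrow(idx))) {
    a <- fps[[idx[r, 1]]]; b <- fps[[idx[r, 2]]]; c <- fps[[idx[r, 3]]]
    dab <- fingerprint_distance(a, b)
    expect_identical(dab, fingerprint_distance(b, a))
    expect_gte(dab, 0L)
    if (dab == 0L) expect_identical(fingerprint_bits(a), fingerprint_bits(b))
    expect_lte(fingerprint_distance(a, c),
               dab + fingerprint_distance(b, c))
  }
})

test_that("library construction enforces shared plans and unique labels", {
  lib <- fingerprint_library(list(a = fp_of(c(1, -1, 0, 1, 1)),
                                  b = fp_of(c(-1, -1, 0, 1, 1))))
  expect_s3_class(lib, "fes_library")
  expect_identical(lib$label, c("a", "b"))

  expect_error(
    fingerprint_library(list(a = fp_of(c(1, 1, 1, 1, 1)),
                             a = fp_of(c(-1, 1, 1, 1, 1)))),
    regexp = "unique", class = "fes_validation_error"
  )
  other_plan <- fes_fingerprint(c(1, 0, 1), c(1, 10, 100, 1000),
                                scheme = "ternary", reference_label = "ref")
  expect_error(fingerprint_library(list(a = fp_of(c(1, 1, 1, 1, 1)),
                                        b = other_plan)),
               class = "fes_compatibility_error")
  other_ref <- fes_fingerprint(c(1, -1, 0, 1, 1), edges5, scheme = "ternary",
                               reference_label = "another odor")
  expect_error(fingerprint_library(list(a = fp_of(c(1, 1, 1, 1, 1)),
                                        b = other_ref)),
               regexp = "reference", class = "fes_compatibility_error")
  expect_error(fingerprint_library(list()), class = "fes_validation_error")
})

test_that("classification finds the nearest entry and surfaces ties", {
  lib <- fingerprint_library(list(
    bacillus = fp_of(c(1, -1, 0, 1, 1)),
    medium = fp_of(c(-1, -1, 0, 1, 1)),
    air = fp_of(c(0, 0, 0, 0, 0))
  ))
  hit <- classify_fingerprint(fp_of(c(1, -1, 0, 1, 1)), lib)
  expect_identical(hit$label, "bacillus")
  expect_identical(hit$distance, 0L)
  expect_false(hit$ambiguous)

  # one flip from 'bacillus', two or more from the others (brute-force check)
  q <- fp_of(c(1, -1, 0, -1, 1))
  d_all <- vapply(lib$fingerprint, fingerprint_distance, integer(1), a = q)
  expect_identical(unname(d_all), c(1L, 2L, 4L))
  one <- classify_fingerprint(q, lib)
  expect_identical(one$label, "bacillus")
  expect_identical(one$distance, 1L)

  # equidistant query: both labels returned, flagged ambiguous
  tie <- classify_fingerprint(fp_of(c(0, -1, 0, 1, 1)), lib)
  expect_setequal(tie$label, c("bacillus", "medium"))
  expect_true(all(tie$ambiguous))

  # permutation invariance of the library order
  lib_rev <- fingerprint_library(list(
    air = fp_of(c(0, 0, 0, 0, 0)),
    medium = fp_of(c(-1, -1, 0, 1, 1)),
    bacillus = fp_of(c(1, -1, 0, 1, 1))
  ))
  expect_setequal(classify_fingerprint(q, lib_rev)$label,
                  classify_fingerprint(q, lib)$label)
})
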