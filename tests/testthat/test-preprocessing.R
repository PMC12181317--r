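wn3 <- c(950, 1375, 1800)

test_that("single-beam to absorbance conversion follows the log law", {
  wn <- c(950, 952, 954)
  s <- tiny_set(matrix(c(1, 1, 1), 1), wn)
  expect_equal(as.numeric(absorbance_from_single_beam(s, c(1, 1, 1))$absorbance),
               c(0, 0, 0))
  s2 <- tiny_set(matrix(c(0.1, 1, 1), 1), wn)
  expect_equal(absorbance_from_single_beam(s2, c(1, 1, 1))$absorbance[1], 1)
  expect_error(absorbance_from_single_beam(s, c(1, 0, 1)), "positive")
  expect_warning(a <- absorbance_from_single_beam(tiny_set(c(-1, 1, 1), wn),
                                                  c(1, 1, 1)), "capped")
  expect_equal(a$absorbance[1], 5)

  # algebraic round-trip on random positive intensities
  set.seed(21)
  sm <- matrix(stats::runif(30, 0.1, 2), 3)
  ref <- stats::runif(10, 0.5, 2)
  st <- tiny_set(sm, seq(950, 968, by = 2))
  a <- absorbance_from_single_beam(st, ref)
  expect_equal(sweep(10^(-a$absorbance), 2, ref, "*"), sm,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("range restriction slices the closed interval and is idempotent", {
  coh <- planted_cohort(seed = 2, n_patients = 1, n_spectra = 2)
  full <- restrict_range(coh, 950, 1800)
  expect_equal(full$absorbance, coh$absorbance)
  r <- restrict_range(coh, 950, 1480)
  expect_equal(length(r$wavenumbers), 266)
  expect_identical(restrict_range(r, 950, 1480)$absorbance, r$absorbance)
  expect_true("range_restricted" %in% r$state)
  expect_error(restrict_range(coh, 200, 300), "no grid points")
})

test_that("two-point baseline correction zeroes the anchors", {
  s <- tiny_set(c(2, 5, 4), wn3)
  b <- baseline_correct_two_point(s, c(950, 1800))
  expect_equal(as.numeric(b$absorbance), c(0, 2, 0))
  lin <- tiny_set(1 + 0.001 * (wn3 - 950), wn3)
  expect_equal(as.numeric(baseline_correct_two_point(lin)$absorbance),
               c(0, 0, 0), tolerance = 1e-12)
  coh <- planted_cohort(seed = 3, n_patients = 2, n_spectra = 2)
  bc <- baseline_correct_two_point(coh, c(950, 1800))
  i <- nearest_index(bc$wavenumbers, c(950, 1800))
  expect_true(all(abs(bc$absorbance[, i]) < 1e-12))
  expect_error(baseline_correct_two_point(s, c(950, 950)), "same grid point")
})

test_that("area normalization sums to one and is scale-invariant", {
  wn <- seq(950, 1480, by = 2)
  s <- tiny_set(rep(0.5, length(wn)), wn)
  a <- area_normalize(s, c(950, 1480))
  expect_equal(as.numeric(a$absorbance), rep(1 / length(wn), length(wn)))
  set.seed(4)
  m <- matrix(stats::runif(3 * length(wn), 0.1, 1), 3)
  s2 <- tiny_set(m, wn)
  a2 <- area_normalize(s2, c(950, 1480))
  expect_equal(rowSums(a2$absorbance), rep(1, 3), tolerance = 1e-12)
  for (k in c(0.5, 3, 1000)) {
    ak <- area_normalize(tiny_set(k * m, wn), c(950, 1480))
    expect_equal(ak$absorbance, a2$absorbance, tolerance = 1e-12)
  }
  expect_error(area_normalize(tiny_set(-m, wn), c(950, 1480)), "non-positive")
})

test_that("min-max normalization attains exactly 0 and 1 and is affine-invariant", {
  s <- tiny_set(c(2, 5, 4), wn3)
  mm <- minmax_normalize(s)
  expect_equal(as.numeric(mm$absorbance), c(0, 1, 2 / 3))
  expect_equal(minmax_normalize(mm)$absorbance, mm$absorbance)  # idempotent
  set.seed(5)
  m <- matrix(stats::rnorm(40), 4)
  base <- minmax_normalize(tiny_set(m, seq(950, 968, 2)))
  for (ab in list(c(2, 0), c(0.3, -1), c(10, 5))) {
    tr <- minmax_normalize(tiny_set(ab[1] * m + ab[2], seq(950, 968, 2)))
    expect_equal(tr$absorbance, base$absorbance, tolerance = 1e-12)
  }
  expect_true(all(apply(base$absorbance, 1, min) == 0))
  expect_true(all(apply(base$absorbance, 1, max) == 1))
  expect_error(minmax_normalize(tiny_set(c(1, 1, 1), wn3)), "constant")
})

test_that("atmospheric compensation strips water lines it can model", {
  g <- wavenumber_grid()
  wref <- water_vapor_reference(as.numeric(g))
  m <- planted_band_models()$normal
  wet <- class_band_model(m$class, m$bands, 0, 0, 0, 0, 0,
                          water_vapor_amp = 0.3)
  dry <- class_band_model(m$class, m$bands, 0, 0, 0, 0, 0)
  sw <- simulate_spectrum(wet, g)
  sd_ <- simulate_spectrum(dry, g)
  comp <- atmospheric_compensation(sw, wref)
  line_idx <- nearest_index(as.numeric(g), 1772)
  resid <- abs(comp$absorbance - sd_$absorbance)
  expect_lt(max(resid[, line_idx]), 0.01 * 0.3)   # < 1% of line height
  # zero reference leaves the spectrum unchanged
  same <- atmospheric_compensation(sd_, rep(0, length(g)))
  expect_equal(same$absorbance, sd_$absorbance)
  # an already-clean spectrum is barely touched
  comp2 <- atmospheric_compensation(sd_, wref)
  expect_lt(max(abs(comp2$absorbance - sd_$absorbance)), 0.02)
})

test_that("the preprocessing chain runs in its fixed order and records state", {
  coh <- planted_cohort(seed = 6, n_patients = 2, n_spectra = 3)
  out <- preprocess_chain(coh)
  expect_identical(out$state, c("raw", "range_restricted",
                                "baseline_corrected", "area_normalized",
                                "minmax_normalized"))
  expect_equal(range(out$wavenumbers), c(950, 1480))
  # alternative order behind the switch
  alt <- preprocess_chain(coh, preprocess_spec(minmax_last = FALSE))
  expect_identical(alt$state, c("raw", "range_restricted",
                                "baseline_corrected", "minmax_normalized",
                                "area_normalized"))
  expect_equal(rowSums(alt$absorbance[, window_indices(alt$wavenumbers, 950, 1480)]),
               rep(1, n_spectra(alt)), tolerance = 1e-12)
  expect_error(preprocess_chain(coh, preprocess_spec(atmospheric = TRUE)),
               "water_reference")
})
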