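test_that("normalization scales by the maximum and is idempotent", {
  wl <- canonical_grid()
  vals <- rep(0.5, length(wl)); vals[1:3] <- c(2.0, 1.0, 0.5)
  sp <- spectrum(wl, vals)
  n <- normalize_spectrum(sp)
  expect_equal(n$absorbance[1:3], c(1.0, 0.5, 0.25))
  expect_equal(max(n$absorbance), 1)
  expect_true(n$is_normalized)
  expect_equal(normalize_spectrum(n)$absorbance, n$absorbance)

  zero <- spectrum(wl, rep(0, length(wl)))
  expect_error(normalize_spectrum(zero), "cannot normalize")
})

test_that("absorbance lookup is exact on the grid and refuses off-grid queries", {
  const <- spectrum(canonical_grid(), rep(1, 601))
  expect_equal(absorbance_at(const, 254), 1)
  expect_equal(absorbance_at(const, 800), 1)
  expect_error(absorbance_at(const, 253.5), "not on the spectrum grid")

  srfa_like <- synthetic_srfa_spectrum()
  expect_equal(absorbance_at(srfa_like, 254), 0.54, tolerance = 0.005)
})

test_that("slope fit recovers noiseless exponential parameters to 1e-6", {
  wl <- canonical_grid()
  sp <- spectrum(wl, 0.8 * exp(-0.018 * (wl - 275)) + 0.01)
  f <- fit_spectral_slope(sp, c(275, 295))
  expect_equal(f$s, 0.018, tolerance = 1e-6)
  expect_equal(f$k, 0.01, tolerance = 1e-6)
  expect_equal(f$a_ref, 0.8, tolerance = 1e-6)
  expect_true(f$converged)
  expect_false(f$non_exponential)

  # recovery across a grid of (a_ref, S, K) combinations
  for (s_true in c(0.005, 0.012, 0.03, 0.05)) {
    for (k_true in c(0, 0.02)) {
      sp2 <- spectrum(wl, 0.6 * exp(-s_true * (wl - 350)) + k_true)
      f2 <- fit_spectral_slope(sp2, c(350, 400))
      expect_equal(f2$s, s_true, tolerance = 1e-6)
      expect_equal(f2$k, k_true, tolerance = 1e-6)
    }
  }
})

test_that("slope fit tolerates instrument-level noise (within 5% at sd 1e-4)", {
  # tolerance fixed after inspecting the recovery distribution over 100 seeds
  wl <- canonical_grid()
  for (seed in 1:10) {
    y <- 0.8 * exp(-0.018 * (wl - 275)) + 0.01 +
      withr::with_seed(seed, stats::rnorm(length(wl), 0, 1e-4))
    f <- fit_spectral_slope(spectrum(wl, y), c(275, 295))
    expect_lt(abs(f$s - 0.018) / 0.018, 0.05)
  }
})

test_that("a flat spectrum is flagged non-exponential, not an error", {
  flat <- spectrum(canonical_grid(), rep(0.5, 601))
  f <- fit_spectral_slope(flat, c(275, 295))
  expect_true(f$non_exponential)
})

test_that("fitted slope is strictly monotone in the generating slope", {
  s_grid <- seq(0.005, 0.05, by = 0.005)
  fitted <- vapply(s_grid, function(s_true) {
    sp <- generate_spectrum(synth_params(a0 = 1, s = s_true, k = 0, seed = 1))
    fit_spectral_slope(normalize_spectrum(sp), c(275, 295))$s
  }, numeric(1))
  expect_true(all(diff(fitted) > 0))
})

test_that("the ten indices obey their defining identities", {
  sp <- exp_spectrum(s = 0.02, k = 0)  # a(200) = 1, pure exponential
  idx <- compute_indices(sp)
  v <- as_index_vector(idx)

  # sr is exactly the ratio of the fitted slopes
  fits <- attr(idx, "fits")
  expect_identical(v[["sr"]], fits$s275$s / fits$s350$s)
  # one decay rate in both windows => sr = 1 within fit tolerance
  expect_equal(v[["sr"]], 1, tolerance = 1e-6)

  # e2e3 is exactly the lookup ratio; closed form for a pure exponential
  norm <- normalize_spectrum(sp)
  expect_identical(v[["e2e3"]],
                   absorbance_at(norm, 250) / absorbance_at(norm, 365))
  expect_equal(v[["e2e3"]], exp(0.02 * 115), tolerance = 1e-12)

  # absorbance coefficients come from the normalized spectrum, so lie in [0, 1]
  coefs <- v[c("a254", "a280", "a325", "a355", "a412", "a440")]
  expect_true(all(coefs >= 0 & coefs <= 1))
})

test_that("indices are invariant to rescaling of the raw spectrum", {
  base <- synthetic_srfa_spectrum()
  v0 <- as_index_vector(compute_indices(base))
  for (c_scale in c(0.2, 0.5, 2)) {
    scaled <- spectrum(base$wavelength, base$absorbance * c_scale)
    vc <- as_index_vector(compute_indices(scaled))
    expect_equal(vc, v0, tolerance = 1e-9)
  }
})

test_that("the synthetic reference reproduces the bundled SRFA row at printed precision", {
  v <- as_index_vector(compute_indices(synthetic_srfa_spectrum()))
  expect_equal(round(unname(v), 2),
               c(0.01, 0.02, 0.54, 0.40, 0.22, 0.14, 0.05, 0.03, 0.70, 4.74))
})
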