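test_that("percent error matches the published worked cells", {
  expect_equal(percent_error(0.36, 0.40), 10)
  expect_equal(percent_error(0.22, 0.22), 0)
  expect_equal(round(percent_error(0.16, 0.22)), 27)
  expect_equal(round(percent_error(0.22, 0.16)), 38)
  expect_equal(round(percent_error(0.53, 0.54)), 2)
  expect_equal(round(percent_error(0.8, 0.70)), 14)
  expect_equal(round(percent_error(4.7, 4.74)), 1)
})

test_that("percent error is asymmetric, zero on identity, scale-invariant", {
  for (i in 1:20) {
    ab <- withr::with_seed(i, stats::runif(3, 0.01, 5))
    a <- ab[1]; b <- ab[2]; cc <- ab[3]
    expect_equal(percent_error(a, a), 0)
    expect_equal(percent_error(cc * a, cc * b), percent_error(a, b),
                 tolerance = 1e-12)
    if (abs(a - b) > 1e-6) {
      expect_false(isTRUE(all.equal(percent_error(a, b), percent_error(b, a))))
    }
  }
  expect_error(percent_error(1, 0), "zero")
})

test_that("pe_profile scores against each standard and takes the minimum", {
  srfa <- bundled_standard("SRFA")
  ppfa <- bundled_standard("PPFA")

  self <- pe_profile(srfa$indices, list(srfa), raw_a254 = 0.2)
  expect_equal(unname(self$per_index_pe$SRFA), rep(0, 10))
  expect_equal(self$pe_avg[["SRFA"]], 0)

  doubled <- pe_profile(2 * srfa$indices, list(srfa), raw_a254 = 0.2)
  expect_equal(unname(doubled$per_index_pe$SRFA), rep(100, 10))
  expect_equal(doubled$pe_avg[["SRFA"]], 100)

  cross <- pe_profile(ppfa$indices, list(srfa, ppfa), raw_a254 = 0.2,
                      sample_id = "PPFA")
  pe <- cross$per_index_pe$SRFA
  expect_equal(round(pe[["a254"]]), 2)
  expect_equal(round(pe[["a280"]]), 10)
  expect_equal(round(pe[["a325"]]), 27)
  expect_equal(round(pe[["sr"]]), 14)
  expect_equal(round(pe[["e2e3"]]), 1)
  expect_equal(cross$pe_avg[["PPFA"]], 0)
  expect_equal(cross$pe_avg_min, 0)
})

test_that("pe_avg is always the equal-weighted mean of the per-index PEs", {
  srfa <- bundled_standard("SRFA")
  for (i in 1:25) {
    fake <- withr::with_seed(100 + i, stats::runif(10, 0.001, 6))
    names(fake) <- muvi_index_names
    rep_ <- pe_profile(fake, both_standards(), raw_a254 = 0.2)
    for (std in names(rep_$per_index_pe)) {
      expect_equal(rep_$pe_avg[[std]], mean(rep_$per_index_pe[[std]]),
                   tolerance = 1e-9)
    }
    expect_equal(rep_$pe_avg_min, min(rep_$pe_avg))
  }
})

test_that("replicate aggregation averages PEs and checks concordance", {
  srfa <- bundled_standard("SRFA")
  mk <- function(pe_vec) {
    # report with prescribed per-index PEs: invert PE -> index value
    va <- srfa$indices * (1 + pe_vec / 100)
    pe_profile(va, list(srfa), raw_a254 = 0.2, sample_id = "x")
  }
  r10 <- mk(rep(10, 10)); r40 <- mk(rep(40, 10))

  same <- aggregate_replicates(list(r10, r10, r10))
  expect_equal(same$per_index_pe$SRFA, r10$per_index_pe$SRFA, tolerance = 1e-9)
  expect_true(same$concordance_ok)
  expect_equal(same$replicate_count, 3L)

  # spread 30 > 20 percentage points on every index
  spread <- aggregate_replicates(list(r10, r10, r40))
  expect_false(spread$concordance_ok)
  expect_equal(unname(spread$per_index_pe$SRFA), rep(20, 10), tolerance = 1e-9)

  # two replicates at 20 and 30 average to 25, spread 10 is concordant
  r20 <- mk(rep(20, 10)); r30 <- mk(rep(30, 10))
  two <- aggregate_replicates(list(r20, r30))
  expect_equal(unname(two$per_index_pe$SRFA), rep(25, 10), tolerance = 1e-9)
  expect_true(two$concordance_ok)

  other <- pe_profile(srfa$indices, list(srfa), raw_a254 = 0.2, sample_id = "y")
  expect_error(aggregate_replicates(list(r10, other)), "mix sample ids")
})

test_that("the dual-cutoff decision rule reproduces the worked cases", {
  # molasses: shape matches (PE 38.8) but raw absorbance fails the gate
  d1 <- classify(0.005, 38.8)
  expect_identical(d1$verdict, "non_fulvic")
  expect_false(d1$gate_a254_passed)
  expect_true(d1$gate_pe_passed)

  d2 <- classify(0.212, 32.1)
  expect_identical(d2$verdict, "fulvic")

  # lignosulfonate: boundary absorbance 0.080 is not > 0.08, and PE >= 70
  d3 <- classify(0.080, 76.9)
  expect_identical(d3$verdict, "non_fulvic")
  expect_false(d3$gate_a254_passed)
  expect_false(d3$gate_pe_passed)

  d4 <- classify(0.168, 76.1)
  expect_identical(d4$verdict, "non_fulvic")
  expect_true(d4$gray_zone)

  # strict boundaries: PE exactly 70 fails, just below passes
  expect_identical(classify(0.2, 70)$verdict, "non_fulvic")
  expect_identical(classify(0.2, 69.99)$verdict, "fulvic")
})

test_that("gray-zone mode downgrades borderline passes to indeterminate", {
  expect_identical(classify(0.2, 65, gray_zone_mode = TRUE)$verdict,
                   "indeterminate")
  # gray zone above the cutoff: still flagged, verdict indeterminate not fulvic
  expect_identical(classify(0.2, 85, gray_zone_mode = TRUE)$verdict,
                   "indeterminate")
  # outside the gray zone the binary rule applies
  expect_identical(classify(0.2, 30, gray_zone_mode = TRUE)$verdict, "fulvic")
  expect_identical(classify(0.2, 95, gray_zone_mode = TRUE)$verdict,
                   "non_fulvic")
  # failing the absorbance gate is never indeterminate
  expect_identical(classify(0.01, 65, gray_zone_mode = TRUE)$verdict,
                   "non_fulvic")
})

test_that("classification is monotone in both inputs", {
  pe_grid <- seq(0, 120, by = 2.5)
  verdicts <- vapply(pe_grid, function(pe) classify(0.2, pe)$verdict,
                     character(1))
  # once non-fulvic by PE, higher PE never flips back
  expect_true(all(diff(verdicts == "fulvic") <= 0))

  a_grid <- seq(0.0, 0.3, by = 0.01)
  verdicts_a <- vapply(a_grid, function(a) classify(a, 30)$verdict,
                       character(1))
  expect_true(all(diff(verdicts_a == "fulvic") >= 0))
})

test_that("SSSAD is zero on identity, scale-invariant, and additive in squares", {
  std <- synthetic_srfa_spectrum()
  expect_equal(sssad(std, std), 0)

  scaled <- spectrum(std$wavelength, std$absorbance * 3)
  expect_equal(sssad(scaled, std), 0, tolerance = 1e-12)

  # +0.1 on the scaled series at exactly one of the nine wavelengths -> 0.01.
  # The series is scaled by the zeroed 290 nm value and zeroed by the series
  # minimum (330 nm), so perturb one interior point of the scaled shape by
  # inverting the scaling at 310 nm.
  grid_wl <- seq(290, 330, 5)
  v <- vapply(grid_wl, function(w) absorbance_at(std, w), numeric(1))
  scale_fac <- (v - min(v))[1]
  bumped <- std$absorbance
  bumped[std$wavelength == 310] <- bumped[std$wavelength == 310] + 0.1 * scale_fac
  sp_b <- spectrum(std$wavelength, bumped)
  expect_equal(sssad(sp_b, std), 0.01, tolerance = 1e-9)
  expect_equal(sssad(sp_b, std, squared = FALSE), 0.1, tolerance = 1e-9)

  flat <- spectrum(canonical_grid(), rep(0.5, 601))
  expect_error(sssad(flat, std), "SSSAD scaling undefined")
})
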