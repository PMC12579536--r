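# Shared fixtures, all built in code.

# Exact single-exponential spectrum on the canonical grid (raw, unnormalized).
exp_spectrum <- function(a0 = 1, s = 0.02, k = 0, lambda_ref = 200,
                         sample_id = "exp") {
  wl <- canonical_grid()
  spectrum(wl, a0 * exp(-s * (wl - lambda_ref)) + k, sample_id = sample_id)
}

# Write a two-column CSV spectrum file; returns the path.
write_two_column <- function(wl, a, header = TRUE, sep = ",",
                             path = withr::local_tempfile(fileext = ".csv",
                                                          .local_envir = parent.frame())) {
  lines <- paste(wl, a, sep = sep)
  if (header) lines <- c(paste("wavelength_nm", "absorbance", sep = sep), lines)
  writeLines(lines, path)
  path
}

both_standards <- function() list(bundled_standard("SRFA"), bundled_standard("PPFA"))

# Percent-error report for one raw spectrum against both bundled standards.
report_for <- function(sp, sample_id = sp$sample_id) {
  pe_profile(compute_indices(sp), both_standards(),
             raw_a254 = absorbance_at(sp, 254), sample_id = sample_id)
}
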