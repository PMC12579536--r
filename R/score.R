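#' Percent error of a sample index against a standard index
#'
#' \deqn{PE = |v_a - v_s| / |v_s| \times 100}
#' where \eqn{v_a} is the sample's index value and \eqn{v_s} the standard's.
#' Asymmetric by design: the standard is always the denominator.
#'
#' @param va Sample index value.
#' @param vs Standard index value; must be nonzero.
#' @return Percent error (>= 0). Vectorized.
#' @examples
#' percent_error(0.36, 0.40)  # 10
#' @export
percent_error <- function(va, vs) {
  if (any(vs == 0)) {
    stop("standard index value is zero; percent error undefined", call. = FALSE)
  }
  abs(va - vs) / abs(vs) * 100
}

new_pe_report <- function(sample_id, per_index_pe, raw_a254,
                          replicate_count = 1L, concordance_ok = TRUE) {
  pe_avg <- vapply(per_index_pe, mean, numeric(1))
  structure(
    list(sample_id = sample_id,
         per_index_pe = per_index_pe,         # named list: standard -> 10 PEs
         pe_avg = pe_avg,                     # named: standard -> mean PE
         pe_avg_min = min(pe_avg),
         raw_a254 = raw_a254,
         replicate_count = as.integer(replicate_count),
         concordance_ok = concordance_ok),
    class = "muvi_pe_report"
  )
}

#' @export
print.muvi_pe_report <- function(x, ...) {
  cat(sprintf("<muvi_pe_report> %s (%d replicate%s)\n", x$sample_id,
              x$replicate_count, if (x$replicate_count == 1) "" else "s"))
  cat(sprintf("  raw A254: %.3f AU\n", x$raw_a254))
  for (std in names(x$per_index_pe)) {
    cat(sprintf("  vs %s: PE_avg = %.1f%%\n", std, x$pe_avg[[std]]))
  }
  cat(sprintf("  PE_avg (min over standards): %.1f%%\n", x$pe_avg_min))
  if (!x$concordance_ok) {
    cat("  WARNING: replicate PEs differ by > 20 percentage points\n")
  }
  invisible(x)
}

#' Percent-error profile of a sample against reference standards
#'
#' Compares a sample's ten index values independently against each reference
#' standard, producing a per-index percent-error profile and the
#' equal-weighted average percent error (PE_avg) per standard. The minimum
#' PE_avg over the standards (`pe_avg_min`) is what feeds the decision rule:
#' the lower of the two standards' scores is used, so a sample resembling
#' either standard passes.
#'
#' @param sample A `muvi_indices` object or named numeric vector with the ten
#'   index values.
#' @param standards List of `muvi_standard` objects (or a single one).
#' @param raw_a254 The raw (non-normalized) absorbance at 254 nm in AU, kept
#'   for the screening gate.
#' @param sample_id Identifier recorded in the report.
#' @return A `muvi_pe_report`.
#' @examples
#' srfa <- bundled_standard("SRFA")
#' ppfa <- bundled_standard("PPFA")
#' pe_profile(ppfa$indices, list(srfa, ppfa), raw_a254 = 0.2, sample_id = "PPFA")
#' @export
pe_profile <- function(sample, standards, raw_a254, sample_id = "sample") {
  if (inherits(standards, "muvi_standard")) standards <- list(standards)
  if (length(standards) < 1) {
    stop("need at least one reference standard", call. = FALSE)
  }
  va <- as_index_vector(sample)
  per_index <- lapply(standards, function(std) {
    stopifnot(inherits(std, "muvi_standard"))
    percent_error(va, std$indices)
  })
  names(per_index) <- vapply(standards, `[[`, character(1), "name")
  new_pe_report(sample_id, per_index, raw_a254)
}

#' Aggregate replicate percent-error reports
#'
#' The workflow measures each test sample in triplicate; each replicate
#' yields a percent-error profile. Per-index PEs are averaged across
#' replicates, then PE_avg is recomputed from the averaged per-index values
#' (both steps are linear, so the order only matters for the concordance
#' check). Replicates are expected to agree: if for any index (against any
#' standard) the spread (max - min) across replicates exceeds 20 percentage
#' points, `concordance_ok` is set to `FALSE` — flagging that the
#' acquisition should be repeated — but aggregation still proceeds, since
#' re-measurement is a lab action, not a software one.
#'
#' @param reports List of `muvi_pe_report` objects for the same sample and
#'   the same set of standards.
#' @param concordance_limit Maximum tolerated spread in percentage points
#'   (default 20).
#' @return A single aggregated `muvi_pe_report`.
#' @export
aggregate_replicates <- function(reports, concordance_limit = 20) {
  if (length(reports) < 1) stop("need at least one report", call. = FALSE)
  ids <- unique(vapply(reports, `[[`, character(1), "sample_id"))
  if (length(ids) != 1) {
    stop("reports mix sample ids: ", paste(ids, collapse = ", "), call. = FALSE)
  }
  std_names <- names(reports[[1]]$per_index_pe)
  ok <- all(vapply(reports, function(r)
    identical(names(r$per_index_pe), std_names), logical(1)))
  if (!ok) stop("reports use different standard sets", call. = FALSE)

  concord <- TRUE
  per_index <- lapply(std_names, function(std) {
    mat <- do.call(rbind, lapply(reports, function(r) r$per_index_pe[[std]]))
    spread <- apply(mat, 2, function(v) max(v) - min(v))
    if (any(spread > concordance_limit)) concord <<- FALSE
    colMeans(mat)
  })
  names(per_index) <- std_names
  raw_a254 <- mean(vapply(reports, `[[`, numeric(1), "raw_a254"))
  new_pe_report(ids, per_index, raw_a254,
                replicate_count = length(reports), concordance_ok = concord)
}

#' Apply the MUVI decision rule
#'
#' The binary decision combines two criteria, both strict inequalities:
#' \itemize{
#'   \item raw (non-normalized) absorbance at 254 nm greater than 0.08 AU —
#'     very low raw absorbance at 254 nm indicates non-humified material
#'     (e.g. molasses, organic acids) regardless of spectral shape;
#'   \item minimum average percent error across the standards below 70%.
#' }
#' The verdict is `"fulvic"` only if both pass, otherwise `"non_fulvic"`.
#' A PE_avg in the 60--90% gray zone is flagged; with `gray_zone_mode =
#' TRUE`, a gray-zone sample that passes the absorbance gate is downgraded
#' to `"indeterminate"` (orthogonal confirmation such as FTICR-MS or C-NMR
#' recommended). The default is the plain binary rule.
#'
#' @param raw_a254 Raw absorbance at 254 nm (AU).
#' @param pe_avg_min Minimum PE_avg across standards (percent, >= 0).
#' @param a254_cutoff,pe_cutoff,gray_zone Decision thresholds: absorbance
#'   gate (AU), PE gate (percent) and gray-zone bounds (percent).
#' @param gray_zone_mode Logical; enable the indeterminate verdict.
#' @return A `muvi_decision` list: `verdict`, `gate_a254_passed`,
#'   `gate_pe_passed`, `gray_zone`, `rationale`.
#' @examples
#' classify(0.212, 32.1)   # fulvic
#' classify(0.005, 38.8)   # non_fulvic: fails the A254 gate
#' @export
classify <- function(raw_a254, pe_avg_min, a254_cutoff = 0.08,
                     pe_cutoff = 70, gray_zone = c(60, 90),
                     gray_zone_mode = FALSE) {
  stopifnot(is.finite(raw_a254), is.finite(pe_avg_min), pe_avg_min >= 0,
            gray_zone[1] <= pe_cutoff, pe_cutoff <= gray_zone[2])
  gate_a254 <- raw_a254 > a254_cutoff
  gate_pe <- pe_avg_min < pe_cutoff
  gray <- pe_avg_min >= gray_zone[1] && pe_avg_min <= gray_zone[2]

  if (gate_a254 && gate_pe) {
    verdict <- "fulvic"
    rationale <- sprintf("A254 %.3f > %.2f and PE_avg %.1f%% < %.0f%%",
                         raw_a254, a254_cutoff, pe_avg_min, pe_cutoff)
  } else {
    verdict <- "non_fulvic"
    why <- c(
      if (!gate_a254) sprintf("raw A254 %.3f not > %.2f AU", raw_a254, a254_cutoff),
      if (!gate_pe) sprintf("PE_avg %.1f%% not < %.0f%%", pe_avg_min, pe_cutoff))
    rationale <- paste(why, collapse = "; ")
  }
  if (gray_zone_mode && gray && gate_a254) {
    verdict <- "indeterminate"
    rationale <- sprintf(
      "PE_avg %.1f%% in the %g-%g%% gray zone; orthogonal confirmation recommended",
      pe_avg_min, gray_zone[1], gray_zone[2])
  }
  structure(
    list(verdict = verdict, gate_a254_passed = gate_a254,
         gate_pe_passed = gate_pe, gray_zone = gray, rationale = rationale),
    class = "muvi_decision"
  )
}

#' @export
print.muvi_decision <- function(x, ...) {
  cat(sprintf("<muvi_decision> %s (%s)\n", toupper(x$verdict), x$rationale))
  invisible(x)
}

#' Squared sum of scaled absorbance differences (SSSAD)
#'
#' The prior-art screening statistic contrasted with the index-based
#' workflow. Both spectra are reduced to their values at 290, 295, ..., 330
#' nm; each series is zeroed by subtracting its minimum and scaled by
#' dividing by its (zeroed) value at 290 nm; the statistic is the sum of
#' squared differences between the two scaled series. The scaling removes
#' any multiplicative factor, so SSSAD is concentration-invariant. With
#' `squared = FALSE` the plain sum of absolute differences is returned
#' instead.
#'
#' @param sample,standard [spectrum()] objects covering 290--330 nm on the
#'   canonical grid.
#' @param squared Logical; sum of squared (default) or absolute differences.
#' @return A nonnegative scalar; 0 when the scaled shapes coincide.
#' @export
sssad <- function(sample, standard, squared = TRUE) {
  scale_series <- function(s) {
    v <- vapply(seq(290, 330, by = 5), function(w) absorbance_at(s, w),
                numeric(1))
    v <- v - min(v)
    if (v[1] == 0) {
      stop("zeroed absorbance at 290 nm is zero; SSSAD scaling undefined",
           call. = FALSE)
    }
    v / v[1]
  }
  d <- scale_series(sample) - scale_series(standard)
  if (squared) sum(d^2) else sum(abs(d))
}
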