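#' Absorbance spectrum objects
#'
#' A `muvi_spectrum` holds one UV-Vis absorbance trace: a strictly increasing
#' wavelength grid (nm) and the measured absorbance (AU) at each wavelength,
#' together with sample metadata. All downstream index calculations assume
#' the canonical 200--800 nm grid at 1 nm steps (see [canonical_grid()]).
#'
#' @param wavelength Numeric vector of wavelengths in nm, strictly increasing,
#'   all within 190--1100 nm (the range of common benchtop spectrophotometers).
#' @param absorbance Numeric vector of absorbance values (AU), same length as
#'   `wavelength`; all values must be finite.
#' @param sample_id,replicate_id Character identifiers for the sample and the
#'   replicate measurement.
#' @param pathlength_cm Cuvette pathlength in cm. Stored for provenance; the
#'   workflow operates on measured absorbance directly (normalization cancels
#'   pathlength), but a value other than 1 cm triggers a warning.
#' @param toc_ppm_c Optional total organic carbon concentration of the test
#'   portion in ppm C (samples are typically diluted to ~5 ppm C).
#' @param is_normalized Logical; `TRUE` once the spectrum has been divided by
#'   its maximum absorbance (see [normalize_spectrum()]).
#' @return A `muvi_spectrum` object (a list with the fields above).
#' @examples
#' s <- spectrum(200:800, exp(-0.02 * (0:600)), sample_id = "demo")
#' s
#' @export
spectrum <- function(wavelength, absorbance, sample_id = "sample",
                     replicate_id = "r1", pathlength_cm = 1.0,
                     toc_ppm_c = NULL, is_normalized = FALSE) {
  wavelength <- as.numeric(wavelength)
  absorbance <- as.numeric(absorbance)
  if (length(wavelength) != length(absorbance)) {
    stop("`wavelength` and `absorbance` must have the same length", call. = FALSE)
  }
  if (length(wavelength) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (anyNA(wavelength) || !all(is.finite(wavelength))) {
    stop("wavelengths must be finite", call. = FALSE)
  }
  if (anyNA(absorbance) || !all(is.finite(absorbance))) {
    stop("absorbance values must be finite", call. = FALSE)
  }
  if (anyDuplicated(wavelength)) {
    dup <- wavelength[duplicated(wavelength)][1]
    stop(sprintf("duplicate wavelength %g nm (corrupted export?)", dup),
         call. = FALSE)
  }
  if (is.unsorted(wavelength)) {
    warning("wavelengths were not sorted ascending; resorting", call. = FALSE)
    o <- order(wavelength)
    wavelength <- wavelength[o]
    absorbance <- absorbance[o]
  }
  if (min(wavelength) < 190 || max(wavelength) > 1100) {
    stop("wavelengths must lie within 190-1100 nm", call. = FALSE)
  }
  if (!is.numeric(pathlength_cm) || length(pathlength_cm) != 1 ||
      !is.finite(pathlength_cm) || pathlength_cm <= 0) {
    stop("`pathlength_cm` must be a positive number", call. = FALSE)
  }
  if (pathlength_cm != 1) {
    warning(sprintf("pathlength %g cm differs from the standard 1 cm cuvette",
                    pathlength_cm), call. = FALSE)
  }
  if (!is.null(toc_ppm_c)) {
    if (!is.numeric(toc_ppm_c) || length(toc_ppm_c) != 1 || toc_ppm_c <= 0) {
      stop("`toc_ppm_c` must be a positive number or NULL", call. = FALSE)
    }
  }
  structure(
    list(sample_id = as.character(sample_id),
         replicate_id = as.character(replicate_id),
         wavelength = wavelength,
         absorbance = absorbance,
         pathlength_cm = pathlength_cm,
         toc_ppm_c = toc_ppm_c,
         is_normalized = isTRUE(is_normalized)),
    class = "muvi_spectrum"
  )
}

#' @export
print.muvi_spectrum <- function(x, ...) {
  cat(sprintf("<muvi_spectrum> %s / %s\n", x$sample_id, x$replicate_id))
  cat(sprintf("  %d points, %g-%g nm%s\n", length(x$wavelength),
              min(x$wavelength), max(x$wavelength),
              if (x$is_normalized) " (normalized)" else ""))
  cat(sprintf("  absorbance range: %.4g to %.4g AU\n",
              min(x$absorbance), max(x$absorbance)))
  invisible(x)
}

#' @export
as.data.frame.muvi_spectrum <- function(x, ...) {
  data.frame(wavelength_nm = x$wavelength, absorbance = x$absorbance)
}

#' Canonical wavelength grid
#'
#' The canonical internal grid used by every index calculation: 200 to 800 nm
#' inclusive at 1 nm steps, matching the measurement range of the workflow.
#'
#' @param start,stop,step Grid bounds and step in nm.
#' @return Numeric vector of wavelengths.
#' @export
canonical_grid <- function(start = 200, stop = 800, step = 1) {
  seq(start, stop, by = step)
}

#' Check a spectrum is on the canonical grid
#' @noRd
assert_canonical <- function(s, grid = canonical_grid()) {
  stopifnot(inherits(s, "muvi_spectrum"))
  if (length(s$wavelength) != length(grid) ||
      any(abs(s$wavelength - grid) > 1e-9)) {
    stop("spectrum is not on the canonical 200-800 nm / 1 nm grid; ",
         "use resample_to_grid() first", call. = FALSE)
  }
  invisible(TRUE)
}

# Delimiter auto-detection among comma / semicolon / tab. Decimal commas are
# rejected explicitly rather than silently misparsed.
detect_delimiter <- function(lines) {
  counts <- vapply(c("," = ",", ";" = ";", "\t" = "\t"), function(d) {
    sum(vapply(lines, function(l) lengths(regmatches(l, gregexpr(d, l, fixed = TRUE))),
               integer(1)))
  }, numeric(1))
  if (all(counts == 0)) {
    stop("could not detect a delimiter (comma, semicolon or tab) in the file",
         call. = FALSE)
  }
  names(counts)[which.max(counts)]
}

#' Read absorbance spectra from a delimited text file
#'
#' Reads instrument-exported spectra in one of two layouts: `two_column`
#' (wavelength, absorbance) or `wide` (first column wavelength, one absorbance
#' column per replicate). The delimiter (comma, semicolon or tab) is
#' auto-detected; header and unit lines (non-numeric rows) are skipped.
#' Files using a decimal comma are rejected with an explicit error rather than
#' silently misparsed.
#'
#' @param path Path to a delimited text file.
#' @param dialect `"two_column"` or `"wide"`.
#' @param sample_id Sample identifier attached to the returned spectra;
#'   defaults to the file name without extension.
#' @return A list of [spectrum()] objects, one per absorbance column.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("wavelength_nm,absorbance", "200,1.2", "201,1.1", "202,1.0"), f)
#' read_spectrum(f)[[1]]
#' @export
read_spectrum <- function(path, dialect = c("two_column", "wide"),
                          sample_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    stop(sprintf("empty file: %s", path), call. = FALSE)
  }
  delim <- detect_delimiter(lines)
  if (delim != ",") {
    # with a non-comma delimiter, a comma inside a field means decimal commas
    if (any(grepl(",", lines, fixed = TRUE))) {
      stop("file appears to use decimal commas; export with decimal points",
           call. = FALSE)
    }
  }
  rows <- strsplit(lines, delim, fixed = TRUE)
  parsed <- lapply(rows, function(f) suppressWarnings(as.numeric(trimws(f))))
  numeric_row <- vapply(parsed, function(v) length(v) >= 2 && !anyNA(v), logical(1))
  if (delim == ",") {
    # a two-field comma row like "254,1" is ambiguous with "254.1" in a
    # semicolon file, but within a comma file decimal commas would make
    # every row non-numeric; catch that case explicitly
    if (!any(numeric_row) && any(grepl(";|\t", lines))) {
      stop("file appears to use decimal commas; export with decimal points",
           call. = FALSE)
    }
  }
  if (!any(numeric_row)) {
    bad <- which(!numeric_row)[1]
    stop(sprintf("no parsable numeric rows; first bad line (%d): %s",
                 bad, lines[bad]), call. = FALSE)
  }
  widths <- lengths(parsed[numeric_row])
  ncol <- max(widths)
  if (any(widths != ncol)) {
    bad <- which(numeric_row)[which(widths != ncol)[1]]
    stop(sprintf("inconsistent column count; first bad line (%d): %s",
                 bad, lines[bad]), call. = FALSE)
  }
  mat <- do.call(rbind, parsed[numeric_row])
  if (nrow(mat) < 2) {
    stop("fewer than 2 usable data rows", call. = FALSE)
  }
  if (dialect == "two_column" && ncol(mat) != 2) {
    stop(sprintf("two_column dialect expects 2 columns, found %d", ncol(mat)),
         call. = FALSE)
  }
  wl <- mat[, 1]
  # wide files: replicate names from the header row when one exists
  header <- rows[!numeric_row]
  rep_names <- paste0("r", seq_len(ncol(mat) - 1))
  if (ncol(mat) > 2 && length(header) >= 1 &&
      length(header[[1]]) == ncol(mat)) {
    nm <- trimws(header[[1]])[-1]
    if (all(nzchar(nm))) rep_names <- nm
  }
  lapply(seq_len(ncol(mat) - 1), function(j) {
    spectrum(wl, mat[, j + 1], sample_id = sample_id,
             replicate_id = rep_names[j])
  })
}

#' Write a spectrum to canonical two-column CSV
#'
#' @param s A [spectrum()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path) {
  stopifnot(inherits(s, "muvi_spectrum"))
  df <- as.data.frame(s)
  # full precision so read -> write -> read round-trips exactly
  lines <- c("wavelength_nm,absorbance",
             paste(format(df$wavelength_nm, digits = 17, trim = TRUE,
                          scientific = FALSE),
                   format(df$absorbance, digits = 17, trim = TRUE),
                   sep = ","))
  writeLines(lines, path)
  invisible(path)
}

#' Subtract a blank (baseline) spectrum
#'
#' Pointwise subtraction of a buffer/DI-water baseline measured on the same
#' wavelength grid. Negative values after correction are retained, not
#' clipped (clipping would bias the slope fits), but a minimum below
#' -0.005 AU triggers a warning since it usually indicates a bad blank.
#'
#' @param sample,blank [spectrum()] objects on identical wavelength grids.
#' @return The corrected spectrum, keeping `sample`'s metadata.
#' @export
blank_correct <- function(sample, blank) {
  stopifnot(inherits(sample, "muvi_spectrum"), inherits(blank, "muvi_spectrum"))
  if (length(sample$wavelength) != length(blank$wavelength) ||
      any(abs(sample$wavelength - blank$wavelength) > 1e-9)) {
    stop("sample and blank are on different wavelength grids; ",
         "resample with resample_to_grid() first", call. = FALSE)
  }
  corrected <- sample$absorbance - blank$absorbance
  if (min(corrected) < -0.005) {
    warning(sprintf(
      "blank-corrected absorbance reaches %.4g AU (< -0.005); check the blank",
      min(corrected)), call. = FALSE)
  }
  out <- sample
  out$absorbance <- corrected
  out$is_normalized <- FALSE
  out
}

#' Resample a spectrum onto a regular grid
#'
#' Linear interpolation onto the inclusive grid `seq(grid_start, grid_stop,
#' step)`. Extrapolation outside the measured range is refused. When a query
#' wavelength coincides with a measured one the measured value is returned
#' unchanged.
#'
#' @param s A [spectrum()] object.
#' @param grid_start,grid_stop,step Target grid in nm (default the canonical
#'   200--800 nm at 1 nm).
#' @return A [spectrum()] on the requested grid.
#' @export
resample_to_grid <- function(s, grid_start = 200, grid_stop = 800, step = 1) {
  stopifnot(inherits(s, "muvi_spectrum"))
  grid <- seq(grid_start, grid_stop, by = step)
  rng <- range(s$wavelength)
  if (grid_start < rng[1] || grid_stop > rng[2]) {
    stop(sprintf(
      "requested grid %g-%g nm extends beyond the measured range %g-%g nm; refusing to extrapolate",
      grid_start, grid_stop, rng[1], rng[2]), call. = FALSE)
  }
  # exact pass-through where query points coincide with measured points
  idx <- match(grid, s$wavelength)
  vals <- numeric(length(grid))
  hit <- !is.na(idx)
  vals[hit] <- s$absorbance[idx[hit]]
  if (any(!hit)) {
    vals[!hit] <- stats::approx(s$wavelength, s$absorbance,
                                xout = grid[!hit], method = "linear")$y
  }
  out <- s
  out$wavelength <- grid
  out$absorbance <- vals
  out
}
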