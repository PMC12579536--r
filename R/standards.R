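#' Bundled fulvic acid reference standards
#'
#' Returns the published index values for the two IHSS hydrophobic fulvic
#' acid reference standards used by the MUVI workflow: Suwannee River fulvic
#' acid (SRFA) and Pahokee peat fulvic acid (PPFA). These printed (rounded)
#' values are the canonical bundled standards: users without IHSS material
#' cannot re-derive them from spectra. Note that the low precision of some
#' entries (the slopes are printed to 1--2 significant digits) limits how
#' precisely percent errors on the slope indices can be reproduced.
#'
#' @param name `"SRFA"` or `"PPFA"`.
#' @return A `muvi_standard` list: `name`, `indices` (named numeric vector in
#'   [muvi_index_names] order), `source = "bundled"`.
#' @examples
#' bundled_standard("SRFA")$indices[["a254"]]
#' @export
bundled_standard <- function(name) {
  tbl <- standards_table()
  i <- match(name, tbl$name)
  if (is.na(i)) {
    stop(sprintf("unknown standard '%s'; available: %s", name,
                 paste(tbl$name, collapse = ", ")), call. = FALSE)
  }
  vals <- as.numeric(tbl[i, muvi_index_names])
  names(vals) <- muvi_index_names
  new_standard(name, vals, source = "bundled")
}

#' List bundled standard names
#' @return Character vector of available standard names.
#' @export
list_standards <- function() {
  standards_table()$name
}

standards_table <- function() {
  path <- system.file("extdata", "reference_standards.csv", package = "muvi",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

new_standard <- function(name, indices, source) {
  indices <- indices[muvi_index_names]
  if (anyNA(indices) || !all(is.finite(indices))) {
    stop("standard must have all 10 index values finite", call. = FALSE)
  }
  if (any(indices <= 0)) {
    stop("standard index values must be strictly positive ",
         "(they are percent-error denominators)", call. = FALSE)
  }
  structure(list(name = as.character(name), indices = indices, source = source),
            class = "muvi_standard")
}

#' @export
print.muvi_standard <- function(x, ...) {
  cat(sprintf("<muvi_standard> %s (%s)\n", x$name, x$source))
  print(round(x$indices, 4))
  invisible(x)
}

#' Build a reference standard from measured spectra
#'
#' Computes the ten indices for each replicate spectrum of a standard
#' solution (typically triplicate 5 ppm C portions) and averages them
#' field-wise into a [bundled_standard()]-compatible reference.
#'
#' @param spectra List of [spectrum()] objects (>= 1 replicate), each on the
#'   canonical grid and normalizable.
#' @param name Name for the resulting standard.
#' @param windows Slope-fit windows, as in [compute_indices()].
#' @return A `muvi_standard` with `source = "computed"`.
#' @export
standard_from_spectra <- function(spectra, name, windows = default_windows()) {
  if (length(spectra) < 1) {
    stop("need at least one replicate spectrum", call. = FALSE)
  }
  idx <- lapply(seq_along(spectra), function(i) {
    tryCatch(as_index_vector(compute_indices(spectra[[i]], windows)),
             error = function(e) {
               stop(sprintf("index computation failed for replicate %d (%s): %s",
                            i, spectra[[i]]$replicate_id, conditionMessage(e)),
                    call. = FALSE)
             })
  })
  mean_idx <- colMeans(do.call(rbind, idx))
  new_standard(name, mean_idx, source = "computed")
}
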