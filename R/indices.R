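#' Index names
#'
#' The ten spectral indices, in canonical order: the two exponential spectral
#' slopes (per nm), six normalized absorbance coefficients, the slope ratio
#' and the E2:E3 absorbance ratio.
#'
#' @format Character vector of length 10.
#' @export
muvi_index_names <- c("s275", "s350", "a254", "a280", "a325", "a355",
                      "a412", "a440", "sr", "e2e3")

#' Normalize a spectrum by its maximum absorbance
#'
#' Divides the absorbance at every wavelength by the maximum absorbance over
#' the 200--800 nm range, so the resulting spectrum has maximum 1. All index
#' calculations operate on normalized spectra; normalization makes the
#' indices insensitive to concentration and pathlength.
#'
#' @param s A [spectrum()] on the canonical grid.
#' @return The normalized spectrum (`is_normalized = TRUE`). Idempotent.
#' @export
normalize_spectrum <- function(s) {
  assert_canonical(s)
  m <- max(s$absorbance)
  if (m <= 0) {
    stop("maximum absorbance is <= 0; cannot normalize ",
         "(blank or inverted spectrum?)", call. = FALSE)
  }
  out <- s
  out$absorbance <- s$absorbance / m
  out$is_normalized <- TRUE
  out
}

#' Look up the absorbance at an exact grid wavelength
#'
#' The wavelengths of interest (250, 254, 280, 325, 355, 365, 412, 440 nm)
#' are integers on the canonical 1 nm grid, so this is an exact lookup, not
#' an interpolation.
#'
#' @param s A [spectrum()] on the canonical grid.
#' @param wavelength Wavelength in nm; must lie on the grid.
#' @return The absorbance value at that wavelength.
#' @export
absorbance_at <- function(s, wavelength) {
  assert_canonical(s)
  i <- which(abs(s$wavelength - wavelength) < 1e-9)
  if (length(i) != 1) {
    stop(sprintf("wavelength %g nm is not on the spectrum grid", wavelength),
         call. = FALSE)
  }
  s$absorbance[i]
}

#' Fit the exponential spectral slope over a wavelength window
#'
#' Fits the three-parameter model
#' \deqn{a_\lambda = a_{\lambda_0} e^{-S(\lambda - \lambda_0)} + K}
#' to the points inside the window by nonlinear least squares
#' (Levenberg-Marquardt). `S` (per nm) measures how fast absorbance decays
#' with wavelength and correlates with molecular weight and aromaticity;
#' `K` is a background constant. The reference wavelength
#' \eqn{\lambda_0} is the window start, which only rescales the amplitude,
#' not the slope.
#'
#' Initialization is deterministic: the starting slope comes from ordinary
#' least squares on `log(a - min(a) + 1e-6)` versus wavelength, the starting
#' background is the window minimum, and the starting amplitude is the value
#' at \eqn{\lambda_0} minus the background. Up to three further attempts with
#' deterministically perturbed backgrounds are made if the optimizer fails.
#' Bounds: `S` in (0, 1], `K` in [-0.1, 1], amplitude >= 0.
#'
#' A fit whose slope or amplitude collapses to (numerically) zero is flagged
#' `non_exponential` rather than raising an error; downstream percent errors
#' for such samples are large, which is the desired behaviour for
#' non-humified materials.
#'
#' @param s A normalized [spectrum()] on the canonical grid.
#' @param window Length-2 numeric, window start and stop in nm; needs at
#'   least 6 grid points.
#' @param lambda0 Reference wavelength; defaults to the window start.
#' @return A `muvi_slope_fit` list: `s`, `a_ref`, `k`, `lambda0`, `window`,
#'   `rss`, `converged`, `non_exponential`.
#' @examples
#' wl <- canonical_grid()
#' sp <- spectrum(wl, 0.8 * exp(-0.018 * (wl - 275)) + 0.01)
#' fit_spectral_slope(normalize_spectrum(sp), c(275, 295))
#' @export
fit_spectral_slope <- function(s, window, lambda0 = window[1]) {
  assert_canonical(s)
  stopifnot(length(window) == 2, window[1] < window[2])
  inw <- s$wavelength >= window[1] & s$wavelength <= window[2]
  if (sum(inw) < 6) {
    stop("slope window must contain at least 6 grid points", call. = FALSE)
  }
  x <- s$wavelength[inw]
  y <- s$absorbance[inw]

  eps <- 1e-6
  k0 <- min(y)
  ylog <- log(y - k0 + eps)
  s0 <- -unname(stats::coef(stats::lm(ylog ~ x))[2])
  s0 <- min(max(s0, 1e-4), 1)
  aref0 <- max(y[which.min(abs(x - lambda0))] - k0, eps)

  resid_fn <- function(par) par[1] * exp(-par[2] * (x - lambda0)) + par[3] - y
  jac_fn <- function(par) {
    e <- exp(-par[2] * (x - lambda0))
    cbind(e, -par[1] * (x - lambda0) * e, rep(1, length(x)))
  }
  lower <- c(0, 1e-12, -0.1)
  upper <- c(Inf, 1, 1)
  ctrl <- minpack.lm::nls.lm.control(ftol = 1e-12, ptol = 1e-12, maxiter = 500)
  # deterministic restart ladder over the background start value
  k_starts <- unique(pmax(pmin(c(k0, k0 / 2, 0, k0 + 0.01), 1), -0.1))

  best <- NULL
  for (k_try in k_starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = c(aref0, s0, k_try), fn = resid_fn,
                         jac = jac_fn, lower = lower, upper = upper,
                         control = ctrl),
      error = function(e) NULL)
    if (is.null(fit)) next
    # info codes 1-3 signal convergence of the Levenberg-Marquardt iteration
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
    if (fit$info %in% 1:3) break
  }
  if (is.null(best)) {
    stop(sprintf("spectral slope fit failed on window %g-%g nm after %d starts",
                 window[1], window[2], length(k_starts)), call. = FALSE)
  }
  co <- best$par
  structure(
    list(s = co[2], a_ref = co[1], k = co[3],
         lambda0 = lambda0, window = window,
         rss = best$deviance,
         converged = best$info %in% 1:3,
         non_exponential = co[2] <= 1e-8 || co[1] <= 1e-8),
    class = "muvi_slope_fit"
  )
}

#' @export
print.muvi_slope_fit <- function(x, ...) {
  cat(sprintf("<muvi_slope_fit> window %g-%g nm (lambda0 = %g)\n",
              x$window[1], x$window[2], x$lambda0))
  cat(sprintf("  S = %.6g per nm, a_ref = %.4g, K = %.4g, rss = %.3g\n",
              x$s, x$a_ref, x$k, x$rss))
  if (x$non_exponential) cat("  flagged non-exponential\n")
  invisible(x)
}

# Slope-fit windows. S@275 uses 275-295 nm so that it is self-consistent with
# the slope ratio SR(275/350), which is defined on the 275-295 and 350-400 nm
# intervals.
default_windows <- function() {
  list(s275 = c(275, 295), s350 = c(350, 400))
}

#' Compute the ten MUVI spectral indices
#'
#' On the normalized spectrum: absorbance coefficients at 254, 280, 325, 355,
#' 412 and 440 nm by exact grid lookup; spectral slopes `s275` (window
#' 275--295 nm) and `s350` (window 350--400 nm) by exponential fit
#' ([fit_spectral_slope()]); the slope ratio `sr = s275/s350`; and the E2:E3
#' ratio `e2e3 = a250/a365`. Because the spectrum is normalized first, the
#' indices are invariant to rescaling of the raw spectrum (concentration,
#' pathlength).
#'
#' @param s A normalized [spectrum()] on the canonical grid (a raw spectrum
#'   is normalized on the fly).
#' @param windows Named list with `s275` and `s350` window bounds (nm).
#' @return A `muvi_indices` object: a named numeric vector of the ten index
#'   values (see [muvi_index_names]) with the two slope fits attached as the
#'   `"fits"` attribute.
#' @examples
#' wl <- canonical_grid()
#' sp <- spectrum(wl, exp(-0.02 * (wl - 200)))
#' compute_indices(sp)
#' @export
compute_indices <- function(s, windows = default_windows()) {
  assert_canonical(s)
  if (!s$is_normalized) s <- normalize_spectrum(s)
  f275 <- fit_spectral_slope(s, windows$s275)
  f350 <- fit_spectral_slope(s, windows$s350)
  a365 <- absorbance_at(s, 365)
  if (a365 == 0) {
    stop("absorbance at 365 nm is zero; a250/a365 ratio undefined",
         call. = FALSE)
  }
  vals <- c(
    s275 = f275$s,
    s350 = f350$s,
    a254 = absorbance_at(s, 254),
    a280 = absorbance_at(s, 280),
    a325 = absorbance_at(s, 325),
    a355 = absorbance_at(s, 355),
    a412 = absorbance_at(s, 412),
    a440 = absorbance_at(s, 440),
    sr   = f275$s / f350$s,
    e2e3 = absorbance_at(s, 250) / a365
  )
  structure(vals, fits = list(s275 = f275, s350 = f350),
            class = c("muvi_indices", "numeric"))
}

#' @export
print.muvi_indices <- function(x, ...) {
  cat("<muvi_indices>\n")
  print(round(unclass(x)[muvi_index_names], 4))
  invisible(x)
}

#' Coerce an index set to a plain named numeric vector
#' @param x A `muvi_indices` object or named numeric vector.
#' @return Named numeric vector in canonical index order.
#' @export
as_index_vector <- function(x) {
  v <- unclass(x)[muvi_index_names]
  attributes(v) <- list(names = muvi_index_names)
  if (anyNA(v)) stop("index set is missing values for: ",
                     paste(muvi_index_names[is.na(v)], collapse = ", "),
                     call. = FALSE)
  v
}
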