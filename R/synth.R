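# Run code with a fixed RNG seed, restoring the caller's RNG state after.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Parameters for synthetic spectrum generation
#'
#' Describes one synthetic absorbance spectrum. The base curve follows the
#' exponential model characteristic of humic substances,
#' \eqn{a_\lambda = a_0 e^{-s(\lambda - 200)} + k}, or one of three
#' adulterant archetypes invented for test coverage (they carry no claim of
#' chemical fidelity):
#' \itemize{
#'   \item `"flat"` — constant absorbance (grossly non-humic shape);
#'   \item `"gaussian_mixture"` — a sum of Gaussian bands, mimicking discrete
#'     chromophores of non-humified materials (e.g. lignosulfonates);
#'   \item `"near_zero"` — constant ~0.005 AU, mimicking colorless adulterants
#'     such as molasses or organic acids whose raw absorbance at 254 nm falls
#'     far below the 0.08 AU screening gate.
#' }
#' Metal-binding difference bands can be added as Gaussians; the
#' characteristic band centers are approximately 200, 240, 276, 316, 385 and
#' 547 nm (see [metal_band_centers]). Measurement noise is additive i.i.d.
#' Gaussian in AU (spectrophotometer noise near the detection floor is
#' approximately signal-independent). Generation is fully seeded: identical
#' parameters give byte-identical spectra.
#'
#' @param a0 Amplitude at 200 nm (AU), >= 0.
#' @param s Exponential decay rate per nm, >= 0.
#' @param k Background constant (AU).
#' @param noise_sd Standard deviation of additive Gaussian noise (AU), >= 0.
#' @param metal_bands List of `c(center_nm, width_nm, height_au)` triplets;
#'   widths must be positive (default width in practice: 15 nm).
#' @param shape One of `"exponential"`, `"flat"`, `"gaussian_mixture"`,
#'   `"near_zero"`.
#' @param bands For `shape = "gaussian_mixture"`: list of
#'   `c(center, width, height)` triplets forming the base curve.
#' @param seed Integer seed; mandatory.
#' @return A `muvi_synth_params` list.
#' @export
synth_params <- function(a0 = 1.0, s = 0.018, k = 0.005, noise_sd = 0,
                         metal_bands = list(),
                         shape = c("exponential", "flat", "gaussian_mixture",
                                   "near_zero"),
                         bands = list(c(280, 30, 0.5), c(350, 40, 0.3)),
                         seed) {
  shape <- match.arg(shape)
  if (missing(seed) || is.null(seed)) {
    stop("`seed` is mandatory: unseeded generation is not reproducible",
         call. = FALSE)
  }
  stopifnot(a0 >= 0, s >= 0, noise_sd >= 0)
  check_bands <- function(b, what) {
    for (x in b) {
      if (length(x) != 3 || x[2] <= 0) {
        stop(sprintf("each %s must be c(center_nm, width_nm > 0, height_au)",
                     what), call. = FALSE)
      }
    }
  }
  check_bands(metal_bands, "metal band")
  check_bands(bands, "mixture band")
  structure(
    list(a0 = a0, s = s, k = k, noise_sd = noise_sd,
         metal_bands = metal_bands, shape = shape, bands = bands,
         seed = as.integer(seed)),
    class = "muvi_synth_params"
  )
}

#' Metal-binding difference band centers
#'
#' Approximate centers (nm) of the difference-spectrum bands produced by
#' metal ion binding to fulvic acids; bands at 385 and 547 nm perturb the
#' long-wavelength indices (a412, a440) while leaving the 254/280 nm region
#' essentially untouched.
#'
#' @format Numeric vector of 6 wavelengths (nm).
#' @export
metal_band_centers <- c(200, 240, 276, 316, 385, 547)

gaussian_band <- function(wl, center, width, height) {
  height * exp(-((wl - center)^2) / (2 * width^2))
}

#' Generate one synthetic absorbance spectrum
#'
#' Evaluates the base curve for the chosen shape on the canonical 200--800 nm
#' grid, adds any metal-binding Gaussian bands and seeded Gaussian noise.
#'
#' @param p A [synth_params()] object.
#' @param sample_id,replicate_id Identifiers for the resulting spectrum.
#' @return A [spectrum()] on the canonical grid (raw, not normalized).
#' @examples
#' sp <- generate_spectrum(synth_params(s = 0.018, seed = 42))
#' compute_indices(sp)
#' @export
generate_spectrum <- function(p, sample_id = "synthetic", replicate_id = "r1") {
  stopifnot(inherits(p, "muvi_synth_params"))
  wl <- canonical_grid()
  base <- switch(p$shape,
    exponential = p$a0 * exp(-p$s * (wl - 200)) + p$k,
    flat = rep(p$a0, length(wl)),
    gaussian_mixture = {
      v <- rep(p$k, length(wl))
      for (b in p$bands) v <- v + p$a0 * gaussian_band(wl, b[1], b[2], b[3])
      v
    },
    near_zero = rep(0.005, length(wl))
  )
  for (b in p$metal_bands) {
    base <- base + gaussian_band(wl, b[1], b[2], b[3])
  }
  if (p$noise_sd > 0) {
    base <- base + with_seed(p$seed, stats::rnorm(length(wl), 0, p$noise_sd))
  }
  spectrum(wl, base, sample_id = sample_id, replicate_id = replicate_id)
}

#' Generate replicate synthetic spectra
#'
#' Emulates the triplicate measurement workflow: `n` spectra drawn from the
#' same parameters with seeds `seed, seed + 1, ..., seed + n - 1`, so the
#' set is deterministic while replicates differ only by noise.
#'
#' @param p A [synth_params()] object.
#' @param n Number of replicates (>= 1).
#' @param sample_id Sample identifier shared by the replicates.
#' @return List of `n` [spectrum()] objects with replicate ids `r1..rn`.
#' @export
generate_replicates <- function(p, n, sample_id = "synthetic") {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("`n` must be a positive integer", call. = FALSE)
  }
  lapply(seq_len(n), function(i) {
    pi <- p
    pi$seed <- p$seed + i - 1L
    generate_spectrum(pi, sample_id = sample_id,
                      replicate_id = paste0("r", i))
  })
}
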