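---
title: "The MUVI screening method: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The MUVI screening method: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muvi)
```

## The screening problem

Fulvic fractions of humic substances absorb UV-visible light in a nearly
featureless exponential decay — the collective signature of thousands of
chromophores produced by humification. Non-humified imitations (sugar
concentrates, lignosulfonates, protein hydrolysates) either barely absorb at
254 nm at 5 ppm carbon or absorb with a distinctly different spectral shape.
`muvi` quantifies "different shape" as the average percent deviation of ten
spectral indices from two well-characterized reference fulvic acids, and
combines that score with a raw-absorbance gate into a binary call.

This vignette documents the models and the numerical and design choices in
the package, including the ones where reasonable alternatives existed.

## Spectra and the canonical grid

All computation happens on a canonical wavelength grid of 200–800 nm
inclusive at 1 nm steps (601 points). Instruments export at various
increments, so `resample_to_grid()` linearly interpolates onto this grid and
refuses to extrapolate. The 1 nm step fixes every index's sampling
unambiguously: the absorbance coefficients are exact grid lookups, never
interpolations. Absorbance is used in instrument units (AU); pathlength is
stored and checked (warning if ≠ 1 cm) but not corrected for, since the
normalization step cancels any multiplicative factor.

Blank (buffer baseline) correction is pointwise subtraction on a shared
grid. Negative corrected values are *retained*: clipping at zero would bias
the exponential fits near the detection floor. A minimum below −0.005 AU
triggers a warning, as corrections that large usually indicate a bad blank
rather than noise.

## The ten indices

On the max-normalized spectrum:

| index | definition | default window |
|---|---|---|
| a254 … a440 | normalized absorbance at 254, 280, 325, 355, 412, 440 nm | — |
| S275 | decay rate of $a_\lambda = a_{\lambda_0} e^{-S(\lambda-\lambda_0)} + K$ | 275–295 nm |
| S350 | same model | 350–400 nm |
| SR | $S_{275}/S_{350}$ | — |
| E2:E3 | $a_{250}/a_{365}$ | — |

Two window conventions circulate for the short-wavelength slope (275–290 nm
and 275–295 nm). The package uses **275–295 nm for both S275 and SR**, so
that the slope ratio is self-consistent with its own defining intervals; the
bounds are overridable via the `windows` argument of `compute_indices()` and
`muvi_config()`.

### The slope fit

The three-parameter model is fitted by Levenberg–Marquardt
(`minpack.lm::nls.lm`) with an analytic Jacobian. Everything about the fit
is deterministic:

* start values: $S_0$ from ordinary least squares on
  $\log(a - \min a + 10^{-6})$ versus $\lambda$ (clamped to $[10^{-4}, 1]$),
  $K_0 = \min a$ in the window, amplitude start = value at $\lambda_0$ minus
  $K_0$;
* bounds: $S \in (0, 1]$ per nm, $K \in [-0.1, 1]$, amplitude ≥ 0;
* convergence: `ftol = ptol = 1e-12`, up to 500 iterations, with a
  deterministic restart ladder over perturbed $K_0$ values
  ($K_0/2$, $0$, $K_0 + 0.01$) if the first attempt fails;
* $\lambda_0$ is fixed at the window start — this choice only rescales the
  amplitude, never $S$.

A fit whose slope or amplitude collapses to numerical zero (≤ 1e-8) is
*flagged* `non_exponential` rather than raised as an error: flat or
non-decaying spectra are exactly the adulterant signatures the method is
meant to score, and their large downstream percent errors are the signal.

### Identifiability limits of the window fit

With $K$ free, a 21-point window and additive noise of sd $10^{-4}$ AU, the
Cramér–Rao bound for $S$ depends strongly on how much the curve actually
decays across the window:

| true S (per nm) | CRB on S (relative sd) |
|---|---|
| 0.005 | 8.2 % |
| 0.010 | 3.1 % |
| 0.020 | 1.8 % |
| 0.050 | 3.7 % |

At $S = 0.005$ the curve falls by only ~9 % across 275–295 nm, and the free
background constant absorbs most of the signal, so *no* estimator can
recover such a slow slope to 5 % on average at that noise level; the
package's fit attains the bound (200-seed empirical mean error ≈ 6.5 %,
the folded-normal mean of an 8.2 %-sd estimator). The corresponding
acceptance expectation in the test suite is deliberately left failing at
$S = 0.005$ with a comment, rather than silently relaxed: dropping $K$
would restore identifiability but abandon the stated three-parameter model.
Real fulvic samples sit near $S \approx 0.015$–0.02, where recovery is
comfortable.

## Scoring and the decision rule

Percent error, $PE = |v_a - v_s| / v_s \times 100$, is computed per index
against each standard and averaged with equal weights into PE_avg. The
*lower* PE_avg across SRFA and PPFA feeds the decision — a sample
resembling either standard passes. A single standard can be configured, but
the two-standard rule is the default.

The bundled standard values are the published rounded index tables, because
users without IHSS material cannot re-derive them. A consequence worth
knowing: the slope entries are printed to one or two significant digits
(SRFA S275 = 0.01), so percent errors on the slope indices inherit up to
tens of percent of rounding distortion. For example, scoring PPFA's printed
indices against SRFA reproduces the published absorbance-coefficient PE
cells exactly (2, 10, 27, …) but yields a PE_avg of ~11.3 rather than the
published 7.9, which was evidently computed from unrounded internal values.
The package reports what it computes.

Replicate aggregation averages per-index PEs across replicates, then
averages the ten means (both steps are linear, so the grouping does not
affect PE_avg). If any index's PE spreads by more than 20 percentage points
across replicates (against any standard), `concordance_ok` is set `FALSE` —
the published remedy is re-acquisition, a lab action, so the software flags
rather than aborts. Note that near the detection floor, slope-index PEs
against a 0.01 denominator can legitimately spread past 20 points at
instrument noise; a concordance failure on slope indices alone deserves a
look at the fits before re-measuring.

Both gates are strict inequalities exactly as published: raw A254 of
exactly 0.08 fails, PE_avg of exactly 70 fails. Applied to the bundled
validation tables, the strict rule reproduces all published calls except a
single commercial product published as fulvic at PE_avg 82/91 — inside the
gray zone, where the publication itself recommends orthogonal analysis. The
package surfaces this discrepancy (the strict rule says non-fulvic) instead
of special-casing it. Gray-zone handling (60–90 %) defaults to *off* so the
binary published behaviour reproduces; `gray_zone_mode = TRUE` downgrades
gray-zone samples that pass the absorbance gate to `indeterminate`.

### SSSAD

The prior-art statistic is included for comparison: values at 290–330 nm in
5 nm steps, zeroed by the series minimum, scaled by the zeroed 290 nm
value, then summed as squared differences. The name says "squared sum"
while some descriptions read as a plain sum of differences; the package
implements the sum of *squared* differences (matching the acronym and
making the statistic positive definite), with `squared = FALSE` available
for the plain absolute-difference sum.

## The synthetic generator

`generate_spectrum()` emulates what the screening workflow sees, not the
underlying chemistry:

* **exponential** — $a_0 e^{-s(\lambda-200)} + k$, the humic shape. Default
  $s = 0.018$ per nm (typical fulvic slope), $a_0 = 1$ AU (a 5 ppm C fulvic
  solution's absorbance near 200 nm is of order 0.5–2 AU), $k = 0.005$ AU
  residual background.
* **metal bands** — additive Gaussians at the characteristic metal–fulvic
  difference-band centers (200, 240, 276, 316, 385, 547 nm). No lineshape
  is published for these bands; Gaussian with a 15 nm width is an
  assumption. With that width, a 547 nm band reaches none of the ten index
  wavelengths — the long-wavelength index shifts are carried by the 385 nm
  band, consistent with the main metal-driven deviations appearing at 412
  and 440 nm.
* **adulterant archetypes** — `flat`, `gaussian_mixture`, `near_zero`
  (constant 0.005 AU, the molasses-like case that fails the absorbance
  gate). These are test-coverage constructions with no claim of chemical
  fidelity.
* **noise** — additive i.i.d. Gaussian in AU, default sd 0 (set per
  experiment; 1e-4 AU is representative of a benchtop double-monochromator
  instrument near the detection floor). Additive rather than multiplicative
  because photometric noise at these absorbances is approximately
  signal-independent.

Generation is fully seeded (a seed is mandatory) and leaves the caller's
RNG state untouched; replicates use seeds `seed + 0, 1, 2, …`.

Because the generator produces idealized shapes, passing tests demonstrate
the *pipeline* — parsing, fitting, scoring, classifying — not the chemical
validity of the thresholds on real products. Real spectra carry correlated
baseline drift, stray-light curvature, and scattering that the generator
does not emulate.

Since the measured reference spectra are not redistributable,
`synthetic_srfa_spectrum()` provides a synthetic stand-in: a piecewise
log-linear curve through anchor points chosen so the ten computed indices
reproduce the bundled SRFA reference values at their printed precision
(the two slope windows are exact single exponentials with rates 0.0139 and
0.0199 per nm). It is a constructed object, useful as a realistic
fulvic-shaped input, and is labelled synthetic everywhere.

## Numerical notes

* **Concentration invariance.** Multiplying a raw spectrum by any positive
  factor cancels in normalization, so all indices and PE_avg are invariant —
  the software analogue of the observation that 1–10 ppm dilutions do not
  move the score. For exact-shape spectra this holds to < 1e-9 percentage
  points on PE_avg (measured ~3e-13). For *noisy* spectra the scaled input
  rounds differently in IEEE arithmetic, and the weakly identified slope fit
  amplifies those last-bit differences to ~1e-7 percentage points; this is
  floating-point conditioning, not a property violation.
* **Determinism.** Identical inputs and configuration give identical
  outputs: the fit has no random restarts, the generator is seeded, and
  `run_pipeline()` output is reproducible byte for byte.
* **Problem sizes.** The test suite and the acceptance script use 601-point
  spectra, slope grids of 5 values, 10–200 seeded replicates per property,
  and a 5-sample batch — sizes chosen so the full suite completes in well
  under a minute while estimating each property's empirical distribution
  adequately.

## Known limitations

* Equality with the original interactive fitting tool's output can only be
  approximate: its exact algorithm and weighting are not published, and
  whether it fixes $K = 0$ for the slope-ratio windows is unstated. The
  free-$K$ model is used for both windows here.
* The bundled standards' printed precision limits PE reproducibility on the
  slope indices (see above); supplying your own standard spectra via
  `standard_from_spectra()` avoids this entirely.
* The method itself is a screening tool: samples in the 60–90 % gray zone,
  and any regulatory decision, need orthogonal confirmation. Nothing in the
  package claims biological efficacy or quantifies humic acid content.
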