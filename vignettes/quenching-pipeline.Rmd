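---
title: "Models and methods of the ANAP quenching pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods of the ANAP quenching pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anapquench)
```

This vignette is the package's own account of the science it implements:
the models behind each fitting function, the assumptions they rest on, the
synthetic-data generator that stands in for instrument data, and the
numerical and design choices that were genuinely open.

## The measurement problem

ANAP is a small, environment-sensitive fluorophore that can replace a
single amino acid in a receptor. Serotonin quenches it by photoinduced
electron transfer, a contact-range interaction: in solution the quench rate
tracks collision frequency, and in a receptor binding site it tracks
occupancy. Three regimes carry the information:

1. **Steady-state solution quenching** calibrates the quencher (Stern–Volmer
   constant).
2. **Time-resolved kinetics** distinguish dynamic (collisional) quenching
   from static complexation and characterize the transient charge-transfer
   product that shows the process is chemically reversible.
3. **Cell concentration–response curves** convert receptor-bound ANAP
   fluorescence into an apparent binding curve (EC50, slope).

## Steady-state model

`sv_ratios()` computes F0/F from band-averaged (445–455 nm, inclusive
endpoints on the measured grid, no interpolation) blank-subtracted spectra;
`fit_stern_volmer()` fits `F0/F = F_intercept + K_sv [Q]` by unweighted
ordinary least squares. Unweighted, because the ratios at different
concentrations have similar relative noise and the straight-line model is
itself an approximation; the intercept is left free and is expected near 1.

The inner-filter correction multiplies each observed intensity by
`10^((g·OD_ex + OD_em(λ))/2)` with `g = 0.2` for a low-volume cuvette whose
short 0.2 cm path faces the excitation light. The formula is implemented
exactly as stated, including the division of the summed optical densities
by 2; the geometry of combining the path factor with that division is taken
as given rather than re-derived. Absorbance spectra are smoothed before the
correction with a Gaussian kernel (σ = 0.25 nm, truncated at ±4σ,
renormalized at the edges so boundary points are unweighted averages of
what remains under the kernel). Blank subtraction precedes the correction,
since the correction applies to the fluorophore-attributable signal.
Negative intensities after blank subtraction are retained and flagged, not
clipped — clipping would bias band means upward.

Ratios below 1 occur at low quencher concentrations (solvatochromic
enhancement); `quench_fraction()` reports them as negative with a flag, and
`fit_stern_volmer(drop_enhancement = TRUE)` optionally excludes them. The
default keeps all points.

## Reconvolution lifetime model

Lifetimes of 2–3 ns must be extracted from traces excited by an 8 ns FWHM
pulse and binned at 0.4 ns, so `fit_reconvolution()` never deconvolves:
it fits the trace to a causal discrete convolution of the unit-sum IRF with
a decay law — single exponential, biexponential, or second-order
`a/(1 + k t)` — plus a flat baseline and a time-origin shift `t0`.

Numerical choices:

* **Weighting.** Poisson (variance `max(counts, 1)`) for photon-counting
  traces; uniform for ΔOD traces, which also means the fit goes straight
  through any residual electromagnetic-interference ripple rather than
  notch-filtering it.
* **Optimization.** Levenberg–Marquardt on log-lifetimes, with a
  variable-projection start: amplitudes and baseline are linear given the
  shape parameter, so a 30-point log-spaced lifetime grid with exact linear
  solves locates the global valley before the joint fit polishes it. Three
  additional coarse starts (τ = 0.5, 2, 8 ns) are kept as a safety net. The
  joint problem has genuine local minima when τ is below the IRF width;
  the grid start removed every case of this we observed.
* **Bounds.** `t0` is confined to ±5 ns to prevent lifetime/shift
  degeneracy; lifetimes to [10⁻³, 10³] ns. A fit ending on the `t0` bound
  is flagged.
* **Uncertainties.** Parameter standard errors come from the Gauss–Newton
  covariance at the optimum scaled by the reduced χ².

**TAS assembly.** `build_tas_trace()` applies the −log10 intensity-ratio
construction pointwise; bins with a nonpositive numerator are masked (and
counted), never dropped, so grids stay aligned. The detector-saturation
artifact around peak irradiance is excluded by an explicit mask window;
when none is given, TAS fits default to starting one IRF-peak-plus-two-FWHM
after the trigger. `residual_plateau()` reports the late-window mean ± SE
and calls the decay "recovered" when the mean is within 2 SE of zero.

**Model comparison.** `compare_decay_models()` ranks the three laws by BIC
on the weighted residuals (AICc and reduced χ² are reported alongside),
with near-ties (Δ < 2) resolved toward fewer parameters. BIC rather than
AICc is a deliberate deviation: the candidates are nested, and the extra
lifetime of the biexponential is unidentified when the truth is a single
exponential, so the deviance improvement under the null is heavier-tailed
than χ²₂ and AIC-family criteria select the larger model at a fixed
~15 % rate no matter the signal-to-noise; BIC's log(n) penalty keeps the
selection consistent, which is what a "best fit by a single exponential"
claim needs.

## Photobleach correction and the Hill fit

Each cell contributes five agonist-free PRE exposures; `fit_bleach()` fits
their band intensities against cumulative exposure time to
`A·exp(−t/τ_b) + C`. The offset `C` is included by default (plateau
bleaching is common) and bounded at zero — a plateau is a fluorescence
level — because unbounded offsets admit near-linear fits whose
extrapolation corrupts the correction of later exposures. A non-decreasing
PRE series returns a flagged no-bleach model. `bleach_correct()` divides
every spectrum by the predicted fractional intensity normalized to the
first exposure.

`normalize_response()` maps corrected band intensities to
`(F − F_min) / (F_lowest − F_min)` with `F_min` the highest-concentration
point (option: mean of the top two) — the convention of subtracting the
saturating level and scaling by the lowest applied concentration. The
output is affine-invariant in the input intensities.

`fit_hill()` fits the modified Hill equation in log10 concentration with
the slope factor free in sign. **The asymptotes are fitted by default.**
With shallow slopes (|h| ≈ 0.46) a realistic concentration range leaves
the normalized data an affine transform of the underlying logistic — the
lowest applied concentration is not yet at zero occupancy nor the highest
at full occupancy — so a two-parameter fit of the bare logistic cannot
return the generating midpoint even on noiseless data. Free `fmax`/`fmin`
absorb that residue exactly; `fix_asymptotes = TRUE` restores the
two-parameter form. The fit is performed in log10(EC50), making it
invariant to concentration-unit rescaling.

**Confidence intervals.** Pooled multi-cell fits bootstrap over cells
(seeded, 1000 resamples by default). With six cells, plain percentile
intervals undercover: in a calibration study the cluster-bootstrap SE
underestimated the sampling SD by ~1.2–1.3×, as expected for so few
clusters. The interval therefore uses the bootstrap SE (log scale for
EC50) inflated by √(n/(n−1)) with t(n−1) quantiles — standard few-cluster
practice. Percentile intervals are retained for point-level bootstraps.

Estimator variance in this pipeline is dominated not by spectral noise but
by the bleach-extrapolation tilt: the bleach curve is fitted to the 0–40 s
PRE window and extrapolated to 50–120 s, and each cell's prediction error
grows monotonically along its exposure (hence concentration) sequence.
This also leaves the maximal-quench statistic (`maximal_quench()`, one
minus the saturating-to-lowest intensity ratio, mean ± SEM across cells)
with a small negative bias (under one point on a 66 % quench) relative to
the generator's configured ceiling; with the true bleach curve substituted
the statistic is unbiased. Both facts are asserted by the test suite.

## The synthetic-data generator

One seeded `sim_config()` drives every generator; each output derives an
independent substream from the master seed and a stream name through an
avalanche hash with a short burn-in (a linear seed map left first draws
correlated across related Mersenne streams), records it in metadata, and
restores the caller's RNG state, so datasets are bit-reproducible.

What it emulates, and the defaults:

* **Emission bands** are log-normal in wavelength (red-tailed, rising from
  zero at peak − 3·width), peaks at 451 nm (ANAP in DMSO, width 23 nm),
  495 nm (receptor-bound ANAP, width 30 nm), 562 nm (mOrange, width
  25 nm). The mOrange band is never spectrally unmixed downstream; the
  ANAP reporting band (detected peak ± 5 nm) simply avoids it, while the
  ANAP red tail does overlap mOrange, reproducing the apparent mOrange
  dimming when ANAP quenches.
* **Titrations** scale the fluorophore signal by `1/(intercept + K_sv·c)`
  relative to c = 0, so measured ratios reproduce the Stern–Volmer line
  exactly before noise; an intercept below 1 then appears as the small
  low-concentration enhancement seen in real data. Quencher
  autofluorescence grows linearly with concentration, anchored at 15.2 %
  of the total at 448 nm for the 100 mM reference — the single stated
  datum, extended linearly as the simplest consistent model. A stray-light
  floor (≥ 10 noise SD) is present in both sample and blank so raw spectra
  stay nonnegative without clipping; it cancels in subtraction. Beer–
  Lambert attenuation uses a linear OD ramp (2.0 M⁻¹ at 370 nm falling to
  zero at 600 nm), and the downstream correction inverts it exactly.
  Additive Gaussian noise, σ = 0.5 % of peak amplitude.
* **TRPL** convolves the configured lifetimes (2.776 ns ANAP, 2.231 ns
  5-HT, 2.14 ns quenched ANAP) with a Gaussian IRF (8 ns FWHM, centred at
  20 ns) on 0.4 ns bins over 80 ns, scales to realistic peak counts and
  draws Poisson counts per bin averaged over 64 shots (Gaussian mode
  available; whether Poisson statistics survive analog averaging is left
  open, so both exist).
* **TAS** constructs the pumped trace so the assembled ΔOD equals an
  IRF-convolved 3.18 ns exponential (peak 50 mOD), adds a saturating
  artifact in a 16–23 ns window ("the few nanoseconds at peak
  irradiance"), a damped-sinusoid EMI ripple on the pumped channel only
  (80 MHz, 20 ns damping, amplitude at the shot-noise scale — the ripple is
  qualitative; no quantitative claim is made about the real interference),
  and Gaussian noise scaled by 1/√500 averages (0.2 mOD, chosen to
  reproduce the order of the reported ±0.08 ns fit precision). Steady-state
  and lifetime quenching are parameterized independently throughout: the
  reported K_sv and the lifetime shortening are not mutually consistent
  under τ0/τ = 1 + K_sv[Q], so neither is derived from the other.
* **Cells** get five PRE exposures (10 s each) and eight concentration
  steps (10 nM–100 µM) with bleach fractions from `A = 0.3, τ_b = 60 s,
  C = 0.7`; τ_b is set so the decay is identifiable within the 40 s PRE
  window — the protocol itself presumes that. The ANAP band scales by
  `1 − q_i·OccN(c)` with `OccN` the Hill occupancy range-normalized over
  the applied concentrations: the configured ceiling q then equals, by
  construction, the measured saturating-versus-lowest quench statistic,
  which is itself defined relative to the applied range. Per-cell ceilings
  are drawn from N(0.66, 0.17) (clamped to [0.05, 0.995]) so the SEM
  across six cells is ~7 points; per-cell EC50s carry 10 % log-normal
  scatter (biological variability, and the justification for cell-level
  bootstrap); multiplicative Gaussian noise of 3 % per wavelength point.
  No noise magnitudes are stated for the real cell data; these are
  generator choices.

What the generator does **not** emulate: vibrational cooling at picosecond
times (the real traces show early-time residuals the single-exponential
model ignores; the synthetic traces are exactly in-model), detector
afterpulsing, wavelength-dependent instrument response, cell-to-cell
spectral shape differences, focus drift, and any kinetics of binding and
unbinding. Passing recovery tests therefore demonstrates the correctness
of the estimators under the stated noise models, not robustness to every
artifact of real instruments.

## Problem sizes in the test and acceptance runs

Traces use 201 bins (80 ns at 0.4 ns). Titrations use 8 concentrations up
to 100 mM with 3 replicates where replicates matter. Cell runs use 6 cells
× (5 PRE + 8 concentrations). Stochastic checks use 100 seeds (200 for the
Stern–Volmer unbiasedness check and the maximal-quench average), with 400
bootstrap resamples inside the per-seed coverage loops; the user-facing
default remains 1000 resamples.

## Known limitations

* The bleach model is extrapolated beyond the PRE window by design of the
  protocol; its prediction error dominates EC50 uncertainty with few
  cells, and no CI construction at n = 6 is exactly calibrated (measured
  per-parameter coverage ≈ 92–94 % at nominal 95 %).
* The inner-filter correction assumes the printed geometric form; no
  cuvette ray-tracing is attempted.
* Exposure order confounds concentration with cumulative illumination;
  the pipeline corrects the mean bleach but cannot remove per-cell
  extrapolation error. Randomized concentration order would, but the
  protocol applies concentrations monotonically.
* EMI is fitted through, not filtered; strongly interference-dominated
  traces will bias lifetimes.
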