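---
title: "Methods: time-resolved muscle X-ray diffraction analysis"
author: "musclexrd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: time-resolved muscle X-ray diffraction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(musclexrd)
```

This vignette is the package's own account of the science it implements:
the structural model, the processing chain, the tunable parameters, and
the choices made where the design was genuinely open. Nothing here states
an empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## Coordinates and containers

All reciprocal spacings are in nm^-1 and all real spacings `d = 1/R` in
nm; sarcomere lengths are reported in micrometres. Profiles
(`xrd_profile`) are point samples on a strictly increasing grid, not bins,
with an optional per-point standard deviation used as chi-square weights
`1/sd^2`; series (`xrd_series`) add frame mid-times and the stimulation
protocol. Frame mid-times are the centres of the 3-ms acquisition windows
of a 5-ms frame clock, so with four pre-stimulus frames the resting frames
sit at -18.5, -13.5, -8.5 and -3.5 ms.

## The interference model of the M3 reflection

The thick filament is centrosymmetric about its midpoint; each half
carries 49 layers of myosin motors at axial periodicity `d` (~14.5 nm),
the first layer a distance `hbz` (~80 nm, the half-bare zone) from the
midpoint. Only layers `n_m ... n_d` are assumed axially ordered, each
represented as a point diffractor; the rest contribute nothing. The
meridional intensity is then

$$I(R) = \left[\frac{\sin(N\pi R d)}{\sin(\pi R d)}\right]^2
         \cos^2(\pi R D), \qquad
  N = n_d - n_m + 1,\quad D = 2\,hbz + (n_m + n_d - 2)\,d,$$

an N-slit grating factor (limit $N^2$ at the zeros of the denominator)
times the interference factor of the two arrays, whose fringe period is
exactly $1/D$. The point-diffractor picture ignores the internal axial
mass profile of a motor layer; it is adequate over the narrow M3 window
but cannot describe the M6 reflection or multi-periodicity features (the
transient "star" peak at ~14.8 nm is outside the model by construction —
the fit window excludes nothing, but a single-periodicity model cannot
produce it, which is why the star is handled separately by
`detect_star_peak()`).

### Instrument blur

The model is convolved with a Gaussian point-spread function before
comparison with data. The PSF is specified on the detector face (sigma
~190 µm) and converted to reciprocal space as
`sigma_R = sigma_det/(lambda * L)`; with a 0.1 nm wavelength and 8.26 m
camera this is ~2.3e-4 nm^-1 (`psf_sigma_reciprocal()`, overridable). The
forward model evaluates the intensity on a grid padded by 4 sigma and
crops after convolution, so the generator and the fitter apply
bit-identical smoothing.

### The global chi-square search

`fit_m3_model()` fits `(hbz, d, n_m, n_d, y)` on the 30-point window
0.066-0.072 nm^-1. Because $I(R)$ depends on the integers only through
$(N, D)$, the search runs in $(N, d, D)$ space:

1. **Exhaustive coarse stage.** For every `N` = 1...49, `d` on a 0.05 nm
   grid over [14, 15] and `D` on a 1 nm grid over the range admissible
   given `hbz` in [70, 100], evaluate chi-square with the scale `y`
   profiled out in closed form (weighted linear least squares).
2. **Start selection.** Within each `N`, local minima along `D` are
   de-duplicated by basin (adjacent fringe basins are aliases `D ± 1/R`;
   they separate only after refinement), keeping up to 10 distinct starts.
3. **Refinement.** The best 8 values of `N` are refined by bounded local
   optimisation of `(d, D)`; the leading candidates are then polished by
   nested 1D minimisation (golden-section over `d` with an inner
   minimisation over `D`), because the chi-square valley is steep and
   badly scaled and quasi-Newton steps can stall short of the minimum.
4. **Tie-breaks.** Candidates are ranked by chi-square, then by smaller
   `|N - 45|` (parsimony toward near-full order).

The procedure is fully deterministic. With per-point standard deviations
absent the fit is unweighted; an explicit all-zero sd vector is rejected.

### Layer-index degeneracy

$(n_m, n_d, hbz)$ and $(n_m + k,\, n_d + k,\, hbz - k\,d)$ give identical
intensities, so the integers are not individually identifiable from the
M3 profile alone — only the bounds `1 <= n_m <= n_d <= 49` and
`hbz` in [70, 100] cut the family down. `fit_m3_model()` reports the whole
admissible degenerate set and returns as primary the member whose `hbz` is
closest to the centre of the `hbz` search interval (85 nm). This
convention was chosen over "smallest `n_m`" deliberately: the anatomical
half-bare zone is ~80 nm, and the closest-to-centre rule selects the
plausible member of every degenerate pair, whereas smallest-`n_m` would
sometimes select a twin with `hbz` ~94 nm. Users who prefer a different
convention have the full set in `$degenerate`.

## The 1D processing chain

* **Projection** (`project_meridional`): column sums of an idealised 2D
  array across a ±0.01522 nm^-1 radial band about the meridian, times the
  radial pixel width.
* **Background** (`convex_hull_background`): the lower convex hull of the
  `(R, I)` point set, anchored at the window endpoints and linearly
  interpolated between hull vertices — the standard variant for
  diffraction baselines; it touches the profile at the hull vertices, so
  the subtraction is idempotent. A small residual background is then
  removed point-wise from a reflection-free reference region
  (`subtract_residual_background`); hull first, residual second.
* **Sub-peak fits** (`fit_gaussians`): constrained multi-Gaussian least
  squares with variable projection — component areas are solved by
  non-negative linear least squares at every step, so only centres and
  widths are optimised nonlinearly. Interference sub-peaks share one axial
  width. The fitter multi-starts from peak-picked and evenly spread
  centres at two width scales (all deterministic) to avoid local minima on
  noisy profiles. Non-convergence is reported via a status flag with the
  best candidate, never as an exception or silent `NaN`.
* **Meridional observables** (`analyze_meridional`): total intensity =
  sum of component areas × cross-meridional width (correcting for lateral
  filament misalignment); spacing = area-weighted mean of `1/centre`;
  normalisation to the mean of the four pre-stimulus frames. The M3 is
  modelled with 3 sub-peaks (LA/MA/HA by ascending `R`), the M6 as a
  2-peak doublet throughout.
* **Star detection** (`detect_star_peak`): a fourth Gaussian on the
  low-angle side is accepted only if it improves the reduced chi-square by
  a factor >= 1.3 (configurable) *and* its spacing exceeds the LA spacing.
  The threshold is meaningful only when the reduced chi-square has its
  natural scale, i.e. when per-point standard deviations accompany the
  profile.

## Layer lines, equator, sarcomere

**Global deconvolution** (`deconvolve_layerlines_global`): one joint fit
across all frames of a series with three global nonlinear parameters (two
centres, one shared log-width) and per-frame areas solved non-negatively.
AL1 is declared identifiable only when the two centres are resolvable
(separated by at least twice the shared width — otherwise the free AL1
centre merely absorbs ML1 residuals) and at least one frame's area
excludes zero at the family level (Bonferroni across frames, 5%). For
series where AL1 is unidentifiable (typical of twitches), `fix_s_al1`
freezes the AL1 spacing at a supplied value, e.g. the tetanus estimate.
Log-width parametrisation enforces positivity; areas are non-negative by
construction.

**Equator** (`fit_equator`): four Gaussians with centres constrained to a
single lattice parameter: `1/d_10`, `z_constant/d_10`, `sqrt(3)/d_10`,
`2/d_10` over 0.02-0.065 nm^-1. The Z-reflection constant is *not* a
measured quantity; the default 1.46 is an implementation choice placing
the Z reflection between (1,0) and (1,1), and should be set explicitly
when it matters.

**Sarcomere orders** (`assign_sarcomere_orders`): peaks detected in
0.0033-0.0083 nm^-1 (centres refined by log-parabolic interpolation, exact
for Gaussian peaks), then the contiguous even-order assignment `n_i` in
6-20 minimising the residuals of `R_i = n_i/SL`, with `SL` the closed-form
least-squares slope. Assignments are accepted within ±15% of the prior
`SL` guess and an RMS residual below 5% of the inter-order spacing;
otherwise the frame is flagged "inhomogeneous", mirroring the frames in
real data where sarcomere dispersion makes assignment impossible. The
sarcomere intensity `I_S` averages the third and fourth peaks inside
0.0052-0.0072 nm^-1 (avoiding beam-stop, module-gap and cytoskeletal
contamination in the flanking regions).

## Kinetics

`fit_halftime()` fits a 4-parameter logistic; the half-time is the fitted
midpoint (the time of crossing half-way between baseline and plateau)
minus a reference time: the first stimulus (0 ms) for activation and
twitch relaxation, the last stimulus (100 ms) for tetanus relaxation.
Steepness is bounded to 0.05-5 per ms; fits with under 80% explained
variance are flagged non-monotone. Fits are unweighted and unconstrained
otherwise. `phase_summary()` averages observables over the standard phase
windows; across muscles it averages per muscle first and reports mean ±
SEM (per-muscle-first is the primary convention; pooled means of derived
quantities can differ by ~1%).

Closed forms: `percent_change` = `100*(active-rest)/rest`;
`amplitude_from_intensity` = `sqrt(I/I_rest)` (note `sqrt(mean(I))` and
`mean(sqrt(I))` differ across muscles — the package converts whatever it
is given and leaves the averaging order to the caller);
`cross_sectional_area` = `2*W/(rho*L0)`, which with mg, g cm^-3 and mm
yields mm^2 directly.

## The synthetic-data module

The generator emulates the statistical structure the analysis assumes:

* **Protocols**: 42-frame twitch (single stimulus at 0) and 68-frame
  tetanus (130 Hz train, stimuli 0-100 ms), 5 ms frame period, four
  resting frames, mid-times as above.
* **Time courses**: products of a rising and a falling logistic with
  independent half-times. Real transients are only *fitted* with
  sigmoids; the product form is the simplest generative shape with
  controllable half-times and is not a claim about mechanism.
* **Noise**: profile generators use multiplicative Gaussian noise with
  per-point sd = `noise_fraction × intensity` (photon-count-like);
  scalar signals use additive Gaussian noise scaled to the dynamic range.
  Default levels (1% for M3 profiles, 2% for series) are set so that the
  published parameter scales are recoverable at the study's frame counts;
  per-frame noise of the experiment itself was not published, so these are
  conditions of the simulation, not claims about the beamline.
* **Ground truth** is always returned alongside, making recovery tests
  one-liners.

What the generator does *not* emulate — detector module gaps, asymmetric
point spread, polarisation, Poisson statistics, per-fibre heterogeneity,
collagen contamination — bounds what passing tests show: they validate
the estimators under the stated noise model, not the full detector
physics.

## Problem sizes and tolerances

The shipped tests and the acceptance script use the study-scale problem
sizes: 30-point M3 windows, 68-frame tetanus and 42-frame twitch series,
20-seed recovery studies. Nonlinear fits run Levenberg-Marquardt with
`ftol` 1e-15 / `ptol` 1e-12; the global search uses coarse steps of
0.05 nm (`d`) and 1 nm (`D`) with golden-section polish to ~1e-10.
Noiseless round trips recover generating parameters to ~1e-9 relative;
the degenerate-twin spacing `hbz` shift equals `d` exactly.

## Known limitations

* No M6 forward model: the doublet is described empirically by two
  Gaussians; interpreting its interference structure would need a model
  of the backbone periodicity that the M3 model does not contain.
* The 2D stage operates on idealised synthetic arrays only; experimental
  detector images require centring, mirroring and gap handling that are
  out of scope.
* The layer-index degeneracy means `n_m`, `n_d`, `hbz` are reported under
  a stated convention; only `N`, `d` and `D` are directly identified.
* Statistical comparison between conditions (beyond means and SEMs) is
  out of scope.
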