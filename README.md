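# musclexrd

Time-resolved small-angle X-ray fibre diffraction analysis of contracting
striated muscle, built around the interference fine structure of the
myosin-based M3 meridional reflection.

## The problem

In skeletal muscle, the regulatory state of the myosin-containing thick
filament is read out from a handful of X-ray observables recorded at 5-ms
resolution during twitch and tetanic contractions: the M3 and M6 meridional
reflections (axial packing of the myosin motors and of the filament
backbone), the first myosin and actin layer lines ML1/AL1 (helical motor
order and actin binding), the equatorial (1,0)/(1,1) reflections (radial
motor movement in the hexagonal filament lattice), and ultra-low-angle
sarcomere orders (sarcomere length). `musclexrd` implements the full 1D
analysis chain for these signals and the structural forward model that
interprets the M3 profile, for anyone analysing or simulating such
experiments.

## The model

Each half of the bipolar thick filament carries 49 layers of myosin motors
with axial periodicity *d* (~14.5 nm), the first layer a distance *hbz*
(half-bare zone, ~80 nm) from the filament midpoint. Treating each ordered
layer (from *n*<sub>m</sub> to *n*<sub>d</sub>) as a point diffractor, the
meridional intensity near the M3 reflection is

    I(R) = [sin(N π R d) / sin(π R d)]² · cos²(π R D),       N = n_d − n_m + 1
    D = 2·hbz + (n_m + n_d − 2)·d

the product of an N-slit grating factor and the interference factor of the
two mirror-symmetric arrays, whose fringes have reciprocal period exactly
1/*D*. After convolution with the instrument point-spread function, the
model is fitted to an observed profile on 0.066–0.072 nm⁻¹ by a global
χ² search: every admissible array length *N* with a coarse lattice over
(*d*, *D*), then bounded local refinement, the intensity scale *y* profiled
out in closed form, weighted by the experimental standard deviations.
Because I(R) depends on the integers only through (*N*, *D*), layer
assignments related by (*n*<sub>m</sub>, *n*<sub>d</sub>, *hbz*) →
(*n*<sub>m</sub>+k, *n*<sub>d</sub>+k, *hbz*−k·d) are exactly degenerate;
the full degenerate set is reported and the anatomically plausible member
is returned as primary.

Around the model sit the supporting stages: meridional projection of 2D
patterns, convex-hull background subtraction, constrained multi-Gaussian
sub-peak fits with shared axial widths, global Gaussian deconvolution of
the overlapping ML1/AL1 layer lines across a whole time series (spacings
and width time-invariant, per-frame areas free), constrained 4-Gaussian
equatorial fits, even-order sarcomere-length assignment, and 4-parameter
logistic half-time fits for activation/relaxation kinetics. A synthetic
data module generates twitch (42-frame) and tetanus (68-frame) protocols
with product-of-sigmoid time courses and known ground truth.

## Worked example

Generate a noisy synthetic M3 profile from the tetanus-plateau parameters
(*hbz* = 90.58 nm, *d* = 14.552 nm, all 49 layers ordered) and refit it:

```r
library(musclexrd)

truth <- tf_model(hbz = 90.58, d = 14.552, n_m = 1, n_d = 49, y = 2)
obs   <- generate_m3_profile(truth, noise_fraction = 0.01, seed = 1)
fit_m3_model(obs)
#> <tf_model> hbz = 90.59 nm, d = 14.5519 nm, n_m = 1, n_d = 49 (N = 49), y = 2, D = 879.67 nm
#>   chi2 = 22.69 (reduced 0.9076), 30 points in [0.066, 0.072] nm^-1
```

The search recovers the generating parameters (reduced χ² ≈ 1, as expected
for 1% noise with matching weights). The kinetics and layer-line layers
work the same way:

```r
prot <- acquisition_protocol("tetanus")
sim  <- generate_timeseries(prot, default_kinetics("tetanus"), seed = 1)
fit_halftime(sim$traces$t_ms, sim$traces$force, "rise", window = c(-20, 95))
#> <halftime_fit> t_half = 16.78 ms (k = 0.149 /ms)

g <- generate_layerline_series(prot,
       ml1 = signal_kinetics(1, 0.09, 8.6, 141.8),
       al1 = signal_kinetics(1, 2.66, 15.3, 123.4),
       noise_sd = 0.02, seed = 1)
deconvolve_layerlines_global(g$series)
#> <layerline_series> S_ML1 = 43.00 nm, S_AL1 = 36.60 nm, width 0.0012 nm^-1, 68 frames
```

Here the force half-time estimate (16.8 ms vs the generative 17.0 ms)
reflects one 2%-noise realisation, and the global deconvolution returns
the generating layer-line spacings (43.0 and 36.6 nm) to 0.01 nm.

## Documentation

The methods vignette (`vignettes/muscle-xray-analysis.Rmd`) describes the
model, the processing chain, every tunable window and threshold, the
synthetic-data assumptions, and known limitations.
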