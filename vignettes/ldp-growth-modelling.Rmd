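---
title: "Modelling light distribution and growth in dense cyanobacterial cultures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling light distribution and growth in dense cyanobacterial cultures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Dense algal and cyanobacterial cultures absorb light so efficiently that
cells shade each other: a culture at a few grams per litre is effectively
opaque a few centimetres from the light source. Mutual shading caps
volumetric productivity, and because the light field inside a vessel is
two-dimensional (rows along the light path, columns along the panel) and
strongly nonlinear in cell concentration, first-principles radiative models
become unreliable exactly where they are needed — at high density.

`ldpsim` takes the data-driven route. The light field is represented as an
18 x 40 8-bit grayscale image, the *light distribution pattern* (LDP),
whose gray values (GSV, 0-255) act as an irradiance proxy. Two surrogate
models are trained:

* **LDPM** — 720 independent support-vector regressors, one per pixel,
  each mapping the two scalar drivers (incident intensity, cell
  concentration) to that pixel's gray value. Training and prediction are
  performed pixel by pixel.
* **GRM** — one support-vector regressor mapping an LDP-derived feature
  vector (the 720 pixels scaled to [0, 1], plus mean gray value and
  dark-area fraction) to the instantaneous specific growth state of the
  culture, in OD~730~ h^-1^.

Coupled, they form an iterative simulator: OD fixes concentration, the
LDPM predicts the light field, the GRM turns it into a growth rate, and a
forward-Euler step advances the OD. The simulator is then used to design
semi-continuous cultivation (SAC): harvest every 24 h back to an optimal
inoculum so the culture never grows deep into the shaded regime.

## The synthetic generator (and what it does and does not emulate)

The original study trains on photographs of back-lit vessels. This package
replaces the camera with a physics-based forward generator so that every
stage has controllable ground truth:

* **Depth decay** follows Beer-Lambert attenuation,
  `I(r) = I0 * exp(-k * C * depth(r))`, with `k = 40` per (g/L) per metre.
  At 3.7 g/L a 5 cm light path transmits well under 0.1% of the incident
  flux, reproducing the observed opacity ceiling near 3.9 g/L.
* **Two-sided illumination** is the superposition of the front field and
  its row-reversed mirror; clipping happens only at grayscale conversion,
  the one place where a [0, 255] range exists.
* **Camera response** is linear with saturation:
  `gsv = clip(0.3 * I + 2 + noise, 0, 255)`, rounded to integers, with
  Gaussian sensor noise of 3 gray units by default (small against a
  0-255 signal). The pond preset halves the gain to 0.15 gray per
  µmol m^-2^ s^-1^ so a 1500 µmol m^-2^ s^-1^ surface stays below
  saturation.
* **Scattering** is proxied by a Gaussian blur across columns (sigma = 1
  pixel). With a laterally uniform source this is a no-op; it matters only
  for column-structured sources.
* **Growth truth** is `mu_max * OD * f(I_mean) * g(dark)`: a Monod light
  response `f = I/(I + 150)` with `mu_max = 0.1 h^-1`, and a shading
  penalty `g` equal to 1 until the dark-area fraction (pixels below
  25.5 gray, i.e. 10% of the maximum) reaches 0.431, then ramping linearly
  to 0 at 0.65. Those two inflections are the empirically observed ones:
  growth peaks when dark areas reach ~43% and collapses as they plateau
  near 65%.

What the generator does **not** emulate: camera placement and exposure
control, raw image resolution before 40 x 18 compression, wall reflections,
true radiative transfer (scattering is a blur, not a phase function), and
photo-adaptation lag under changing light. Passing tests therefore certify
the *pipeline* — that the surrogates can recover a light-to-growth law of
the documented shape from image-valued data — not that the package
predicts any particular real vessel without retraining on its images.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `extinction_coeff` | 40 | per (g/L) per m | opacity ceiling near 3.9 g/L over 5 cm; pond SAC output ~0.7 g/L from a 0.4 g/L inoculum |
| `gsv_slope`, `gsv_intercept` | 0.3, 2 (pond 0.15, 2) | gray per µmol m^-2^ s^-1^ | keeps working intensities inside 0-255 |
| `noise_sd` | 3 | gray | realistic sensor noise, small vs signal |
| `mu_max` | 0.1 | h^-1^ | fast-growing cyanobacterium under saturating light |
| `light_half_sat` | 150 | µmol m^-2^ s^-1^ | Monod half-saturation |
| `dark_penalty_onset`, `dark_penalty_full` | 0.431, 0.65 | fraction | the observed growth-rate inflections |
| dark threshold | 25.5 | gray | 10% of the 8-bit maximum; strict `<` comparison |
| `dcw_per_od` | 0.39 | g/L per OD~730~ | pre-established biomass calibration |
| `dt` (surrogate sim) | 1 | h | day-scale growth; see step-size check below |
| `dt` (truth integrator) | 0.5 | h | reference trajectories |

## Model-fitting choices

The SVR hyperparameters of the original models are not documented, so they
are artifact decisions here. Features are standardized with a shared affine
scaler; labels are standardized per pixel so the epsilon tube has a
consistent meaning. Regularization and epsilon are picked by seeded 3-fold
cross-validation over a 3 x 3 grid (cost 1/10/100, epsilon
0.01/0.05/0.1 on the standardized scale). Running the grid on all 720
pixels would be wasteful; it runs on 9 evenly spread pixels and the winning
pair is shared by all pixels, which is sound because pixels differ mainly
in amplitude (absorbed by label standardization), not in the smoothness of
their response surface. The GRM grid additionally tunes the RBF width:
722-dimensional feature vectors that live on a ~2-dimensional manifold
(everything is driven by intensity and concentration) need a much wider
kernel than the 1/p default.

Pixels whose training labels are constant (deep pixels under dim
conditions) are stored as constants rather than SVRs. In evaluation, the
R^2^ convention is `1 - SSE/SST` about the test mean: per-pixel R^2^ is
computed across test records at each pixel, pixels with zero test variance
are excluded from the per-pixel map (and counted), but their residuals
still enter the pooled overall R^2^ over all (record, pixel) pairs. A
dual-route test asserts the pooled value equals a brute-force flat
concatenation.

Train/test splitting is random by record (80/20, seeded); the original
split protocol is unknown. Saturated gray readings are excluded from the
GSV-irradiance calibration fits, since clipping breaks linearity — whether
the original calibration did the same is unstated, so the exclusion is
documented as this package's convention.

## Numerical choices and degenerate inputs

* Forward Euler for both integrators: the surrogate rate field is
  data-driven and not smooth enough to reward higher-order schemes. At the
  default `dt = 1 h` the benchmark trajectory sits within ~1% of its own
  refinement; the packaged step-size check halves the truth integrator's
  0.5 h step and requires the final OD to move by < 1%.
* Predicted rates are floored at zero and flooring events counted; the SAC
  accounting can therefore never report a cycle below zero growth (the
  negative-productivity warning branch is defensive).
* Predictions outside the trained intensity/concentration box are still
  returned but flagged as extrapolation, and the simulator propagates the
  flags; the trained concentration ceiling (~3.9 g/L) is a hard
  trust boundary.
* Ties in the inoculum optimizer break toward the lower OD: a thinner
  inoculum is cheaper and better lit.
* Block-mean pooling for image compression (the compression operator is
  otherwise unspecified): it preserves mean brightness, which is exactly
  the quantity gray values are standing in for; it is idempotent, and for
  divisible shapes equals exact block averaging.

## Study conditions and problem sizes

The packaged benchmarks (also run by the test suite and the acceptance
script) use: a 20 x 20 condition grid (80-800 µmol m^-2^ s^-1^ x
0.1-3.9 g/L) for surrogate fidelity; 15 x 15 and 16 x 14 grids for the
photobioreactor (double-sided 574 µmol m^-2^ s^-1^) and pond
(Texas-summer step program: 400/800/1300 for 1 h each, 1500 for 10 h,
then back down, dark to hour 24) pipelines; truth growth curves from 8
initial ODs per preset; SAC plans of 24 h cycles reset to OD 2.3 (PBR) or
0.4 g/L (pond). These sizes give the surrogates enough support to meet
the fidelity bounds while keeping a full run on a single CPU in minutes.

```{r example}
library(ldpsim)
fx <- fit_surrogate_pipeline("pbr_double", seed = 1)
sim <- simulate_growth(fx$ldpm, fx$grm, 2.3, fx$preset$schedule)
opt <- optimize_initial_od(fx$ldpm, fx$grm, seq(1, 6, by = 1),
                           fx$preset$plan, fx$preset$schedule)
```

## Known limitations

* The generator's optics are one-dimensional physics replicated across
  columns; the surrogates have never seen genuinely two-dimensional
  structure (e.g. bubbles, vortices), although the representation supports
  it.
* The GRM learns growth only along the trajectories it was trained on;
  off-schedule light programs require retraining the pipeline for that
  schedule family.
* Photo-adaptation lag under changing light is deliberately not modelled;
  simulated growth under stepped programs will lead real cultures slightly.
* Nutrients and temperature are assumed non-limiting and constant, matching
  the fed/controlled cultivation regime the models describe.
* The harvest analytics are algebraic conversions (Stokes' law, solids
  content, adherence fractions), not a sedimentation transport model; the
  settling time course helper in the analysis scripts is an illustrative
  plug-flow toy.
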