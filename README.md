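# ldpsim

Surrogate modelling of light availability and growth in dense
cyanobacterial cultures, and simulation-guided design of semi-continuous
algal cultivation (SAC). The package is aimed at bioprocess modellers who
want to reason quantitatively about mutual shading — the growth ceiling
that appears when cells absorb light before it reaches the back of the
vessel — without a radiative-transfer model.

## The core idea

The light field inside a flat vessel is represented as an 18 × 40 8-bit
grayscale image, the *light distribution pattern* (LDP), with gray values
(GSV ∈ [0, 255]) proportional to irradiance. Two machine-learning
surrogates are coupled:

- **LDPM** (light-distribution prediction model): 720 independent
  support-vector regressors, one per pixel, each mapping the two drivers
  — incident intensity *I* (µmol m⁻² s⁻¹) and cell concentration *C*
  (g/L) — to that pixel's gray value.
- **GRM** (growth-rate model): one support-vector regressor mapping an
  LDP feature vector (720 pixels scaled to [0, 1], plus mean GSV and the
  dark-area fraction — the fraction of pixels below 25.5 gray, 10% of the
  8-bit maximum) to the instantaneous growth rate in OD₇₃₀ h⁻¹.

The coupled simulator iterates OD → *C* → LDPM → features → GRM → rate →
forward-Euler OD update, and drives a SAC optimizer that picks the
inoculum concentration maximizing per-cycle productivity
`(OD_end − OD_reset) · 0.39 g/L per OD · 24 h / interval`.

Because camera data cannot ship with the package, a physics-based
generator (Beer–Lambert attenuation, linear camera response with
saturation and noise, Monod light response with a dark-area growth
penalty ramping in between dark fractions 0.431 and 0.65) produces LDP
corpora and ground-truth growth curves with the same statistical
structure, and serves as the oracle for every test. Harvest analytics
(OD↔DCW, solids content, Stokes settling, aggregation/BATH fractions,
areal conversions) round out the pipeline.

## Worked example

```r
library(ldpsim)

# train both surrogates for the double-lit photobioreactor preset
fx  <- fit_surrogate_pipeline("pbr_double", seed = 1)

# simulate one 24 h SAC cycle from the optimal inoculum
sim <- simulate_growth(fx$ldpm, fx$grm, 2.3, fx$preset$schedule)
tail(sim, 1)
#>    time    od730      rate dark_fraction extrapolated
#> 25   24 10.04859 0.4428447     0.4694444         TRUE

# pick the inoculum by simulation, check against the generator truth
opt <- optimize_initial_od(fx$ldpm, fx$grm, seq(1, 6), fx$preset$plan,
                           fx$preset$schedule)
opt$best_od
#> [1] 3
```

A culture reset to OD 2.3 grows to OD ≈ 10.0 in 24 h (3.02 g/L/day of dry
biomass); by hour 24 the dark-area fraction has reached ≈ 0.47, i.e. the
culture has just crossed into the shading-penalized regime — which is why
harvesting daily, and the optimizer's preferred inoculum of OD ≈ 3,
maximize sustained productivity. The `TRUE` extrapolation flag on the
final step is the domain guard doing its job: OD 10.05 corresponds to
3.92 g/L, a hair above the 3.9 g/L concentration ceiling the LDPM was
trained on.

The numbered scripts under `analysis/` walk the full study: corpus
generation, GSV calibration (mean R² 0.995 across 23 concentrations),
LDPM training (held-out overall R² 0.9999 noise-free, 0.9963 under
3-gray sensor noise, 100% of pixels above R² 0.90), GRM training
(held-out R² 0.997), coupled simulation against the ground truth (max
relative OD error 3.6% over 24 h), SAC vs fed-batch over a week
(3.0 g/L/day sustained vs decay to 0 by day 7), inoculum optimization
for the photobioreactor and the Texas-summer pond (surrogate optimum
0.30 g/L vs brute-force truth 0.26 g/L), and the harvest analytics
table. Each writes its outputs under `results/`.

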