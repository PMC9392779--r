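# replom

Single-aggregate growth kinetics from real-time localization microscopy.

Protein amyloid spherulites — dense-core, radially fibrillar aggregates of
proteins such as insulin — grow over minutes to hours. In real-time
binding/photobleaching localization microscopy, each labeled monomer that
binds the growing aggregate yields one diffraction-limited spot that is
localized to tens of nanometers and then bleaches, so the accumulating
localization table is simultaneously a super-resolution image and a
time-stamped record of growth. Bulk assays (ThT fluorescence, turbidity)
average over a heterogeneous ensemble; this package is for analysts who
want per-aggregate kinetics: which aggregates grow isotropically, which
grow as a linear core that later branches, how fast each phase is, and
what activation energy each phase carries.

## What it computes

Per localization movie:

1. **Segmentation** — approximate Euclidean minimum spanning tree on a
   30-nearest-neighbor candidate graph; edges above the 95th length
   percentile cut; clusters under 100 localizations dropped
   (`segment_aggregates()`). Per frame, the aggregate is the largest
   connected subgroup of its cumulative localizations under a stricter
   10-neighbor / 400 nm tree (`frame_membership()`).
2. **Area vs time** — a Gaussian mixture (one component per 5 points, at
   least 25) fitted to each frame's members; the area is the region where
   the fitted density exceeds its grid average (`estimate_area_gmm()`,
   `build_growth_curve()`).
3. **Growth-law fits** — piecewise models integrated and fitted by a
   two-pass chi-square scheme:

   A_lin (anisotropic):  dA/dt = r1 (t<t0); r2 (t0<=t<t1); r2·s(t) (t>=t1)
   A_par (isotropic):    dA/dt = r1 (t<t0); r2·t/2 (t0<=t<t1); (r2·t/2)·s(t)

   with s(t) = 1/(1 + exp(5(t − τ − t1)/τ)). The lower reduced chi-square
   (on a common noise scale) decides the morphology
   (`classify_morphology()`); rates r1, r2 (anisotropic) or r_x
   (isotropic) are extracted per aggregate (`extract_rates()`).
4. **Arrhenius analysis** — per-temperature mean ln-rates regressed on
   1/T (weighted by 1/SE²); Ea = −slope·R in kJ/mol (`fit_arrhenius()`).
5. **Instrument metrics** — imaging resolution as the FWHM of a Poisson
   maximum-likelihood 2-D Gaussian fitted to stacked single-emitter spots
   (`estimate_resolution()`), and the fluorophore bleaching lifetime from
   the multi-frame survival fraction, τ = −1/ln(s)
   (`estimate_lifetime()`).

A simulator (`simulate_aggregate()`, `simulate_rate_ensemble()`,
`simulate_spot_stack()`, `simulate_bleach_traces()`) generates
localization movies, rate ensembles, spot stacks and bleaching traces
with exact ground truth, so the full chain is testable without microscope
data. `run_pipeline()` orchestrates everything from localization tables
to an output directory with a reproducibility manifest; a thin CLI lives
at `inst/cli/replom.R`.

## Worked example

Fit and classify a synthetic anisotropic growth curve (3% area noise),
then recover an activation energy from a three-temperature rate ensemble:

```r
library(replom)

p <- growth_params(r1 = 0.01, r2 = 0.05, t0 = 400, t1 = 3000, tau = 500,
                   A0 = 0.03, kind = "A_lin")
set.seed(7)
t <- seq(0, 4000, by = 40)
A <- integrate_model(p, t) * (1 + rnorm(101, 0, 0.03))
curve <- growth_curve(data.frame(t = t, area_um2 = A), frame_interval = 40)
call <- classify_morphology(curve)
print(call)
#> morphology: anisotropic (model A_lin, margin 0.865)
extract_rates(call$fits$A_lin, call$morphology, temperature = 37)
#>   aggregate_id  morphology     phase       rate     rate_se  units temperature_C flagged
#> 1            1 anisotropic    linear 0.01038297 0.007271314 um^2/s            37   FALSE
#> 2            1 anisotropic branching 0.04997577 0.000410155 um^2/s            37   FALSE

spec <- arrhenius_sim_spec(Ea = 105, lnA = log(0.05) + 105e3 / (8.314 * 318.15),
                           temperatures = c(305.15, 310.15, 318.15),
                           n_per_temperature = c(11, 25, 18),
                           rate_scatter_cv = 0.3, seed = 1)
fit_arrhenius(simulate_rate_ensemble(spec))
#> arrhenius_fit: Ea = 104.0 +/- 5.0 kJ/mol, lnA = 36.34 +/- 1.90
```

The growth-curve fit recovers the generating rates (r1 = 0.0104 vs 0.01
um²/s for the linear core; r2 = 0.0500 vs 0.05 um²/s for the branching
phase), classifies the curve as anisotropic, and the Arrhenius fit
recovers the generating barrier (104 ± 5 vs 105 kJ/mol) from realistic
per-aggregate scatter (30% CV, 11–25 aggregates per temperature at
32/37/45 °C).

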