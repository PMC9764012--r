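# capkinetics

Kinetics of capillary blood-flow responses to acute local changes in oxygen
and carbon dioxide concentration.

## What this package is for

When the O₂ or CO₂ concentration at the surface of a skeletal muscle is
stepped (for example with a microfluidic gas-exchange chamber under the rat
EDL muscle on an intravital microscope), the capillary bed responds over
seconds to minutes: red blood cell (RBC) velocity, lineal density
(cells/mm), tube hematocrit, RBC supply rate (cells/s) and RBC oxygen
saturation (SO₂, %) all shift. This package is for microcirculation
researchers who want to quantify those dynamics: it simulates per-capillary
second-by-second hemodynamics with known ground truth, optionally renders
and re-analyzes dual-wavelength space–time images (kymographs), fits the
field's delayed-exponential response models under the standard constraints,
and computes baseline-referenced, Dunnett-adjusted onset and peak
statistics.

## The model at its core

Population-mean responses follow a delayed mono-exponential

    Y(t) = Yb + Y0 * (1 - exp(-(t - X0)/tau))   for t >= X0,   Y(t) = Yb before

where `Yb` is the baseline magnitude, `X0` the onset delay (s), `Y0` the
signed asymptotic amplitude, and `tau` the time constant — the time after
onset to reach 63% of the full response. Combined challenges (an O₂ step at
60 s, a CO₂ step at 120 s) superimpose two delayed components:

    Y(t) = Yb + Y1*(1 - exp(-(t - X1)/tau1))·[t>=X1] + Y2*(1 - exp(-(t - X2)/tau2))·[t>=X2]

Fits minimize squared error over the 51–180 s (or 51–240 s) window subject
to the delay constraint `X0 > 60` (the step time), via a delay-grid search
with profiled time constants and linearly solved amplitudes, finished by
bounded Levenberg–Marquardt. Statistical onsets compare every post-step
second to each capillary's 51–60 s baseline mean with paired differences
and a Dunnett max-|T| family adjustment.

## A worked example

Simulate the 7–2% O₂ challenge (a hypoxic step at t = 60 s) with a
40-capillary population under the study's reference conditions, fit every
measure's mean trace, and summarize onsets:

```r
library(capkinetics)

cfg <- validate_config(list(
  protocols = "O2_7to2", seed = 1, outdir = "capkinetics-run",
  population = list(n_capillaries = 40)))
res <- run_pipeline(cfg, quiet = TRUE)

res$fits[, c("challenge", "measure", "X0", "Y0", "tau", "r_squared")]
#>   challenge        measure    X0      Y0    tau r_squared
#> 1   O2_7to2       velocity 60.00 127.650 35.505    0.9932
#> 2   O2_7to2 lineal_density 65.00  13.432 26.607    0.9718
#> 3   O2_7to2     hematocrit 65.00   3.762 26.607    0.9718
#> 4   O2_7to2    supply_rate 62.65  11.884 34.479    0.9910
#> 5   O2_7to2            so2 62.24 -27.442  1.475    0.9993

res$onsets[, c("measure", "baseline_mean", "onset_time", "peak_time",
               "percent_change")]
#>          measure baseline_mean onset_time peak_time percent_change
#> 1       velocity        278.26         63       174          46.46
#> 2 lineal_density         53.86         69       174          26.93
#> 3     hematocrit         15.09         69       174          26.93
#> 4    supply_rate         15.84         67       174          76.55
#> 5            so2         69.90         63       160         -40.55
```

Reading the fit table: velocity responds with a ~128 µm/s amplitude and a
35.5 s time constant (slow vasomotor recruitment), while SO₂ drops by ~27
percentage points with a 1.5 s time constant — the near-instant imposed
change in tissue oxygen. The onset table shows velocity becoming
significantly elevated 3 s after the step and peaking 46% above baseline;
the generating population used the reference parameter set, so these
recovered values sit close to the published ones (τ = 35.54 s, 63 s first
significant velocity response).

Each run writes, per protocol: `ground_truth.csv` (+ JSON sidecar of
generating parameters and seeds), `fit_parameters.csv`, `onset_table.csv`,
`mean_<measure>.png` plots (mean ± SEM with the fitted curve), and a
`manifest.json`; identical config + seed reproduces every byte. Set
`mode: "sti"` to also render and re-analyze dual-wavelength TIFF kymograph
pairs via `render_sti()` / `analyze_sti_pair()`. A thin CLI lives at
`inst/scripts/capkin.R` (`Rscript capkin.R run --config run.yml`).

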