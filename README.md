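# crowdopt

Visual crowding — the inability to identify a peripheral target
surrounded by similar flankers — analysed as *optimal integration* of
target and contextual orientation signals, rather than as a hard-wired
processing bottleneck. `crowdopt` is an R package for researchers in
visual psychophysics and computational neuroscience who run (or model)
orientation-reproduction crowding experiments: a peripheral oval target
is flanked above and below by oval flankers, and the observer reproduces
the target orientation.

## What it computes

Writing θ for the flanker offset relative to the target, the analysis
decomposes total reproduction error into bias *B*(θ) and scatter *S*(θ),
with E = √(B² + S²), and confronts the measured curves with two
mechanistic accounts:

* **Ideal observer** — the response is the weighted combination
  wF₁ + wF₂ + (1−2w)T with the error-minimizing weight
  w = σ²_T / (2σ²_T + σ²_F + 2d²), so bias follows 2wd and
  integration shuts off quadratically as target and flankers diverge.
* **Causal inference** — the flanker pair is pooled into one compound
  cue and fused with the target with reliability weight
  σ²_T / (σ²_C + σ²_T), gated by the (Gaussian) probability that the
  two arise from one cause; the predicted bias is exactly a
  derivative-of-Gaussian (DoG) in θ.

Around those cores the package provides the standard pipeline: trial
tables as delimited text with a column-mapping dialect, the
response-time (0.5–3 s) and gross-error (35°) exclusion filters,
per-observer bias/scatter summaries averaged over the two targets,
reliability calibration from extreme offsets, regression-to-the-mean
estimation, joint DoG fits with the width yoked between bias and
scatter curves, α and β/γ model fits with R², the spacing analysis
(flanker weight vs. normalized target–flanker distance), the
1000-iteration bootstrap of the DoG centre that discriminates global
(joint-flanker, centre −15°) from local (independent-flanker, centre
0°) integration in the locked-flanker design, and a fully seeded
synthetic observer that generates trial tables under either hypothesis
(plus an independent-flanker and a null generator).

## Worked example

Simulate the main (yoked-flanker) experiment under the ideal-observer
hypothesis, then run the analysis stages:

```r
library(crowdopt)

spec   <- design_spec("yoked", n_trials_per_cell = 30, n_observers = 10,
                      seed = 1)
trials <- simulate_experiment(spec, generative_params("ideal_observer"))

flt <- filter_trials(trials)
flt$report
#> filter report: 22800 trials in, 3608 RT-removed (15.8%),
#>   1320 error-removed (6.9% of survivors), 17872 retained

summaries <- summarize_conditions(flt$trials)
rounded   <- summaries[summaries$target_aspect == 1.4, ]

fit_dog(rounded)
#> DoG fit: a = 0.2444, m = 0.32 deg, s = 28.16 deg, b = 0.103 deg (SSE 8.584)
#> scatter:  a = -5.983, m = -0.05 deg, b = 12.58 deg (shared s; SSE 3.639)

fit_alpha(rounded, sigma_t = 13.2, sigma_f = 10, rho = 0.665)
#> ideal-observer fit: alpha = 0.7039  (sigma_t = 13.20, sigma_f = 10.00, rho = 0.665)
#> R^2 bias = 0.950, R^2 scatter = 0.961
```

The filter report recovers the generator's artifact rates (15.9% RT
outliers; 6.9% gross errors among survivors). The DoG fit shows the
crowding signature: an assimilative S-shaped bias centred near 0° with
maximal slope ≈ 0.24 (the weight given to the flankers) and a scatter
dip sharing the same 28° width — precision is best exactly where
crowding is strongest. The α fit recovers the generative scaling 0.7,
i.e. the simulated observer weights flankers at 70% of the
error-minimizing weight after regression to the mean (ρ = 0.665).

`reproduce_targets()` recomputes the desk-scale published quantities
(maximal weights 0.78/0.53 for the two reliability conditions, their
regression-capped predictions 0.52/0.35, ρ = 0.67, the 984/16 = 61.5
bootstrap likelihood ratio, the 0.21 Bouma ratio) and reports pass/fail
per quantity. A thin command-line wrapper lives in `inst/cli/crowdopt`
(`simulate`, `analyze`, `reproduce-targets`).

## Documentation

The methods vignette
(`vignettes/crowding-optimal-integration.Rmd`) documents the models and
their assumptions, the calibration conventions, every numerical choice
in the fitting (multi-start bounds, the /s² width convention, shared-s
rationale), what the synthetic observer does and does not emulate, and
the package's known limitations — including the deliberate mismatch
between DoG-fitted slopes and the ideal-observer model's point slope on
model-generated data.
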