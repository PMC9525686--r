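---
title: "Crowding as optimal integration: models, fitting and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Crowding as optimal integration: models, fitting and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crowdopt)
```

## The problem

In peripheral vision, an oriented target flanked above and below by
similar oriented shapes is hard to identify — visual crowding. In an
orientation-reproduction paradigm crowding shows up as two measurable
effects as a function of the target–flanker orientation difference
$\theta$: an assimilative *bias* $B(\theta)$ (mean signed error pulled
toward the flankers, S-shaped in $\theta$, peaking around 15–20°) and a
change in *scatter* $S(\theta)$ (root variance of the errors, U-shaped,
minimal where target and flankers coincide). Total error combines the two
Pythagoreanly, $E = \sqrt{B^2 + S^2}$, and is *smallest* where crowding is
strongest — the signature of a system that trades a small bias for a
larger gain in precision.

`crowdopt` implements this analysis end to end: trial-table handling and
exclusion filters, condition summaries, two mechanistic models with
closed-form predictions, descriptive derivative-of-Gaussian (DoG) fits,
the bootstrap test that separates global (joint-flanker) from local
(independent-flanker) integration, and a seeded synthetic observer that
generates trial tables under each hypothesis so that every stage can be
validated without experimental data.

## The two models

**Ideal observer.** The response is a weighted combination
$R = wF_1 + wF_2 + (1-2w)T$ of internal representations of the target
($T$, scatter $\sigma_T$) and the two flankers (each $F_i$, scatter
$\sigma_F$). Minimizing expected squared error over $w$ gives

$$w_{opt} = \frac{\sigma_T^2}{2\sigma_T^2 + \sigma_F^2 + 2d^2},$$

where $d$ is the distance between the mean flanker orientation and the
target. Unreliable targets and reliable, similarly-oriented flankers
raise the weight; it vanishes quadratically as the orientations diverge
and never reaches 0.5. Bias is $2 w_{opt} d$; scatter is the root
variance of the combination. Two data-driven scalars complete the
response model: $\rho$, the regression-to-the-mean factor (responses
shrink toward the 45° stimulus-set mean; estimated from the mean
reproductions of the two targets as their reproduced separation over the
true 20°), and $\alpha$, a free scaling allowing sub-optimal weighting.

**Causal inference.** The flankers are first pooled into a compound cue
(variance $\sigma_F^2/2$), which is fused with the target with the
classical reliability weight
$w^{max} = \sigma_T^2/(\sigma_C^2 + \sigma_T^2)$, *gated* by the
probability that compound and target share a common cause — a Gaussian in
their separation with space constant set by the summed variances. The
bias is exactly a derivative-of-Gaussian in $\theta$; two free scalars
$\beta$ (amplitude) and $\gamma$ (width stretch, entering the gate as
$\gamma^2$) absorb sub-optimality. A Gaussian prior over the common
cause is supported (`common_cause_prob()`); the default is the
flat-prior limit. The same gating behaviour arises if similarity is
measured by the peak (or area) of the pointwise product of the two cue
densities (`gaussian_product_peak()`).

## Parameters and their calibration

| quantity | meaning | default / source |
|---|---|---|
| $\sigma_T$, $\sigma_F$ | representation scatter, degrees | 13.2 (rounded ovals) and 10.0 (elongated), from response scatter at extreme offsets ($|\theta| \ge 30°$), where the integration gate is shut (`estimate_reliability()`) |
| $\rho$ | regression to the mean | 0.665 from mean reproductions 50.5° and 37.2° of the 55°/35° targets (`regression_to_mean()`); reported to two decimals as 0.67 (half-up) |
| $\alpha$ | ideal-observer scaling | fitted; 0.7 is the reference value for rounded targets |
| $\beta$, $\gamma$ | causal-inference scalings | fitted; 0.71 / 1.51 reference values |
| DoG $a, m, s, b$ | maximal slope, centre, width, offset | fitted, `s` shared between bias and scatter curves |

Because $\sigma_T$ and $\sigma_F$ are calibrated *from response scatter*,
the package treats them as response-scale quantities throughout:
predicted scatter is not additionally scaled by $\alpha$ or $\rho$, and
the synthetic observer places its combination noise at response scale
(below). Scaling the whole estimate, as a literal reading of the
response equation would suggest, would shrink simulated scatter below the
very baseline used to calibrate it; we resolve that internal tension by
letting $\alpha$ (and $\rho$) scale the flanker-induced *bias* only.

## Data handling conventions

* **Filters.** Responses outside 0.5–3 s after stimulus offset are
  removed first; then gross reproduction errors (> 35°) among the
  survivors. Boundary values are retained (strict inequalities for
  removal). The sequential order makes the two reported fractions a
  partition: RT fraction of all trials, error fraction of RT survivors.
  Pooled and per-experiment fractions are both reported, since a pooled
  percentage across experiments is ambiguous otherwise.
* **Summaries.** Per observer, condition, offset and target: mean error
  and the standard deviation of the residuals (sample variance, $n-1$).
  Bias and scatter average these over observers with equal weight, then
  over the two targets with equal weight — which cancels the
  regression-to-the-mean constant $(1-\rho)(45-t)$. Cells with fewer
  than two trials contribute to bias only and are flagged.
* **Orientations are linear degrees.** All offsets are within ±45° of
  the target by design; no circular statistics are applied.
* **Locked-flanker data.** The offset axis is the variable flanker's
  offset; which physical flanker (top/bottom) was locked is recorded but
  ignored in grouping, as the design randomizes it.

## The synthetic observer

`simulate_experiment()` draws a full factorial design (offsets −45..45°
in 5° steps, targets 35°/55°, the two aspect-ratio conditions, four
spacings for the spacing experiment, a +15° locked flanker for the
locked design, a 22.5–67.5° target grid with orthogonal/absent flankers
for the control), shuffles trial order per observer under a seed with
per-observer sub-streams, and generates responses under one of four
hypotheses: `ideal_observer`, `causal_inference`,
`independent_flanker` (each flanker acts through its own
offset-dependent weight — in the locked design this predicts a curve
centred near 0° and raised by the locked flanker's constant pull,
whereas the pooled models predict a centre near −15°), and `null`.

Choices worth knowing:

* Weights are computed from the *true* stimulus offsets, not the noisy
  internal draws, so per-cell bias and scatter have closed forms and
  Monte-Carlo runs can be checked against them exactly. This is a
  simplification: a fully internal observer would jitter its weight from
  trial to trial.
* The deterministic response component is
  $\rho\,t + (1-\rho)45 + \alpha\rho \cdot 2wd$; the stochastic
  component realizes the combination variance
  ($w(\varepsilon_{F1}+\varepsilon_{F2}) + (1-2w)\varepsilon_T$) at
  response scale, for the calibration-consistency reason above. The null
  model therefore recovers $\sigma_T$ exactly in expectation.
* Artifacts emulate real sessions: log-normal response times
  (median 1.2 s) with a configurable fraction (default 15.9%) forced
  outside the 0.5–3 s window; gross errors (default 6.9% of the
  remainder) forced beyond the 35° criterion; optional uniform-response
  lapses on (0°, 90°).
* Flanker integration falls off with normalized target–flanker distance
  (spacing/eccentricity) through a configurable multiplier: 1 up to
  0.21 (the main geometry), a smooth drop to 0 at 0.40, a slight
  repulsive dip (−0.1) near 0.42, zero beyond 0.5 — the qualitative
  critical-spacing profile of crowding.
* Per-cell trial counts are not published for the study this emulates;
  the defaults (e.g. 8–17 trials per cell) were chosen once to land in
  the range of the published totals (≈10.7k/14.4k/16.6k trials per
  experiment) and are not tuned thereafter.

## Fitting: numerical choices

All nonlinear fits use multi-start Levenberg–Marquardt (`minpack.lm`)
with box bounds; centres start at −15°, 0°, +15° and widths at 15° and
30°; convergence tolerances are $10^{-15}$ on the objective and
parameters, and the best start by residual sum of squares wins. The DoG
exponent is $\exp(-(\theta-m)^2/s^2)$ — no factor 2 — so $s$ equals the
Gaussian SD times $\sqrt 2$; every width conversion in the package goes
through this one convention. The bias and scatter curves share $s$
(one integration process), all other parameters are per-curve, and the
bias centre $m$ and scatter centre are fitted separately. $R^2$ uses the
total sum of squares about each observed curve's own mean; the joint
$\beta/\gamma$ objective weights the bias and scatter SSEs equally (both
in squared degrees; configurable). $\alpha$ enters linearly and is
solved in closed form. Degenerate data (no flanker effect) leave
$\gamma$ unidentifiable; such fits are flagged rather than reported.

For the spacing analysis the DoG width is additionally constrained to
15–60°: beyond the critical spacing the bias curve is flat, and an
unconstrained width can collapse onto single-point noise, turning the
"weight" into an artifact. The crowding signature's width is set by the
summed cue variances (≈20–30° here), so the band is generous.

**A known and deliberate mismatch.** The ideal-observer bias curve is
not a DoG: it decays as $\theta/(c + 2\theta^2)$, keeping ≈60% of its
peak at $\theta = 45°$. A least-squares DoG over the ±45° grid therefore
reports a maximal slope of ≈0.22–0.25 for a curve whose true slope at
the origin is $\alpha\rho\,2w_{opt}(0) \approx 0.36$. The two numbers
measure different functionals of the same curve; on real data, whose
tails return to zero faster, the DoG slope and the model slope happen to
agree much more closely. When comparing descriptive weights with model
slopes, compare like with like (e.g. fit the DoG to the noiseless model
curve first). For the causal-inference model the DoG identity is exact:
$a = \beta\rho\,w^{max}$, $s = \gamma\sqrt{2(\sigma_C^2+\sigma_T^2)}$,
and `fit_dog()` on noiseless `ci_bias()` output recovers both to
optimizer precision. (The published widths "18.8 and 19.2" for the
parameter-free gate do not match this conversion, which gives 21.2 and
19.3; the discrepancy is documented rather than resolved, and $\gamma$
absorbs it in fitting.)

## The bootstrap model-comparison

`bootstrap_centres()` resamples trials with replacement within each
(observer, offset) cell — preserving the design balance; observer-level
resampling is a coarser alternative the user can emulate by subsetting —
then re-summarizes, refits the bias DoG with all parameters free, and
records the centre. Centres are classified by proximity to 0°
(independent-flanker prediction) versus −15° (joint-flanker prediction):
the midpoint rule counts $m > -7.5°$ toward zero, exact ties go to the
reference side, and the count ratio is the reported likelihood ratio.
Iterations whose fit fails are retried up to three times with fresh
resamples, then recorded as missing and excluded from the counts.

At realistic trial counts a *single* simulated dataset's centre estimate
has a standard deviation near 2°, so validation runs in this package
replicate the simulation (three independent datasets) and summarize the
bootstrap medians with their median; the bootstrap within one dataset
quantifies resampling noise, not dataset-draw noise, and the outer
replication covers the latter. The package's validation suite runs the
recovery checks at 10 observers × 30 trials/cell (yoked) and
13 observers × 17 trials/cell (locked design, 250 bootstrap iterations),
matching the per-condition scale of the emulated study.

## What the synthetic tests do and do not show

The generator reproduces the *structure* of real data — design balance,
regression to the mean, response-scale scatter levels, exclusion-rate
artifacts, the spacing fall-off — but its noise is Gaussian,
homoscedastic within cell, and independent across trials. It contains no
serial dependence between consecutive trials, no observer-level
heterogeneity in $\sigma$ or $\alpha$, no oblique-effect anisotropy, and
its weights do not jitter with the internal representations. Passing
recovery tests therefore shows the pipeline is correct and well
calibrated at realistic signal-to-noise, not that the models are true of
any particular dataset. Group-average fitting (no per-observer random
effects) mirrors the emulated analysis.

## Worked example

```{r example, eval = FALSE}
spec <- design_spec("yoked", n_trials_per_cell = 30, n_observers = 10,
                    seed = 1)
params <- generative_params("ideal_observer")   # alpha 0.7, rho 0.665
trials <- simulate_experiment(spec, params)

flt <- filter_trials(trials)
flt$report

summaries <- summarize_conditions(flt$trials)
rounded <- summaries[summaries$target_aspect == 1.4, ]

estimate_reliability(rounded)        # ~13.2 deg at extreme offsets
fit_dog(rounded)                     # descriptive DoG, yoked width
fit_alpha(rounded, sigma_t = 13.2, sigma_f = 10, rho = 0.665)
fit_beta_gamma(rounded, sigma_t = 13.2, sigma_f = 10, rho = 0.665)
```

The same stages are scriptable through `run_simulate()` /
`run_analyze()` with a YAML config, or the thin command-line wrapper in
`inst/cli/crowdopt`; `reproduce_targets()` recomputes the closed-form
published quantities (maximal weights 0.78/0.53, capped predictions
0.52/0.35, regression factor 0.67, likelihood ratio 61.5, Bouma ratio
0.21) from their printed inputs.
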