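---
title: "Methods: accumulated O2 deficit estimation and its estimators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: accumulated O2 deficit estimation and its estimators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(o2deficit)
library(dplyr)
```

## The accumulated O2 deficit principle

Anaerobic energy release during strenuous exercise cannot be measured
directly. The accumulated O2 deficit (AOD) principle estimates it
indirectly: the total rate of energy release ("O2 demand", expressed in
O2-equivalent units) is assumed to increase linearly with mechanical
power,

$$Y = a + bP,$$

with $Y$ the demand in mmol s$^{-1}$, $P$ the power in W, $a$ the
intercept (mmol s$^{-1}$) and $b$ the slope (µmol J$^{-1}$; numerically
$Y = a + bP/1000$). The relation is established at submaximal powers,
where steady-state O2 uptake equals the demand, and extrapolated to
supramaximal intensities. Over an exhausting bout of duration $t$ at
power $P$, the accumulated demand is $Y(P)\,t$; subtracting the
accumulated O2 uptake (the aerobic contribution) leaves the accumulated
O2 deficit, an O2-equivalent measure of anaerobic energy release,
conventionally normalised per kg body mass.

Everything internal to the package uses molar units (mmol s$^{-1}$, W,
µmol J$^{-1}$); the volumetric L$_{STPD}$ min$^{-1}$ convention appears
only at the reporting edge, through a fixed STPD molar volume of
22.4 L mol$^{-1}$ (22.393 is available as an argument for users who
prefer the real-gas value). The 22.4 default reproduces the standard
round-number conversions used in cohort summaries.

## Nine ways to establish the relation

`fit_demand_relations()` implements nine estimators that differ in which
measurements they regress on and whether the intercept is free or
forced:

* **M0** (reference): ordinary least squares on steady-state VO2 at
  8–10 min of repeated 10-min constant-power bouts, excluding low
  powers (below).
* **M1**: same bouts, but the 3–4-min window — cheaper, but the slow
  component has not fully developed, so slopes are biased low.
* **M2**: M1 data with the intercept forced to the cohort mean of the
  individual M1 intercepts.
* **M3**: OLS on a 4-min stepwise incremental protocol (one session,
  under an hour, combinable with lactate-threshold testing).
* **M4**: M0 data plus every low-power and loadless measurement —
  deliberately including the low-power non-linearity.
* **M5–M8**: a fixed intercept with the slope drawn through the mean of
  the `n_high_points` highest-power steady points. The intercept is the
  cohort mean of M0 intercepts (M5), zero (M6, "gross efficiency"),
  resting VO2 (M7) or loadless-pedaling VO2 at the session frequency
  (M8, both "net efficiency").

Two points where the estimators' definitions were genuinely open were
resolved as follows. The forced-intercept slope of M2 is a constrained
least-squares fit, $b = \sum P(y-a_0)/\sum P^2$ — an alternative reading
(re-anchoring the average point) is not used; with $a_0$ equal to the
free-fit intercept the constrained fit reproduces the free-fit slope
exactly, which the suite asserts. And M0 regresses on *all* steady
bouts at or above the low-power threshold, including those above the
lactate threshold, up to the highest power sustainable for 10 min;
restricting to below-threshold bouts is not supported because the
reference protocol is defined by bout duration, not lactate state.
For M5 the common intercept is the mean of the M0 intercepts and for M2
the mean of the M1 intercepts, so each forced-intercept method inherits
the intercept of the window it shares data with. Ties at the top power
are averaged before the high-power anchor is formed, and `n_high_points`
defaults to 1 with 2–3 recommended as a safeguard against occasional
poor measurements.

### Inclusion rules

Below roughly 75 W at 1.5 Hz pedaling (about 1 W kg$^{-1}$) the measured
VO2 exceeds the linear extrapolation from higher powers — repeated limb
accelerations and compensatory upper-body work cost oxygen that does no
ergometer work. At 0.75 Hz the effect is weaker and the limit is 30 W.
Powers *exactly at* the threshold are kept (the exclusion is of powers
below it); `fit_config(boundary = "drop")` flips this. Thresholds are
resolved by nearest configured frequency and relations are never pooled
across frequencies, because the intercept itself varies (cubically) with
pedaling frequency.

The lactate threshold is the power at which blood lactate first reaches
4.0 mmol L$^{-1}$, linearly interpolated between bracketing
measurements. A subject whose lactate never reaches the criterion has
all bouts classified below threshold; a measurement is "at or above
threshold" when its bout power is at or above the interpolated threshold
power.

## Exercise models and the AOD computation

Supramaximal exercise is modelled as constant intensity to exhaustion on
a five-row canonical grid: 100/120/150/200/250% of the VO2max-equivalent
demand, times to exhaustion 217/120/60/30/10 s, and aerobic fractions
0.75/0.63/0.47/0.30/0.10 of total energy release (from pooled
exhaustion-trial data). `exercise_models()` recomputes each row's demand
(fraction × cohort mean VO2max) and power (inverting the reference
relation); `reference_exercise_models()` returns the grid with the
demand and power columns as printed for the original 13-subject
reference cohort, which is what a worked-example reproduction should
feed the engine (`exercise_model_source = "reference"` in the pipeline).
Aerobic fractions at non-canonical times interpolate piecewise-linearly
in log(time), clamped at the endpoints — only the five canonical rows
are used in any reported comparison.

For every method the accumulated *uptake* is anchored to the reference
total, $u = f_{aer}\, Y_{ref}\, t$: all methods are assumed to share the
same power, time to exhaustion and accumulated uptake, so they differ
only through the demand relation being tested. Anchoring uptake to each
test method's own demand would let a method's error cancel out of its
own comparison. For the reference method's own rows the engine exposes
both demand paths — the model's reference demand or the method's
relation evaluated at the model power (`reference_demand_source`); on an
unrounded relation the two coincide exactly, and the suite asserts this.
A negative deficit is flagged, not raised: it is a diagnostic of a
demand relation that extrapolates below the assumed uptake.

Per-kg normalisation uses the individual mass for per-subject results
and the cohort mean mass for cohort-mean results. The 13-subject
reference cohort's mean mass is never printed in the original summary
tables; it is reconstructed from the group means (3 women at 74 kg, 10
men at 82 kg → 80.15 kg) and remains overridable (`body_mass` in
`run_config()`).

Method comparison (`compare_methods()`) reports, per method and exercise
model, per-subject residuals against the reference, their mean bias,
between-subject SD, and a one-sample matched-pair t-test against zero
(implemented from its closed form and cross-checked against
`stats::t.test` in the suite). A Bonferroni option adjusts across the
eight method contrasts; omnibus two-way ANOVA with a many-to-one
post-hoc is deliberately out of scope — the paired contrasts against the
reference are the quantity of interest.

## The synthetic-cohort generator

No subject-level raw data are available for this class of study, so the
generator is a first-class module: it emulates the *measurement
structure* the estimators face, with known ground truth, making every
estimator property testable.

Per subject, the noise-free model is

$$\text{steady}(P) = a + bP + e(f)\,\max(0, 1 - P/P_{nl}(f))^2,
\qquad e(f) = \text{rest} + k f^3 - a,$$

with the 3–4-min window value $\text{steady}/(1+d)$, where $d$ is 1.8%
below and 4.9% at-or-above the subject's lactate-threshold power, and a
+0.015 mmol s$^{-1}$ offset on the stepwise protocol's 4-min values at
1.5 Hz (zero at 0.75 Hz). Design choices worth making explicit:

* **Low-power excess shape.** Only the existence of a non-linear excess
  below $P_{nl}$ (75 W at 1.5 Hz, 30 W at 0.75 Hz) is established, not
  its shape; the quadratic decay is the smoothest sign-definite choice
  vanishing with zero slope at the threshold, which makes estimators
  restricted to $P \ge P_{nl}$ exactly unbiased while M4 shows the
  raised-intercept/lowered-slope signature.
* **Loadless anchoring.** Loadless VO2 follows the cubic law
  $\text{rest} + k f^3$ (defaults 0.26 + 0.1185 f³ mmol s$^{-1}$, so
  0.66 at 1.5 Hz), and the loaded curve is continuous with it at
  $P = 0$. The excess amplitude is therefore *derived* as
  $e(f) = \text{loadless}(f) - a$ (≈0.16 at 1.5 Hz with default means)
  rather than drawn independently — anchoring to the measured loadless
  and resting levels was preferred over an independently specified
  excess, which cannot be consistent with both. Disabling
  `low_power_excess` removes the whole non-linearity, collapsing
  loadless pedaling onto the line (this is what makes the noiseless
  identifiability test exact for M4, not just M0). The $f^3$ scaling of
  the excess across frequencies is a generator convention, not an
  established magnitude.
* **Multiplicative drift.** The slow component is applied as a fraction
  of the steady value (the primary way it is reported); absolute
  increases of the right order (~0.03–0.11 mmol s$^{-1}$) then emerge at
  realistic VO2 levels. A side effect is that the 4-min relation's
  intercept sits slightly *above* the truth (the deflation is larger at
  high powers, pivoting the fitted line), while its slope is biased low
  — the documented short-bout signature.
* **Lactate curve.** A logistic in power centred at the subject's
  threshold power (scale 20 W), crossing 4.0 mmol L$^{-1}$ exactly at
  the centre and saturating near 7 mmol L$^{-1}$; only the crossing
  matters downstream.
* **Noise.** Gaussian, SD 0.03 mmol s$^{-1}$, independent per
  measurement window — chosen so the standard error of a pooled drift
  estimate at n ≈ 150 paired windows is of order ±0.005 mmol s$^{-1}$,
  matching the precision such studies report.
* **Population.** 13 subjects (3 women), intercept 0.50 ± 0.05, slope
  8.8 ± 0.8, VO2max 2.9 ± 0.6, resting 0.26 ± 0.03 (mmol s$^{-1}$ /
  µmol J$^{-1}$), truncated at physiological floors; bout powers span
  30–95% of the VO2max-equivalent power in ≤22 W steps, step protocols
  rise 22 W (men) or 11 W (women) every 4 min from 40 W. Rare extreme
  draws (VO2max near the 1.2 mmol s$^{-1}$ floor) can leave fewer than
  two usable points above the low-power threshold; such fits are
  skipped with a warning, as a real analysis would drop such a subject.

What the generator does *not* emulate: breath-by-breath VO2 kinetics
(mono-exponential on-transients), day-to-day drift, heart-rate dynamics
beyond a placeholder, or inter-site equipment effects. Passing tests
therefore demonstrate estimator properties under clean steady-state
sampling with the stated phenomena, not robustness to every feature of
real gas-exchange data.

## Reproducibility and numerical choices

Fits use `stats::lm`; the suite checks them against an independent
normal-equations solver and a brute-force grid minimiser to 1e-10.
Cohorts are deterministic functions of (config, master seed) — the
subject draw and the measurement noise use two derived seeds — and the
pipeline runners stamp every output with the package version, a config
hash and the seed, so identical configs give bit-identical files.

Problem sizes used by the suite: single cohorts of 13 subjects for
directional checks, and 200 replicate cohorts (one frequency) for the
parameter-recovery check of the reference estimator, which bounds the
mean coefficient bias at 1%. Reproducing the published worked example
feeds the printed coefficient and model tables through the engine;
because those inputs are rounded to 2 decimals (and the printed summary
averaged per-subject values computed from unrounded coefficients), the
short-duration AOD columns reproduce within ±0.02 mmol kg$^{-1}$ while
the 2-min and 3.6-min columns can deviate by up to ~0.07 — a rounding
artefact of the inputs, not an engine property, which exact agreement of
the two demand paths on unrounded relations confirms.

## Known limitations

* The linearity assumption itself is taken as given; non-linear demand
  extrapolation is deliberately unsupported (numerically non-robust for
  extrapolation, which is the whole game here).
* Times to exhaustion and aerobic fractions are inputs from prior
  pooled data, not estimated; the 217-s row at 100% intensity is known
  to conflict with laboratory experience and is retained only because
  all methods share it, so comparisons are unaffected.
* Douglas-bag gas arithmetic, VO2max protocols and heart-rate analyses
  are upstream of this package: VO2 and VO2max arrive as data.
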