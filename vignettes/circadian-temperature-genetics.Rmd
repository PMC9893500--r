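---
title: "Circadian temperature phenotypes and their genetics: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian temperature phenotypes and their genetics: models, choices, limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(circatherm)
```

This vignette is the package's own account of the science it implements:
the models, the tunable parameters and why their defaults are what they
are, what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limits. Nothing here states an empirical
result that the test suite or `scripts/acceptance.R` does not itself
compute.

## The measurement problem

A reticulo-rumen bolus or rectal logger samples core temperature every
5 minutes. The series is a daily rhythm (cattle body temperature
oscillates on a 24-h cycle) overlaid with three kinds of corruption:
out-of-range sensor glitches, drinking bouts (cold water transiently cools
the reticulo-rumen by 0.5–2 °C with a recovery over tens of minutes), and
missing stretches. The analysis phenotypes are the parameters of the daily
rhythm, so cleaning must remove corruption without touching the rhythm
itself.

### Range filter

Values below 32 °C or above 42 °C are physiologically impossible for
cattle core temperature and are flagged `out_of_range`. The bounds are
inclusive: exactly 32.0 or 42.0 is retained, because the rule targets
values *below* and *above* the limits. The filter is idempotent and never
edits a retained value.

### Drinking-bout screen

"Autoregressive order 4 with adaptive filtering" describes a family of
screens rather than one algorithm, so the implementation is documented
precisely here:

* AR(4) coefficients and a local mean are refitted every 24 h (288
  samples) on the reconstructed series; the noise scale is the MAD of
  one-step residuals of the *raw* window. Computing the scale from the
  reconstruction would let it collapse after imputation and send the
  screen into a runaway (everything flagged) — this failure mode is real
  and is why the scale source is fixed to raw data.
* Predictions are recursive: a flagged sample is replaced by its
  prediction before predicting the next one, so an entire excursion is
  judged against the clean baseline rather than its own depressed tail.
* Entry threshold: residual below −`z_threshold` robust SDs (default 3).
  Exit: hysteresis at −1 robust SD with a one-sample debounce (one
  isolated upcrossing does not end an excursion). Runs are force-closed
  after 6 h so a genuine baseline shift cannot be swallowed.
* On entry, the few samples immediately before the trigger that already
  sit below the entry-time baseline are back-flagged: a slow slide into a
  bout is tracked, not jumped over, by a one-step predictor.
* The first day is additionally screened in reverse time: a bout in the
  first few samples has no forward history, but its recovery ramp is a
  detectable excursion backwards.
* Only negative residuals are flagged. Drinking cools the rumen; a
  positive spike is left alone by design.

Flagged samples are either excluded (`action = "drop"`, the default) or
replaced by their prediction and flagged `imputed`. Both modes are
provided because vendor-side preprocessing pipelines differ on this point
and neither choice is recoverable from a cleaned export.

On synthetic streams with known corruption the screen recovers roughly
85–93% of artifact-affected samples at the default threshold with
single-digit false-positive percentages (the test suite computes these on
seeded 4-day streams with 5 bouts/day).

### Completeness

Streams with less than 80% of the expected samples are excluded. The rule
is a plain fraction with an inclusive pass at exactly 0.80; at 288
samples/day, 230 retained samples (79.9%) fail and 231 (80.2%) pass.

## Cosinor phenotypes

Each animal-day is fitted with
$y(t) = k + \alpha\,\cos(2\pi (t-\varphi)/24) + e(t)$:
MESOR $k$ (°C), amplitude $\alpha \ge 0$ (°C), acrophase $\varphi$ (clock
hours of the peak, anchored to local midnight). The period is fixed at
exactly 24 h; no period estimation is attempted. The fit is the exact
linear reparameterization $y = k + b_1\cos\omega t + b_2\sin\omega t$ with
$\alpha = \sqrt{b_1^2+b_2^2}$, $\varphi = \mathrm{atan2}(b_2, b_1)$; for a
single fixed-period component this *is* the nonlinear least-squares
solution, which the tests confirm against both a grid search over the
phase and an iterative nonlinear minimizer started from multiple phases.

Rhythmicity is the 2-df F-test of $b_1 = b_2 = 0$. Days with p > 0.05 are
excluded from summaries; the inequality is strict, so a day at exactly
0.05 is kept. A constant series carries no rhythm evidence and is reported
with $\alpha = 0$, p = 1 rather than a 0/0 F statistic. Fits use actual
timestamps, so gaps and irregular spacing need no resampling.

Per-regime summaries average $k$ and $\alpha$ arithmetically over valid
days and average peak time *circularly* (23.5 h and 0.5 h average to
0.0 h, not 12.0 h). Whether the original analyses averaged acrophase
linearly or circularly is not documented anywhere we could find; circular
is the defensible choice and is what the package does. MESOR classes
(high/medium/low) use the half-SD rule within each regime-device stratum
with boundary values assigned to the middle class.

## Efficiency indices

ADG is the OLS slope of serial weights on day. Metabolic weight is
mid-test BW^0.75, with mid-test BW defined as the regression-line
prediction at the test midpoint — the raw mid-test weighing would inject
one day's gut-fill noise into every index, and the source analyses do not
say which convention they used. Intake is standardized to
MEI = DMI × dietME / 10 (MJ ME/kg DM), with diet ME from TDN via
ME = (TDN%/100) × 4.409 Mcal/kg × 4.184 MJ/Mcal × 0.82. The intake model's
response is the standardized MEI by default (a raw-DMI mode exists behind
`response = "dmi"`); fits are within year-regime groups, residuals are
standardized within group, and RIG = −RFI_s + RBG_s. Efficiency classes
use the half-SD rule with direction of merit: low RFI is efficient, high
RBG/RIG is efficient, boundaries are neutral.

## The animal model

The two regimes are treated as two traits of the same animal:

$$ y_t = X_t b_t + Z u_t + e_t, \quad t \in \{\mathrm{FW}, \mathrm{WS}\} $$

with $u \sim N(0,\, G_0 \otimes A)$ over all pedigree animals and residual
pairs correlated within animal, $e \sim N(0,\, R_0 \otimes I)$. Fixed
effects per trait are whatever the supplied formula encodes — in the
emulated design, pen and year plus the initial-weight covariate; regime is
the trait dimension, not a fixed effect. The first level of each factor is
dropped. A univariate repeated-measures alternative (records stacked,
regime as a fixed effect, pure R) is provided for comparison via
`gibbs_univariate()`; with no pedigree it collapses to the conjugate
normal–inverse-gamma model whose closed-form posterior the tests check.

A is built by the tabular method and its inverse by Henderson's rules with
inbreeding; the tests verify A against an independent path-counting
oracle and A·A⁻¹ = I.

### Sampler

The Gibbs sampler is compiled (RcppArmadillo) and draws, per iteration:
the fixed-effect block from its matrix-normal full conditional; each
animal's $(u_{FW}, u_{WS})$ pair from its bivariate normal full
conditional (single-site, using A⁻¹); then $G_0$ and $R_0$ from
inverse-Wishart full conditionals via Bartlett decompositions. All
randomness comes from R's RNG, so `set.seed()` reproduces chains exactly.
Non-PD scale matrices are jittered on the diagonal before factorization;
a non-finite draw aborts with the iteration index. A chain of `n_iter`
iterations with burn-in `b` and thinning `h` stores
`floor((n_iter − b)/h)` draws — the full production geometry (10⁶
iterations, 10⁵ burn-in, thinning 250) stores exactly 3,600. The package
default is a desk-scale 20,000/2,000/10.

### Priors matter at this cohort size — deliberately documented

Defaults are inverse-Wishart with identity scale and df = 3 for both
$G_0$ and $R_0$. With ~160 phenotyped steers in ~40 paternal half-sib
families of 3–4, the likelihood localizes the *sum* of variances well but
the additive share poorly: single-cohort REML estimates of h² scatter over
most of [0, 1] when the generating value is 0.5. Two consequences,
verified computationally in this package's test suite:

* Under the identity-scale default the posterior is regularized away from
  the [0, 1] boundary; across 20 simulated cohorts (truth h² = 0.5 per
  regime, r_g = 0.7, unit trait variances) the 95% HPD intervals cover
  the truth in ≥ 90% of replicates for both heritabilities and the
  genetic correlation.
* Under a near-flat prior (scale 0.01·I) the data dominate: when the
  generating G₀ is zero, the posterior h² concentrates near zero (upper
  95% HPD bound well under 0.2), which is the right behaviour for a
  does-the-data-support-any-heritability question. But near-flat priors
  also let single-cohort posteriors sit hard against a boundary far from
  the generating value, so fixed-truth interval coverage degrades.

Neither prior is "correct"; at this design size the posterior is
genuinely prior-sensitive, and any serious analysis should report a
sensitivity check across prior scales (both are one argument away in
`chain_config()`). The same caveat applies to published estimates from
cohorts of this size.

Posterior summaries report, per draw, $h^2_t = \sigma^2_{a,t} /
(\sigma^2_{a,t} + \sigma^2_{e,t})$, $r_g = \sigma_{a,12} /
\sqrt{\sigma^2_{a,1}\sigma^2_{a,2}}$ and $r_p$ from summed
(co)variances, then posterior mean, PSD, and the shortest interval
containing 95% of draws (verified against an exhaustive window search).

## The synthetic trial

The generator reproduces the *statistical structure* the analysis
assumes, at the emulated study's scale:

* **Design**: 2 years × 80 steers, FW (85 calendar days) and WS (78)
  regimes, two pens; 24 sires/year with 8 shared across years; one dam
  per steer per year with 19 shared (≈140 unique dams).
* **Genetics**: additive values drawn so cov(a) = A ⊗ G₀ via Cholesky
  factors; default G₀/R₀ are anchored to a rumen-MESOR-like trait
  (additive variances 0.013/0.007 °C², genetic correlation ≈ 0.69,
  heritabilities ≈ 0.78/0.50). Recovery experiments use unit trait
  variances instead — the natural standardized scale for a calibration
  study, and the scale on which the default prior is weakly informative.
* **Telemetry**: cosine rhythm around a day-specific MESOR that wanders
  as a stationary AR(1) (ρ = 0.7, innovation SD 0.03 °C) about the animal
  mean — day-to-day variance of circadian parameters is not documented
  for this kind of trial, so these are stated choices, not estimates.
  Ambient coupling is −0.011 °C body per °C ambient anomaly (sized so the
  FW−WS MESOR contrast matches the ≈0.12 °C observed across a ≈11 °C
  seasonal contrast); measurement noise SD 0.05 °C; drinking bouts at 6
  events/day with instantaneous 0.5–2.0 °C drops and 20-min recovery
  half-life; 0.2% of samples replaced by out-of-range glitches; whole
  days lost with probability 0.08 (which, over an 85-day FW window,
  leaves ≈78 analyzable days). The truth channel marks a sample as
  artifact-affected when the bout displaces it by more than twice the
  noise SD.
* **Performance**: biweekly weights on a linear trajectory with 4 kg
  weighing noise; intake = 0.5 + 2.2·ADG + 0.09·MWT + 0.05·ΔBF + RFI
  with a 0.5 kg/d true-RFI SD. Because RFI is cohort-defined, the truth
  channel stores the intake deviation *orthogonalized within the cohort*
  against the true regressors; this is what an ideal index would recover.
* **Weather**: dry-bulb as a seasonal sinusoid (coldest mid-January)
  plus daily noise, parameterized so typical prairie FW and WS windows
  average ≈ −11.7 °C / 82% RH and ≈ −0.8 °C / 73% RH.

What it does **not** emulate: drinking physiology or rumen fermentation
(bouts are phenomenological dips), diurnal feeding-time structure in
intake, heteroscedastic or drifting sensor error, culling/re-testing
dynamics, genotype-by-regime interaction beyond what G₀ encodes, and
maternal or pen environmental effects on the phenotypes. Passing tests
therefore demonstrate correctness of the estimation machinery under the
stated generative model — not that real telemetry is this well-behaved.

## Other numerical and design choices

* **TDN→ME conversion** uses 4.409 Mcal DE per kg TDN (the value that
  reproduces the published two-decimal ME figures); the frequently
  quoted rounded constant 4.4 is available via an argument.
* **THI** uses the NRC-style dry-bulb/RH formula
  THI = (1.8T+32) − (0.55 − 0.0055·RH)(1.8T−26); the exact published
  variant used by any given study is often unrecoverable, so the formula
  is a documented, swappable choice.
* **Telemetry reading** never silently drops data: malformed rows and
  duplicate timestamps become error records; the first duplicate wins.
* **LS-means** are computed by balanced reference-grid averaging over an
  additive fixed-effects model (and cross-checked against emmeans in the
  tests). Random-animal mixed models for class comparisons are out of
  scope; the package's class tables are descriptive adjusted means.
* **Partial correlation** is within-animal centering of both daily
  series (equivalently residual-on-residual regression), with the t-test
  df reduced by the number of animal means removed.
* **Between-regime correlations** pair each animal's FW value with its
  WS value; pooling across years is the default, matching the emulated
  analysis; year-centering is a one-liner upstream if wanted.

## Problem sizes

The test suite and acceptance checks run at deliberate desk scale: 50
noisy days for the cosinor-oracle equivalence, 1,000 null days for the
type-I error of the rhythmicity test, cohorts of 80 for the RFI
contracts, pedigrees up to 12 animals for the path-counting oracle, and
20 replicate cohorts of 160 steers with 20,000-iteration chains for the
genetic-parameter coverage experiment. These sizes were chosen so the
whole suite completes in minutes while leaving each check statistically
meaningful; the production chain geometry is available through
`chain_config()` when real inference is at stake.

## Known limitations

* Single-component cosinor only: ultradian components and
  population-mean cosinor with covariates are out of scope.
* The artifact screen is tuned for dip-like artifacts against a slowly
  varying baseline; step changes in sensor calibration will be partially
  flagged and partially absorbed.
* The bivariate sampler requires complete two-regime records per
  phenotyped animal (the emulated design measures every steer in both
  regimes; device-subset analyses just use the instrumented subset).
* Only pedigree relationships are supported — no genomic relationship
  matrices, no REML, no more-than-two-trait models.
* At ~160 records the genetic-parameter posterior is prior-sensitive;
  see the priors section above.
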