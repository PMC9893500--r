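# circatherm

Circadian core-body-temperature phenotypes, production-efficiency indices,
and their genetic parameters for beef cattle tested across winter feeding
regimes.

Rumen boluses and rectal loggers record a steer's core temperature every
5 minutes for months at a time. `circatherm` turns those streams into
quantitative phenotypes and asks the questions a breeder would ask of them:
are the daily rhythm parameters heritable, are they the same trait in a
Fall-Winter (FW) and a Winter-Spring (WS) feeding regime, and do they
predict which animals convert feed efficiently? It is aimed at animal
scientists and quantitative geneticists working with telemetric temperature
data from performance-tested cattle, and at anyone who needs a tested,
end-to-end reference pipeline for this kind of analysis.

## What it computes

**Circadian phenotypes.** Each animal-day of cleaned telemetry is fitted
with a single-component 24-h cosinor

    y(t) = k + α · cos( 2π (t − φ) / 24 ) + e(t)

where *k* is the MESOR (rhythm-adjusted mean, °C), *α* ≥ 0 the amplitude
(half the peak-to-trough range, °C) and *φ* the acrophase (clock time of
the daily peak, h). The fit uses the exact linear reparameterization
`y ~ cos(ωt) + sin(ωt)`, which is algebraically identical to the nonlinear
least-squares problem for a fixed period. Rhythmicity is the 2-df F-test of
zero amplitude; days with p > 0.05 are excluded. Cleaning applies the
physiological range filter (retain 32–42 °C), an AR(4) rolling screen for
drinking-bout artifacts (negative excursions only), and an 80%
completeness rule.

**Efficiency indices.** From serial weights and intake records it derives
ADG (OLS slope of weight on day), metabolic mid-test weight (BW^0.75),
energy-standardized intake (MEI = DMI × diet ME / 10, with diet ME from
TDN), and the residual indices

    MEI_j = β0 + β1 ADG_j + β2 MWT_j + β3 ΔBF_j + RFI_j
    ADG_j = β4 + β5 MEI_j + β6 MWT_j + β7 ΔBF_j + RBG_j
    RIG_j = −RFI_s,j + RBG_s,j

with half-SD classification into efficient / neutral / inefficient.

**Genetic parameters.** A Bayesian bivariate animal model treats the FW and
WS expressions of a phenotype as two traits: y_t = X_t b_t + Z u_t + e_t,
u ~ N(0, G0 ⊗ A) over the pedigree (A from the tabular method), residual
pairs correlated within animal, e ~ N(0, R0 ⊗ I). A compiled Gibbs sampler
(matrix-normal block for fixed effects, single-site bivariate updates per
animal, inverse-Wishart draws for G0 and R0) yields posterior means, PSDs
and shortest 95% HPD intervals for h² per regime, genetic variances, and
the genetic (r_g) and phenotypic (r_p) correlations between regimes.

**Synthetic trial.** Because raw trial data of this kind are rarely public,
a first-class generator simulates the whole study design — a multi-sire
pedigree (24 sires/year, one-third shared across two years), genetically
structured FW/WS phenotypes with configurable G0/R0, 5-min telemetry with
drinking-bout dips, sensor glitches and day dropout, biweekly weighings,
intake with a true-RFI channel, and winter weather — with every corruption
logged in a truth channel so the cleaning and estimation stages can be
scored against known ground truth.

## Worked example

Simulate a week of rumen telemetry for one steer, clean it, and fit daily
cosinors:

```r
library(circatherm)
cfg   <- simulation_config(seed = 11)
sim   <- simulate_temperature_series("steer_042", mesor = 39.8,
                                     amplitude = 0.25, acrophase = 16,
                                     days = 7, config = cfg, seed = 11)
clean <- remove_drinking_artifacts(filter_physiological_range(sim))
daily <- fit_cosinor_daily(clean)
summarize_regime(daily)
#>   animal_id device regime mean_mesor mean_amplitude mean_peak_time n_valid_days
#> 1 steer_042  rumen     FW      39.75         0.2384          16.09            7
```

The generating values (MESOR 39.8 °C, amplitude 0.25 °C, peak 16 h) are
recovered from data carrying ~6 drinking dips per day, sensor glitches and
measurement noise; every fitted day passed the rhythmicity screen.

Efficiency indices for a simulated cohort of 80 steers on the high-forage
diet (TDN 57.27% DM, so ME = 8.66 MJ/kg DM):

```r
set.seed(11)
n    <- 80
perf <- simulate_performance(sprintf("A%03d", 1:n),
                             adg_true = rnorm(n, 0.85, 0.15),
                             start_wt = rnorm(n, 262, 16), seed = 11)
eff  <- efficiency_traits(perf$performance, perf$weights,
                          diet_me = me_from_tdn(57.27))
head(eff[, c("animal_id", "adg", "mei", "rfi", "rbg", "rig", "rfi_class")], 4)
#>   animal_id   adg  mei    rfi     rbg    rig   rfi_class
#> 1      A001 0.708 7.54  0.144 -0.1001 -1.171     neutral
#> 2      A002 0.894 8.50  0.593 -0.0332 -1.617 inefficient
#> 3      A003 0.674 6.69 -0.420 -0.0384  0.622   efficient
#> 4      A004 0.627 7.49  0.445 -0.1760 -2.493 inefficient
table(eff$rfi_class)
#> inefficient     neutral   efficient
#>          26          31          23
```

RFI is in kg DM/d of reference-diet equivalents (negative = eats less than
predicted for its gain, size and fatness change = efficient); RIG is in SD
units, higher = better. Class proportions track the expected ≈31/38/31%
split of a half-SD rule.

For a genetic analysis, `simulate_pedigree()` + `simulate_genetic_values()`
produce a cohort with known h² and r_g, and
`gibbs_bivariate()` / `summarize_posterior()` estimate them; see the
methods vignette (`vignettes/circadian-temperature-genetics.Rmd`) for the
model, priors and their consequences at realistic cohort sizes.

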