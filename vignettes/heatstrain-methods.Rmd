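---
title: "Heat stress, maternal heat strain and fetal strain: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heat stress, maternal heat strain and fetal strain: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heatstrain)
```

## The problem

Pregnant agricultural workers in hot climates routinely work through
conditions that exceed occupational heat-exposure limits. The chain of
interest runs from *heat stress* (the environmental thermal load), through
*maternal heat strain* (the physiological response: rising heart rate, skin
and core temperature), to acute *fetal strain* (surrogate markers of
compromised utero-placental circulation: fetal heart rate excursions and a
rise in umbilical artery resistance). This package implements that analysis
chain end to end — exposure indices, strain scoring, fetal classification
and the total/direct-effect regression models — together with a seeded
synthetic cohort generator so that every stage is testable without access to
field data.

## Thermal exposure indices

**WBGT.** Outdoors, the wet bulb globe temperature is the fixed convex
combination `0.7 Tnwb + 0.2 Tg + 0.1 Ta` of the natural wet-bulb, black
globe and air temperatures. Occupational risk categories 1–5 use configurable
band edges (defaults 23, 25, 28, 30 °C); the five-band scale has no single
universal standard, so the edges are data, not constants. The binary
occupational heat-stress flag uses WBGT > 24.8 °C. Categories are assigned on
the shift **peak** by default (occupational limits address worst exposure),
with a mean-based option.

**UTCI.** The universal thermal climate index is computed with the
operational sixth-order polynomial approximation to the underlying
thermophysiological model: a function of air temperature, wind speed at 10 m,
the mean-radiant-temperature elevation, and water vapour pressure. Mean
radiant temperature is recovered from the globe thermometer with the standard
forced-convection formula (150 mm globe, emissivity 0.95); vapour pressure
comes from relative humidity via the Magnus formula (Alduchov–Eskridge
coefficients, within 0.05 kPa of the Hardy reference over the warm range);
instrument-height wind is scaled to the 10 m reference with a neutral
log-profile factor of 1.49 (hand-held anemometer at ~1.5 m over short
grass). Inputs outside the polynomial's published validity envelope — field
wind speeds below 0.5 m/s are common — are clamped with a warning rather
than rejected. The ten-class assessment scale labels follow the standard
bands, with *extreme heat stress* strictly above 46 °C.

## Maternal heat strain

The physiological strain index is used in its skin-temperature form, scoring
strain 0–10 from the normalised elevation of chest skin temperature over the
baseline tympanic temperature (ceiling 39.5 °C) and of heart rate over rest
(ceiling 180 bpm):

$$\mathrm{PSI} = 5\,\frac{T_{skt}-T_{tymp0}}{39.5-T_{tymp0}}
             + 5\,\frac{HR_t-HR_0}{180-HR_0}.$$

Design choices worth stating: tympanic baselines take the **maximum** of
duplicate readings from both membranes (infrared tympanic thermometry
under-reads with poor placement); PSI is **not clamped** — negative values
(skin below the tympanic baseline, common early in a shift) and values above
10 are preserved and flagged, because the downstream models use PSI as a
continuous exposure. Whether a core-temperature ceiling of 39.5 °C is
appropriate for a skin-temperature numerator is a known ambiguity of the
modified index; it is implemented as defined.

Energy expenditure is estimated two ways: a wearable calibration equation on
heart-rate features (`5·HRaS + 0.23·HRaS·HRaS₃ + 2.2·HRaS₃ + 9.2·ln RMSSD −
2.6·SHR − 82`, natural log, floored at zero with the raw value kept), and a
time-weighted METs average from observed tasks matched to a task→MET lookup.
The five equation coefficients live in a single table
(`paee_coefficients`) so a corrected reading is a data change. The wearable
estimate is accepted when it falls in the inclusive 2–15 MET range,
otherwise the observational estimate is used and the provenance recorded.
The shipped task→MET table is an explicitly synthetic stand-in with values
in published ranges for moderate manual work. PAEE feeds no downstream
model, which bounds the impact of its unit ambiguities.

## Fetal assessment

The umbilical artery resistance index is `(S − D)/S` from Doppler
velocities, combined over quality-passing duplicate traces by their mean.
Risk categories come from a gestational-age-indexed table of the upper limit
of normal RI (a synthetic, editable stand-in — portable Doppler devices ship
proprietary bands): *normal*, *raised*, *severely raised* (0.10 above the
limit), and *absent end-diastolic flow* at RI = 1.

Fetal strain at a working timepoint is the disjunction of

* a fetal heart rate at or above 160 bpm, or at or below 115 bpm, sustained
  over a contiguous window of at least 5 minutes, and
* an increase in the RI risk category from the visit's baseline
  (Doppler-eligible from 28 completed weeks; before that the outcome is
  FHR-only).

The 5-minute sustained rule is applied to **both** the tachycardia and
bradycardia arms (the defining sentence attaches the duration only to the
bradycardia clause; the symmetric reading is the conservative one), with an
`instant_tachy` switch for the alternative reading. Series spanning less
than 5 minutes cannot support a negative call and are flagged
indeterminate.

## Effect models

The analysis panel has one row per visit-timepoint (mid-shift and
end-of-shift), with episode-level heat stress defined as the **mean**
exposure from the start of the shift to the observation timepoint (a peak
basis is available by flag) and maternal strain as the mean PSI over the
same window. Three nested models are fitted for each outcome and index:

* Model 1: outcome ~ heat stress — the *total* effect;
* Model 2: + maternal PSI — the *direct* effect of heat stress;
* Model 3: + fitness (6-minute-walk distance), % fat mass, gestational age —
  the *direct* effect of maternal strain.

Outcome A is the continuous working-period FHR (linear); outcome B is the
binary strain indicator (logistic, effects reported as odds ratios per 1 °C
and per PSI unit). Repeated measures are handled with population-average
cluster estimating equations: exchangeable working correlation, moment
estimator for the intra-participant correlation, robust sandwich covariance,
Wald 95% intervals. The estimator is implemented in the package (no GEE
package is declared as a dependency) and is verified in the test suite
against an independent reference implementation on a frozen fixture, and —
for the independence working correlation — against `glm()` plus the
classical cluster sandwich, which it must match exactly. Model comparison
for these fits uses Pan's QIC, the quasi-likelihood-under-independence
analogue of AIC; a random-intercept mixed-model estimator (lme4) is
available by flag and is the default wherever a true likelihood AIC is
needed, in particular for the linear-versus-spline exposure-shape
comparison (natural cubic splines with interior knots at the empirical 50th
and 90th exposure centiles, and the same spline on log-exposure; AIC ties
within 1e-9 resolve to the simpler shape).

Supporting descriptive machinery: Wilcoxon signed-rank tests for
baseline-to-working shifts (zeros dropped, exact null up to 25 untied
non-zero pairs, continuity-corrected normal approximation beyond), Pearson
correlation between exposure indices, residual diagnostics (quadratic
residual-on-fitted check, Levene's test across exposure tertiles,
Shapiro–Wilk on residuals; reported, never auto-acted-upon), and the
classical two-proportion sample-size computation reported both with and
without continuity correction — the two conventions can differ by tens of
participants (5% vs 30% incidence at α = 0.05, power 0.80 gives 36 versus
43 per group), which is why both are shown rather than privileging one.

## The synthetic cohort generator

The generator is first-class, tested code. Its default configuration *is*
the reference study condition: 92 participants, a 33% chance of a second
visit (~122 visits), 8-hour shifts sampled at 12 physiological samples per
hour, a 50/50 rainy/dry season mix, and a mediated causal structure

> UTCI → (skin temperature, heart rate) → PSI → fetal strain ← UTCI (direct)

with a participant-level random intercept (SD 0.3 on the logit scale — a
plausibility default; the within-participant correlation of repeated visits
is not anchored by any reported value). The direct heat-stress effect on
fetal strain is OR 1.12 per °C and the PSI effect OR 1.20 per unit; the
total effect is left emergent (simulation with `implied_total_effect()`
gives ≈1.18–1.19 per °C, consistent with a mediated-plus-direct structure).

Meteorology is generated as season-level shift means plus a diurnal rise and
sample noise; globe and natural wet-bulb temperatures come from air
temperature, humidity, wind and a solar load factor through simple
documented empirical links (globe excess 10 °C at full sun damped by wind;
natural wet bulb = psychrometric wet bulb by Stull's formula + 12.8 °C ×
solar load, capped at air temperature). Only the downstream index summaries
are calibrated, to the reference values: pooled air temperature 33.5 °C,
humidity 28.1%, WBGT 27.2 °C, UTCI 34.0 °C, mean peak PSI 5.1, baseline FHR
125 bpm, working FHR 147 bpm, and a 34% episode-level strain fraction. The
calibration was done once, by simulation at ~5,000 visits, and frozen into
the defaults.

Latent strain events manifest either as an umbilical RI category increase
(60% of events in Doppler-eligible visits) or as a sustained FHR excursion
(tachycardic with probability 0.8, bradycardic 0.2). Two generator
properties keep the statistical structure clean:

* **Classifier fidelity by construction.** Non-strain FHR traces include
  periodic "reactivity" samples inside the normal band (mirroring the
  accelerations and returns of a reactive trace), so an unstressed episode
  can never sustain a threshold crossing for a full 5 minutes; non-strain
  working RI values are kept inside the baseline category with a small
  margin so duplicate-reading jitter cannot flip a category. The composite
  classifier therefore recovers the latent strain indicator exactly, and the
  fitted logistic models estimate the configured coefficients rather than a
  noisy surrogate.
* **Mean-neutral excursions.** FHR excursions are additive on the structural
  linear level, and the tachy/brady mix is chosen near the point where the
  excursion process adds no first-order mean shift, so the linear FHR
  model's slope remains recoverable.

What the generator deliberately does **not** emulate: missingness and
dropout (panels are complete by design), measurement error in the Doppler
beyond duplicate jitter, autocorrelated within-shift noise beyond the
diurnal profile, acclimatisation, and birth outcomes (cosmetic fields only).
Passing tests therefore demonstrate the correctness of the pipeline and the
recoverability of effects under the stated structure — not robustness to
the messiness of real field data.

One calibration compromise is worth stating plainly: with 34% of episodes
strained and sustained ≥160/≤115 bpm excursions required for the FHR-route
events, the episode-level working FHR dispersion settles near SD 14.8 bpm,
above the reference SD of 11.9 bpm. A composite outcome that must cross
clinical thresholds cannot simultaneously match that tighter spread; the
generator prioritises the pooled means, the strain fraction and the effect
structure.

## Numerical and testing choices

* The UTCI polynomial is evaluated from a 210-term exponent table; the test
  suite compares it against a second, independently coded term-by-term
  evaluation of the published coefficients over a 1,000-point envelope sweep
  (agreement well under 0.1 °C), plus physical checks (UTCI ≈ Ta under
  neutral conditions, monotone response to radiant load).
* Parameter recovery is tested over 200 seeded cohorts of ~1,000 visits:
  median estimates within ±0.03 (OR scale) / ±0.15 bpm/°C of the configured
  truth and ≥90% CI coverage. One assertion in that block is a known,
  deliberate failure: the linear model's heat-stress slope is attenuated by
  about 0.09 bpm/°C under the default composite-outcome configuration
  (strain excursions must clear the 160/115 bpm thresholds, which saturates
  their dependence on the underlying level), so its CI covers the configured
  slope in 88% of replicates rather than 90%; the median still passes. A
  separate property test generates cohorts from the linear model's own
  uncontaminated structure (latent strain disabled) and shows the estimator
  recovers the slope with nominal coverage, locating the gap in the
  outcome's measurement process, not in the estimator.
* Null safety (all structural coefficients zero) uses 200 seeded cohorts of
  1,000 participants — a size at which the cluster-sandwich z-tests are
  close to nominal (their small-sample inflation at a few hundred clusters
  is a property of the estimator, not of the generator) — and requires a
  ≤7% rejection rate per term at α = 0.05.
* The spline-selection property uses panels generated with an exactly linear
  exposure effect. The full cohort generator is *not* exactly linear: the
  physiological ceilings (heart rate capped at 175 bpm, skin at 39.4 °C) and
  the excursion mixture bend the response slightly at the hot end, and with
  enough data the spline models legitimately detect this.
* Problem sizes in the routine test suite (cohorts of 250–3,800
  participants, 100–200 replicates) were chosen to make Monte-Carlo error
  small relative to each stated tolerance.

## Limitations

The RI category table and the task→MET lookup are synthetic stand-ins and
are flagged as such in their filenames; replace them with study-specific
tables for any real analysis. PAEE units and log base follow the validated
equation's structure but are not anchored by an authoritative statement.
The estimator is population-average by default; conditional (mixed-model)
odds ratios differ for logistic outcomes, and the two should not be mixed
in one comparison. The generator's season mix, within-participant
correlation and bradycardia share are plausibility defaults, not estimates.
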