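---
title: "Methods: rest-activity rhythms and mood-disorder phenotyping in actimood"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rest-activity rhythms and mood-disorder phenotyping in actimood}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(actimood)
```

# Scope

`actimood` implements a complete case-control comparison of probable
bipolar disorder (BD), probable unipolar mania (UM) and a no-mood-disorder
control group on objective (wrist-accelerometer) and subjective
(questionnaire) rest/activity measures, in the style of large population
cohorts such as UK Biobank. Because participant-level data of that kind is
access-restricted, the package ships a synthetic cohort generator whose
defaults encode the published group structure, so every stage — phenotyping,
circadian metrics, sleep detection, comparison statistics — is executable
and testable end to end.

# Phenotyping rules

Participants reporting any of seven conditions (severe neurological
diagnosis, brain cancer/injury, personality disorder, psychosis,
schizophrenia, sleep apnoea/insomnia, shift work as the main job) are
excluded before any criteria are evaluated.

The mania core is met when the participant reports having been "hyper" or
irritable for two days or more *and* at least 3 manic symptoms. Probable
major depression requires 2+ weeks of depressed mood or anhedonia, at least
5 depressive symptoms, *and* a consultation with a health professional.
Labels combine as: BD = mania core + depression; UM = mania core without
depression; control = neither. When a participant completed the more
detailed online follow-up instrument, its answers take precedence over the
touchscreen baseline; both instruments use the same absolute symptom
thresholds even though their symptom scales differ (0–4 touchscreen, 0–8
online), because the classification rule is stated once, in absolute terms.

Three deliberate design choices where the underlying rules are silent:

* **Depression without mania** is labelled `DEPRESSION_ONLY` and analysed in
  no group. Folding these participants into the controls would contaminate
  the "no mood disorder" comparison group.
* **Missing gating answers** make a participant `UNCLASSIFIABLE` (counted
  and dropped), never silently a control. A definite "no" on both gates,
  however, settles the criterion without symptom counts, since the symptom
  questions are only asked after a positive gate.
* Episode **duration** and **problematic** items are carried in the data
  model but are not criteria: the classification rule uses only the 2-day
  gate and the symptom count.

# Circadian metrics

All metrics operate on nonnegative epoch magnitudes (milli-g) with wear
flags; analysis days run **noon-to-noon**, so a single main sleep period is
never split by a day boundary.

* **AA** — mean over all worn epochs of the record.
* **M10 / L5 / RA** — per day, the maximum mean over contiguous 10-h
  windows and the minimum mean over contiguous 5-h windows, sliding at
  epoch resolution with windows fully inside the day (no wrap). The daily
  relative amplitude `(M10 − L5)/(M10 + L5)` is averaged across days
  (the default; forming RA from averaged M10 and L5 instead is available
  via `method = "average_profile"` — the per-day average is the reading
  most consistent with "of a given day ... averaged across all days").
* **IS** — on hourly means, the ratio of between-clock-hour variance to
  total variance: 1 for identical days, about `1/d` for `d` days of white
  noise (the exact first-order expectation is `23N/(24d(N−1))`).
* **IV** — the normalised mean squared successive difference of the hourly
  series: 2 for white noise, `2(1 − cos(π/12)) ≈ 0.068` for an
  hourly-sampled 24-h cosine, 4 for strict hourly alternation.

Numerical conventions: hours with worn fraction below 0.5 are missing; days
with fewer than 20 of 24 complete hours are dropped from RA/IS/IV (counted,
never imputed); a constant signal makes IS/IV undefined and they propagate
as `NA` with a `reason` attribute — never as 0. Undefined daily RA
(M10 + L5 = 0) drops the day with a count.

# Sleep detection

The reference pipelines for wrist accelerometry score sleep from raw
triaxial postural angle, which cannot be recovered from magnitude-only
epochs. `actimood` therefore uses a documented threshold detector: activity
is smoothed with a 30-min rolling median, an epoch is "low" below
`θ = 0.1 ×` the participant's median daytime (09:00–21:00) activity, and the
sleep window is the longest contiguous low block of ≥ 3 h in the
noon-to-noon day. Epochs inside the window are scored asleep when their raw
value is below θ. Mean sleep duration is the mean of nightly slept hours;
efficiency is the mean of nightly slept/window ratios. All constants
(θ fraction, minimum block, smoothing width, 20-h minimum wear) are exposed
as arguments. Naps are intentionally not scored — subjective reports include
napping, the objective estimate does not, which motivates the napper
exclusion below. Durations are categorised as short (< 7 h), regular
(7–9 h, both endpoints inclusive) and long (> 9 h).

On noiseless generator output the detector recovers the true onset and
offset to within one epoch; with per-epoch wake probability `p` inside the
window, detected efficiency concentrates at `1 − p`.

# Comparison statistics

Continuous RA, IS, AA and sleep efficiency are sign-inverted and, together
with IV, cut into quintiles (type-7 sample quantiles on the pooled analysed
sample, boundary ties to the lower bin), so a higher quintile always means
a more negative outcome. Chronotype condenses to early / intermediate
(reference) / late; happiness items to happy (reference) / unhappy; getting
up to not-difficult (reference) / difficult; "do not know" and "prefer not
to answer" are excluded.

Each exposure is compared across BD vs UM, UM vs control and BD vs control
by logistic regression with the first-named group as the outcome, so
OR > 1 always means the exposure is more likely in that group. Partly
adjusted models use age, sex, Townsend deprivation, education and ethnicity
(+ season of wear, by meteorological quarter, for accelerometer-derived
exposures); fully adjusted models add BMI, smoking, alcohol and
psychotropic-medication status. Wald 95% intervals are reported; results
with any cell under 10 are flagged, and separation or non-convergence is
flagged rather than raised. When any expected cell of a binary contrast's
2×2 table falls below 5, Fisher's exact test replaces the logistic estimate
for that contrast. One pooled Benjamini–Hochberg family covers all fully
adjusted p-values across the three comparisons (the family definition is
otherwise underdetermined; pooling is the most conservative reading), with
discoveries at adjusted p < 0.05.

**Sleep discrepancy.** Regular nappers are excluded; the objective duration
is rounded to the nearest hour and `diff = subjective − round(objective)`
classifies participants as accurate (0), overestimating (> 0) or
underestimating (< 0). This orientation — subjective in excess of objective
counts as *over*estimation — is the one consistent with the published
pattern in which the group with the highest underestimation share sleeps
objectively longest; the alternative reading of the procedure's verbal
description would invert every label. A multinomial model (accurate as
reference) regresses the three-level outcome on group plus either covariate
set. Fewer than three observed outcome levels is an error advising a binary
model.

Descriptives use Pearson chi-squared (with Cramér's V) for categorical
variables and one-way ANOVA (with eta-squared) for continuous ones. The
ANOVA is implemented from group summary statistics
(`SSB = Σ n_g (m_g − m)²`, `SSW = Σ (n_g − 1) s_g²`), which makes it
applicable to published tables; on exact summaries it reproduces the
raw-data `anova(lm(...))` to numerical precision. The neuroticism score
sums 12 binary items and is missing when any item is missing.

# The synthetic cohort generator

`cohort_config()` defaults encode the modelled study's structure: group mix
BD/UM/control ≈ 0.075/0.019/0.906 (plus a 12% depression-only stratum and
~6% excluded via seven independent 0.85% flags), per-group demographics
taken from the published descriptive table, questionnaire response
probabilities that give ≥ 99% phenotyping recovery of the generating
stratum, and wellbeing/sleep item distributions that approximate the
published group proportions (e.g. reported anxiety 74%/15%/6% for
BD/UM/control).

The actigraphy signal model is: while awake,
`mesor + amplitude · max(0, cos(2π(t − peak)/24))` plus truncated-at-zero
Gaussian noise; one sleep window per noon-to-noon day with participant-level
onset/length anchors perturbed nightly; day-level phase jitter shifting both
the diurnal peak and sleep timing; daytime low-activity bouts at a
configurable rate; and isolated wake bouts inside the sleep window with
per-epoch probability `p`. Group defaults (mesor 38/42/40 milli-g, in-bed
windows 10.3/9.0/9.5 h, wake probabilities 0.26/0.25/0.24 for
BD/UM/control) reproduce the published qualitative ordering: UM most
active with the shortest sleep, BD least active with the longest, most
fragmented sleep and ~0.75 efficiency. Epochs default to 60 s (any divisor
of 3600 is accepted) over 7 days.

What the generator deliberately does **not** emulate: device calibration
and temperature drift, raw triaxial output, realistic non-wear structure
(non-wear is i.i.d. epoch dropout, default 0), naps, seasonal or weekday
structure, and correlation between questionnaire items beyond their group
conditioning. Passing tests therefore demonstrate the correctness of the
algorithms and the internal consistency of the pipeline on data with the
assumed structure — not robustness to the messiness of field recordings.

Determinism: every draw flows from the single config seed; per-participant
actigraphy seeds are drawn at cohort generation, so any participant's
series can be regenerated independently. `generate_cohort()` saves and
restores the caller's RNG state.

# Validation strategy and problem sizes

The test-suite oracles are independent of the implementation paths they
check: exhaustive window search for M10/L5, a hand-written step-up loop for
BH, hypergeometric enumeration via `choose()` for Fisher's exact p,
cross-product ratios for unadjusted 2×2 odds ratios, and `anova(lm(...))`
for the summary-statistic ANOVA. Published descriptive statistics (five
chi-squared values, three ANOVA F values, an unadjusted anxiety OR of
47.4) are recomputed from printed counts and summaries shipped as reference
CSVs. Reconstructed from printed (rounded) means and SDs, the Townsend
deprivation F lands at 294.7 against a printed 297.6 — within the interval
attainable under input rounding but outside the package's 0.5% check,
which is left strict rather than widened.

Simulation checks use sizes chosen to keep Monte-Carlo error well inside
the asserted tolerances at desk scale: effect recovery uses 20 cohorts of
20,000 questionnaire-only participants (the injected ln 2 log odds ratio
must sit within 2 Monte-Carlo standard errors); the null type-I rate uses
500 refits at n ≈ 4,000; closed-form metric checks use 1–50 synthetic
weeks.

# Known limitations

* The sleep detector is a threshold heuristic on magnitude data; absolute
  agreement with angle-based reference implementations is out of scope.
* Adjusted odds ratios from the modelled study are not reproducible
  without the restricted participant-level data; the package validates
  against its printed descriptive statistics and against synthetic truth.
* Quintile boundaries react to ties; heavily discretised exposures can
  collapse bins (a warning is raised).
* The multinomial model uses Wald intervals from the observed information;
  very sparse outcome cells deserve the Fisher route instead.
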