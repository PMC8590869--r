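---
title: "The Hemodynamic Stability Index: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The Hemodynamic Stability Index: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hsindex)
```

This vignette is the package's own account of its science: what is modeled,
which quantities are fixed by clinical definitions versus chosen here, and
what a green test suite does and does not establish.

## 1. The outcome: intervention segments

The prediction target is not mortality or a diagnosis but a *treatment
event*: the start of hemodynamic support. Treatment records (point events in
hours since ICU admission, volumes in cc) are scanned against a trigger set
derived from clinical consensus:

* any administration of one of six vasopressor/inotrope drugs;
* fluid therapy reaching 700 cc in 1 h, 1500 cc in 4 h, 2400 cc in 8 h,
  3000 cc in 12 h, or two separate boluses of at least 500 cc within 4 h;
* PRBC transfusion reaching 800 cc within 24 h; or 500 cc within 2 h,
  conditioned on whether *fluid therapy* (a fluid trigger, not merely any
  fluid record) follows within 12 h (it does: instability) or fails to
  follow within 24 h (it does not: instability of a different kind —
  transfusion without volume resuscitation).

A segment opens at the first satisfied trigger and extends while consecutive
treatment records are at most 12 h apart; a longer gap closes it. A stay
with at least one segment is *unstable*.

Interpretation choices the definitions leave open, and how they are fixed
here:

* **At-threshold doses fire.** Cumulative volume ≥ threshold triggers, so
  the printed dose is itself a triggering dose. Windows are half-open
  `(t − W, t]` anchored at record times of the summed category — sufficient,
  because a category's cumulative sum changes only at its own records.
* **"500 cc twice in 4 h"** is read as two distinct administrations of
  ≥ 500 cc each within 4 h of one another; the merged reading (1000 cc
  cumulative) is already dominated by the 4-h/1500-cc rule.
* **The conditional PRBC volume** ("500 cc") is read as a 2-h cumulative for
  both conditional rules; the followed-by rule states the 2-h window
  explicitly and consistency argues for applying it to both.
* **End of stay** resolves the not-followed rule: no fluid trigger before
  discharge counts as "not followed".
* **Hits are emitted at every satisfaction time**, not only the earliest,
  so that a trigger recurring after a > 12-h quiet period opens a new
  segment.
* Treatments are point events; infusion-duration spreading is a documented
  extension point, as is weight-based (cc/kg) dosing.

One stated monotonicity property — adding a fluid record never delays a
segment start — is *almost* true: the exception is a PRBC transfusion whose
"not followed by fluid" hit (at transfusion time) is converted by the added
record into a "followed by fluid" hit (at the later fluid time). The test
suite asserts the property outside that interaction and documents the
exception rather than hiding it.

## 2. Feature snapshots

At a query time `t` the model sees 33 variables. The exact panel used by the
original clinical deployment is not public; the default registry
(`hsi_registry()`) is a clinically standard approximation — 8 vitals
(plus derived shock index and age), 21 labs/blood gases, 3 ventilator
settings — and is configurable from a CSV/YAML file, because the panel is a
*parameter* of the method, not part of it.

* **Forward fill with expiry.** The last measurement at or before `t` is
  used if its staleness is ≤ 2 h (vitals) or ≤ 26 h (labs and ventilator
  settings); demographics never expire. Diastolic and mean pressure share
  the 2-h vital limit (the definition names only heart rate and systolic
  pressure; grouping the remaining vitals with them is the conservative
  reading).
* **Imputation.** Expired or never-measured values fall back to the
  training-population mean — computed on raw measured values only, never on
  forward-filled copies, which would weight slowly-charted patients —
  except FiO2 (room air, 0.21) and MAWP/PIP (left missing, because imputing
  ventilator settings for unventilated patients invents a ventilator).
  Missingness indicators are deliberately *not* features: charting
  frequency is a site artifact, and a model that learns it does not
  transport.
* **Validity.** A snapshot without a usable heart rate and systolic
  pressure is invalid and is never scored.
* **Operating modes** mask out-of-mode variables as never measured before
  imputation, so a mode can only remove information.
* Invasive/noninvasive pressures merge with invasive priority inside a
  1-minute simultaneity bin; measured values are clipped to plausible
  physiological ranges, and no further artifact rejection is attempted.

## 3. Sampling and splitting

One positive snapshot per unstable stay, at `segment start − lead` (default
lead 1 h); one negative snapshot per stable stay at a seeded uniform time in
`[6 h, discharge]`, re-drawn up to 10 times if the snapshot is invalid.
Nothing is sampled from the first 6 h of any stay (admission chaos), and DNR
stays and patients under 18 are excluded. Negatives come only from stable
patients: pre-intervention quiet periods of unstable stays are deliberately
not used, matching the labeling philosophy that instability is a property of
the stay. Splits are by patient, stratified by label, 80/20.

## 4. The additive stump ensemble

Gradient boosting with logistic loss over depth-one trees. Per round, every
variable is scanned; candidate thresholds are midpoints of up to 256
quantile bins of the present values; the winner maximizes the standard
second-order gain `G_L²/H_L + G_R²/H_R − G²/H` on the negative gradients;
leaf values are Newton steps `−G/H`, clipped to |v| ≤ 4 (a guard against
pure leaves) and shrunk by the 0.1 learning rate. Samples missing the chosen
variable contribute nothing to that stump and are excluded from its split
search — the absence itself carries no signal, by design. Ties break toward
the lowest variable index and lowest threshold; training is deterministic
given input order. Defaults (200 rounds, learning rate 0.1) follow the
published training recipe.

Because every stump is univariate, summing each variable's stumps yields an
exact decomposition: `raw_score = baseline + Σ_v risk_v(x_v)` with
`baseline` the training-prevalence log-odds. `risk_curve()` returns
`risk_v` on a grid (the ≥ branch applies at a threshold point), and the
additivity identity is asserted *exactly* in the tests, not to a tolerance.

**Calibration.** Platt scaling on a held-out patient-disjoint 20% of the
training stays (the published recipe does not say where its calibration data
comes from; a patient-disjoint slice is the choice least likely to inherit
boosting overfit). The fit minimizes log loss of `σ(−(a·s + b))` with
Platt's smoothed targets; after calibration the mean predicted probability
matches calibration prevalence within one percentage point (asserted).
`HSI = 100 × (1 − p)` orients the index so that higher means more stable.

## 5. Uncertainty and abstention

The published description decomposes predictive uncertainty into *model* and
*feature* components without giving the construction (it lives in an
unavailable supplement). The concrete realization chosen here, documented as
such:

* `sigma_model`: standard deviation of the raw score across B patient-level
  bootstrap refits (default 50; 20 in the test suite for runtime).
* `sigma_feature`: standard deviation of the primary model's raw score over
  K joint redraws (default 20) in which every imputed, masked or absent
  variable is resampled from its training empirical marginal; measured
  values are never perturbed. Redraws are independent across variables — the
  simplest defensible choice; a joint correlation model is an extension
  point.
* The interval is `raw ± z·sqrt(sigma_model² + sigma_feature²)` (z = 1.96),
  and the model abstains when the interval contains the decision threshold
  (default: the breakeven threshold).

Two consequences are asserted empirically on synthetic data: masking
variables can only raise feature uncertainty (hence abstention), and the
error rate among non-abstained predictions never exceeds the overall error
rate.

## 6. The synthetic cohort: what it emulates, what it does not

`generate_cohort()` produces the *shape* of a real ICU extraction: ~18%
intervention prevalence; stable stays shorter (median ≈ 29 h) than unstable
ones (median ≈ 95 h); vitals on a 5-minute grid with 10% dropout; labs on
irregular 6–24-h grids (so the 2 h/26 h expiry rules actually bite);
ventilator settings only on ventilated stays; dual invasive/noninvasive
pressure charting on a subset; 5% DNR stays; unstable archetypes split
pressor/fluid/PRBC ≈ 53/33/14 to match the reported intervention mix.

The planted deterioration is a *compensated-shock* story chosen once at
design time: over a 6–18-h window, perfusion labs drift (lactate
+0.5 mmol/L/h, bicarbonate −0.9, base excess, pH, creatinine; hematocrit and
hemoglobin fall for the transfusion archetype; FiO2 demand rises on
ventilated stays), while vitals decompensate only in the final 3 h (heart
rate +4 bpm/h, systolic −5 mmHg/h). This is why, on this cohort as in real
data, the multivariate score clearly outperforms shock index and systolic
pressure alone, lab access adds a large AUC increment, and signal decays
gracefully as the prediction lead grows from 1 h to 12 h. Neuro and stepdown
units get the drift at half strength (~20% of stays), reproducing the
qualitative subgroup degradation reported for those units. Treatment doses
are drawn above their trigger thresholds with margin, and stable-stay
nuisance boluses are small (< 500 cc) and sparse (> 13 h apart) so that no
window can accumulate a trigger — the labeler, not the generator, certifies
this in tests.

What the generator does **not** emulate: pharmacokinetics, inter-variable
correlation beyond the planted trends, charting-frequency pathologies,
infusion durations, or any real database schema. A green planted-signal test
therefore establishes that the pipeline *recovers a signal of this stated
form at these magnitudes* — it says nothing about performance on real
clinical data, and the published real-data AUCs are intentionally not
reproduction targets.

## 7. Numerical choices

* Quantile-bin split search (256 bins) makes training O(rounds × variables ×
  bins) after a single binning pass, and deterministic.
* Breakeven is the threshold minimizing |precision − recall| on the discrete
  PR curve (exact equality is rarely attainable on finite data); ties go to
  the higher-specificity threshold. Specificity targets use ≥ (conservative);
  an unreachable target is flagged degenerate, not silently nearest-matched.
* AUC uses midranks, so it equals pairwise concordance with ties counted
  half — asserted against a brute-force oracle.
* Model JSON is written with 17 significant digits so a round-tripped model
  scores bit-identically; a registry hash in the file refuses scoring
  against a different variable panel.
* Scores calling "unstable" at `score ≥ threshold` everywhere; the ≥ branch
  convention also applies to risk curves at threshold points.

## 8. Known limitations

* The 33-variable registry approximates an unpublished panel; per-variable
  fill limits beyond the two published classes are not modeled.
* Point-event treatments: infusion durations and rate-based pressor
  thresholds are out of scope.
* The abstention statistic is one defensible realization of an
  underspecified mechanism; its coverage is validated only loosely (≥ 80%
  empirical coverage at z = 1.96 on synthetic data).
* Lead-time evaluation scores one 1-h-lead-trained model at earlier
  snapshots rather than retraining per lead — the cheaper and, we judge,
  intended reading.
* Negative sampling draws one snapshot per stable stay; class re-weighting
  and multi-snapshot training are out of scope.
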