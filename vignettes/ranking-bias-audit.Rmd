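---
title: "Auditing ranking bias in smartphone-sensing depression models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing ranking bias in smartphone-sensing depression models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the generative
model behind the synthetic cohorts, the feature and metric definitions,
the statistical machinery, and the numerical and design choices made
where the underlying methodology left them open.

## 1. What the audit establishes

An AI tool that predicts clinically-significant depression (CSD,
reporting-week mean PHQ-8 total ≥ 10) from sensed behavior outputs a
risk score in [0, 1]. Even when every subgroup is ranked correctly
*internally*, the tool can systematically order one subgroup's scores
above another's; healthy members of the high-scored subgroup then
outrank depressed members of the low-scored one. The audit quantifies
this with three pairwise-AUC metrics (Subgroup, BNSP, BPSN), isolates
the effect of each subgroup membership on the predicted risk with GEE,
and asks *why* the model misranks by comparing its Shapley attribution
directions against per-subgroup explanatory logistic slopes.

The three metrics decompose the pooled AUC exactly: the pooled AUC is
the pair-count-weighted mean of the four within/cross subgroup-class
blocks (a property the test suite checks numerically). In the canonical
two-subgroup construction — perfect within-subgroup separation but all
of subgroup A's scores above all of subgroup B's — both Subgroup AUCs
are 1.00 while the pooled AUC is 0.75, because the cross block
`A(pos_B, neg_A)` contributes 0. Exhaustive pair enumeration gives
BNSP = 1.0 / 0.0 and BPSN = 0.0 / 1.0 for the two subgroups; these are
frozen as exact expectations in the tests.

## 2. The synthetic cohort generator

The generator defines the study conditions under which every downstream
stage is validated. It emulates a 16-week protocol: GPS sampled every 5
minutes, screen on/off events, and PHQ-8 surveys delivered 3 times per
reporting week in weeks {1, 4, 7, 10, 13, 16}. How many surveys arrive
per reporting week is protocol-dependent ("multiple times a week"); 3 is
the default and it is configurable.

**Attributes.** Six attributes (age band, sex at birth, race, family
income, insurance, employment) are drawn independently per participant
from the marginals of the 650-participant cohort the package emulates
(`study_attribute_marginals()`), e.g. 74% female, 82% White, 62%
employed.

**Behavioral knobs.** Each participant has latent knobs with explicit
priors: home and 1–5 routine places (visited on a fixed daily template),
movement regularity in [0, 1] (Beta(8, 2), mean 0.8 — the probability a
day follows the template rather than a shuffled schedule), per-epoch
screen session rates (Gamma; means 0.6/5/6/7 sessions per 6-hour epoch
for night/morning/afternoon/evening), mean session length (log-normal,
median 3 min), and habitual sleep onset (Normal(23.5 h, 1 h)) and
duration (Normal(7.5 h, 0.8 h), clamped to 3–13 h). Subgroup shifts move
knob means additively in prior-SD units; the defaults shift morning
session rates by +0.32 SD for 18–25-year-olds and −0.62 SD for
65–74-year-olds, matching the standardized medians reported for morning
phone use in the emulated study.

**Streams.** Dwell positions are jittered with 10 m Gaussian noise;
place-to-place transitions are straight lines at 20 km/h (comfortably
above the 1 km/h transition threshold at the 5-minute cadence); sessions
are suppressed and truncated inside the habitual sleep window (including
the window that spills over from "day −1" into the first morning).
Stream-level missingness drops 10% of GPS fixes and 5% of sessions by
default; whole reporting weeks are missed with probability 0.06, the
value that reproduces the emulated study's completeness-filter attrition
(938 enrolled → ~650 fully observed, since (1−0.06)^6 ≈ 650/938).

**Outcomes.** Latent week severity is

    severity = intercept + baseline_p + Σ coef(attr, subgroup, knob) · z_knob + ε_week

with `baseline_p ~ N(0, 4)` points between participants,
`ε_week ~ N(0, 2)`, and response-level noise `N(0, 1)` around the week's
severity before rounding and clipping to 0–24. Knobs are standardized by
their *prior* moments, so coefficients are in PHQ-8 points per knob SD.
The intercept is calibrated by seeded Monte Carlo so the pooled fraction
of reporting weeks with mean total ≥ 10 hits the 0.46 target. Totals are
decomposed into the 8 item scores by largest-remainder rounding of
configurable item weights (uniform by default) — the methodology treats
only totals, but realistic input files need item-level rows.

The default couplings plant the sign-flip structure the audit is meant
to expose: morning session rate −2.0 points/SD for 18–25 vs +1.6 for
65–74, and movement regularity −0.5 for employed vs +1.5 for
on-disability participants. Under the default residual scale
(≈ 4.6 points), these correspond to explanatory log-odds slopes of
roughly −0.74/+0.59 and −0.18/+0.55 per SD, the magnitude pattern of the
emulated study's reported morning-phone and circadian-movement
coefficients.

**Determinism.** Every stage derives its RNG stream from the master seed
(`derive_seed()`), per participant and per stage; a fixed seed gives
byte-identical cohort files.

## 3. Feature extraction choices

* **Window alignment.** A sample's features cover the 14 days ending
  with its reporting week, `[7w−14, 7w)` days from study start. For week
  1 this window is clipped at the study start; expected-fix counts,
  phone zero-fill days and candidate sleep nights are computed over the
  clipped window so week 1 is not spuriously voided.
* **Transition and clustering.** Speed is the haversine distance to the
  previous fix over elapsed time; > 1 km/h flags transition. Stationary
  fixes are clustered by density (30 m radius, minimum 5 fixes) — a
  deterministic choice with no cluster-count parameter, in line with the
  GPS-feature lineage this feature set comes from. Fixes are snapped to
  a 5 m grid with multiplicity weights before the O(u²) neighborhood
  pass, which bounds the cost per window while staying within ~7 m of
  point-level clustering, negligible against the 30 m radius.
* **Location features.** Variance is `log(var(lat) + var(lon))` (floored
  at 1e−12 before the log); entropy uses natural logs over the
  stationary-fix distribution across clusters; home is the plurality
  cluster between 00:00 and 06:00 (falling back to the overall plurality
  cluster when no nighttime fixes exist), and home time is reported as a
  *fraction* of stationary fixes (the lineage is ambiguous between hours
  and fraction; fraction is documented here). Circadian movement is the
  log of the summed lat + lon least-squares spectral power fraction in
  the 23.5–24.5 h band, each normalized by total power over 2–26 h
  periods (0.25 h grid). Note a physical ceiling: over a 14-day window
  the spectral resolution near 24 h is ≈ P²/T ≈ 1.7 h, wider than the
  1 h band, so even a pure 24 h sinusoid concentrates only ~2/3 of its
  power in the band; the feature is informative relatively, not as an
  absolute fraction of 1.
* **Phone usage.** Sessions are on→next-off; for unlock-only streams a
  session is capped at 10 minutes or the next unlock, whichever comes
  first. Session time is apportioned to days and 6-hour epochs by
  overlap; unlocks count where the session starts. The "6–12 PM" epoch
  is read as 06:00–12:00 (morning), following the in-text gloss of
  morning phone usage. Days without use count as zeros — absence of
  phone use is informative, so a window with no events yields zeros, not
  missing values. All deviation features use the population SD
  (divisor n).
* **Sleep.** Per night, sleep is the longest gap between interactions
  starting between 20:00 and noon the next day, within 3–14 h; onset is
  the circular mean of gap-start clock times; all three features are
  missing below 7 valid nights. Inferred sleep is *mechanically* coupled
  to morning session rates (morning interactions truncate the gap), a
  point that matters when interpreting per-subgroup slopes.
* **Preprocessing.** Features with training-set |skewness| > 3 (the
  threshold is a documented choice; the methodology says only "skewed")
  get `log1p` after shifting the training minimum to zero. Missing
  values are filled by iterative chained-equations imputation
  (mean-initialized per-feature linear models, 8 sweeps, fitted on
  training rows only, replayed verbatim on new rows); features are then
  standardized by training mean and SD. Changing any test row never
  changes the fitted transform, and the transform serializes to JSON.

## 4. Models, validation, calibration

Cross-validation partitions on participants: all 6 samples of a
participant share a fold, 5 near-equal folds, reshuffled each trial. Per
fold, preprocessing and the model are fitted on the training folds only;
out-of-fold predictions are concatenated per trial and summarized as the
median and 2.5/97.5 percentiles across trials. The default model is the
grid's best performer in the emulated study — a random forest with 100
trees, depth 10, balanced class weights — with the full printed grid
available via `model_grid()`. Non-logistic scores are Platt-scaled with
prior-smoothed targets; the calibrator is fitted on scores cross-fitted
over an inner 3-fold split of the training fold (the methodology is
silent here; cross-fitting avoids calibrating on optimistic in-sample
scores). The naive baseline re-predicts each participant's week-1 mean
total (÷ 24 for the [0, 1] contract; any monotone map gives identical
ranking metrics).

A caution the test suite works around deliberately: concatenating
out-of-fold predictions biases the null AUC *below* 0.5 in small cohorts
(a fold with excess positives was trained on a deficit of them, so its
predictions sit systematically low). The chance-level check therefore
runs at 200 participants, where this pooling artifact is small relative
to the ±0.05 band.

## 5. Bias metrics, GEE, attribution

* **Ties** in the pairwise AUC get half credit (the Mann–Whitney
  midrank convention). Backgrounds pool the *other subgroups of the same
  attribute* only; "Don't know"/"Prefer not to answer" are not reported
  as rows but remain in backgrounds; subgroups need ≥ 15 participants to
  be reported. The per-trial reference is the median subgroup when an
  attribute has more than two reported subgroups, else the maximum.
* **GEE.** Gaussian identity link ("a type of linear regression"),
  exchangeable working correlation, clustered on participant with all
  trials' rows stacked (each participant's repeated samples *and*
  repeated trials share a cluster); sandwich standard errors; CI =
  estimate ± 1.96 SE. The closed-form exchangeable inverse makes the
  cost linear in cluster size. Per-trial averaging before the fit is
  available behind `mode = "trial_mean"`. References are the
  lowest-mean-risk subgroup for RH and the highest for CSD, with
  lexicographic tie-breaks. The implementation is validated against an
  independent reference implementation on a fixture, against OLS in the
  one-observation-per-cluster limit, and for ~95% CI coverage over 500
  simulated replicates.
* **Shapley.** Model-agnostic permutation sampling with interventional
  semantics against the empirical background: per permutation one
  background row is drawn (cycling the background without replacement,
  reshuffled per epoch — a variance-reduction choice that keeps the
  Monte-Carlo background mean close to the exact baseline), features are
  switched background→actual in permutation order, and prediction deltas
  accumulate. Within a permutation the deltas telescope exactly, so
  efficiency (Σφ = prediction − baseline) holds up to the background-mean
  error; at `n_permutations` equal to the background size it holds to
  numerical precision. Fewer than 10 permutations are refused. The
  model's per-feature direction is the sign of the correlation between
  feature value and attribution.
* **Explanatory slopes.** Per (attribute, feature):
  `CSD ~ feature × subgroup` logistic models, marginal slope = base +
  interaction with delta-method CIs from a participant-clustered
  covariance; a ridge fallback covers quasi-separation (point estimates
  only, with a warning). Within-attribute models are unadjusted for the
  other attributes by default (`adjust = TRUE` is available); the
  emulated methodology does not state whether its explanatory models
  adjusted. The consistency report flags a (feature, subgroup) pair when
  the subgroup's CI-excluding-zero slope opposes the model direction.

## 6. Test-bed conditions and problem sizes

The validation suite runs entirely on synthetic cohorts, at sizes chosen
as the package's own desk-scale conditions: marginal checks at n = 650
participants; base-rate calibration at n = 300; planted-slope sign
recovery over 50 seeded replicates of n = 500 (planted on sex at birth —
two large subgroups, 74/26 — so the asymptotic regime actually holds;
the default age-band plant leaves the 65–74 subgroup with ~17 of 500
participants, far too few for near-certain sign recovery); GEE recovery
of a 0.03 risk offset at 500 clusters; an end-to-end planted-bias run at
200 participants × 10 trials; and a null-generator chance-level check at
200 participants.

Two findings from building that test bed are worth recording. First, a
planted sign flip only disadvantages a subgroup if the coupled behavior
has *overlapping* distributions across subgroups; pairing the flip with
a mean shift on the same knob lets even a subgroup-blind flexible model
infer membership from the feature value and partially resolve the
conflict. The planted-bias config therefore flips signs without shifting
the knob. Second, "the planted pairs and only those" is well-posed only
per examined feature: the planted knob propagates into several
correlated features (morning duration, days-with-use, and — through gap
truncation — inferred sleep), so the consistency check examines the
directly mapped feature plus a control feature driven by an uncoupled
knob.

## 7. What passing does and does not show

The generator produces dwell/transition geometry, daily periodicity,
epoch-structured phone use, sleep windows, clustered outcomes and
missingness — enough for every pipeline stage to have real work and
known ground truth. It does not emulate real GPS noise fields, irregular
sampling cadence, device churn, geographic semantics, weekday/weekend
structure, or intra-individual symptom dynamics; coordinates are
abstract. Green tests therefore certify the *machinery* — feature
definitions, leakage-free validation, metric algebra, estimator
correctness, sign recovery under known couplings — not that any
particular real-world cohort exhibits the planted effects. The emulated
study's real-data headline numbers are out of scope by construction:
its raw sensor data is not publicly available, and the package
reproduces the phenomena qualitatively on synthetic cohorts instead.
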