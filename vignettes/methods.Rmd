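---
title: "Methods: sensor-based MRC scaling and multi-rater reliability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sensor-based MRC scaling and multi-rater reliability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(proxiscale)
```

## Overview

`proxiscale` models a drift-test experiment in which proximal weakness of
acute stroke patients is graded on a modified 9-point MRC scale by one
expert (GS) and two non-experts (TS1, TS2), while a 3-axis accelerometer
attached to the limb records each 20 s session. The package covers the full
analysis: a generative model of the cohort, kinematic feature extraction,
class balancing of the skewed grade distribution, cost-sensitive ordinal
classification, and the agreement/reliability statistics used to compare
manual and automated grading. This vignette documents the models, the
defaults and why they were chosen, the numerical decisions, and the limits
of what the synthetic experiments can show.

## The synthetic cohort generator

No public dataset of drift-test accelerometry exists, so every analysis in
the package runs against a simulated cohort whose *structure* matches the
clinical protocol: `n_patients` (default 36) times 4 limb observations,
each observed by every configured rater within a short interval, so the
true grade is constant across sessions.

**Grade composition.** True grades are drawn from {5, 7, 8, 9} with default
probabilities 0.542, 0.271, 0.152, 0.035 for grades 9, 8, 7, 5 — the skewed
composition typical of an acute-stroke unit where most limbs are unaffected.
`grade_counts` forces an exact quota instead (used by the acceptance script
to fix the composition at 78/39/22/5 of 144).

**Movement model.** A limb with true grade g tilts away from its held
orientation following

$$\theta_g(t) = r_g\,t + a_g \sin(2\pi f_g t) \quad [\text{degrees}],$$

a linear drift plus a sinusoidal oscillation. The accelerometer measures
the gravity vector in the sensor frame, `(sin θ, 0, cos θ)` in g, plus
i.i.d. Gaussian noise per axis. This forward model was chosen because it is
(i) physically plausible for a slowly sagging limb, (ii) monotone in
severity, and (iii) exactly invertible by the feature extractor, which
gives closed-form oracles for testing: with zero noise the reconstructed
trajectory must equal $|\theta_g(t)|$ to machine precision, and the final
drift of a pure-drift trace must be $rT$.

**Kinematic defaults.** Per grade (5, 7, 8, 9): drift rate
$r$ = 1.6, 0.8, 0.35, 0.10 deg/s; oscillation amplitude
$a$ = 4.0, 2.5, 1.5, 0.6 deg; frequency $f$ = 0.40, 0.30, 0.25, 0.20 Hz;
sensor noise SD 2e-4 g per axis (the noise floor of a low-pass-filtered
MEMS accelerometer). These were fixed once, analytically, so that the
cohort-level feature statistics land on the right scale under the default
composition. Over a 20 s window the approximate expectations are
MeanDrift ≈ $10 r$, MaxDrift ≈ $20 r + a$, and SumOsc ≈
$20 r + 80\,a f$ plus the noise's total-variation contribution (≈ 13 deg
at 1000 samples). Mixing over the composition gives cohort means of roughly
3.3, 7.8 and 46 degrees — a few degrees of mean drift, single-digit maximum
drift for most limbs, and SumOsc in the tens of degrees. Session-to-session
variability multiplies $r$ and $a$ by a log-normal factor with log-SD
`0.15 * session_noise_scale`.

**Rater model.** A manual rating is drawn from a row-normalised exponential
confusion kernel, $P(\text{rated } j \mid \text{true } i) \propto
\exp(-|j - i| / s)$ on class indices. Spread $s = 0$ is a perfect rater;
$s \to \infty$ is uniform guessing. Defaults: expert $s = 0.35$
(≈ 90% exactly right), non-experts $s = 0.9$ (≈ 55–60% exactly right, most
errors adjacent). These were set from the analytic kernel so that the
expert–non-expert percent agreement is near 0.55 and the three-rater manual
Krippendorff alpha falls in the "fair" band (0.21–0.40), matching the
regime the method is meant to improve on.

**Random streams** are split per (observation, rater) with a multiplicative
congruential mix of the master seed, so cohorts are bitwise reproducible
and appending a rater does not perturb the draws of existing raters.

**What the generator does not emulate.** Real traces contain tremor
harmonics, voluntary corrections, sensor re-orientation and free-fall-like
artifacts; real feature distributions are heavier-tailed and overlap more
between grades; real rater errors are not symmetric in ordinal distance.
Consequently the synthetic experiments demonstrate *mechanism and
direction* (the pipeline runs end to end; automated scaling is more
reliable than noisy manual scaling when features are informative), not
clinical effect sizes: the ML reliability indices obtained here are higher
than could be expected on patients.

## Feature extraction

The drift angle is the static tilt angle
`acos(clamp(<a/|a|, ref>, -1, 1))` against a per-session reference
orientation — the simplest signal-to-angle conversion that is exactly
invertible for the forward model. `"auto"` estimates the reference from
the first 0.5 s of samples (biased if the patient moves immediately, a
documented limitation); the simulator's known gravity reference is used
when present. Samples with `|a| < 0.1` g are flagged as free-fall artifacts
and interpolated; more than 10% flagged is an error. An optional 4th-order
5 Hz Butterworth low-pass (via the `signal` package) can be applied before
the angle computation; it is off by default so the closed-form test oracles
hold exactly.

Features over the window: `mean_drift` (mean angle), `max_drift` (max
angle), and `sum_osc`, defined as the total variation
$\sum_k |\theta_k - \theta_{k-1}|$ of the raw angle. "Accumulated
oscillation" admits several readings (detrended, band-passed); total
variation on the raw angle was chosen as the assumption-free one and is
applied uniformly to every session, so cross-rater comparisons are
unaffected by the choice.

## Class balancing

For original class counts $n(T_i)$ and target $N$ over $M$ classes, the
boosting factor $SBF_i = (N/M - n(T_i))/n(T_i)$ determines the synthetic
count $n(SB_i) = N/M - n(T_i)$. $N$ must be divisible by $M$ (enforced
rather than silently rounded, so the per-class identity is exact); a class
already above $N/M$ is clamped to factor 0 with a warning — the scheme only
over-samples. Synthetics are SMOTE interpolations
$x + u(x_{nn} - x)$, $u \sim U(0,1)$, between a class member and one of its
$k = 5$ nearest same-class neighbours (Euclidean distance on z-scored
features, interpolation in raw feature space); $k$ is auto-reduced to
$n_{class} - 1$, and a singleton class falls back to 1%-jitter duplication
with a warning. Every synthetic therefore lies on a segment between two
same-class originals — a property the tests verify geometrically.

## Ordinal costs and the decision rule

The linear cost matrix penalises by ordinal distance on class indices,
$c_{ij} = |j - i|$; with the observed scale {5, 7, 8, 9} grades 5 and 7 are
*adjacent classes* (distance 1, not 2). Raw-grade distances are available
via `grade_values` for sensitivity analyses. The imbalance-scaled variant
multiplies row $i$ by $(\sum_{k \ne i} n_k)/n_i$ computed on the balanced
set; with equal counts this is a constant $(M-1)$-fold scaling, under which
minimum-expected-cost decisions are provably unchanged (tested). The
printed form of the imbalance weighting is ambiguous as typeset (the
fraction cancels to 1 read literally); the implemented reading — total
instances outside the class over instances in the class — is the one that
yields a meaningful per-class factor, and it is isolated behind
`imbalance_cost_matrix()` so an alternative reading is a one-function
change.

Prediction minimises expected cost $\sum_j c_{ij} p_j$ over the posterior
$p$. Ties break toward the lower class index, i.e. the more severe grade —
the clinically conservative direction (flagging weakness for review is
cheaper than missing it).

## Ensembles, cost-sensitive boosting, and model selection

Base learners are CART trees (`rpart`, depth-limited, `cp = 0`). Bagging
averages tree probability outputs over bootstrap resamples. AdaBoost
follows the multi-class SAMME weighting; the cost matrix enters the weight
update as `w <- w * exp(alpha * c_norm(pred, true))` with `c_norm` scaled
to max 1 — a distant mistake is up-weighted more than an adjacent one.
RUSBoost additionally trains each round on a class-balanced undersample
drawn with probability proportional to the current weights. Cost
sensitivity is applied at both entry points (boosting update and prediction
rule) and each can be ablated via `cost_in_boosting` / a 0/1 cost matrix.

The cross-validated objective is the mean held-out expected cost computed
on **original instances only** — SMOTE synthetics stay in every training
fold. Validating on interpolated points would leak information from their
parent originals and flatter the model; the originals-only choice is the
conservative one.

`select_model()` searches family × `n_learners` [10, 300] × depth [1, 8] ×
learning rate [0.01, 1] (log scale). The default engine fits a
Gaussian-process surrogate (RBF kernel, length-scale 0.5 on the unit-scaled
encoding with the family one-hot, nugget 1e-6) to the evaluation history
and proposes the expected-improvement maximiser over a 128-point random
candidate pool; the first evaluations cycle through all candidate families.
A seeded random search is available as the fallback engine. The incumbent
objective trace is non-increasing by construction and the incumbent is
retrained on the full balanced set.

## Agreement and reliability statistics

All statistics are implemented from their defining formulas (and tested
against independent oracles: a direct ANOVA via `aov()` for the ICC, two
algorithmically distinct reimplementations for alpha, exhaustive
enumeration for the decision rule):

* **Percent agreement** — exact-match fraction over pairwise-complete
  cases; not chance-corrected.
* **Bland–Altman** — mean difference, sample SD, limits of agreement
  mean ± 1.96 SD (multiplier configurable).
* **ICC(2,k)** — two-way random, absolute agreement, average measures:
  $(MS_R - MS_E)/(MS_R + (MS_C - MS_E)/n)$, CI by the McGraw–Wong F-based
  single-measure interval stepped up by Spearman–Brown, p-value from
  $MS_R/MS_E$. Because absolute agreement charges rater-offset variance, a
  noise-free table with rater offsets has ICC < 1 (closed form
  $MS_R/(MS_R + MS_C/n)$, asserted in the tests). For negative point
  estimates the F-based interval is not meaningful and NA bounds are
  returned. Zero between-subject variance reports ICC 0 with a warning.
* **Krippendorff's alpha** — coincidence-matrix formulation: each ordered
  within-subject rating pair contributes $1/(m_u - 1)$; $\alpha = 1 -
  D_o/D_e$. Subjects with fewer than two ratings are dropped; missing data
  are handled natively. The default distance metric is **nominal** (0/1),
  matching the common annotation-task convention for this analysis — with
  mostly-adjacent disagreements nominal alpha is the more conservative
  choice — with ordinal (rank-mass) and interval metrics selectable.
* **Fleiss' kappa** — category-proportion formulation; requires equal
  rater counts. For two raters this is Fleiss' formula on k = 2 (not
  Cohen's kappa), applied uniformly to every rater set.

## The experiment pipeline

`run_experiment()` trains on the expert session only: GS-session features,
GS manual ratings as labels (an option trains on the simulated true grades
for oracle studies). The fitted model re-scores the TS1/TS2 sessions from
their sensor features; the non-experts' manual ratings are never visible to
the model. The report mirrors the three-rater-set layout (GS–T1, GS–T2,
GS–T1–T2) for alpha and kappa, for the manual and the ML panels, plus
per-feature Bland–Altman and ICC blocks and confusion matrices against GS.
`run_ablation()` repeats the ML arm with and without cost adjustment on the
identical cohort (verified by a cohort digest), so the three method rows
are directly comparable.

Training per-limb versus pooled is not distinguishable from the feature
set; the pipeline pools observations across limbs and excludes the limb id
from the features.

## Problem sizes and determinism

The shipped tests run the full pipeline at the study scale (36 patients,
144 observations, N = 600) where a single experiment takes ~2 s, and use
12-patient cohorts with N = 144 for the structural pipeline tests; the
reliability-direction experiment aggregates 20 seeds at full scale with the
fixed default ensemble (bagging, 60 trees, depth 4) rather than the full
50-iteration model search, since the manual-versus-ML comparison does not
depend on which ensemble family wins. Oracle cross-checks use 50 random
rating tables (alpha), 100 tables (ICC) and 1000 random posteriors
(decision rule). Every stochastic step — cohort, SMOTE, shuffling, fold
assignment, training resamples, the optimizer — derives its stream from a
single master seed, and reports are byte-identical under a fixed seed.

## Known limitations

* The generator's clean grade-to-kinematics mapping overstates feature
  informativeness; ML reliability indices on synthetic cohorts are upper
  bounds, not clinical estimates.
* The auto-reference of the angle conversion assumes an initially still
  limb.
* SumOsc on the raw angle absorbs the sensor-noise total variation; at
  much higher sampling rates or noise levels the optional low-pass filter
  should be enabled.
* Alpha confidence intervals (bootstrap) and weighted-kappa variants are
  out of scope.
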