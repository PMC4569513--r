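---
title: "Quantifying limb ischemia and predicting recovery: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying limb ischemia and predicting recovery: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limbperf)
```

`limbperf` turns intraoperative image sequences of an ischemic hind limb
into scalar physiology features and a cross-validated classifier of
functional recovery. This vignette documents the models, the tunable
parameters, the synthetic data the tests rely on, and the design decisions
taken where more than one reasonable choice existed.

## Imaging model

Two modalities are acquired at nominal 5-minute intervals through a
baseline period, an occlusion period (pneumatic tourniquet or direct
vessel clamping; 210 min for the 3.5-hour arms, 282 min for the 4.7-hour
arms), and 30 minutes of reperfusion.

**Oxygenation (3CCD).** For each color frame the region-of-interest mean of
(red − blue) is computed in signed double precision — integer camera
intensities are promoted first, so the subtraction can never wrap. The
series is reported as the percent difference from baseline,
$100\,(v_t - v_0)/|v_0|$, where $v_0$ is the mean over all frames before
occlusion start. Averaging the whole pre-occlusion window is more stable
than any single frame; `extract_profile(baseline = "first_frame")` restores
the single-frame variant. Whether raw or normalized channel values enter
the subtraction is immaterial for the canonical feature because the
percent difference cancels any positive scaling of the channels; both raw
values and percent differences are carried in the profile table.

**Perfusion (infrared).** The ROI mean intensity is mapped to °F by an
affine calibration fitted from reference (intensity, temperature) pairs —
an exact solve for two pairs, least squares for more. The slope must be
positive (warmer tissue is brighter); degenerate pairs are rejected.

**ROI tracking.** The acquisition tool tracks a rectangular ROI through the
sequence. The algorithm here is template matching by normalized
cross-correlation: the template is the previous frame's ROI (re-anchored
every frame, which tolerates slow drift), the search covers integer shifts
up to a quarter of the ROI size in each direction, and ties break toward
the smallest displacement so a static scene reproduces the initial ROI
exactly. The attained correlation, clamped to $[0,1]$, is stored as
per-frame confidence; a zero-variance template (blank frame) falls back to
the previous ROI with confidence 0 and a warning. A consequence worth
knowing: a featureless ROI placed entirely inside a homogeneous region
cannot be tracked — the ROI should straddle visible structure such as the
limb boundary.

## Perfusion features

From each profile, `locate_landmarks()` finds

* the **maximum-ischemia value**: the *minimum* over the occlusion window
  (both R-B and temperature fall during ischemia). The windowed extremum
  was chosen over the final pre-release sample because noise can place the
  true trough earlier; `max_ischemia = "last_pre_release"` selects the
  alternative reading.
* the **maximum-reperfusion value**: the maximum within 10 min after
  release. Capping this window keeps the 30-min PORH slope a decay
  measurement even for signals still rising late in follow-up.
* **post-release readings** at nominal offsets 5/10/30 min, matched to the
  nearest sample within ±2.5 min (half the sampling interval).

The **slope of reperfusion** is the rise from the ischemia minimum to the
reperfusion maximum divided by the time from release to that maximum —
"duration of reperfusion" is not otherwise well defined when the signal
peaks early, and this is the only definition under which a hyperemic
overshoot yields a finite positive slope. A fixed 10-min denominator is
available via `duration = "fixed_10"`. The **PORH slopes** divide the drop
from the reperfusion maximum to each nominal offset reading by the elapsed
time between them; they are negative while the overshoot decays, and they
error (propagated as missing data) when the nominal offset does not fall
after the maximum. With offsets anchored at release, a maximum sitting
exactly on the 5- or 10-min sample makes the corresponding slope
undefined; in real acquisitions the color peak is typically caught between
grid samples (frames can be pulled from continuous video), which is what
the synthetic generator emulates. Because the infrared recovery is
monotone, its window maximum sits at +10 min and the infrared 5- and
10-min PORH slopes are structurally undefined on synthetic cohorts; the
pipeline drops such never-observed columns from the models rather than
imputing them.

Sign conventions: ischemic drops negative, overshoot positive, decay
slopes negative. All slope features are invariant under shifting the value
axis and scale linearly with it.

## Clinical scores and chemistry

Blood urea nitrogen (mg/dL of urea-bound nitrogen) converts to serum urea
as $\mathrm{BUN} \times 10 / 28.02$ mmol/L (two nitrogens of 14.01 g/mol
per urea); analytes are then expressed per mmol urea to guard against
hydration artifacts, with bicarbonate (CO2) deliberately left
unnormalized. Locomotion uses the modified Tarlov scale (0 complete
paralysis … 5 normal gait); **full recovery is Tarlov 5 at day 7**.
Drop-foot is not part of the definition — residual neuropathy can coexist
with a normal gait score, and the recovered group in real data shows a
small nonzero mean drop-foot. Histopathology totals five 0–5 subscores
(edema, inflammation, degeneration, necrosis, regeneration; maximum 25).
Missing draws and scores stay missing in these modules; imputation is the
classifier's responsibility.

## Group statistics

One-way ANOVA (with Bonferroni-multiplied pairwise contrasts, capped at 1)
serves normally distributed comparisons across arms; the Kruskal–Wallis
rank test (tie-corrected, chi-square p) serves ordinal or two-group
comparisons such as recovered vs not recovered. A sample with no variation
at all returns statistic 0 and p = 1 rather than an error. Correlation
screens default to Spearman — the method text's choice; Pearson is kept
available since published tables often report it — with pairwise-complete
deletion and a strict importance flag at $|\rho| > 0.7$. Significance
tiers: `*` < 0.05, `**` < 0.01, `***` < 0.001, and in outcome-summary
tables a dagger for p ≤ 0.1.

## PLSDA classifier

The two classes are coded −1/+1 with "did not return to normal locomotion"
as the positive (detection-target) class. Predictors are mean-centered
only — no autoscaling — and latent variables are extracted by the NIPALS
iteration ($w \propto X^\top y$, $t = Xw$, $p = X^\top t/t^\top t$,
$q = t^\top y/t^\top t$, deflation of both $X$ and $y$); the regression
vector is $b = W(P^\top W)^{-1}q$. One or two latent variables are allowed;
`select_ncomp()` picks between them by cross-validated AUC, ties favoring
the simpler model. Scores at or above the threshold (default 0, the coding
midpoint) are assigned to the positive class, so an exact tie is called
"not recovered" — the conservative call for a screening tool. Requesting a
latent variable beyond the rank of the predictors is an error, as is a
zero-variance predictor block.

Rows missing their outcome, or missing more than 20% of their features
(the threshold is configurable; the source text says only "excessive"),
are excluded and logged; remaining missing cells are imputed by column
means. Cross-validation uses random subsets: 4 folds × 10 iterations,
stratified by class so every fold can be scored (unstratified assignment
is available). Centering and imputation are refit inside each training
fold — the held-out animals never touch them. Sensitivity, specificity and
AUC are averaged over iterations (the headline numbers); pooled
out-of-fold results and the resubstitution ("calibration") fit are
reported alongside. AUC uses the rank-based Mann–Whitney form, giving tied
pairs half credit, and equals the trapezoidal area under the ROC sweep.

A note on mean-centering without scaling: features with large numeric
ranges (LDH, CK) dominate the covariance, so the all-features model can be
*worse* than the imaging-only model when those features carry mostly
noise. This is a real property of the published procedure, reproduced
here, not a defect.

## Synthetic cohort generator

The generator exists so the pipeline can be exercised end to end with
known ground truth. Its defaults encode the emulated study: arms
sham/3.5 h-occlusion/3.5 h-tourniquet/4.7 h-occlusion/4.7 h-tourniquet of
sizes 5/5/5/6/5; 5-min sampling with release snapped onto the grid;
30 min follow-up; arm recovery rates 0.99/0.75/0.75/0.25/0.25; two
expired animals (post-operative data dropped) and two imaging equipment
failures (color sequence truncated at release), leaving 22 usable of 26.
Severity scalars (0 / 1 / 1.4 / 1.7 / 2.1) order the arms: tourniquets
above occlusions, 4.7 h above 3.5 h.

Oxygenation curves fall fast then drift down during occlusion, rise
linearly to a hyperemic peak 1.5–3.5 min after release (carried as one
extra sampled frame), and decay exponentially (τ = 6 min) to a small
residual — above baseline at +10 min, near baseline at +30. Temperature
falls linearly during occlusion and recovers monotonically with no
overshoot; 4.7-hour arms recover only 55–75% of the drop within follow-up
and end below baseline. Chemistry follows log-time bumps with amplitudes
proportional to severity (CK/AST/LDH peak at day 1, ALT at day 3, BUN
3 h post-release, a bicarbonate nadir before 24 h, potassium still climbing
at day 7) under multiplicative log-normal noise; cytokine columns are pure
noise by design. Rendered frames draw the limb as a warm, high-R-B ellipse
on a neutral background — enough to exercise tracking and channel math, with
no anatomical realism; optional per-frame drift exercises the tracker.

Recovery is drawn from a logistic link on the two discriminative imaging
features (infrared whole-leg value at +5 min and the 3CCD PORH decay
slope), standardized within arm, with effect size β (default 2). The
per-arm intercept is calibrated numerically so the marginal recovery rate
matches the configured arm rate at any β; at β = 0 with equalized arm
rates the outcome is independent of the features. Analytic ("true")
feature values of the noise-free curves are stored with every cohort, and
at noise 0 the pipeline recovers them to float round-off.

What passing tests on this generator do **not** show: robustness to
anatomical appearance, camera motion beyond slow drift, lighting or
white-balance drift, real biochemical covariance between analytes, or
outcome mechanisms other than the built-in logistic link. The generator
validates the machinery, not the biology.

## Numerical choices and problem sizes

All randomness flows through explicit integer seeds; identical seeds give
byte-identical outputs, including written CSV/JSON artifacts. Tracking
ties break toward zero displacement; landmark ties toward the earlier
sample. NIPALS declares rank exhaustion below 1e−12 on weight or score
norms. The validation suite sizes its simulations to run on one CPU in a
few minutes: 10,000 replicates for the null calibration of the group tests
(n = 22, two groups), 250 permutations for the classifier's permutation
null (the per-permutation CV AUC has sd ≈ 0.14 at n = 22, so the mean
needs that many draws for a Monte-Carlo error well under the 0.05 band),
20 replicate cohorts per effect size for the β-monotonicity and
model-ordering checks.

## Known limitations

* Tracking assumes approximately rigid translation between consecutive
  frames; rotation and deformation are unmodeled.
* The PORH slopes depend on where the reperfusion maximum falls relative
  to the nominal offsets; sparse sampling near the peak makes early
  offsets undefined (kept as missing data, by design).
* PLSDA here is strictly two-class with 1–2 latent variables and no
  variable-importance scores.
* With 22 animals, cross-validated metrics are noisy (AUC sd ≈ 0.1 between
  reruns with different fold seeds); conclusions should rest on replicate
  cohorts, as the acceptance checks do.
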