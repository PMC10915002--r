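---
title: "Classifying spontaneous pain states from S1 calcium traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying spontaneous pain states from S1 calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Spontaneous (non-evoked) pain is the clinically dominant complaint in
chronic pain, yet preclinical assays mostly measure evoked responses, or
rely on behavioral paradigms (conditioned place preference) that need
intact learning and reward circuits. `painstate` implements an
explainable alternative: read the state of the animal directly from
primary somatosensory cortex (S1) population activity. Layer 2/3 neurons
are imaged through a cranial window with a slow genetically encoded
calcium indicator (GCaMP6s) at roughly 5 Hz while the head-fixed mouse
behaves on a treadmill; a 30 fps infrared video provides a motion-energy
trace from which movement and stationary epochs are segmented. Each
recording session, reduced to one fluorescence time series per ROI
(segmented neuron), is classified into one of three states: **non-pain**
(baseline, sham, vehicle), **pain** (inflammatory, neuropathic, chemical,
or Parkinsonian models), or **drug-induced analgesia**. The analgesic
state is a separate class because cortical activity under analgesics does
not simply revert to baseline — it shows its own signature, and a binary
model would misread it.

## Preprocessing

Per ROI, the raw trace is convolved with a unit-sum Gaussian window of
size 29 frames (reflect padding, $\sigma = (29-1)/6$ frames so $\pm 3
\sigma$ spans the window). The baseline of a trace is tied to its 30th
percentile: every frame whose smoothed value lies at or below that
percentile is a baseline frame, and $\mu$ and $\sigma$ are the mean and
standard deviation over that frame set. Two normalizations are applied:

$$\Delta F = \frac{X - \mu}{\mu}, \qquad Z = \frac{X - \mu}{\sigma}.$$

One ambiguity is worth naming: a percentile is a single number, but a
standard deviation "of baseline signals" needs a *set* of baseline
frames. We therefore take the sub-percentile frame set as the baseline
(mean and sd over it), and expose the alternative — $\mu$ as the
percentile value itself — behind `baseline_mode = "percentile-value"`.
The default is the frame-set mean, because it makes the two formulas
internally consistent with a single baseline definition.

Movement segmentation thresholds the video-rate motion energy (a frame is
movement-positive iff energy strictly exceeds the threshold, which in
practice is set by a blinded experimenter) and maps flags down to the
imaging clock: an imaging frame is movement-positive if any video frame
starting within its inter-frame interval is. "Total" means all frames
regardless of the mask.

## The D statistic and the 13 features

For an evaluation session A and a same-subject reference session B with
$n$ matched ROIs, let $X_i$ be ROI $i$'s mean normalized signal over a
frame subset, floored at zero. The activity share of ROI $i$ is
$X_i / \sum_j X_j$, and

$$D_i = \left(\frac{X_i}{\sum_j X_j}\right)_{\!A} -
        \left(\frac{X_i}{\sum_j X_j}\right)_{\!B}.$$

Cells with $D_i > 0.3$ are *up-regulated*, cells with $D_i < -0.2$
*down-regulated*; the two ratios (counts over $n$) are the features.
Crossing normalization ($Z$, $\Delta F$) with frame subset (movement,
stationary, total) gives $2 \times 2 \times 3 = 12$ ratio features, and
the mean pairwise Pearson correlation between ROIs across the whole
session is the 13th.

Three consequences of this construction shape everything downstream:

* **Conservation.** Shares sum to one in each session, so
  $\sum_i D_i = 0$ and the positive mass of $D$ is at most 1. At most
  $\lfloor 1/0.3 \rfloor = 3$ cells can exceed the up threshold
  simultaneously, and at most 4 can sit below $-0.2$: observed up/down
  ratios are intrinsically small fractions, and planting many
  simultaneous strong up-cells makes each one *harder* to detect.
* **Only dominant cells are visible.** A cell can only lose 0.2 of share
  if it held it, and can only gain 0.3 of share by coming to dominate the
  session. The statistic is sensitive to changes in the few
  highest-amplitude cells, not to diffuse rate shifts.
* **The percentile baseline compresses tonic changes.** A tonically more
  active cell raises its own 30th percentile, so sustained rate increases
  partly normalize away; episodic, large-amplitude activity is what moves
  shares.

Design choices within this operation: $X_i$ is the subset **mean** (not
sum), so movement and stationary subsets of unequal length are
comparable; negative normalized means are floored at zero because shares
must form a distribution (signed alternatives are noted as open);
the correlation feature is computed once, on the smoothed
$\Delta F$ traces of session A over all frames, since only one
correlation feature exists in the feature list. The asymmetric
thresholds $+0.3/-0.2$ are fixed defaults, exposed as configuration. The
reference session B is, by default, the subject's dedicated pre-treatment
baseline recording; a session is never paired with itself (that pair has
an identically zero $D$).

If a session has no movement (or no stationary) frames, the three
affected features become `NA` sentinels and are imputed with
training-set column means inside each cross-validation fold, keeping
fold membership intact without leaking test information.

## Screening, reduction, classification

Each feature is screened by the ROC-AUC (Mann–Whitney $U/(n_1 n_2)$,
ties counted half) for three contrasts: baseline vs. pain, pain
vs. analgesics, and pain vs. analgesics plus baseline, pooling raw
sessions. The screen is diagnostic only; all 13 features go forward.

Features are standardized with training statistics and reduced by PCA
from 13 to 6 components; all six are used. The classifier is a dense
network — one hidden layer (default 8 rectifying units via
`nnet`), softmax head, cross-entropy loss with inverse-class-frequency
weights, BFGS optimization, deterministic under a fixed seed. The
hidden size, weight decay, and iteration cap are configuration. The
*predicted pain value* of a session is the softmax probability of the
pain class.

**False-label management.** Spontaneous pain cannot be guaranteed
present throughout every pain-labeled recording. A model trained on the
full training set scores all pain-labeled sessions, and the
`floor(0.10 * n_pain)` sessions with the lowest predicted pain values
are removed before the final fit; other classes are never touched, and
boundary ties break by session-id order for determinism. The removal
pass runs once by default (`filter_iterations` exposes deeper
recursion, since the recursion depth is not otherwise pinned down).

**Validation** is leave-one-subject-out: all sessions of one animal form
the test fold, and the false-label filter, the imputation means, the PCA,
and the classifier are fitted strictly on the remaining subjects. The
test suite enforces this as an invariant: arbitrarily corrupting a
held-out subject's features and labels leaves that fold's fitted model
bit-identical.

## The synthetic cohort generator

No public recordings accompany this pipeline, so `generate_cohort()`
produces cohorts whose statistical structure matches what the analysis
assumes, with a ground-truth sidecar (planted ROI sets, bout intervals,
motion threshold, per-ROI multipliers) emitted for oracle tests.

Per session: locomotion bouts arrive as a Poisson process (default 5
bouts/min of 4 s — a treadmill mouse moving about a third of the time)
and drive both a video-rate motion-energy trace and the imaging-frame
movement mask; per-ROI calcium events are Poisson (default 0.08 Hz per
ROI) and are convolved with a double-exponential kernel (rise 0.2 s,
decay 1.5 s — typical GCaMP6s kinetics; the indicator is named in the
experimental design but its kinetics are configurable here); a common
smooth latent drive added to all ROIs with a state-dependent weight sets
the mean pairwise correlation (default 0.05 for non-pain and pain, 0.15
for analgesia, where the correlation level is distinctively shifted);
Gaussian noise is added and fluorescence floored at zero.

Heterogeneity is deliberate and is the part that matters most:

* **Amplitude ladder.** Per-ROI transient amplitudes follow a fixed
  log-normal quantile ladder (log-sd 1.8), permuted per subject. A few
  high-amplitude cells therefore dominate total activity in every
  subject — the regime in which the D statistic operates at all (see the
  conservation notes above). Drawing amplitudes independently instead
  leaves occasional subjects with flat profiles in which no planted
  effect is geometrically detectable.
* **Session gain.** Every session re-draws a per-ROI gain (log-sd 0.45),
  emulating longitudinal recording variability (window clarity, focus,
  expression drift). This is what gives *baseline* session pairs their
  natural nonzero up/down ratios; without it, null-cohort ratio features
  are identically zero and the feature matrix is rank-deficient.
* **Planted state effects.** For each state and movement condition, a
  configured fraction of ROIs has its event rate multiplied (up) or
  divided (down) by `effect_size`. Identities are fixed per subject
  across sessions (matched-ROI modulation must be consistent for D to
  see it); down-cells are drawn from the highest-amplitude cells (only
  they have share to lose) and up-cells from the adjacent band,
  interleaved so the two pools are amplitude-matched and disjoint.
  Default fractions keep planted up-sets small (pain: 7% during
  movement) because of the simultaneity bound above; pain raises up- and
  down-regulation during movement and mainly down-regulation when
  stationary, while analgesia keeps its own movement up-shift, returns
  down-regulation toward baseline, and shifts the correlation level.

No quantitative effect sizes are published for these ratios, so the
defaults are free parameters of the generator, chosen once for
plausibility and detectability rather than calibrated to any in-vivo
dataset. What passing tests show is therefore that the *pipeline*
recovers structure it was told to plant — not that real S1 data contains
that structure at those magnitudes. The generator also makes no attempt
at pixel-level imaging, neuropil contamination, slow photobleaching, or
correlated motion artifacts; it consumes none of the upstream
registration/segmentation machinery.

## Numerical choices and degenerate inputs

* Percentiles use linear interpolation; ties at the percentile value are
  included in the baseline set.
* A constant (zero-sd) baseline makes Z scoring undefined and a zero
  baseline mean makes delta-F/F undefined; both fail with the ROI index
  named. Zero-variance ROIs are excluded from the correlation feature
  with a warning; fewer than two usable ROIs is an error.
* Shares whose total is at or below `1e-8` after flooring raise a
  degenerate-session error rather than returning noise-dominated ratios.
* `up + down + stable` is exact (not just near 1): the stable ratio is
  computed as `1 - (up + down)`.
* PCA demands at least 7 training rows and at least 6 nonzero singular
  values; rank-deficient feature matrices fail with the rank named.
* All randomness descends from one root seed, fanned out deterministically
  per subject, session, fold, and stage; two runs with the same
  configuration and seed produce bit-identical results bundles.

## Validation scale

The bundled validation runs at desk scale, chosen to finish in minutes
on one CPU while keeping sampling noise tolerable: parameter-recovery
cohorts use 10 subjects with 3 sessions per state per subject (90
evaluation sessions plus 10 reference recordings; 30 ROIs, 240 s at
5 Hz), a strong-effect condition of `effect_size = 20` against a matched
null (`effect_size = 1`, state-independent drive), and the
pooled leave-one-subject-out pain-vs-rest AUC as the summary. The
property suites use 1000 randomized session pairs for the conservation
checks and 100 random instances for each oracle-equivalence check.

## Known limitations

* The ROI map between sessions is an input (identity for synthetic
  cohorts); real longitudinal ROI matching is out of scope.
* AUC figures obtained on synthetic cohorts characterize the pipeline's
  recovery behavior under the generator's assumptions and say nothing
  about in-vivo effect sizes.
* The single-hidden-layer classifier is intentionally small; with tens
  of sessions and six inputs, capacity is not the binding constraint,
  and the architecture is swappable through configuration.
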