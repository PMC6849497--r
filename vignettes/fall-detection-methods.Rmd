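---
title: "Fall detection by multi-sensor classifier fusion: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fall detection by multi-sensor classifier fusion}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(falldetect)
```

## The problem and the decision system

A chest-worn unit streams tri-axial acceleration (m/s²) and angular
velocity (rad/s) at a nominal 10 samples/s, plus video frames from a
wearable camera that is normally idle. The task is binary at the system
level — fall versus non-fall — but the sensor classifiers are trained on six
motion classes (still, lying down, sitting up, standing up, bending, fall),
because distinguishing the ADLs from each other reduces the chance that an
energetic ADL is mistaken for a fall.

Each whole recording is one classification window. Its feature vector is
the six per-axis signal powers, defined here as the *mean-square* sample
value per channel. The mean-square (rather than a sum of squares) is a
deliberate choice: it makes the feature invariant to recording length, so
trials of different durations are comparable points in the same 6-D space.
No detrending or gravity removal is applied; the ±1.5 m/s² ADL envelope is
interpreted on the raw signal.

Three binary votes are fused by a majority gate (fall iff ≥ 2 votes):

* **k-NN** on the 6-D features, Euclidean distance, no feature scaling.
  The accel-power and gyro-power coordinates differ by orders of magnitude,
  which means distance is dominated by gyro power; that asymmetry is
  accepted as-is because the fall signature lives precisely there.
* **Gaussian naive Bayes** with per-class per-feature means and standard
  deviations (denominator n−1) and empirical class-frequency priors.
* **Visual frame differencing**, consulted only when the camera trigger has
  fired (any |gyro| sample > 120 rad/s or |accel| sample > 1.5 m/s²).

When the camera stays idle — or frames are missing despite a trigger, which
is logged as a warning — the visual vote is fixed at 0. The gate is always
3-input; a fixed-0 third input is the only consistent reading of an idle
camera, and it means a sensor-only fall verdict requires both k-NN and
naive Bayes to agree.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| sampling rate | 10 | samples/s | nominal rate of the sensing chip |
| recording duration | 5 | s | long enough to contain one motion event |
| ADL accel envelope | 1.5 | m/s² | observed ADL bound; camera trigger level |
| ADL gyro envelope | 120 | rad/s | observed ADL bound; camera trigger level |
| fall spike factor | 2.5 | × gyro envelope | "large margin" above the trigger |
| fall spike width | 0.5 | s | transient duration of an impact |
| visual threshold | 7 | % | empirically determined fall threshold |
| k candidates | odd 1–15 | — | odd k reduces vote ties; range is a package choice |
| CV folds | 5 | — | standard small-sample choice |
| variance floor | max(σ, 1e-6·global SD, 1e-12) | feature units | prevents density blow-up on constant features |

The gyro unit deserves a note: ±120 rad/s is physically unusual for MEMS
gyroscopes (most saturate near ±35 rad/s), but the stated thresholds are
followed verbatim; all internal consistency (trigger, spike factor,
simulator envelopes) is relative to these bounds, so the unit convention
cancels out of every decision.

## What the simulator emulates — and what it does not

No public dataset accompanies the system this package replicates, so a
seeded generator stands in for the human-subject recordings. It reproduces
the *statistical contract* the classifiers rely on, not biomechanics:

* **ADL classes** are one raised-cosine bump per channel (occupying the
  middle half of the window) with a class-specific amplitude — fractions
  0, 0.2, 0.4, 0.6, 0.8 of the envelope for still, lying down, sitting up,
  bending, standing up — and a class-specific channel mixing pattern, plus
  white Gaussian noise. The amplitude ordering and channel patterns make
  the five ADLs mutually distinguishable in power space, mirroring the
  per-class differences in false-positive rates that real trials show.
  Raised cosines were chosen because their power is analytically
  checkable (a bump of peak A over fraction w of the window contributes
  3A²w/8 to the mean-square).
* **Noise** is specified per sensor, 0.05 m/s² (accel) and 2 rad/s (gyro):
  a single "channel-unit" noise level cannot serve two sensors whose
  scales differ by two orders of magnitude. Non-fall samples are clipped
  at 99.5% of the envelope after noise injection, so the envelope
  invariant holds for *every* generated sample rather than merely with
  high probability.
* **Falls** are an ADL-like baseline plus a 0.5 s transient on one gyro
  axis whose peak *sample* reaches 1.05 × 2.5 × 120 rad/s — the sampled
  bump is rescaled so the guarantee holds even when the bump centre falls
  between sample instants, and the 5% headroom keeps noise from pulling
  the maximum back under 300 rad/s.
* **Frame sequences** are a static luminance gradient with a ±2% global
  drift per frame (ADL) versus a one-step 25% scene shift (fall),
  plus unit-SD pixel noise, clipped to [0, 255]. This matches the
  classifier's consecutive-difference statistic by construction.
* Per-recording seeds are derived from the base seed by a fixed integer
  hash of (seed, class index, trial index), so corpora are reproducible
  and recordings mutually independent.

Consequences for interpretation: because fall gyro power exceeds every ADL
gyro power by construction, the synthetic classes are close to linearly
separable and the end-to-end protocol typically scores near 100% — the
tests therefore demonstrate *correctness of the pipeline and the stated
lower bound*, not field performance. Real falls (tripping without rotation,
sensor detachment, near-envelope ADLs) are not represented, and neither is
camera optics: passing here says nothing about those failure modes.

## Numerical choices

* **Posterior computation** is done in log space with a log-sum-exp
  normalisation. A product of six Gaussian densities underflows easily;
  the explicit `evidence()` operation exists to mirror the textbook
  total-probability formula and for testing, but `posterior()` never
  multiplies raw densities. The evidence sum is read as the prior-weighted
  *joint* likelihood over all six features, per its surrounding
  definition ("total probability of all the features given each class").
* **k-NN ties**: all points at the k-th distance vote (order-independent);
  a class vote tie goes to the smaller summed voter distance, then to the
  earlier class in the fixed enumeration. `select_k` ties go to the
  smaller k — the less complex model, consistent with the usual
  over/underfitting argument.
* **Thresholds are strict inequalities**: a sample exactly at ±120 rad/s
  does not trigger the camera, a frame difference of exactly 7% is not a
  fall ("exceeds" is read literally).
* **Cross-validation folds** are stratified by class under a recorded
  seed; unstratified folds could leave a fold without some class,
  making per-class error undefined.
* Degenerate inputs are rejected at construction (windows with fewer than
  two samples, non-uniform timestamps, frames of mismatched shape,
  classes with under two training points), not at use.

## Problem sizes

The shipped tests train on corpora of 8–40 trials per class and evaluate
the full protocol at 40 trials/class training and 100 trials per scenario
(1000 test recordings), the same sizes the reference trial protocol uses;
the whole suite and the acceptance script each complete in well under a
minute on a single CPU.

## Known limitations

* The simulator is intentionally minimal; it validates the decision
  system, not sensor physics or human biomechanics.
* The per-trial (whole-recording) windowing follows the reference
  protocol; streaming sub-window detection is out of scope.
* The visual difference metric (mean absolute pixel difference, % of full
  range) is one reasonable reading of "percentage difference between
  consecutive frames"; the threshold argument of `visual_classify()`
  makes the boundary explicit, and alternative metrics can be slotted in
  at the call site.
* Notification delivery (the original system tweets) is reduced to
  structured event lines written by `cmd_classify()`.
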