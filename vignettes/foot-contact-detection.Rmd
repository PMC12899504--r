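---
title: "Detecting foot contacts in high-dynamic movements from inertial sensors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting foot contacts in high-dynamic movements from inertial sensors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Biomechanical analysis of cutting and deceleration movements hinges on
knowing when the foot is on the ground: initial contact (IC) and toe-off
(TO) delimit the stance window from which loading, asymmetry and
injury-risk metrics are computed.  In the laboratory these events come from
a force platform; in the field only wearable inertial measurement units
(IMUs) are available, and gait-oriented event detectors break down in
high-dynamic, multidirectional tasks such as a 90° sidestep cut (COD) or a
sprint with deceleration (DEC).

`fcdetect` implements a peak-pattern detection chain for exactly this
setting: two single-signal detectors, a hybrid combination, the
force-platform reference rule they are validated against, the agreement
statistics of a concurrent-validity study, and a seeded synthetic-trial
generator that plants known events so every stage can be tested
quantitatively without access to laboratory recordings.

## Signals and reference

A trial bundles three synchronized channels on one clock: the vertical
ground reaction force (vGRF, nominally 1000 Hz), the pelvis vertical
velocity (PVV, 60 Hz, from the pelvis-mounted sensor's fused output), and
the triaxial foot linear acceleration (60 Hz), whose per-sample Euclidean
norm is the resultant foot acceleration (RFA).

The reference stance window is read off the vGRF: IC is the first frame in
which the force *exceeds* 50 N, TO the first subsequent frame in which it
*drops below* 50 N.  The inequalities are strict; samples exactly at the
threshold trigger neither event.  Real plates ring near the threshold, so a
debounce (`min_contact_s`, default 50 ms) skips supra-threshold windows
shorter than a plausible contact; setting it to 0 restores the literal
rule.  When several windows survive, the longest is returned, mirroring the
detectors' longest-contact rule.  Whether the plate signal should be
filtered before thresholding is an open question in the field; `fcdetect`
thresholds the raw vGRF.

## The three detectors

All detector signals are first smoothed with a low-pass third-order
Butterworth filter at 20 Hz.  The filter is applied forward and backward
(zero phase): a causal 3rd-order/20 Hz filter at a 60 Hz rate would delay
events by several samples and bias every offset, so zero phase is the
default (a causal mode remains available for sensitivity checks).
Boundaries are handled by odd reflection so that no spurious extrema appear
near the edges; a monotone input stays monotone.

Candidate extrema are strict sign changes of the first difference with a
prominence floor of `min_prominence_frac` (default 5%) of the filtered
signal's range; the floor suppresses noise-born micro-peaks that the bare
"all local extrema" definition would admit.

**PVV detector.**  Local minima of the filtered pelvis vertical velocity
are candidate ICs and local maxima candidate TOs.  For each candidate IC
(in time order), candidate TOs after it are examined and the first one
accepted for which (1) the TO follows the IC, (2) a descent follows the TO
— the derivative of the filtered signal drops below −0.1 m/s² at some
sample after the TO and before the next candidate TO — and (3) the TO is
the highest candidate maximum between the IC and that descent onset.  The
descent threshold is stated in the source material in m/s² although it
gates the derivative of a velocity; `fcdetect` reads it as an SI
acceleration applied to the central-difference derivative of the filtered
60 Hz signal.  The search window for the descent (up to the next candidate
TO) and the comparison set for condition (3) (candidate maxima in the
IC–descent interval) are the package's own completions of rules whose
bounds the original description leaves open.

**RFA detector.**  Candidate peaks are prominent local maxima of the
filtered resultant acceleration.  For each candidate IC peak, later peaks
are scanned in order: peaks below 30 m/s² are not eligible toe-offs and are
discarded; the first eligible peak whose inter-peak valley drops below
`u_shape_frac` (default 0.5) times the lower of the two peak heights is the
TO.  The valley condition operationalizes the characteristic "U shape" of
the stance phase between the impact and push-off spikes; the 0.5 factor is
exposed in the configuration.

Both detectors enumerate *all* acceptable (IC, TO) pairs; the pair with the
longest duration is the reported contact (ties go to the earlier IC),
because in a COD/DEC trial the platform step is the long stance amid
shorter running steps.  An empty candidate set is reported as a failure
flag, never as an error.

**Hybrid detector.**  The foot-acceleration detector is the primary source
for both events.  If it fails, the pelvis detector's result is returned
(`PVV_BOTH`).  If it succeeds but the filtered acceleration at its IC falls
below the 60 m/s² gate — a soft landing without a sharp impact spike — the
IC is replaced by the pelvis-detected IC while the TO remains
acceleration-based (`PVV_IC_RFA_TO`); when that substitution would invert
the window (pelvis IC at or after the acceleration TO) or the pelvis
detector failed, the acceleration result is kept unchanged.  The gate value
is read from the same filtered signal the detector searches.

## Agreement statistics

Offsets are `reference − detected` in milliseconds, so positive means the
detector fired early.  Summaries report the median and quartiles (linear
interpolation between order statistics, `quantile` type 7), the IQR, the
mean and SD (n−1), Bland–Altman limits of agreement `mean ± 1.96 SD`, and
the number of offsets outside the limits as the outlier count.  Failed
detections are excluded from summaries and reported as separate counts.

The error model is `offset ~ task + sex + leg + (1 | participant)` with
DEC/female/dominant as reference levels, fit by REML with Satterthwaite
p-values.  The adjusted R² and overall model p are computed on the
fixed-effects-only least-squares fit; this marginal convention can produce
small negative adjusted R² for null models, which is expected behaviour,
and is the package's own choice among the several R² definitions in use
for mixed models.  Pearson correlations probe error sources (movement
speed for the pelvis signal, acceleration magnitude for the foot signal).

## What the synthetic generator emulates

Each generated trial plants an IC/TO pair analytically and builds the three
channels from smooth parametric bumps (Gaussians and a logistic drop) —
waveform *landmarks*, not biomechanical simulation:

* **vGRF**: a Gaussian stance bump whose 50 N crossings fall exactly at the
  planted times, with peak forces of 1.5–2.2 kN and 1 N sensor noise.
* **Pelvis vertical velocity**: a landing trough, a push-off peak and a
  steep post-toe-off descent over a faint 0.35 Hz oscillation, with 0.01 m/s
  noise (fused velocity outputs are smooth).  The trough minimum is planted
  8 ms (half an IMU sample) after the true IC — the pelvis decelerates
  slightly after touchdown — which reproduces the later-IC tendency of
  pelvis-based detection while keeping noise-free recovery within one
  sample.
* **Foot acceleration**: a fixed random unit direction scaled by a
  resultant profile with an impact peak at IC and a push-off peak at TO
  (90 ± 12 m/s², truncated at 70) over a ~3 m/s² baseline, with 1.5 m/s²
  per-axis noise.  IC peak heights follow the study conditions
  (94.6 ± 36.8 m/s², truncated below at 5); 17.5% of trials are
  *low-acceleration* (soft-landing) trials whose IC peak is drawn below
  57.8 m/s².  Peak sharpness degrades continuously as the peak height
  falls below 75 m/s² — small peaks are broad loading humps centred
  slightly (≤ 6 ms) after touchdown rather than impact spikes — which is
  the mechanism behind both the negative correlation between acceleration
  magnitude and IC reliability and the hybrid gate's usefulness.
* **Distractor steps**: ordinary sharp-impact trials may carry a preceding
  shorter running step; its stance and the flight gap to the main step are
  both strictly shorter than the main stance, so the longest-contact rule
  stays identifiable.  Soft-landing trials are generated without
  distractors: a broad loading peak next to a distractor's push-off peak
  would fill the inter-peak valley and make the planted configuration
  ambiguous even without noise.

Stance durations are drawn from 478.3 ± 162.1 ms truncated at ±2 SD
(symmetric truncation keeps the mean unbiased).  Planted task/sex/leg
effects shift the IMU-visible landmarks relative to the vGRF truth;
optional trigger jitter shifts the whole IMU clock.

Under zero noise every generated trial is solved by all three detectors to
within one IMU sample — the generator/detector contract the test suite
enforces.  The generator does **not** emulate soft-tissue artifact, sensor
drift, orientation error, or the true waveform families of human movement;
passing tests therefore demonstrate algorithmic correctness and the
documented qualitative behaviour (hybrid best at IC on cohorts rich in soft
landings), not field-level accuracy on real athletes.

## Numerical choices and problem sizes

Sample indices are 0-based; event times are seconds on the shared trial
clock.  Cross-rate event mapping uses nearest-sample rounding with half-up
midpoints.  Rate conversion low-pass filters at 90% of the target Nyquist
(zero phase) and interpolates at the target sample times, preserving `t0`
and DC exactly.  The derivative is a central difference (one-sided at the
ends).  CSV interchange writes 12 significant digits, so round trips are
faithful to better than 1e-9.

The packaged checks run at deliberately desk-friendly sizes chosen to keep
the full suite under a minute while leaving no behaviour untested: 200-trial
cohorts (25 participants × 8 trials) for event-recovery and ordering
checks, 200 random signals against the brute-force candidate oracles, and
100-seed simulations at the study scale (34 × 8) for mixed-model
calibration.

## Known limitations

* The detectors assume one dominant stance per trial; long continuous
  captures need prior segmentation.
* Thresholds (50 N, −0.1 m/s², 30 m/s², 60 m/s²) were tuned for COD/DEC
  tasks; other movements likely need re-tuning, which the configuration
  exposes but the package does not attempt.
* The pelvis descent threshold of −0.1 m/s² is small relative to the
  derivative noise of real 60 Hz signals, so the descent condition is
  nearly always satisfiable under noise; the prominence floor is what keeps
  the candidate set clean.  Analyses of threshold sensitivity should vary
  `min_prominence_frac` jointly.
* Negative adjusted R² values from the marginal fit are reported as-is.
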