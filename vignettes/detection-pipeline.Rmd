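---
title: "Detecting cigarette drags and smoking instances from wrist IMU data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cigarette drags and smoking instances from wrist IMU data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The detection model

Smoking a cigarette produces a stereotyped motion signature on the
dominant wrist: a quick rotation raising the hand to the mouth, a
still hold while inhaling, the reverse rotation away, and then the
same cycle repeated every half minute or so until the cigarette is
finished. `puffr` encodes exactly that structure as a three-stage
pipeline over uniformly sampled 6-axis IMU data (accelerometer in
m/s², gravity-inclusive; gyroscope in rad/s; nominal 100 Hz):

* **Stage 1** reduces the raw stream to discrete *motion features*.
  Two complementary mechanisms are used, reflecting what each sensor
  measures best. The gyroscope magnitude is binned and thresholded
  into a moving/stationary mask — stillness is a gyroscope property —
  and stationary runs with an elevated gravity pitch become DWELL
  (hand-stationary-at-mouth) events. The transient raise and lower
  gestures are recognised by a decision-tree classifier over
  short accelerometer/gyroscope summary windows.
* **Stage 2** assembles RAISE → DWELL → LOWER triplets into single
  drag detections, accepting only raises lasting 0.3–0.7 s and dwells
  lasting 0.4–8.0 s (closed intervals), with at most 0.5 s between
  consecutive pattern elements. The lower phase is deliberately
  unconstrained in duration: moving the hand away is required, how
  fast is not informative.
* **Stage 3** designates a smoking instance whenever at least six
  drags occur with every consecutive inter-drag interval strictly
  under 80 s. A gap of 80 s or more resets the run; a run longer than
  six drags is one episode, not several.

The stage-2/3 constants are the pipeline's reference operating point
and are exposed in `drag_thresholds()` and `session_config()`; nothing
in the implementation hard-codes them, which is what lets the test
suite recover each of them as an empirical decision boundary.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `rate_hz` | 100 | Hz | nominal sensor rate; irregular input is linearly resampled first |
| `window_s` / `hop_s` | 0.2 / 0.1 | s | windows short enough to resolve a 0.3 s raise, 50% overlap |
| `gyro_bin_s` | 0.1 | s | stationarity decided at the same 0.1 s granularity |
| `gyro_threshold_rad_s` | 0.5 | rad/s | raises/lowers peak at several rad/s; sensor noise sits far below |
| `min_dwell_quiet_s` | 0.3 | s | shorter quiet spans are inter-gesture transitions, not holds |
| `dwell_pitch_min_rad` | 0.6 | rad | separates hand-at-mouth stillness from a resting hand (pitch ≈ 0) |
| `raise_min_s`..`dwell_max_s` | 0.3/0.7/0.4/8.0 | s | the drag pattern's published duration bounds |
| `max_feature_gap_s` | 0.5 | s | "followed by" tolerance between pattern elements |
| `min_drags`, `max_gap_s` | 6, 80 | –, s | the session rule |
| `instance_tolerance_s` | 60 | s | event-matching tolerance for instance-level scoring |
| `kappa_bin_s` | 600 | s | unit of agreement for diary comparison |

Stage-1 values are this package's calibration choices (the temporal
pattern stages, not stage 1, carry the published constants); all are
config-exposed and embedded in trained classifiers, and detection
refuses a classifier whose training `window_s`/`hop_s` disagree with
the requested configuration.

## Design decisions

**DWELL requires posture, not just stillness.** A resting wrist is
stationary for minutes at a time; emitting every quiet run as DWELL
would label idle recordings as hand-at-mouth holds. A dwell is
therefore a quiet run *and* an elevated gravity-pitch estimate
`atan2(mean a_x, mean a_z) ≥ 0.6` rad over the run — stationarity from
the gyroscope, posture from the accelerometer. This also keeps stage-1
output for a clean two-drag recording to exactly six events
(R, D, L, R, D, L).

**The tree is retrainable; a rule fallback exists.** An on-device
deployment would fix the window classifier on participant training
data; no such data ships with this package, so `puffr` defines its own
feature vector (per-axis mean/SD/min/max/energy + axis-pair correlations),
trains on simulator output (`train_default_classifier()`), reports
held-out per-class accuracy, and serialises the result with its
configuration. `rule_window_classifier()` (sign and magnitude of the
mean pitch rate) is a transparent, training-free alternative.

**Windows merge only when adjacent.** Same-label windows one hop apart
merge into an event whose bounds are the window-centre span padded by
half a hop; with 0.1 s hops this recovers clean gesture boundaries to
within one hop, which matters because stage 2 then measures durations
against 0.3–0.7 s bounds.

**Inter-drag intervals are start-to-start.** "Time between drags" is
ambiguous; start-to-start is robust to variable dwell lengths and is
the default (`gap_mode = "end_to_start"` is available). The 80 s bound
is strict exactly as printed; duration bound checks carry a 1e-9 s
tolerance so that grid-constructed durations are not rejected by
floating-point round-off.

**Event matching maximises pair count.** Detections are matched
one-to-one to truth by decreasing temporal overlap, and the matching
is then completed along augmenting paths so it attains the maximum
achievable number of matched pairs. A pure first-come greedy pass can
strand a prediction whose only admissible truth was claimed by a
prediction that had alternatives, which would miscount both FP and FN;
the augmented matching is still deterministic (overlap order, then
earlier-start tie-breaks).

**Kappa is computed on binned presence.** Diary agreement has no
natural per-event alignment, so detected and true smoking presence are
compared in fixed 10-minute bins; in multi-seed benchmarks bins are
pooled across seeds before computing kappa, which avoids the
degenerate per-seed case of a recording with no smoking at all.

## What the simulator emulates — and what it does not

`simulate_session()` / `simulate_free_living()` generate wrist-pitch
gestures as minimal-jerk rotations: the pitch-rate channel follows
`ω(τ) = (A/T)·30(τ² − 2τ³ + τ⁴)` so it integrates exactly to the
excursion `A`, the accelerometer channels are the gravity projection
of the integrated angle plus i.i.d. Gaussian noise (SD 0.3 m/s²
accelerometer, 0.05 rad/s gyroscope), and walking is an oscillatory
arm-swing bout. Smoking drags draw raise ~ U(0.35, 0.65) s, dwell ~
U(1, 4) s, start-to-start gaps ~ U(20, 60) s — strictly interior to
the detector bounds so boundary tests are unambiguous — with ten drags
per cigarette. Drinking sips (raise U(0.5, 1.0) s, dwell U(1, 3) s)
and eating bites (raise U(0.6, 1.2) s, dwell U(0.2, 0.6) s) share the
raise/hold/lower shape with overlapping duration and pitch ranges, so
stage 1 alone cannot separate them: single sips can and do pass the
stage-2 pattern, and only the stage-3 timing structure rejects them.
Truth smoking instances are labelled by applying the same session rule
to the truth drags. No distributional information about real drag and
gap durations beyond the bounds was available; these ranges are
declared defaults, not estimates.

The simulator does not model sensor bias or drift, roll/yaw motion
during gestures, postural variety (all gestures start from a resting
wrist), chain smoking, non-dominant-hand wear, or the sheer behavioural
diversity of a real 24 h day. Benchmark results on simulated data
therefore demonstrate the pipeline's correctness and its designed
discrimination mechanism — timing structure, not gesture shape — and
are not estimates of human-participant performance, which validations
of wrist-worn detectors on real smokers place substantially lower.

## Numerical and degenerate-input conventions

Resampling is linear interpolation onto a uniform grid anchored at the
first timestamp (idempotent at the stream's own rate). Streams shorter
than one bin or one window yield empty masks/feature tables rather
than errors. Precision and recall are flagged undefined (`NA`) when
their denominators are zero, never reported as 0; accuracy exists only
in laboratory mode, where true negatives are recorded. Cohen's kappa
returns 1 for identical constant sequences (expected agreement 1). All
randomness flows through explicit integer seeds (`withr::with_seed`),
making streams, annotations and CLI outputs byte-identical across
runs.

## Problem sizes used in the shipped checks

The test suite trains the stage-1 tree on three simulated dense
sessions plus background recordings (~20k windows), verifies stage-2
against exhaustive triplet search on feature sequences of up to 8
events, stage-3 against a maximal-run oracle on 1 000 random drag
sequences of up to 30 drags, and benchmarks the full pipeline over 10
seeds per scenario with 2 h free-living recordings. These sizes keep a
full run in the low minutes on one core while leaving every rule
boundary and oracle comparison exact.

## Known limitations

* Stage-1 defaults were calibrated against the simulator's kinematics;
  real recordings will likely need retraining via
  `train_window_classifier()` on labelled windows and possibly a
  different `gyro_threshold_rad_s`.
* The pipeline is subject-independent by design; no per-user
  adaptation is provided.
* Very long drag runs are reported as a single instance; separating
  back-to-back cigarettes is out of scope.
* Electronic cigarettes, whose drag timing differs, are not covered.
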