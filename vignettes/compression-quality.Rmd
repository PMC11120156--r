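---
title: "Assessing chest-compression quality from pose keypoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing chest-compression quality from pose keypoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cprqa)
```

## The problem and the signal

High-quality CPR is defined by a handful of measurable quantities:
compression depth between 5 and 6 cm, rate between 100 and 120 per minute,
full chest recoil between presses, and straight elbows (extension beyond
165°) so that force is transmitted vertically. `cprqa` estimates all of
these from a single cheap signal: the 2-D image-plane trajectories of six
upper-limb pose keypoints (shoulders, elbows, wrists), time-stamped per
frame. The pose estimator that produces those keypoints is behind an
adapter boundary and never imported; mobile pose models and their quirks
(fluctuating frame rate, per-keypoint confidence, dropouts) are represented
in the data contract instead: every frame carries its own timestamp, and
every keypoint a confidence in [0, 1].

One convention governs everything: **image y grows downward**. The
physically lowest wrist position in a frame is therefore the *maximum* of
the two wrist y values, and a compression moves the wrist toward larger y.
The two "arm" keypoints shown by typical phone overlays are mapped to the
shoulders of the standard 17-point skeleton; that mapping is our decision
(the six displayed upper-limb points are consistent with
shoulders/elbows/wrists) and is isolated in one place, `KP_NAMES`.

## Press detection

The heart of the package is a three-state machine over the lowest-wrist-y
signal (`detect_presses()`, one frame at a time via `detector_step()`):

* **State 0 — rest.** The resting height `initialHeight` is tracked (as
  the running mean of rest samples, which is unbiased under pixel noise)
  until the wrist starts moving down.
* **State 1 — first descent.** The descending extreme is tracked; when the
  wrist turns upward having exceeded `start_threshold_px` (default
  15.5 px) below `initialHeight`, the press start is anchored at that
  bottom. Sub-threshold dips return to state 0.
* **State 2 — steady cycling.** The machine first requires the wrist to
  return within `return_threshold_px` (default 5 px) of `initialHeight` —
  full chest recoil arms the next press. Each subsequent bottom that
  returns within `return_threshold_px` of the previous bottom emits one
  press event whose `press_time` is the bottom-to-bottom interval; the
  machine then re-arms in place, so a session yields one event per press
  after the first (n bottoms give n − 1 events).

Anchoring press times at bottoms makes `press_time` a full-cycle period,
consistent with `frequency = 60 / press_time`; a 0.6 s press is 100/min
and 0.5 s is 120/min. Depth divides the bottom's excursion below
`initialHeight` by the calibration (px/cm): the conversion must be supplied
by the user, either directly or as a reference length in frame, since no
monocular system can know absolute scale.

Numerical choices that matter:

* **Hysteresis** (default 1 px): "starts to move down/up" is a sign change
  of the frame-to-frame difference exceeding the hysteresis, suppressing
  jitter flip-flops at the extremes.
* **Parabolic bottom refinement** (default on): the sampled extreme is
  quantised to the frame grid (up to half a frame of error, which at 30 fps
  biases a median frequency by several per minute at rates that do not
  divide the frame rate). A three-point quadratic fit around each bottom
  recovers the sub-frame vertex time and value; the shift is clamped to one
  frame interval for robustness. Refinement runs on the *raw* signal even
  when the optional moving-average smoother (window 3, default off) is
  enabled for state transitions, because smoothing attenuates the true
  press amplitude and would bias depth low.
* **Timeout** (default 3 s): a bottom arriving implausibly long after the
  previous one re-anchors instead of emitting, so no press event spans an
  inter-cycle pause. The source flow defines no pause behaviour; without
  the timeout a 5 s pause would be reported as a single 12/min press.
* **Presence gating**: frames in which any of the six keypoints falls
  below `min_confidence` (default 0.3, the common operating point of
  mobile pose estimators) reset the machine to state 0 — a stale
  `initialHeight` is unsafe after an occlusion.
* Thresholds 15.5/5 px are resolution-dependent constants adopted as
  defaults verbatim; `detector_config()` can rescale them by a px/cm
  calibration for other capture resolutions.

## Per-press metrics and feedback bands

The elbow angle φ at elbow B between shoulder A and wrist C is defined by
the law of cosines, `cos φ = (BC² + AB² − AC²)/(2·BC·AB)`. Two details:
the cosine form must be inverted to the angle (a straight arm must read
180°, not 1, for the 165° threshold to mean anything), and since
`BC² + AB² − AC² = 2(A−B)·(C−B)` exactly, the implementation evaluates the
identical angle as `atan2(|u × v|, u·v)`, which does not suffer the
catastrophic cancellation of the squared-length ratio near collinearity.
Agreement with an independent `acos(u·v/|u||v|)` oracle is tested to
1e-9 degrees on 10,000 random triples.

Band classification uses closed compliant intervals — depth exactly 5 or
6 cm and rate exactly 100 or 120/min are compliant — because the source
material is inconsistent about strictness at the boundaries and a training
device should not scold a trainee for hitting the stated target exactly.
One flow-chart step even says depth "more than 5 cm" is too deep,
contradicting the 5–6 cm standard stated three times elsewhere; we follow
the standard: shallow < 5, ok ∈ [5, 6], deep > 6, all configurable.
Posture is sampled at the press-bottom frame (the moment of maximal load)
and is "normal" only when **both** elbows exceed 165°. Feedback events
carry stable codes (`TOO_SHALLOW`, `TOO_FAST`, `POSE_ABNORMAL`, ...) with
display strings in a configurable catalog, since the source uses two
different phrasings for the same condition; at most one event per
criterion is raised per press.

## Phase classification and cycle tracking

Sessions alternate active compression (CPR) and pauses (UNCPR). The
original system classifies camera images with a two-class softmax network
whose weights are unavailable; we preserve the two-class softmax design but
classify on keypoint-derived *motion* features, keeping the package
self-contained and trainable at desk scale. Windows of 1 s (spanning at
least one compression at any compliant rate) slide with 50% overlap; each
yields wrist-y variance, mean |frame-to-frame delta| and peak-to-peak
amplitude, all normalised by the shoulder-to-shoulder distance so the
features are invariant to image scale. The default classifier is a
deterministic amplitude threshold (0.5 shoulder-widths — compression
amplitudes in realistic geometry are several times it, pause jitter an
order of magnitude below); `train_phase_classifier()` fits an optional
one-hidden-layer tanh network by BFGS on the cross-entropy (reproducible
from its seed, serialised as versioned JSON).

Cycle logic: each UNCPR→CPR transition increments the cycle count, the
session's first CPR onset opening cycle 1. Termination follows the
five-cycle protocol: once `max_cycles` cycles have opened, the session
ends when the final cycle's presses complete — the press count reaching
`presses_per_cycle`, or the phase exiting to UNCPR. The phase-exit clause
matters because n detected events correspond to n + 1 bottoms: a 30-press
cycle yields 29 bottom-to-bottom events, so an event count alone can never
reach 30. Presses beyond the fifth cycle are ignored and reported as such.

## The synthetic generator: a stated world

`generate_session()` emulates what a pose backend would see during a
training session, with every ground-truth quantity known:

* Wrist y follows a raised cosine, `h0 + A(1 − cos 2πft)/2`, with
  `A = depth_cm × px_per_cm` and `f = rate/60`: the trace starts *at rest
  height*, matching a detector armed in state 0, and bottoms sit at the
  half-period points. Defaults: 5.5 cm, 110/min, 10 px/cm — the centre of
  the compliant bands; 30 presses per phase (one standard cycle); 5 s
  pauses (a realistic pulse-check gap); a 2 s lead-in at rest; 30 fps
  (typical of on-device pose estimation).
* Arms are placed by `arm_geometry()` so the elbow angle is exact by
  construction (default 172°, a compliant but not perfectly straight
  posture); wrists are 4 px apart, hands stacked.
* Gaussian pixel noise (default 0) and keypoint dropout (confidence set to
  0, coordinates untouched) are applied after the geometry, emulating
  keypoint jitter and detection failures; everything is reproducible from
  the seed.
* Partial chest recoil is available (`recoil_fraction < 1`) for robustness
  tests: the inter-press tops then stay below rest height, which the
  state-2 recoil condition is designed to punish.

What the generator does **not** model — and therefore what a green test
suite does not establish — includes: real pose-model error structure
(which is autocorrelated and outlier-prone rather than i.i.d. Gaussian),
perspective and camera motion, torso biomechanics (the whole arm rides
rigidly on the wrist waveform), hand-placement on the sternum (not
computed by this system), and the calibration procedure itself. Results on
synthetic traces bound the method's algorithmic error, not its end-to-end
field accuracy.

In validation across depths {4, 5.5, 7} cm and rates {90, 110, 130}/min at
1 px noise, recovery runs with the window-3 smoother enabled as the
analysis configuration for noisy input; per-press metrics then jitter at
the band edges, so the "feedback pattern matches construction" check is
phrased at session level: corrective events for a majority of presses when
a cell is built non-compliant, at most a 10% minority when compliant.

## Agreement with a reference device

`evaluate_against_reference()` reproduces the published evaluation
*procedure*: per-press depths from a reference device (e.g. an
instrumented manikin) are paired with estimated presses by nearest bottom
time within 0.3 s (below half a compliant period, so neighbours cannot be
confused; unmatched presses are reported and excluded), then mean absolute
error, the percentage of presses within 0.5 cm (boundary inclusive), and a
two-sided paired t-test on the differences are computed. The source names
no test; the paired t-test is the standard choice for paired continuous
agreement, with a Wilcoxon signed-rank option for heavy-tailed differences.
Identical series make the test degenerate: p is reported as 1 with a
warning rather than NaN. The published agreement values themselves derive
from a private manikin session and are not recomputable here; the
implementation is instead verified against brute-force oracles and a
type-I-error calibration (≈5% rejections over 1,000 null replicates).

## Worked session

```{r}
sess <- generate_session(synthetic_spec(true_depth_cm = 5.5,
                                        rate_bpm = 110,
                                        n_phases = 2,
                                        presses_per_phase = 10,
                                        seed = 1))
report <- run_session(sess$trace, calibration(px_per_cm = 10))
report
summary(report)
```

```{r, fig.width = 7, fig.height = 3.5}
plot(report)
```

## Known limitations

* Depth is only as good as the px/cm calibration, and a monocular view
  conflates out-of-plane motion with depth.
* The 15.5/5 px detector thresholds were adopted as published without
  knowing the capture resolution they were tuned for; rescale them via
  `detector_config(px_per_cm=, reference_px_per_cm=)` when in doubt.
* The presence gate is all-or-nothing per frame; a single flickering
  keypoint resets the detector. Heavy dropout regimes need the smoother
  and a lower `min_confidence`.
* Interruption-length monitoring (pauses under 10 s) is part of the
  high-quality CPR standard but, like hand placement, outside what this
  pipeline computes.
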