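---
title: "Motion-based confidence scores for rPPG heart-rate estimates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motion-based confidence scores for rPPG heart-rate estimates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(rppgconf)
```

## The problem

Remote photoplethysmography (rPPG) estimates heart rate from a face video:
cardiac blood-volume variation subtly modulates skin color, and the dominant
frequency of that modulation, extracted from the mean color of a skin region
of interest (ROI), is the pulse rate. The measurement is contact-free and
cheap, but it fails silently — head motion, talking, and lighting changes
produce color fluctuations that can dwarf the pulse signal, and the spectral
peak then locks onto an artifact instead of the heart beat. A monitoring
system needs to know *when to trust* each estimate.

`rppgconf` implements a confidence score for windowed rPPG heart-rate
estimates built entirely from four cheap motion descriptors of the analysis
window. A classifier trained on labeled windows (reliable / unreliable by
absolute error against a reference oximeter) emits a continuous score in
[0, 1]; downstream systems threshold it according to their own cost
trade-offs, so evaluation is threshold-free via ROC/AUC.

## The pipeline

Heart rate is computed per 12-second sliding window at a 1-second hop:

1. **ROI**: the convex hull of the facial landmarks minus the convex hulls
   of the eye and mouth landmark sets, rasterized center-inclusively
   (a pixel belongs to the ROI when its center is inside or on the hull).
2. **Color trace**: per-frame mean of each RGB channel over the ROI.
3. **BVP extraction**: `GREEN` (mean-subtracted green channel), `CHROM`
   (chrominance projection `X = 3R_n - 2G_n`, `Y = 1.5R_n + G_n - 1.5B_n`,
   `S = X - (σ_X/σ_Y) Y` on window-mean-normalized channels), or `POS`
   (`S1 = G_n - B_n`, `S2 = G_n + B_n - 2R_n`,
   `h = S1 + (σ_{S1}/σ_{S2}) S2`). The projections are applied over the
   full window. No artifact removal or denoising is applied before or
   after — the confidence score must see the pipeline's raw behavior.
4. **HR estimation**: zero-phase Butterworth band-pass (order 6,
   0.65–4.0 Hz = 39–240 bpm), a Hann window, a periodogram zero-padded to
   8192 points, and three-point parabolic interpolation of the in-band
   power maximum. The passband, filter order, and zero-phase application
   are exposed in the API; the defaults follow common practice in open
   rPPG frameworks.

### The four motion features

For a window of $n$ frames with $l$ landmarks:

* **TI** (temporal perceptual information, after ITU-T Rec. P.910):
  $\max_{i=2..n} \sigma[M_i]$ where $M_i = L_i - L_{i-1}$ is the luminance
  difference image and $\sigma$ the *population* standard deviation over
  all pixels. Luminance uses BT.601 weights (0.299, 0.587, 0.114), kept as
  real values. TI is computed over the **full frame**, not the ROI: it
  measures scene motion, and background activity is exactly what lets it
  decouple from the face-centric features. (ROI-only TI would be blind to
  that distinction; the choice is exposed through which frames you hand
  the function.)
* **FM_X, FM_Y** (face motion): the mean of the absolute per-axis landmark
  displacement over all $l$ landmarks and all $n-1$ consecutive frame
  pairs, i.e. normalization $1/(l(n-1))$, in raw pixel units (no face-size
  normalization).
* **FSM** (face size motion): $\frac{1}{n-1}\sum_{i=2}^n |N_i - N_{i-1}|$
  where $N_i$ is the ROI pixel count — a proxy for motion along the
  camera axis.

All four are nonnegative; TI is invariant to global additive luminance
shifts, FM to constant landmark offsets, and FM scales linearly with the
motion trajectory.

### Labels and the confidence model

Windows are labeled by absolute error against the reference heart rate
(mean of the oximeter's instantaneous-HR samples in the window): error
strictly below 2 bpm → reliable (1), strictly above 6 bpm → unreliable (0),
and the ambiguous band [2, 6] — boundaries included, because the defining
inequalities are strict — is discarded from both training and testing.
A single hard threshold would put near-identical errors (1.99 vs 2.01 bpm)
in different classes; the guard band removes that instability.

The default classifier is **bagged trees**: 30 bootstrap decision trees,
each cost-complexity-pruned back to at most 9 splits, scored by the mean of
the per-tree class-1 terminal-node probabilities. We implement the ensemble
directly over `rpart` because the configuration is stated as a *per-tree
split cap* with probability averaging; `rpart`'s complexity table makes the
split cap exact, and averaging terminal-node probabilities (rather than
0/1 votes) avoids a 31-level score quantization that degrades rank metrics.
Each tree considers all four features at every split (bagging, not a
random-subspace forest). The roster also includes a single tree, LDA,
logistic regression, Gaussian naive Bayes, linear and RBF SVMs, 1-NN,
AdaBoost over depth-4 trees (30 learners, learning rate 0.1, implemented
directly for the same reason), and a single-hidden-layer neural network
with 10 units (`nnet`; a deeper ReLU network is not available in the
supporting libraries, and the roster entry is an approximation — the
ensemble methods are the recommended models).

Evaluation is always **subject-stratified**: a greedy balancing assignment
(largest subject first into the currently smallest fold, after a seeded
shuffle) puts every subject's windows into exactly one fold, so the model
can never exploit subject identity. Schemes: k-fold CV within each dataset,
k-fold CV over all datasets combined, and cross-dataset (train on all but
one dataset, test on it).

## The synthetic scene generator

Real rPPG corpora are distributed on request only, so the package ships a
deterministic scene generator that emulates their study conditions: 8-bit
RGB frames (640×480 at 25–30 fps in the emulated recordings), an elliptical
skin-colored face whose interior is additively modulated by a two-harmonic
pulse waveform (green-dominant channel gains 0.33 : 1 : 0.5), analytic
landmarks (12 on the face ellipse, 4 per eye, 4 on the mouth — no detector,
hence no detector nondeterminism), and a 60 Hz oximeter-style reference
trace carrying both waveform and instantaneous HR.

The generator's imperfection model is what makes motion *matter*, and each
term has a physical reading:

* **Tracking lag and jitter**: the landmark track reports the face pose 3
  frames late, with per-landmark Gaussian jitter proportional to the face's
  instantaneous speed (detector latency; accuracy degrading with motion
  blur). Under fast motion the lagged hull overlaps background, so
  background pixels contaminate the color trace.
* **Specular shading**: an additive white component on the face
  proportional to signed displacement from the rest pose (the glossy lobe
  brightens toward the key light).
* **Mixed chromatic lighting**: the face's illumination is multiplied per
  channel by a linear field along x, y and distance (defaults on a
  green–magenta mix axis). Moving through mixed indoor lighting changes
  the face's color cast — a distortion that is *not* a single fixed
  chromatic direction plus intensity, which is precisely the blind spot of
  CHROM/POS-style projections: they cancel one dominant distortion
  direction per window and are otherwise robust. Without this term the
  projections survive almost any rigid motion of this renderer, which
  real-world data contradicts.
* **Talking**: the rendered mouth opens at a syllable-like rate past the
  landmark-defined mouth exclusion hull, exposing dark-red mouth interior
  to the ROI. Its chromatic direction is "anti-greenish", which the
  projections cannot suppress without destroying the pulse — so talking
  degrades all three methods, translation degrades GREEN at low amplitude
  and all methods at higher amplitude, global flicker degrades GREEN only,
  and pure background motion degrades none. This spread of
  failure-vs-feature signatures mirrors what motivated the score.

What the generator does **not** model: facial texture and non-rigid
expression, head rotation (only translation and scale), compression
artifacts, and abrupt illumination events. Passing tests on this corpus
show that the pipeline, features, labeling and evaluation machinery behave
as designed and that the score's discriminative mechanism works when motion
causes failure; they do not certify performance on any real dataset.

### The desk-scale study

`run_synthetic_study()` renders 40 clips — three pseudo-datasets of
14/13/13 clips at 30/25/30 fps, five subjects each — cycling through nine
scene types (still, x/y translation, flicker, z-scale, background motion,
talking, combined translation, talking with head jitter). Per-clip
conditions are drawn from continuous ranges under the clip's seed: HR
55–130 bpm, motion 0.8–1.5 Hz at 2–10 px peak, scale 4–10%, mouth opening
70–150%, pixel noise 1.5 counts, pulse amplitude 4 counts. Motion
amplitudes ramp from 0 to their maximum across each clip, the way real
subjects alternate stillness and movement; this also means every clip
sweeps the full severity continuum, so cross-validation folds always see
the reliable/unreliable boundary. Clips are rendered at 160×120 for 60 s —
the emulated geometry scaled down so that the whole study (≈ 66,000 frames)
runs in minutes on one core; all geometric quantities scale with the frame,
so nothing but pixel count changes.

At this scale the combined-CV AUC of the default model is ≈ 0.90 (GREEN),
0.95 (CHROM), 0.96 (POS), and all four features correlate positively with
absolute error — the qualitative structure reported for real corpora
(moderate positive correlations, FSM weakest; AUC a little above 0.9).

## Numerical choices and degenerate inputs

* Population (not sample) SD in TI; unrounded luminance differences.
* Pixel coordinates are 0-based, x = column, y = row, origin top-left;
  hull rasterization includes boundary pixels (tolerance 1e-9).
* CHROM with `σ_Y = 0` falls back to `S = X`; POS with `σ_{S2} = 0` to
  `h = S1`; constant traces give identically zero BVP.
* A window containing any frame with an empty or degenerate ROI produces
  no estimate (reason `no_roi`) rather than an interpolated one.
* Parabolic peak interpolation is clamped to ±0.5 bin and disabled at the
  band edges; an identically zero in-band spectrum gives `NA` (reason
  `no_estimate`).
* Reference HR per window is the mean of the instantaneous-HR samples in
  the window; if the reference lacks an HR channel the same spectral
  estimator used for the video is applied to the reference waveform.
* Boundary errors of exactly 2.0 or 6.0 bpm are discarded.
* All randomness flows from explicit integer seeds; identical
  configuration and seed reproduce frames, landmarks, traces and CSV
  outputs bit-identically.

## Known limitations

* The generator's corruption mechanisms are stylized; real failures
  include rotation, occlusion and sensor artifacts it does not model.
* SVM roster entries use library defaults rather than an inner
  hyperparameter search; the neural-network entry is a single-hidden-layer
  approximation.
* The 1-NN score is inherently binary (its neighbour's label), so its ROC
  has a single operating point; it is included for completeness.
* Confidence scores are not calibrated probabilities; only their ranking
  is evaluated. Choosing an operating threshold is application-dependent
  and out of scope.
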