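---
title: "Estimating instantaneous VO2 from wearable cardiorespiratory signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating instantaneous VO2 from wearable cardiorespiratory signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Overview

`vo2wear` estimates instantaneous oxygen uptake (VO₂, ml/kg/min) from the
channels a chest-worn sensing vest provides: single-lead ECG at 200 Hz, two
respiration belts at 25 Hz and tri-axial acceleration at 25 Hz. The design
premise is that VO₂ is jointly encoded in cardiac drive (heart rate),
ventilation (breathing rate and depth) and external work (motion
intensity), and that a boosted-tree regressor over features from all three,
plus subject demographics, recovers it across rest, walking, incremental
treadmill exercise and recovery without knowing the activity type.

This vignette records the package's methodological choices: the model and
its assumptions, the tunable parameters and their defaults, what the
synthetic cohort generator does and does not emulate, the numerical
decisions, and known limitations.

# Signal conditioning

**ECG.** A 201-tap linear-phase FIR band-pass (Hamming design) with a
3–45 Hz passband at 200 Hz. The band suppresses baseline wander and T-wave
energy below 3 Hz and powerline/EMG energy above 45 Hz while amplifying
the QRS complex. 201 taps give a transition band of roughly 3 Hz and more
than 40 dB of stopband rejection; the filter's constant group delay of 100
samples is removed after filtering so R-peak timing is unbiased. The tap
vector is recentred (mean subtracted) to place an exact null at DC; the
change elsewhere in the response is below 10⁻⁵. Applied single-pass —
linear phase makes a forward-backward pass unnecessary.

**Respiration.** Belt signals carry large, slowly varying offsets
(posture, belt tension). A periodized db4 discrete wavelet transform
decomposes the signal to level 9; reconstructing from the approximation
alone yields the baseline (content below 25/2¹⁰ ≈ 0.012 Hz), which is
subtracted. A zero-phase (forward-backward) order-4 Butterworth band-pass
at 0.1–0.35 Hz then isolates the breathing band. No wavelet package is
available in the supported dependency set, so the package carries its own
compact periodized DWT whose perfect-reconstruction property is pinned by
a unit test.

**Acceleration.** Each axis is low-pass filtered at 0.32 Hz (zero-phase
order-4 Butterworth), preserving the gravity (posture) component. Note
this removes gait harmonics (≥ 1 Hz) almost entirely; see the discussion
of MADs under *Design decisions*.

All IIR chains reflect-pad the signal (odd extension) before filtering and
strip the pad afterwards, so start-up transients never reach the features;
the pad length (1000–2000 samples) exceeds the filters' impulse-response
decay by a wide margin.

# Features

* **HR / HR%** — R peaks are detected with the Hamilton rule set
  (band-limited differentiation, rectification, 80 ms moving-window
  integration, adaptive QRS/noise threshold with coefficient 0.3125,
  200 ms refractory period, searchback when a gap exceeds 1.5× the recent
  mean RR). R–R intervals outside [0.24, 3] s (20–250 BPM) are discarded.
  HR at each 1 s tick is the mean of 60/RR over intervals whose
  terminating peak lies in the trailing 4 s window; empty windows carry
  the previous value forward (a streaming-compatible convention). HR% is
  HR relative to the age-predicted maximum 208 − 0.7·age.
* **RR / DApt** — breaths are alternating local maxima/minima of the
  cleaned belt signal with at least 1/0.7 s separation (≤ 42 breaths/min)
  and an amplitude floor of 0.05 SD to reject micro-ripples; each peak
  pairs with the nearest preceding trough. RR = 60 / peak-to-peak
  interval; DApt = peak minus trough amplitude, an uncalibrated tidal
  proxy. Both are timestamped at the breath peak and resampled to 1 Hz.
* **SVM / MADs** — SVM is the Euclidean norm of the filtered axes; MADs
  is the mean absolute successive SVM difference over non-overlapping
  1 s blocks aligned to the 1 Hz grid (24 differences per block at
  25 Hz).
* Per-breath series are interpolated with shape-preserving
  (Fritsch–Carlson) monotone cubic interpolation; outputs are clamped to
  the envelope of the bracketing support values because the
  Fritsch–Carlson construction can overshoot interior extrema by a few
  tenths of a percent. Outside the support range the nearest endpoint
  value is held.
* All 1 Hz columns (VO₂ reference included) are smoothed with a centered
  31-point moving average, truncated and renormalized at the edges. HR%
  is computed from the smoothed HR.

# Model and evaluation

The regressor is a gradient-boosted ensemble of K regression trees
minimizing squared error with complexity regularization, provided by
xgboost (single-threaded for reproducibility). The package owns everything
around it: the seven feature combinations (HR%+SDI, RD+SDI, MADs+SDI and
their unions; RD = {RR, DApt}, SDI = {age, sex, BMI}, sex encoded
male = 1, female = 0, SDI broadcast to every 1 Hz row), the default
2×2×2 hyperparameter grid {10, 50} trees × depth {1, 5} × learning rate
{1, 0.1}, and the evaluation designs.

Cross-validation folds always split whole subjects, never rows: rows of
one subject are strongly autocorrelated, and row-level folds would leak
identity. Grid search uses subject-grouped five-fold CV and breaks ties
deterministically toward fewer trees, then shallower trees, then the
larger learning rate (the cheaper, less overfit-prone model). LOSO
evaluation asserts in code that the held-out subject never appears in
training, and reports per-subject and pooled MAE/R² (both the mean ± SD
over subjects and the pooled-sample versions — the two diverge when
subjects differ in difficulty), Bland–Altman bias and 1.96·SD limits of
agreement, and per-activity MAE (seconds not covered by an annotation are
kept in pooled metrics but excluded from the per-activity table).
Degenerate cases are defined explicitly: a constant training target
degrades to a warned mean predictor; R² is refused for zero-variance
truth; subjects contributing under 60 s are excluded from LOSO with a
warning.

# The synthetic cohort generator

No public recordings accompany the protocol, so the generator is a
first-class module: it emulates the full experimental session — a
17-minute rest battery of five postures (each with normal, deep, talking
and fast breathing tasks of 60/60/30/30 s and 30 s unannotated gaps
between postures), a 3-minute treadmill warm-up, 3-minute Bruce stages
(speeds 2.74–9.65 km/h) truncated at the first stage whose steady-state
HR reaches the 180 BPM exhaustion criterion, and recovery (≤ 20 min,
default 300 s).

Ground-truth VO₂ relaxes toward each activity's steady state with
first-order kinetics, τ = 35 s (typical on-kinetics). The steady-state
ladder — rest 3.5 (1 MET), walk 12, stages 16/21/28/35/43/50/55
ml/kg/min — rises strictly and spans typical young-adult VO₂max; these
are simulator defaults, not claims about any particular dataset. Coupled
channels:

* HR is affine in VO₂ with AR(1) noise (SD 1 BPM, φ 0.9), clipped below
  HRmax + 5; the slope defaults to (HRmax − rest HR)/40 so HR spans rest
  ≈ 70 BPM to near maximum across the ladder.
* ECG is a Gaussian-QRS pulse train (σ = 12 ms) at intervals 60/HR with
  2% multiplicative HRV jitter, plus 0.25 Hz baseline wander and white
  noise.
* Respiration is a phase-integrated sinusoid at RR(VO₂) (12 breaths/min
  at rest, +0.5 per ml/kg/min) with amplitude A(VO₂), slow drift and
  noise; the abdominal belt is the thoracic signal scaled by 0.8. The
  rest-phase breathing tasks modulate rate and amplitude only.
* Acceleration is posture-dependent gravity plus gait harmonics at a
  step frequency tied to treadmill speed, slow postural sway
  (~0.15 Hz) whose amplitude grows with speed, and white noise.
* References: VO₂ plus N(0, 0.4) at 1 Hz, HR plus N(0, 1) at 1 Hz.

Between-subject heterogeneity is drawn once per subject (resting HR SD
4 BPM, HR-slope gain CV 6%, resting VO₂ SD 0.3, resting RR SD 1.5,
belt-gain CV 15%): real cohorts differ in ways demographics do not fully
explain, and without this the leave-one-subject-out problem is
unrealistically easy.

A configurable sex effect supports crossover experiments: the offset
raises females' *measured* VO₂ during Bruce stages while all wearable
channels follow the unshifted *effort* trace (two kinetics passes). This
mirrors the physiological claim being tested — a different oxygen cost for
the same external work and cardiorespiratory signature — and is exactly
the kind of effect a cross-sex-trained model cannot see in its inputs. If
the offset were simply added to the VO₂ driving all couplings, HR and RR
would shift along with it and a model trained on the other sex would
track it, planting no effect at all.

What the generator does **not** emulate: realistic ECG morphology (P/T
waves, arrhythmia), VO₂ slow-component drift, respiratory sinus
arrhythmia, motion artifacts on ECG or belts, sensor dropout, or
activity-misannotation. Passing recovery experiments therefore show the
pipeline is internally consistent and leak-free — not that laboratory
performance would match.

# Design decisions on open points

* **Which belt feeds RR/DApt** — thoracic by default, with
  `resp_source = "abdominal"` or `"sum"` available.
* **HR source** — derived from the vest ECG by default; `hr_source =
  "hr_ref"` substitutes the chest-strap reference channel.
* **MADs vs the 0.32 Hz low-pass** — a 0.32 Hz low-pass on the axes
  removes gait-frequency content, which would seem to starve MADs of
  motion information. The chains are kept exactly as specified, and the
  simulator's acceleration model includes the slow postural-sway
  component that in practice survives such a low-pass and scales with
  locomotion intensity (torso lean and sway grow with speed and
  incline), so MADs remains a monotone intensity index. MADs block
  indexing is interpreted as non-overlapping 1 s blocks.
* **HR windowing** — trailing (causal) windows, matching a streaming
  implementation; centered windows would shift HR by half a window
  relative to the reference.
* **Five-fold CV grouping** — by subject (see above).
* **Reported R²** — both per-subject mean ± SD and pooled-sample values.

# Problem sizes and numerical tolerances

The validation experiments (test suite and `scripts/acceptance.R`) use a
compressed schedule — identical block structure with rest tasks
20/20/10/10 s, 10 s gaps, 60 s walk/stage/recovery blocks — and a
12-subject cohort (6 male, 6 female), chosen so the complete
simulate → extract → LOSO × 8-cell grid experiment is comfortable on a
single CPU; the full-duration protocol remains the simulator default.
Formula implementations are required to match brute-force oracles to
1e-9 relative tolerance; realized filter gains must match the designed
transfer functions within 0.01 absolute at the probe frequencies; the
narrow (0.008–0.028 normalized) band-pass amplifies double-precision
rounding to about 1e-4 absolute, which the linearity test tolerances
acknowledge.

# Known limitations

* DApt is uncalibrated; it cannot be converted to liters of ventilation.
* The 0.1–0.35 Hz respiration band attenuates breathing above 21
  breaths/min, so RR and DApt degrade at high exercise intensity; the
  model then leans on HR% and MADs there.
* The Hamilton detector is tuned for upright R waves; inverted leads
  would need a polarity check upstream.
* LOSO on small cohorts has high variance in per-subject metrics; the
  per-activity ablation margins between the larger feature sets are
  small and seed-dependent on 12 simulated subjects.
* EDF export quantizes to 16 bits over each channel's observed range;
  round-trips are exact only to one quantization step.
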