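---
title: "Simulating and decoding motor-imagery EEG with mibci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and decoding motor-imagery EEG with mibci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(mibci)
```

`mibci` implements a full two-class motor-imagery (MI) analysis chain —
trial scheduling, synthetic EEG generation, artifact cleaning, feature
fusion, PSO-SVM classification, cross-validated assessment, and
topographic activation mapping. This vignette explains the models behind
each stage, the parameters that matter, and the design decisions that
were genuinely open.

## The trial paradigm

Two session kinds are modeled. An *assessment* trial lasts 10 s: a cue
period (0–2 s), the MI period (2–7 s) during which the subject imagines
the cued left/right movement, and rest (7–10 s). A *training* trial
lasts 7 s: cue 0–1 s, MI 1–5 s, and a 2 s feedback period in which the
classifier's decision drives the scene. Trials are back-to-back with no
extra inter-trial gap. One assessment day holds 3 sets × 30 trials = 90;
one training day 3 sessions × 40 trials = 120, so a 14-day course
accumulates 1,680 feedback trials and the three assessment days 270.

"Random left and right trials" is implemented as *balanced within each
set* (15 + 15), with only the order seed-shuffled. Unbalanced sets would
make stratified three-fold splits and CSP class-covariance estimates
fragile, and balance is what a well-run study would enforce anyway. The
training-trial length is fixed at 7 s — the enumerated periods end at
7 s, and we read the design as three periods within those 7 s; any
unstated extra rest would only shift onsets, nothing downstream depends
on it.

## The generative model

The generator exists because no public recordings accompany the study
design it emulates; it makes every downstream stage testable against a
known ground truth. Two hemispheric sources sit at the C3 and C4
electrode positions of a 19-channel motor-area montage (FC/C/CP rows,
unit-disc scalp projection, Cz at the origin). Each source emits
band-limited Gaussian noise in the mu (8–13 Hz) and beta (13–30 Hz)
bands — filtered noise rather than sinusoids, so Welch spectra and CSP
see realistic, full-rank signals. Source-to-channel mixing is Gaussian
in scalp distance, `exp(-d² / 2σ²)` with `spatial_spread` σ = 0.4, which
puts meaningful source signal on the whole hemisphere while keeping C3/C4
dominant. Independent 1/f ("pink") noise is added per channel.

During an MI window the *contralateral* source amplitude is multiplied
by

\[ 1 - d \cdot g \cdot e_t \]

where `d` is the subject's ERD depth (`erd_depth`, default 1), `g` the
scene-condition gain, and `e_t` a per-trial *engagement* draw, uniform
on `engagement_range` (default `[0, 1]`). The scene gain encodes how
strongly the stimulation scene recruits motor imagery — packaged
defaults static 0.2 < dynamic 0.5 < vr 0.8. The engagement term models
fluctuating imagery vividness/attention across trials, which is the
dominant cause of single-trial errors in practice: with stationary
sources and 5 s windows, even weak deterministic ERD is detectable
nearly every trial, and recognition rates pin at 100% — far from the
60–85% regime real MI studies operate in. Setting
`engagement_range = c(1, 1)` recovers the fully deterministic model
(used by the generator's own calibration tests: with `d·g = 0.5` and no
channel noise, contralateral mu power during MI is `(1-0.5)² = 0.25` of
baseline).

Injectable artifacts mirror the three noise classes the cleaning chain
targets: per-channel random-walk drift, a common-mode 50 Hz sinusoid
with slowly wandering phase, and ~0.3 s biphasic blink pulses at Poisson
times, weighted toward the anterior row. The clean pulse train is kept
as `aux_blink_ref` so blink removal can be validated.

What the generator does *not* emulate: volume conduction through a head
model, re-referencing effects (the study's reference electrode overlaps
Cz; we leave all channels referenced as generated), ECG/EMG artifacts,
slow nonstationarity across a session, and learning effects across days.
Passing tests therefore demonstrate the pipeline's correctness and
sensitivity under a controlled ERD model, not performance on any real
recording.

## Cleaning chain

The four stages run in a fixed order: baseline → line noise → ICA →
band-pass, then epoching.

* **Baseline**: subtraction of a centered 1 s moving average
  (reflect-padded). The window is not stated by the study design; 1 s
  removes <1 Hz drift while attenuating 8 Hz mu by under 1%.
* **Line noise**: a two-weight LMS adaptive canceller with a quadrature
  sin/cos reference at 50 Hz, honoring "adaptive filter" rather than a
  fixed notch. The reference has unit amplitude, so convergence speed is
  scale-invariant; the default step 0.002 converges in well under 2 s
  while keeping misadjustment leakage below 1% on off-frequency signals.
  Divergence (weight-norm explosion) raises an error.
* **EOG removal**: FastICA (via the `ica` package), with a selection
  rule of ours since none is prescribed: a component is ocular if it
  correlates with the blink reference above 0.7 when a reference exists,
  otherwise if it is both heavy-tailed (kurtosis > 5) and dominated by
  sub-4 Hz power (> 60%). Flagged components are zeroed and the signal
  reconstructed.
* **Band-pass**: a sixth-order Butterworth 8–32 Hz filter applied
  forward-backward (zero phase, so MI windows are not delayed). The
  effective response is the squared single-pass response: gain exactly
  0.5 at the nominal edges, 2.2% residual amplitude at 50 Hz.

Whether band-passing belongs before or after ICA is not prescribed; the
listing order is followed (ICA first), which also lets ICA see the
broadband blink energy it needs.

## Features and classifier

Three blocks are fused per trial: per-channel mean square (19 columns),
Welch band powers with 1 s Hann segments at 50% overlap for mu 8–13 Hz
and beta 13–32 Hz (38 columns), and CSP normalized log-variances with 3
filter pairs (6 columns) — 63 features. "Mean square" is read as mean
squared amplitude: no reference signal exists against which an *error*
could be taken, and mean-square amplitude is the standard time-domain
energy feature. CSP uses trace-normalized per-trial covariances, a ridge
of 1e-9 × trace on the composite, and the whitening construction, whose
filters provably match the generalized eigendecomposition of
`(C1, C1+C2)` (tested against that oracle to principal angles ≤ 1e-6).
Three pairs is standard MI-BCI practice and keeps the spatial block from
dominating the other 57 columns. Standardization means/scales are fitted
on training rows only.

The classifier is an RBF SVM; PSO searches `log10(C) ∈ [-2, 3]`,
`log10(γ) ∈ [-4, 1]` with the canonical constricted constants (inertia
0.72, c1 = c2 = 1.49, 30 particles, 100 iterations by default),
maximizing stratified 3-fold inner accuracy — the same fold geometry as
the outer assessment, so model selection and assessment agree on what
"accuracy" means. The evaluation drivers default to a compact search (15
particles, 25 iterations): the inner-CV accuracy surface over
`(log C, log γ)` is a broad plateau near its optimum on these features,
and the outer rate is indistinguishable while the three-fold assessment
of one 90-trial session stays under half a minute.

## Assessment

`offline_threefold()` makes stratified thirds (30/30/30 for 90 trials);
within each fold CSP, feature standardization and the PSO-SVM are fitted
on the two training folds only. A canary test plants a discriminative
signal in one test fold only and verifies the rate does not move — the
leakage guard is structural, not incidental. `online_recognition_rate()`
builds the day × subject percent-correct table with per-subject average,
standard deviation and best-day flag (first occurrence on ties, which is
the natural reading when several days tie).

`scene_ordering_experiment()` simulates three subjects per scene arm
(90 trials each), with *subject seeds shared across arms* — a matched
design in which the same simulated subjects experience each scene, so
arm contrasts reflect the gains, mirroring the within-subject logic of
pre/post comparisons. It reports mean rate and mean activation
breadth/depth per arm and whether vr > dynamic > static holds for each.

## Activation mapping

`fourth_order_energy()` is the cumulative sum of fourth powers Σx⁴ — the
energy reading, not the fourth cumulant: the mapping pipeline normalizes
and draws energies, and a cumulant (which subtracts 3σ⁴) can be negative
and would not admit the `[0, 1]` normalization that the map convention
requires. For a Gaussian channel E/N → 3σ⁴, which the tests verify.
Per-trial maps min–max normalize across channels (a constant map becomes
0.5 everywhere), making them invariant to overall scale; scalp grids use
inverse-distance-weighted interpolation (power 2) over the unit disc,
exact at electrodes and bounded by the input range. Breadth is the
fraction of scalp pixels above a threshold (default 0.6 on normalized
maps) and depth the mean of those pixels.

For comparing *activation* across conditions the package uses ERD
topographies (`erd_topomap()`): per-channel fractional band-power
suppression of the MI window relative to the same trials' rest window,
`ERD_c = max(0, 1 - sqrt(E_mi / E_rest))` (the square root because
fourth-order energy scales with power squared). This is the field's
standard ERD% map, and it is what "activation" means for motor imagery:
a desynchronized region, darker where suppression is deeper. Unlike
min–max-normalized single-window maps — whose scale the normalization
deliberately discards, so threshold metrics on them cannot respond to a
*global* deepening of the effect — ERD fractions carry absolute meaning,
and both the breadth and the depth of the suppressed region grow
monotonically with the effective ERD depth. Breadth/depth of ERD maps
are read at a 10% suppression threshold, the conventional level below
which single-channel ERD is not considered meaningful.

## Numerical and I/O choices

* Welch PSD uses one-sided density scaling verified by Parseval checks;
  band powers integrate `[lo, hi)`.
* The EDF writer quantizes to 16 bits over a symmetric per-channel
  range; 1 s data records require whole-second recordings (all generated
  sessions satisfy this), and round-trips agree to one quantization
  step. Events travel separately as tab-separated tables (onset,
  duration, trial_type), from which the session kind is inferred by
  trial duration.
* The run configuration is TOML with a strict schema — unknown keys are
  rejected so a typo cannot silently fall back to a default.
* Degenerate inputs are defined, not accidental: empty schedules
  simulate to a minimal silent recording; constant channel-energy maps
  normalize to 0.5; zero-artifact injection returns the input unchanged;
  a single-class training set is an error.

## Problem sizes

The packaged experiments are sized for a single CPU: end-to-end recovery
uses 100 trials per class (null effect vs `d·g = 0.9`), and the
scene-ordering experiment 3 subjects × 90 trials per arm. At these sizes
the null rate's 95% binomial interval is ±6.9 percentage points and the
arm-mean rate differences (static → dynamic ≈ +13, dynamic → vr ≈ +5
points) comfortably exceed the between-seed spread of an arm mean
(≈ 2 points).

## Known limitations

* The generator's stationarity means offline and online rates differ
  only through training-set size, not through drift — the main reason
  real online rates trail offline ones is not modeled.
* ERD is modeled as a flat amplitude factor over the whole MI window; no
  onset latency, ramp, or post-MI rebound (ERS).
* The montage covers only the motor strip, so ICA has no far-field
  channels to separate blinks against; the blink reference criterion is
  correspondingly the primary selection rule.
* Breadth/depth thresholds summarize maps coarsely; no cluster-level
  statistics are attempted.
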