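---
title: "Decoding intentions from ECoG and driving spinal stimulation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding intentions from ECoG and driving spinal stimulation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsitools)
```

`bsitools` re-implements, end to end and at desk scale, the computational
chain of a brain–spine interface: epidural ECoG recorded over the leg area
of the sensorimotor cortex is turned into time–frequency features, decoded
into joint-movement intentions by an adaptive Markov-switching multilinear
decoder, and translated into proportional epidural stimulation commands;
a set of evaluation statistics quantifies every stage. Because raw clinical
recordings are not available at this scale, a fully seeded synthetic
session generator provides co-registered ECoG, cues, EMG and kinematics
with known ground truth, and every claim the package makes is checked
against that ground truth or against closed-form oracles in the test
suite.

## The decoder

The decoder state space has $K = 7$ states: rest plus hip, knee and ankle
flexion bilaterally. Two stages cooperate.

**Gate.** A linear discriminative classifier produces scores
$d^{gate}(t) = \beta^{gate} X(t) + b^{gate}$ from the flattened feature
tensor $X(t)$; a softmax turns them into emission probabilities
$\alpha^{emission}(t)$. These are filtered by a first-order hidden-Markov
model: with a row-stochastic transition matrix $T$ (estimated by counting
cued state transitions, one pseudo-count per cell to avoid absorbing
zeros),

$$\hat\alpha(t) \propto \alpha^{emission}(t) \odot
  \left(\hat\alpha(t-1)^\top T\right),$$

renormalized onto the simplex at every step. The filtered posterior is
initialized uniform. Ties in $\arg\max \hat\alpha$ resolve toward rest —
the fail-safe state that never stimulates.

**Experts.** Each active state has a linear expert
$\phi_k(t) = \beta_k^{expert} X(t) + b_k^{expert}$ (the rest expert is
fixed at zero), and the mixture output is

$$U_k(t) = \phi_k(t)\,\hat\alpha_k(t) \prod_{i \neq k}
  \left(1 - \hat\alpha_i(t)\right),$$

so a command is only large when its state is probable *and* all competing
states are improbable.

### Online calibration

Calibration is iterative and runs while the decoder is being used. The
stream is cut into 15 s batches. Each batch is first decoded with the
current model (so the per-batch accuracy in the calibration history is
prequential, i.e. genuinely held out), the output is blended with the cue
as $(1-a)\cdot\text{decoded} + a\cdot\text{cue}$ with assistance level
$a$, and the coefficients are then updated from the batch. Assistance
starts at 1 and decays linearly to 0 over `assist_batches` (default 10)
batches; it is non-increasing by construction. Expert targets during cued
calibration are a 0→1 ramp over each cue block (a step profile is
available via `target_shape`).

Both heads are refit at every batch from *exponentially weighted
cross-moment accumulators*: $S_{xx} \leftarrow \lambda S_{xx} + X_b^\top
X_b$, and likewise for $S_{xy}$ and the means used for centring. The
forgetting factor $\lambda$ (default 0.99 per batch) geometrically
down-weights old data; $\lambda = 1$ makes the refit exactly the pooled
fit of all data seen so far, which is the oracle property the test suite
verifies against `lm()`.

The refit itself is partial least squares computed directly from the
moments (SIMPLS; default 30 latent components per head, configurable).
This choice deserves a word. The original algorithm family for this
decoder is recursive exponentially weighted N-way PLS; a natural
simplification is to flatten the feature tensor and solve regularized
least squares from the same accumulators, and that variant is available
as `method = "ls"` (Cholesky solve, fixed small relative ridge only when
the moments are rank deficient). But with $F = 3072$ strongly collinear
wavelet features and a few thousand calibration windows, the
least-squares fit — while decoding well — scatters coefficient mass
across non-informative channels, because in that regime the coefficient
estimates have enormous variance. PLS restricts the fit to latent
components built from the feature–label covariance, which both matches
the spirit of the original algorithm and makes the gate weights land on
the channels and bands that actually carry movement information. With
components spanning the feature space, SIMPLS reproduces the
least-squares solution, so the oracle tests hold for both methods. A true
tensor-mode (N-way) factorization remains an extension point.

The latent dimensionality trades capacity against weight interpretability
the usual way: components beyond the signal rank start fitting noise. The
default of 30 suits the full 64-channel problem; the test suite uses 5
components for its deliberately tiny 6-channel recovery problem.

## Feature extraction

The front end mirrors a clinical real-time chain. Raw ECoG (64 channels,
586 Hz) is band-pass filtered 1–300 Hz — realized as a 4th-order
Butterworth applied forward–backward, with the upper edge capped at
$0.99\,f_s/2$ (≈290 Hz) below the Nyquist frequency. Every 100 ms, the
trailing epoch (200–500 ms, default 500 ms) is mapped to the
time–frequency plane with a complex Morlet wavelet transform
($\omega_0 = 6$, a standard resolution trade-off) at 24 fixed centre
frequencies (2, 5, 10, …, 100, 125, 150, 200 Hz — any other axis is a
hard error), the magnitude is taken, and the time axis is decimated to
2–5 taps by averaging contiguous blocks (averaging, not naive
subsampling, to avoid aliasing). The result is a 64 × 24 × taps tensor
per window.

Causality is strict: the transform of a window uses only samples inside
its epoch, reflect-padded at the epoch edges, so appending future samples
never changes past features. (Internally this makes the transform a
linear map of the epoch, which is prebuilt per configuration and applied
to all windows of a channel as one matrix product.) An epoch shorter than
one cycle of the 2 Hz wavelet warns once; its lowest-frequency
coefficients then lean on the reflection padding.

## The synthetic session generator

The generator emulates exactly the statistical structure the decoder and
the evaluation metrics rely on, and nothing more:

* **Background ECoG** is coloured Gaussian noise with power spectral
  density $\propto 1/f$ (exponent configurable), shaped in the frequency
  domain, unit variance, independent across channels.
* **Movement information** is state-locked band-power modulation: for
  each active state, a small set of informative channels (default: three
  dedicated channels per state) multiplies its power in the beta
  (10–40 Hz, ×2) and gamma (40–100 Hz, ×3) bands during that state's cue
  blocks. Gains are *power* ratios; gains above one are realized by
  adding independent band-limited noise of the appropriate variance,
  gains below one by attenuating the background's own band component.
  The Welch-estimator oracle in the test suite recovers the configured
  ratios within sampling error.
* **Cues** follow the clinical calibration protocol: a pseudo-random
  order of active-state blocks, each active state exactly `n_reps` times
  (30 by default, as in the walking-model protocol), rest interleaved
  before every active block, block durations from {2, 4} s.
* **EMG** is Gaussian noise at rest; stimulation commands drive a
  rectified Gaussian carrier scaled by the recruitment sigmoid of the
  commanded program, since envelope statistics are all the evaluators
  use.
* **Recruitment curves** are raised-cosine sigmoids between a motor
  threshold and a saturation amplitude — exactly 0 at threshold, exactly
  maximal at saturation, exactly half-maximal at the midpoint — so the
  closed-form checks in the tests are exact rather than asymptotic.
* **Kinematics**: the knee angle rests at 170° and dips to 110° as a 1 s
  raised-cosine pulse per programmed step; only threshold crossings and
  step lengths matter downstream.

Every stream derives from one master seed through fixed per-signal
sub-streams, so identical configurations give byte-identical sessions.
What the generator does **not** emulate: volume conduction and
cross-channel correlation, non-stationary artefacts (EOG/ECG, movement),
electrode drift, realistic EMG waveforms, or any biophysics of cortex or
spinal circuits. Passing tests therefore demonstrate the correctness of
the computational chain under its stated assumptions, not clinical
performance on real recordings.

Effect sizes for signals like these have no canonical values; the default
gains (×2 beta, ×3 gamma on three channels per state) are this package's
definition of a strong, clearly decodable effect, fixed once. The
`effect_size` knob scales the contrast for sensitivity studies.

## Stimulation control

Two control models map decoder output to commands for a 16-electrode
paddle:

* **Proportional control** (six joints, static): each active state's
  mixture output $u_k$, if above the activation threshold
  $\theta_u = 0.1$, is clamped to $[0,1]$ and linearly rescaled into its
  program's amplitude range $[A_{min}, A_{max}]$ (e.g. 14–16 mA at 40 Hz,
  300 µs).
* **Walking control**: the mixture layer is removed; only the argmax
  state of $\hat\alpha$ (if not rest) is stimulated, with
  $\max\hat\alpha$ rescaled from $[p_0, 1]$ (default $p_0 = 0.5$) onto
  the amplitude range. At most one program is ever active — left and
  right steps must never be commanded simultaneously.

Both $\theta_u$ and $p_0$ are configuration keys; rescaling intervals
like these are set per participant by an experimenter in practice, so the
defaults are explicit package choices. Commands are emitted at the decoder cadence
(100 ms) and dispatched to the pulse-generator cadence of 300 ms with
last-command-wins semantics per tick. An optional ramp limiter is *not*
implemented; amplitude safety is enforced by construction (clamping
before rescaling).

The program library itself is built from recruitment data:
`zscore_selectivity()` z-scores muscle responses across electrode
configurations (zero-variance muscles get z = 0), and
`recruitment_grid_search()` selects the configuration maximizing
$z(\text{target}) - \max z(\text{non-targets})$, with the amplitude range
set to the 10%/90% crossings of the isotonic-smoothed recruitment curve
(motor threshold and saturation have no single operational definition;
these crossings are the package's). Ties break toward
the lower threshold, then by configuration id, so selection is
deterministic.

## Evaluation statistics

* **Decoding accuracy**: delay-compensated normalized cross-correlation
  $\frac{1}{\sum_t Z(t)}\sum_t Z(t-\tau)\hat Z(t)$ with $\tau$ the argmax
  of the cross-correlation over a ±5 s window (the search window is a
  package choice; ties resolve to the smallest $|\tau|$).
* **Chance level**: $100/K$ percent, rounded — 14% for seven states.
* **EMG accuracy**: the envelope is the 200 ms forward sliding mean of
  the absolute z-scored EMG, thresholded at 1 (the z-score baseline is
  the whole recording, a package choice); accuracy is the fraction of
  envelope-active time with the decoded state active. Note the forward
  window makes the envelope lead a burst by up to 200 ms.
* **Stepping accuracy**: per-step peak of the decoded probability curve
  and its full width at half the per-step peak; summarized as mean ± sd.
  Probabilities are taken after HMM filtering.
* **Signal stability**: Welch PSD (2 s Hann segments, 50% overlap —
  package choices), RMS over 0.5–292 Hz, band powers for 0.5–10, 10–40,
  40–100 and 100–200 Hz normalized by bandwidth before dB conversion,
  and per-band SNR against the 250–260 Hz noise band; channel-averaged
  in the linear domain, over a 90 s window starting 20 s into the
  recording.
* **Spectrograms**: wavelet magnitudes averaged over 500 ms frames every
  100 ms, z-scored over time per frequency band (constant bands map to
  zero). The offline spectrogram path uses full-signal FFT convolution —
  causality only binds the decoder path.
* **Feature reinforcement**: per electrode and time period, the standard
  deviation of the median event-locked spectrogram (−2 to +2 s around
  each event; clinically four periods of 100 events, configurable down
  for tests), with one pooled linear fit of modulation versus period.
* **Walking-model stability**: PCA over per-state gate coefficient
  vectors (channels × frequencies, averaged over taps), scores in the
  first three components, and per-state Gaussian ellipsoid meshes of
  exactly 1,600 points at the 1.4 sd contour.
* **Gait analysis**: steps detected when the knee angle drops below 135°
  with a 2 s refractory period, failed when the step length is under
  10 cm; 26 kinematic and EMG parameters per gait cycle (cycles
  segmented between successive ipsilateral knee-dip onsets; swing
  defined as knee flexion below 160°, a package choice standing in for
  marker-based event detection), then a standardized PCA with
  per-condition centroid distances to a reference cohort.

## Numerical choices and degenerate inputs

* Softmax is computed with max-subtraction; the filtered posterior is
  renormalized every step and stays on the simplex to 1e-9 over
  arbitrarily long streams (property-tested).
* An all-zero filtered posterior (possible only with degenerate
  transition priors) falls back to the emission probabilities.
* SIMPLS stops extracting components when the deflated covariance or the
  score norm falls below scaled machine tolerances; zero targets yield
  exactly zero coefficients.
* The `ls` fit detects rank deficiency via the Cholesky diagonal ratio
  (< 1e-6) and then applies a ridge of 1e-4 × mean diagonal, counted in
  `calib$ridge_events`.
* Serialization uses tagged, versioned containers; loading checks the
  container type, so a features file can never be read as a session, and
  truncated files fail cleanly. Models store a fingerprint of the
  front-end configuration and refuse features produced with a different
  one.

## Problem sizes

The package's own experiments are sized for a desktop run: the
parameter-recovery experiment uses the full-scale reference conditions — 64
channels at 586 Hz, seven states, 30 repetitions per active state with
2 s cues (≈ 12 minutes of signal, 48 calibration batches) — with 300 ms
epochs and 2 temporal taps for the feature tensor ($F = 3072$), the lower
end of the supported ranges; the richer 500 ms / 5 tap variant
($F = 7680$) is the front-end default and is exercised on short signals
in the unit tests. The last 20% of batches are held out from calibration
and decoded with the final model for the held-out accuracy. Unit tests
use 4–8 channel, 2-state sessions.

## Known limitations

* The generator's independence across channels means spatial weight maps
  are cleaner than on real grids, where volume conduction mixes
  neighbours; the weight-concentration analysis should be read
  accordingly.
* The walking controller's probability-to-amplitude mapping
  ($p_0$, ranges) and the activation threshold are configurable stand-ins
  for values an experimenter sets by hand.
* Gait-cycle segmentation uses knee-dip onsets aligned with the
  simulator; clinical foot-strike detection from motion capture is out of
  scope.
* The decoder is strictly linear-Gaussian in spirit; no nonlinear or
  deep decoding, no per-implant modelling, no electrode re-selection.
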