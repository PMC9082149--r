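---
title: "Reconstructing ECG from PPG: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing ECG from PPG: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgrecon)
```

## The problem and the model

Electrocardiography records the heart's electrical activity;
photoplethysmography records the peripheral blood-volume pulse that the
same heartbeat produces. The two waveforms are mechanistically coupled —
the QRS complex triggers the contraction whose pressure wave becomes the
PPG's systolic wave — but the coupling (the subject's "transfer function")
varies between people, especially with circulatory disease. `ecgrecon`
therefore fits one model per subject: a bidirectional LSTM that reads an
*n*-second PPG window and emits the corresponding *n*-second ECG window,
trained on the first minute of a paired recording and applied to the rest.

Working on fixed-duration windows rather than detected beats is a central
design commitment. Beat-based reconstruction inherits every failure of the
beat detectors; second-based segmentation needs peak detection only once,
during the initial time alignment, and tolerates PPG/ECG period
disagreement within a window.

The assumptions a recording must satisfy:

* both channels are sampled at a common, constant rate (default 125 Hz);
* the pulse arrival time (PAT) — the delay from R peak to systolic peak —
  is approximately constant over the record, so removing one global lag
  aligns the beats;
* the subject's PPG→ECG mapping is stable over the record's duration
  (minutes, not hours);
* the information to be reconstructed lives below the PPG passband's upper
  edge. The ECG is band-limited to 0.5–20 Hz before it is ever used as a
  training target, so high-frequency features (notched QRS, abnormal
  ventricular conduction above ~70 Hz) are outside the model's reach. This
  is a real limitation of the approach, not an implementation shortcut.

## Pipeline stages and their parameters

### Filtering

Both channels pass through a Chebyshev type II band-pass: 0.5–20 Hz for
ECG, 0.5–10 Hz for PPG, stopband attenuation 40 dB. Two decisions were
genuinely open:

* **Realization.** "Fourth-order band-pass" is ambiguous (a band-pass
  prototype of order 4 has 8 poles). We cascade a fourth-order high-pass
  and a fourth-order low-pass section, each literally fourth-order, which
  is numerically well-behaved with a 0.5 Hz edge at 125 Hz. Stopband edges
  sit at 0.5× the lower and 1.25× the upper passband edge.
* **Phase.** The filters run forward-backward (`filtfilt`), i.e.
  zero-phase. Alignment I compares peak *indices across channels*, so any
  group delay would bias the measured pulse arrival time. Odd reflective
  padding (up to 3 s) suppresses the start-up transients that
  forward-backward filtering otherwise leaves at the record ends.

### Peak detection

R peaks use the Pan-Tompkins chain — 5–15 Hz band-pass, five-point
derivative, squaring, 150-ms moving-window integration, adaptive
signal/noise thresholds with a 200-ms refractory period and a search-back
pass — with the final index refined to the ECG maximum within ±100 ms.
Systolic peaks use the two event-related moving averages ("block") method:
the mean-removed, clipped, squared PPG is smoothed with a 111-ms
(peak-scale) and a 667-ms (beat-scale) window; stretches where the short
average exceeds the long average plus an offset (0.02 × mean squared
signal) become blocks, blocks narrower than 111 ms are discarded, and each
surviving block contributes the PPG maximum inside it. Both moving
averages use partial windows at the record edges; zero-padding there would
dilute the beat-scale threshold and admit spurious end-of-record blocks.

### Alignment I (pulse arrival time removal)

For each R peak, the corresponding systolic peak is the first one strictly
before the next R peak. The anchor is the third such correspondence — the
first PPG beat is often poorly formed, and an early beat can pair with the
wrong R peak — and if beat 3 has no correspondence the anchor moves
*forward* to the next valid beat (with a warning), never backward. The PPG
is advanced by the anchor lag, both channels are truncated to common
support, and a negative lag is rejected as a diagnostic (physiologically
the PPG lags the ECG). The PPG is then min-max scaled to [0, 1] over the
full aligned record, matching the stage order (normalization before
splitting); `normalize = FALSE` supports leakage-free variants that scale
on training statistics only. The ECG is never normalized — reconstruction
is evaluated in mV.

### Splitting and segmentation

The nominal layout is 48 s train, 12 s validation, 12 s discarded, 228 s
test: one minute of supervision, then a test horizon 4.75× the training
duration. Alignment I shortens the record by the applied lag, so the
nominal 300 s never quite fits; `fit_split_spec()` shrinks the *discarded
gap* first (it exists to be thrown away) and only if the gap reaches zero
reduces the test duration, in steps of 12 s so the result stays divisible
by every segment length in {1, 2, 3, 4}. Train and validation durations
are never altered — they define the supervision budget. Segmentation is
gapless and non-overlapping within each role, so stitching the segments
reproduces the interval exactly; at *n* = 1 the layout yields 48/12/228
segments, at *n* = 4 it yields 12/3/57.

### The reconstructor

One BiLSTM layer, 25 hidden units **per direction** (the conventional
meaning of the layer-size argument in the major frameworks), sequence
output, followed by a per-timestep linear map from the 50 concatenated
features to one mV value. The output layer is linear: ECG amplitudes are
signed. L1 = L2 = 1e-4 applies to the input kernels (framework
`kernel_regularizer` semantics). Training: mean squared error — chosen to
match the rmse evaluation metric — with Adam at learning rate 0.001 and
batch size 1; windows are independent samples (no state crosses window
boundaries) and are reshuffled each epoch from the model seed. "Max
epochs = 1000" is read as a cap: by default training stops when validation
loss has not improved for 50 epochs and restores the best-validation
parameters; `early_stop_patience = 0` disables this and runs the full
budget. The implementation (forward pass, backpropagation through time,
Adam) is in C++ with its own seeded RNG, so a seed fixes initialization,
shuffling, and hence the entire training trajectory; the BPTT gradient is
verified against finite differences in the test suite. A NaN loss aborts
with a diagnostic rather than training on.

### Alignment II and evaluation

Some reconstructions are time-shifted relative to the reference, which
depresses the correlation without making the morphology wrong. Before the
aligned metrics, the reconstruction is shifted by the integer lag within
±80 ms that maximizes the normalized cross-correlation of the overlap.
Conventions the evaluation fixes: positive lag means the reconstruction
lags the reference; ties go to the smallest |lag|, negative before
positive; metrics after alignment use the truncated overlap (zero-padding
would bias both r and rmse). Per-segment aligned metrics use per-segment
lags; the stitched aligned metrics use one global lag.

The DTW local cost is `sqrt((i - j)^2 + (a_i - b_j)^2)` with the index
difference in raw sample units and the amplitude difference in signal
units, and the distance is labelled mV. The mixed units are deliberate —
this is the distance the evaluation protocol defines — and
`index_cost = FALSE` exposes a unit-consistent amplitude-only cost for
users who prefer it. The path uses steps {(1,0), (0,1), (1,1)}, is
anchored at (1,1) and (m,m), and the per-second distance `d̄` is the plain
quotient distance/duration with no further rounding. For stitched signals
(m ≈ 28 500 at 228 s) the full m×m matrix is impractical, and the optimal
path of a well-reconstructed signal hugs the diagonal, so the default is a
Sakoe-Chiba band of one second of samples; the banded and full solutions
agree on every instance the tests compare (m ≤ 500), and full mode remains
available for short signals.

## The synthetic generator

Real paired recordings from critical-care waveform databases are
credentialed and cannot ship with a package, so the tests and the
acceptance script run on synthetic subjects. Each beat places five
Gaussian bumps on the ECG (P, Q, R, S, T; R at 1.2 mV with 25-ms width,
the T wave 0.28 s later) and two on the PPG (systolic and a smaller
diastolic wave), with beat times on a jittered grid (default 60 bpm,
RR jitter SD 0.02 s) and the PPG delayed by a configurable PAT (default
0.2 s). Beat centers snap to the sample grid and only fully supported
beats are emitted, so the truth annotations are exact: every true systolic
index is exactly `round(pat_s * fs)` samples after its R peak. White (or
optionally band-limited) Gaussian noise is added per channel. Cohorts draw
per-subject heart rate, PAT, and morphology from ranges with per-record
sub-seeds.

What this emulates: quasi-periodic paired beats, a record-constant PAT,
RR variability, a deterministic (hence learnable) PPG→ECG mapping, and
additive noise. What it does not: beat-to-beat morphology variation,
arrhythmia, baseline wander, motion artifacts, sensor saturation, or
PAT drift. Passing the end-to-end test therefore demonstrates that the
pipeline's machinery — alignment, segmentation, training, stitching,
evaluation — works as designed on data satisfying its assumptions; it is
not evidence about performance on clinical recordings.

## Numerical and degenerate-input behavior

* Constant signals: detectors return empty index lists; `normalize_ppg`
  and `pearson_r` reject constant inputs as undefined rather than
  returning NaN.
* Fewer than three beat correspondences, negative lag, records shorter
  than the split, unequal window lengths, and alignment windows larger
  than the signal are all errors with named diagnostics; pipeline errors
  carry the stage name and record id.
* `pearson_r` is clamped to [−1, 1] against rounding; DTW cells outside
  the band are infinite; the band must connect the endpoints.
* Model and record serialization are plain text (CSV / JSON) at full
  precision, so round-trips are bit-stable to 1e-9 or better.

## Problem sizes in the tests

The test suite and acceptance script run at the study's native scale for
everything cheap (300-s records, 125 Hz, 228 one-second test segments) and
cap BiLSTM training at 200 epochs with early stopping — on a clean
synthetic subject the validation loss plateaus long before that (the
worked example stops at epoch 129), so the cap does not bind the result.
Determinism checks use a reduced 16/4/4/24-s layout and 25 epochs: they
exercise the whole pipeline and only need to compare two runs. Exhaustive
DTW oracles run at m ≤ 8 where full path enumeration is feasible.

## Known limitations

* Frequency content above the 20 Hz ECG passband is unrecoverable by
  construction.
* The model is strictly subject-specific; nothing in the package supports
  transferring a trained model across subjects.
* Alignment I assumes one global PAT per record; PAT drift within a record
  degrades the alignment and is not modeled.
* The synthetic generator's fidelity bounds what the tests can show (see
  above); conclusions about clinical data require clinical data.
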