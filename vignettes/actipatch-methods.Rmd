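---
title: "Methods: activity classification from chest-patch accelerometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activity classification from chest-patch accelerometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(actipatch)
```

## The problem

A single chest-worn patch records triaxial acceleration at a nominal
50 Hz together with a device-computed 1 Hz heart-rate series. The goal
is to label what the wearer is doing — lying, sitting, standing,
walking or jogging — so that physiological signals can be interpreted
in context: a heart-rate rise during jogging means something different
from the same rise at rest. Two classifiers address this at different
levels of granularity:

* a **cut-point rule** that thresholds a smoothed movement-intensity
  signal to separate *active* (walking, jogging) from *inactive*
  (lying, sitting, standing) states, cheap enough for streaming use;
* a **1-D convolutional neural network (CNN)** that assigns one of the
  five activity classes to each fixed-duration window.

## Preprocessing

Each axis is band-pass filtered with an order-4 Butterworth between
0.05 Hz and 2 Hz. The high-pass edge removes sensor drift and the
(constant) gravity projection; the low-pass edge removes vibration
noise above the dominant band of trunk movement. The default
`zero_phase` mode applies the filter forward and backward: no phase
delay, with the magnitude response squared (an effective order of 8).
A `causal` single-pass mode is provided for streaming; its gain at each
cutoff is the classic -3 dB, which the test suite verifies within 2%.

Only the last 20 minutes of each recording are analyzed (shorter
recordings are kept whole), excluding setup and calibration periods at
the start. Truncation happens *before* filtering, which confines filter
edge effects to data that is already inside the analysis span; the
reverse order would give practically identical results away from the
cut.

For the sampling-rate experiments the filtered signal is decimated to
5, 10 or 25 Hz after anti-alias low-pass filtering at 0.8x the new
Nyquist frequency (zero-phase order-4 Butterworth, i.e. an 8th-order
magnitude response). Windows are cut **after** resampling so a window
always spans `round(window_s * rate_hz)` samples.

### Windows and labels

Interval labels carry the five activity classes plus two markers:
`transition` (changes between states) and `interference` (deliberate
device manipulation). A window is labeled by the activity of the
interval covering its **final** sample — the most-recent-activity rule,
matching a trailing labeling convention where the label at time *t*
describes the preceding window. Windows overlapping a transition or
interference interval, or containing unlabeled samples, are excluded
from training and evaluation and tallied by reason. Fidgeting during
static activities carries the primary activity's label; it is part of
the class, not a class of its own.

Windows are non-overlapping by default (`stride_s = window_s`). The
stride is configurable; the design-contrast experiments below use a
common stride across window sizes so the contrast measures information
per window rather than training-set size.

## Cut-point classification

The vector magnitude `sqrt(x^2 + y^2 + z^2)` of the filtered axes is
smoothed with a **centered rolling median** over 5 s
(`N = round(5 * fs)` samples; 250 at 50 Hz). The median is robust: up
to half the window can be contaminated by spikes without moving the
output outside the range of the clean samples. Consumed causally, the
centered output is simply delayed by `(N - 1)/2` samples — about 2.5 s
at the default settings — which is what makes the rule viable in near
real time. Edges use the truncated available window; for even `N` the
window extends one sample further forward.

A sample (or a window, summarized by the value at its final sample) is
**active** when the smoothed magnitude strictly exceeds the threshold,
0.07 g by default. A value exactly at the threshold is inactive; the
strictness is a documented tie-break, tested explicitly. The threshold
is interpreted on the *filtered* magnitude, i.e. with the gravity
component removed — applying it to raw magnitudes (which sit near 1 g
at rest) would be meaningless.

**Calibration** reconstructs the threshold from labeled data: pool the
window-level values, scan candidate thresholds on a fixed 0.001 g grid
over the pooled range, and keep the threshold minimizing misclassified
windows (inactive above + active at/below), ties resolved toward the
smaller threshold. On separable data this returns the smallest
zero-error grid point, i.e. the upper boundary of the inactive
distribution; the grid is deterministic, so the procedure is exactly
reproducible and is checked against brute-force enumeration.

A **Mean Amplitude Deviation** (MAD) baseline is included:
`mean(|m - mean(window)|)` over the same 5-s rolling window, with a
published cut-point of 47.73 mG (0.04773 g). When a classifier predicts
no active windows at all, precision is reported as 0 rather than
undefined, so degenerate baselines still produce comparable numbers.

## The CNN classifier

The reference network maps a `window_len x 3` block to five class
probabilities: three convolution blocks (32 filters of width 7 with
max-pool 2; 64 filters of width 5 with max-pool 2; 64 filters of width
3), global average pooling over time, a dense layer of 64 units with
dropout 0.3, and a softmax output. Everything is configuration-driven;
for short inputs kernels are clamped to the available length and pools
skipped, so any window of at least 8 samples is valid (the 1 s x 5 Hz
grid cell, 5 samples, is the one combination that fails and is recorded
as a missing cell).

Training minimizes class-weighted cross-entropy with Adam (learning
rate 1e-3, batch 64, 30 epochs by default). Class weights are inverse
frequencies, `N / (K * N_c)`, so `weight_c * N_c` is constant across
present classes and rare classes (jogging) are not ignored. Per-channel
standardization statistics are computed **on the training fold only**
and stored with the model — the held-out subject leaks into neither the
gradient updates nor the normalization. Given a seed, initialization,
shuffling and dropout are fully reproducible; the network is
implemented directly on BLAS-backed matrix operations (im2col
convolutions), so no external deep-learning runtime is required.

Evaluation is **leave-one-subject-out cross-validation** (LOOCV): one
fold per subject, trained on all others, with fold seed
`config$seed + fold index`. Metrics are support-weighted precision,
recall and F1 plus accuracy; weighted recall is algebraically identical
to accuracy, an identity the tests assert on random instances.
Per-class F1 pools all folds' predictions into one confusion matrix
rather than averaging per-fold scores.

## Sensitivity analyses and the mixed model

`sensitivity_grid()` re-runs LOOCV over window sizes (1, 2, 4, 5, 8,
12 s) and rates (5, 10, 25, 50 Hz), emitting one row per subject, cell
and metric with scores in percent. `cutoff_sensitivity()` re-runs LOOCV
with the band-pass high cutoff at 2, 5, 10, 15 and 20 Hz.

`mixed_effects()` fits
`score ~ C(window, ref = 12) + C(rate, ref = 50) + C(metric, ref = f1) + (1 | subject)`
by REML with Wald z statistics and `beta +/- 1.96 SE` intervals, on the
percent scale, so coefficients read as percentage-point contrasts.
Stacking all four metrics into one response with a metric fixed effect
induces correlation between rows of the same cell; that is a property
of this design, kept deliberately. Per-subject (not per-fold-window)
scores enter the model. Singular fits are flagged, never silenced.
`simulate_metric_table()` generates score tables with known effects;
recovery simulations check that the injected window/rate contrasts fall
inside the fitted 95% intervals in at least 90% of replicates, and
null simulations keep |z| below 1.96 at roughly the nominal rate.

## Resting vitals

A subject's resting heart rate is the median heart rate over lying or
sitting intervals that end before the first walking bout (all of them
if the subject never walks). Deviations from this baseline are paired,
for every 5-s window whose *true* label is walking or jogging, with the
rolling-median magnitude at the window end (nearest heart-rate sample
within 1 s; unmatched windows are dropped and counted). Truth labels
rather than cut-point predictions define "active" so the physiological
analysis is not entangled with classifier errors. The pooled Pearson r
with its exact t-based p-value summarizes the coupling; a per-subject
breakdown is available from the returned pair table.

## The synthetic cohort generator

The generator produces labeled accelerometry plus coupled heart rate
with the statistical structure the analyses assume, so the whole
pipeline can be validated without recorded human data. Per subject it
runs one protocol pass — lying 3 min, sitting 6 min, standing 3 min,
walking 5 min, jogging 2 min, each jittered by +/-30% — joined by 3-8 s
cosine transition ramps, with one deliberate interference burst inside
the sitting block.

Device axes are x lateral, y along the torso, z out of the chest;
gravity lies along -y upright and -z lying. The components that matter
inside the 0.05-2 Hz analysis band are chosen to mirror what a chest
patch actually sees:

* **Gait**: a step-frequency sinusoid on y (walking 1.4-2.2 Hz at
  0.25-0.45 g; jogging 2.4-3.2 Hz at 0.6-1.0 g) with a half-amplitude
  second harmonic, 0.3x anterior-posterior crosstalk, and a lateral
  component at the *stride* frequency (half the step rate). The stride
  factor is 0.25 for walking and 0.5 for jogging: running rocks the
  trunk harder at the stride rate, and this is also what keeps measured
  in-band intensity ordered with effort after the 2 Hz low-pass has
  attenuated the jogging step fundamental — a pure >2.4 Hz sinusoid
  would vanish from the filtered signal, which real jogging does not.
* **Respiration**: a 0.2-0.3 Hz sinusoid on z in every posture,
  0.008-0.015 g upright and 2.5x deeper supine. Separating the static
  postures therefore requires resolving the *amplitude* of a slow
  oscillation — at least one respiratory cycle of context — which is
  what makes short windows genuinely less informative.
* **Postural sway**: 0.1-1 Hz band-limited noise (RMS 0.015 g) on x and
  z while standing only.
* **Fidgets**: Poisson bursts (2/min, 1-3 s, 0.05-0.15 g band-limited
  noise) during sitting and standing; they inherit the primary label
  and create the inactive tail that calibration has to cope with.
* **Noise**: white sensor noise (SD 0.01 g) in static blocks and
  broadband noise above 2 Hz (SD 0.02 g) on all axes everywhere. The
  latter is injected deliberately so that widening the filter's high
  cutoff admits noise without information, reproducing the direction of
  the cutoff-sensitivity finding.

Heart rate is `baseline + 60 bpm/g x (2-s moving average of the
gravity-free magnitude) + AR(1) noise` (marginal SD 2 bpm, lag-1
coefficient 0.9), sampled at 1 Hz, with baselines drawn from
N(65, 5) bpm. `expected_coupling_rho()` computes the correlation this
construction implies between the measured window magnitude and the
heart-rate deviation by deterministic quadrature over the gait
parameter ranges, applying the zero-phase filter gains per spectral
component; component phases are fixed constants so the quadrature sees
exactly the generated waveform. Within-block fluctuations are
neglected, so the value is a design (block-mixture) correlation; the
empirical pooled r converges to it as the number of subjects grows and
the tests check agreement within +/-0.1 on a 60-subject cohort. With
the default gain the design correlation is about 0.7 — the generator's
coupling is tighter than what heterogeneous real cohorts show, because
it omits fitness differences, autonomic drift and measurement artifacts.

Everything is deterministic given `(seed, subject index)`; a cohort
written to disk includes a `manifest.json` with every drawn parameter,
the ground truth for recovery tests.

### What passing tests do and do not show

The generator is a model of signal structure, not of biomechanics: gait
is a harmonic series, fidgets are band-limited noise, posture changes
are smooth ramps. Recovery of the cut-point boundary, high LOOCV F1 and
matching coupling correlations demonstrate that the *pipeline* is
implemented correctly and recovers known structure under realistic
noise — they say nothing about accuracy on recorded human data, where
class overlap (sitting vs standing in particular) is far harsher.

## Numerical and protocol choices

* Filter order 4 (order unstated upstream is a common choice);
  zero-phase for offline analysis, causal for streaming. Transfer-form
  `signal::butter` coefficients were verified numerically stable under
  `filtfilt` at the 0.05-2 Hz band of a 50 Hz signal.
* Rolling-median alignment is centered with truncated edges; the
  centered-window convention is what gives the clean `(N-1)/2`-sample
  causal delay statement.
* Ties at the cut-point go to inactive (strict `>`); calibration ties
  go to the smaller threshold; argmax ties in the CNN go to the earlier
  class in the fixed order lying < sitting < standing < walking <
  jogging.
* Scores enter the mixed model in percent; Wald intervals match the
  +/-1.96 SE convention.
* Validation problem sizes: the standard synthetic study cohort is 10
  subjects with the full protocol (about 2 100 windows); the validation
  harness trains the LOOCV folds for 12 epochs, where the training loss
  has long plateaued on this cohort, and runs the design-contrast
  experiments on a 4-subject cohort at 8 epochs with a common window
  stride. The coupling check uses 60 subjects with a one-third-length
  protocol, trading per-subject duration for the between-subject draws
  that dominate the pooled correlation's variance.

## Known limitations

* Sitting and standing differ only through sway and fidget statistics;
  a chest patch genuinely carries little else, and real-data confusion
  between these classes is expected to be worse than synthetic results
  suggest.
* Transitions are excluded, so performance estimates do not speak to
  continuous monitoring across state changes; the causal primitives
  exist but no streaming service is provided.
* The CNN is a compact reference architecture, not a tuned one;
  hyperparameters live in `cnn_config()` so published variants can be
  dialed in.
* Heart-rate coupling is instantaneous; real cardiovascular dynamics
  lag and adapt, which would lower observed correlations.
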