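# actipatch

Activity classification from chest-patch triaxial accelerometry.

A single chest-worn patch records triaxial acceleration (nominally
50 Hz, in g) and a device-computed 1 Hz heart-rate series. This package
turns those signals into activity context for physiological monitoring:

* **Cut-point classification** — active vs. inactive states from the
  5-s rolling median of the band-passed acceleration vector magnitude
  `m(t) = sqrt(x_f(t)^2 + y_f(t)^2 + z_f(t)^2)`, thresholded at 0.07 g.
  The centered 250-sample median makes the rule usable in near real
  time with a fixed delay of `(N-1)/2` samples (~2.5 s). A Mean
  Amplitude Deviation baseline (cut-point 0.04773 g) is included for
  comparison, and `calibrate_threshold()` re-derives the cut-point from
  labeled data by minimizing the overlap of the active and inactive
  window-value distributions.
* **Five-class CNN** — lying / sitting / standing / walking / jogging
  from fixed-duration windows via a compact 1-D convolutional network
  (three conv blocks, global average pooling, dense + softmax) with
  inverse-frequency class weighting, trained and evaluated under
  leave-one-subject-out cross-validation (LOOCV). Implemented directly
  on BLAS-backed matrix operations; no external deep-learning runtime.
* **Evaluation tools** — support-weighted metrics (weighted recall is
  identically accuracy), per-class F1 pooled across folds, confusion
  matrices, window-size x sampling-rate sensitivity grids, band-pass
  high-cutoff sweeps, and a linear mixed model
  `score ~ window + rate + metric + (1 | subject)` summarizing which
  design parameters drive performance.
* **Resting vitals** — per-subject resting heart rate (median over
  lying/sitting before the first walking bout), heart-rate deviations,
  and their pooled Pearson correlation with movement intensity during
  active windows.
* **Synthetic cohort generator** — labeled chest-patch recordings with
  posture-dependent gravity, gait harmonics, respiration, postural
  sway, fidgets, interference bursts, >2 Hz broadband noise and
  movement-coupled heart rate, deterministic per seed, with a manifest
  of all ground-truth parameters. Everything in the package is testable
  against it at desk scale.

Preprocessing follows the standard chain: keep the last 20 minutes,
band-pass 0.05-2 Hz (order-4 Butterworth, zero-phase by default,
causal mode for streaming), optionally decimate with anti-alias
filtering, then cut labeled windows (most-recent-activity rule;
transition/interference windows excluded and tallied).

## Worked example

```r
library(actipatch)

cfg <- generator_config(n_subjects = 4, seed = 42)
cohort <- generate_cohort(cfg)

## cut-point classification of one subject's windows
tab <- cutpoint_windows(cohort[[1]]$accel, cohort[[1]]$labels)
head(tab, 3)
#>   end_time_s      value label    truth     pred
#> 1       4.98 0.04504318 lying inactive inactive
#> 2       9.98 0.06745929 lying inactive inactive
#> 3      14.98 0.02029147 lying inactive inactive
unlist(evaluate_binary(tab$pred, tab$truth))
#>  accuracy precision    recall        f1
#> 0.9901478 0.9722222 1.0000000 0.9859155

## re-derive the threshold from the labeled cohort
all_tab <- do.call(rbind, lapply(cohort, function(s)
  cutpoint_windows(s$accel, s$labels)))
calibrate_threshold(all_tab$value, all_tab$label)
#> $threshold
#> [1] 0.06921615
#> $overlap_count
#> [1] 12

## five-class CNN under leave-one-subject-out cross-validation
res <- loocv(cohort, cnn_config(seed = 1), epochs = 8)
res
#> <loocv_result> 4 folds, 876 windows (5 s @ 50 Hz)
#> pooled weighted: accuracy 0.792  precision 0.862  recall 0.792  f1 0.780
round(per_class_f1(res), 3)
#>    lying  sitting standing  walking  jogging
#>    0.672    0.561    0.766    1.000    1.000

## heart-rate deviation vs movement intensity during active windows
correlate_vitals(cohort)
#> <vitals_result> 4 subjects, 337 active-window pairs (1 dropped)
#> Pearson r = 0.858, p = 4.28e-99
```

Reading the numbers: each row of `tab` is one 5-s window with its
rolling-magnitude value and the binary decision (`value > 0.07` g);
here 99% of windows are classified correctly and every active window is
caught (recall 1.0). Calibration recovers a threshold within a
millig of the 0.07 g default from the labeled distributions, with 12
windows in their overlap. The CNN, trained on only three subjects per
fold here, separates the locomotion classes perfectly while the static
postures — which differ only through respiration depth, sway and
fidgeting — remain the hard part; larger cohorts push the pooled
weighted F1 above 0.9. The positive Pearson r says heart-rate
deviations from each subject's resting baseline track movement
intensity across active windows.

Per-window predictions, heart rate and labels travel as plain CSV
(`time_s,x_g,y_g,z_g`, `start_s,end_s,activity`, `time_s,hr_bpm`); see
`read_accel()`, `read_labels()`, `read_hr()`. A thin command-line
front-end is installed at `inst/cli/actipatch` with subcommands
`simulate | filter | cutpoint | train-loocv | grid | cutoff-sweep |
mixed-model | vitals | demo`, e.g.

```sh
Rscript inst/cli/actipatch simulate --n-subjects 4 --seed 1 --out cohort/
Rscript inst/cli/actipatch demo --seed 1 --out demo/
```

### Converting annotation-tool exports

Interval labels exported from annotation UIs (e.g. Label Studio) can be
converted to the label CSV dialect with a few lines: flatten each
annotated region to `(start_s, end_s, label)` relative to recording
start, lower-case the label, map anything outside the vocabulary
(lying, sitting, standing, walking, jogging, transition, interference)
onto it or drop it, sort by start time, and write
`start_s,end_s,activity`. The reader validates ordering, overlap and
vocabulary, so conversion mistakes surface immediately.

## Package layout

* `R/io.R` — CSV dialects and validated containers
* `R/preprocess.R` — filtering, magnitude, rolling median, truncation,
  resampling, windowing (`src/rolling.cpp` holds the rolling kernels)
* `R/cutpoint.R` — binary classifier, MAD baseline, calibration
* `R/cnn.R`, `R/loocv.R` — the network and the cross-validation loop
* `R/evaluation.R`, `R/mixed_model.R` — metrics, grids, mixed model
* `R/vitals.R` — resting baselines and coupling
* `R/simulate.R` — the synthetic cohort generator
* `vignettes/actipatch-methods.Rmd` — models, assumptions, design
  choices and limitations
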