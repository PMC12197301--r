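---
title: "Estimating saliva secretion from throat-microphone swallowing sounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating saliva secretion from throat-microphone swallowing sounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(salivaflow)
```

## The problem and the model

Saliva secretion cannot currently be measured continuously: the reliable
procedures (weighing a cotton roll held under the tongue for 30 s, the
spitting method, imaging of the salivary glands) are one-off interventions.
The physiological link that makes continuous estimation possible is oral
clearance: saliva accumulates in the mouth from a residual volume RESID and
is swallowed when it reaches a trigger volume VMAX, so swallowing frequency
rises with the secretion rate. A throat-worn contact microphone hears
swallows (and little else of the environment), which turns secretion
estimation into an audio problem.

`salivaflow` implements the full chain:

audio → event segmentation → swallow classification → timing features →
ridge regression → grams per 30 s,

together with the synthetic generators needed to exercise and validate
every stage without recordings of human subjects, which are private in
this domain.

## Segmentation

"Volume" is implemented as a framed maximum of the absolute amplitude
(frame length 10 ms). A segment opens at the first frame whose envelope
reaches `onset_threshold_fraction` (default 0.10) of the recording's own
maximum envelope, and closes at the start of the first run of consecutive
sub-threshold frames lasting strictly longer than `silence_gap_s` (default
0.1395 s). Swallows consist of one to four short bursts separated by gaps
below that threshold, so the rule keeps one swallow in one segment while
splitting distinct events.

Numerical choices worth stating:

* The envelope definition is a package choice — any monotone loudness
  measure would do; the 10 ms frame quantizes boundaries by at most one
  frame, small against the 139.5 ms gap rule. The gap comparison is strict
  (`> 0.1395 s` terminates).
* The threshold is relative to the whole recording's maximum, which makes
  detection exactly invariant to positive rescaling of the input; an
  absolute threshold is available via `segmentation_config()` for
  recordings whose maximum is itself noise.
* A segment still open at the end of the recording is closed at the end of
  its last sounding frame rather than discarded.
* Segments are standardized to the 3-s classifier length by tail
  zero-padding (preserving onset alignment) or tail truncation.

The test suite checks the implementation against an independent
sample-granularity scan on randomized burst layouts whose gaps stay clear
of the 139.5 ms boundary (merge gaps ≤ 0.12 s, split gaps ≥ 0.16 s), so
frame quantization cannot flip a verdict.

## Time–frequency front-ends

**STFT (Method 1).** Hann window of 10.1 ms with a 5.05 ms hop; at
44.1 kHz these round to 445 and 223 samples. The log-compressed magnitude
(`log(1+x)`, appropriate for the wide dynamic range of swallow bursts) is
bilinearly resized to the CNN input resolution, 48×48 by default. The
input resolution is a package choice: the transform itself does not
dictate one, and 48×48 preserves the burst structure that separates the
classes while keeping desk-scale training practical.

**CWT (Method 2).** Continuous wavelet transform with the complex Gaussian
order-5 mother wavelet (cgau5), computed by FFT convolution with the
analytically differentiated Gaussian, L1-normalized per scale so that
equal-amplitude sinusoids produce equal modulus across scales (the
convention under which the peak row of a tone sits at the nearest
pseudo-frequency, `f = fc/(scale·dt)` with fc ≈ 0.59 for cgau5). The
default scale set is 19 logarithmically spaced scales spanning the throat
microphone's 200 Hz – 3 kHz band; both the count and the band are
configurable, and these defaults are declared choices, not recovered
constants. The modulus is rendered as a 224×224×3 image (min–max
normalized; grayscale replication by default, a colormap mode is
available). Clips are decimated to ~8.8 kHz before the CWT since all
band content lies below 3 kHz.

## Classifiers

Method 1 is a CNN with exactly four 3×3 convolution layers (16/32/64/128
channels), four 2×2 max-pooling layers and three fully-connected layers
(256/64/1), ReLU activations and a sigmoid output, trained with Adam on
binary cross-entropy. Kernel sizes, channel widths and FC widths are
unconstrained by the architecture contract and are documented defaults.

Method 2 consumes the 224×224×3 scalogram images. The only backbone that
ships with the package is `small_cnn_fallback`: a fixed grayscale
average-pooling stem (224 → 32) followed by two convolution/pooling stages
and a two-layer head. It builds and trains entirely offline; `freeze =
TRUE` trains only the head. Requesting `densenet121` raises an error,
because pretrained weights are not bundled with the package — the fallback
is the supported configuration, and the evaluation harness (stratified
folds, per-fold training, accuracy bookkeeping) is identical for any
backbone.

The training engine (im2col convolutions, max pooling, dense layers, Adam,
binary cross-entropy) is implemented in base R with BLAS matrix products;
its gradients are verified against numeric differentiation in the test
suite, and a fixed seed fully determines initialization and data order, so
runs are bit-reproducible. Defaults: 30 epochs, batch 32, learning rate
1e-3, decision threshold 0.5, no early stopping (determinism). The
cross-validation harness uses class-stratified folds with a seeded shuffle
(per-fold class counts within one item of proportionality); grouping whole
subjects into folds is available for cross-subject evaluation, where
accuracy is expected to drop.

## Events and features

Each swallow-labeled segment contributes one event at its onset (onsets,
not midpoints, are what mark swallows). Detections within 2 s are
suppressed by a greedy left-to-right pass that keeps an event only if it
is more than 2 s after the last *kept* event — the standard resolution of
"ignore the second of consecutive swallows", chosen so the rule is
idempotent and guarantees all surviving gaps exceed 2 s. The five features
over a 300-s window are the total count, the counts in the half-open bins
[0,100), [100,200), [200,300) (an event at exactly 100 s counts once, in
the second bin), and the population variance (divisor *n*) of the event
times in s²; the variance of fewer than two events is defined as 0. The
sample-vs-population divisor is not dictated by the feature definition;
population was chosen and is stated here for reproducibility.

## Estimator

Ridge regression with α = 10 on standardized features (means and scales
from the training data, stored with the model) and an unpenalized
intercept. Standardization is what makes a stated α reproducible — without
a scale convention the penalty is meaningless across feature units (counts
vs s²). Predictions are not clipped at zero by default. Evaluation is
leave-one-out cross-validation; the report contains the pooled Pearson
correlation and MAE, the moving-average MAE over the measured range
(window 0.05 g, overlap 0.025 g; the bin grid starts at the multiple of
0.025 g just below the smallest measurement — the grid origin is a package
choice), the half-split MAE (sorted by measurement; with odd *n* the
median trial joins the lower half), and the mean within-subject versus
overall sample SD (divisor *n*−1; subjects with one trial are excluded
from the within-subject figure with a warning).

## The synthetic generators, and what they do and do not show

The generators define the study conditions under which the package is
validated:

* `simulate_oral_clearance()` — deterministic clearance at a flow rate
  between RESID (0.8 mL) and VMAX (1.3 mL); VMAX−RESID = 0.5 mL with the
  0.48 mL/min unstimulated flow norm gives about one swallow per minute,
  matching the commonly reported resting swallow rate. The noiseless event
  count is exactly ⌊flow·T/(VMAX−RESID)⌋ (computed with a 1e-9 relative
  guard so exact-integer boundaries survive floating point). Optional
  per-interval flow noise uses a zero-truncated normal.
* `simulate_cotton_measurement()` — flow × 0.5 min × 1 g/mL (saliva
  density taken as 1 g/mL) plus Gaussian noise clipped at zero; default
  noise SD 0.03 g, a stated tuning constant of the surrogate, not a claim
  about real cotton-roll precision.
* `synthesize_swallow_clip()` / `synthesize_distractor()` — band-limited
  (200 Hz – 3 kHz) noise bursts with trapezoid envelopes for swallows, and
  four distractor signatures (harmonic stack, single broadband burst,
  low-frequency rubbing, single impulse). These are plausible stand-ins
  *by construction*, not reconstructions of real acoustics: no amplitude
  or spectral description of real swallows is available to copy.
* `generate_trials()` — 17 pseudo-subjects × 5 trials; subject mean flows
  N(0.48, 0.103) and within-subject trial flows N(mean, 0.100) mL/min,
  truncated at 0.02. These population constants were derived once from the
  reported variability regime of unstimulated secretion (overall SD
  ≈ 0.078 g, within-subject SD ≈ 0.058 g per 30 s) and are not adjusted.

Consequences for interpretation: passing tests show the pipeline is
*correct* (segmentation, suppression, features, regression and evaluation
all do what they claim) and that the classifiers can separate
well-separated classes. They do not show that real swallow sounds are this
separable from real coughs, or that real secretion obeys deterministic
clearance — the synthetic study's correlation (~0.9) is accordingly higher
than one should expect against wet-lab ground truth, where reported
correlations are nearer 0.6 and swallow-count–secretion correlations
nearer 0.3. The surrogate's measurement-noise floor (0.03 g) and the
1-event quantization of ⌊10·flow⌋ per 5 min bound the achievable MAE at
roughly 0.025–0.03 g, which is where the simulated study lands.

## Problem sizes and numerical choices in the validation suite

The shipped validation uses desk-scale sizes chosen as the package's own
test conditions: 200 random burst layouts for the segmentation oracle,
1000 random event sets for the suppression invariants, a 100-point
parameter grid for the clearance closed form, a 200-clip corpus (100
swallows, 25 of each distractor) with 5-fold CV for both classifiers
(6 epochs for Method 1, 10 for Method 2, batch 16 — enough for the
separable-by-construction corpus), and five seeded replicates of the
85-trial estimation study. `scripts/acceptance.R` recomputes all of these
from a single `--seed`.

## Known limitations

* No resampling: clips at rates other than 44.1 kHz are accepted with a
  warning (all window lengths derive from the rate), but mixed-rate
  pipelines are the caller's responsibility.
* The classifier operates on fixed 3-s standardized segments; swallow
  durations, per-swallow volumes, and multi-class (5-way) labels are out
  of scope.
* No adaptive noise-floor tracking; heavy continuous background sound
  would defeat a recording-relative threshold (use the absolute-threshold
  option).
* The fallback backbone is a compact CNN, not a pretrained DenseNet121;
  with pretrained weights unavailable offline, transfer learning proper
  cannot be exercised, only its harness.
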