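---
title: "Resource-constrained seizure-state classification for LFP signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resource-constrained seizure-state classification for LFP signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lfpdetect)
```

## The problem

Responsive neurostimulation devices for refractory epilepsy must decide, in
real time and on a few microamps of compute budget, whether the local field
potential (LFP) they are sensing contains epileptiform activity. The
classical solution is a band-power detector: band-pass filter, rectify,
smooth, threshold. It is cheap and effective, but tuning it per patient is
a filter-design exercise, and its smoothed envelope necessarily lags the
signal. `lfpdetect` implements that classical chain in embedded-faithful
fixed-point arithmetic, together with a competing classifier small enough
for the same hardware class: a multi-layer perceptron (MLP) of a few dozen
units reading a short window of raw samples, optionally behind a small
convolutional filter bank, quantized to 8-bit weights, with a
consensus-of-three smoothing of its output. Around the two classifiers sit
a synthetic LFP generator, a training pipeline, and an evaluation battery
(ROC, onset latency, clinician-label overlap, frequency-amplitude response
maps).

## The baseline detector

The band-pass stage is an 8--22 Hz Butterworth filter of total order 4,
discretized by bilinear transform with pre-warped edges and factored into
two second-order sections, each `b = g (1, 0, -1)` over `a = (1, a1, a2)`.
The overall gain is distributed so every cascade prefix has unit peak
magnitude, which keeps intermediate signals inside a 16-bit word. The
runtime is Direct Form I with 16-bit coefficients in Q2.13 (a stable
biquad's coefficients fit in ±4), 32-bit accumulators that saturate rather
than wrap (each saturation is counted and reported), and per-section
renormalization by an arithmetic right shift with round-half-away-from-zero.

Rectification is absolute value; the envelope is the exponential moving
average

y[n] = y[n-1] + (|x[n]| − y[n-1]) / 32,

i.e. a smoothing factor of 1/32 — a single right shift in fixed point. The
fixed-point envelope state keeps 15 fractional bits in a 32-bit register so
small envelopes do not dead-band. `y[-1] = 0`, and the threshold comparison
is `>=` (ties classify positive). The decay parameter admits a second
reading (an exponential time constant of 32 samples); the two are
numerically close and the smoothing-factor reading is the default.

The fixed-point path is validated against the floating-point reference run
with the *quantized* coefficient values: the residual is then pure rounding
noise, and each section's half-LSB rounding injection, propagated through
that section's own feedback and all downstream sections, gives an analytic
L1 bound that the implementation is tested against (observed maximum error
is typically a third of the bound on random input).

## The network classifier

The MLP reads 20 consecutive samples (78 ms at 256 Hz), normalized by a
fixed full-scale constant of 50 µV — an implant cannot standardize
per-window online, so the constant is part of the model file. Hidden units
are rectified-linear, the output unit logistic; the default topology
20-8-1 has 177 parameters. The paper-gap choices here (activations,
initializer) are the standard minimal ones compatible with binary cross
entropy. A convolutional variant inserts a filter bank (default 4 kernels
of length 8, stride 2 — sizes are conventions of this package, surfaced in
the constructor) before the dense head.

Scores are produced once per non-overlapping window. The *adjusted* output
averages the three most recent raw scores before thresholding (the first
outputs average whatever history exists). Averaging with a positive kernel
is variation-diminishing, so the adjusted label sequence never toggles more
often than the raw one — this is asserted as a property test over random
traces. A strict unanimous-vote mode (`mode = "votes"`) is available; the
two coincide for unanimous scores and differ only near threshold.

Post-training quantization is symmetric per-tensor: `scale = max|w|/127`,
integers in [−127, 127] (an all-zero tensor gets scale 1). Inference
dequantizes and computes in real arithmetic; bit-exact integer-only kernels
are a deployment concern outside this package's scope. On the synthetic
validation set the measured AUROC cost of quantization is below 10⁻³.

## Training pipeline

Windows are labeled by majority overlap: positive when more than half the
samples of a window fall inside an annotated event. The dataset is then
rebalanced to exactly 3 negatives per positive (all positives kept,
negatives subsampled without replacement) and split 70:30 with
stratification, both before training, so train and validation carry the
same 3:1 bias; balancing before splitting is one of two defensible
orderings and is the package default. Training is plain mini-batch gradient
descent (batch 32, learning rate 0.01, 200 epochs by default) on mean
binary cross entropy with predicted probabilities clipped at 10⁻⁷;
an abort with diagnostic fires on non-finite loss. Everything is
reproducible from a single integer seed per call; no global state is
consulted.

`grid_search()` re-windows the source recordings at every window length,
rebalances, splits, trains a fresh seeded model per cell and records
validation cross entropy. Cells that cannot train (e.g. too few positives
at a window length) are marked invalid rather than failing the surface.
The chosen cell is either the loss argmin or, under the
`"low_complexity"` rule, the smallest model within 10% of the minimum —
the "transition zone" reading.

## Synthetic data: what it emulates and what it does not

The generator stands in for undeposited clinical recordings: long
stretches of background at 1 µVrms punctuated by rare, seconds-long bursts
at 10 µVrms — the two amplitude scales the application domain actually
pins down. Background is pink (1/f) Gaussian noise, the standard first
approximation to inter-ictal LFP. Events default to a "spike-wave"
template: a 4 Hz sawtooth-like fundamental with phase-locked 1/h harmonics
up to the 22 Hz band top, under a 0.5 s raised-cosine taper at each end;
a narrowband alternative draws a sinusoid inside a configurable band.
Events are placed by rejection sampling with a 10 s minimum gap, with
either a Poisson count at a configurable hourly rate (default 1.25/h,
matching ~30 events per 24 h) or a fixed count. One annotation per event
covers exactly the tapered extent.

Three realism caveats matter for interpreting green tests. First, real
inter-ictal background has heavier-tailed envelope statistics (beta
bursts, artifacts) than pink noise, so realistic detector thresholds sit
far higher relative to the median envelope than here. Second, real seizure
onsets build band power over seconds; the 0.5 s taper compresses onset
dynamics. As a consequence both detectors' onset latencies here are
dominated by the taper (~0.3 s), and the latency *gap* between the
adjusted MLP and the filter chain at matched false-positive rate — large
on clinical data — is small on this synthetic material and can fall either
way depending on the realization; the acceptance suite measures it at a
matched per-timestep FPR of 0.1% (a deployment-grade operating point) and
asserts the ordering strictly. Third, the harmonic-comb event template
induces comb-structured generalization: the trained network's
frequency-amplitude response map shows the expected low-frequency lobe and
window-rate (12.8 Hz) periodic side lobes, but its coverage of the
18--22 Hz part of the filter band at the 0.5 level varies with the
training realization. Passing tests therefore demonstrate the pipeline's
correctness and the qualitative structure of the comparisons, not clinical
performance.

## Evaluation battery

ROC curves sweep the threshold over unique score values per output
timestep, with truth derived from the annotations at the classifier's own
output timestamps; AUROC is trapezoidal. Onset latency is the time from an
event's annotated onset to the first positive output within a 10 s search
window (detections before onset are false positives, not negative
latencies); missed events are excluded from the mean and reported
separately. Overlap is the percentage of an event's duration during which
the trace is positive, with labels held piecewise-constant over each
output's hop interval. The response map presents 1 s sinusoidal test tones
(random phase, fresh 1 µVrms background per repeat, 10 repeats) on a
frequency × amplitude grid; the filter chain's score is its peak envelope
normalized by the envelope of a full-scale rectified sinusoid
(2/π × 50 µV) so both classifiers plot on [0, 1] — the normalization is
this package's convention, chosen because a raw envelope has no natural
[0, 1] scale.

## Problem sizes

The shipped tests and the acceptance script run at desk scale, chosen so
the full suite completes in minutes while keeping every comparison
statistically meaningful: a 600 s training recording with 12 events
(~6 500 windows after rebalancing), a 2 400 s evaluation recording with 40
events for latency and overlap, 15 × 5 response-map grids at 10 repeats,
and a two-cell grid search (hidden 1 vs 8 at window 20) for the
complexity-transition check. The 24 h / 30-event density of the emulated
clinical dataset is exercised at the placement level, where it is cheap.

## Known limitations

* Single-channel only; no stimulation-artifact model; no patient-specific
  morphology.
* The latency comparison's sign is condition-dependent at this synthetic
  scale (see above); the pipeline measures it honestly rather than
  reproducing a fixed gap.
* Quantized inference is dequantize-then-multiply, not integer-only.
* The EDF writer covers the single-channel subset of the format (1 s
  records, zero-padded tail); annotations travel as CSV sidecars.
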