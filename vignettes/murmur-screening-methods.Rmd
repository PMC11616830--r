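---
title: "Methods: phonocardiogram murmur screening with a Bayesian residual network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phonocardiogram murmur screening with a Bayesian residual network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The screening problem

Heart murmurs — audible turbulence between the two fundamental heart sounds
S1 and S2 — are an accessible screening indicator of structural heart
disease, particularly in paediatric populations where echocardiography is
scarce. The input to this package is a phonocardiogram (PCG) dataset in the
public challenge layout: per patient, up to six chest-wall recordings
tagged with their auscultation site (aortic, pulmonary, tricuspid, mitral
valve, or unspecified), a murmur label (Present / Absent / Unknown), a
clinical outcome label (Normal / Abnormal), and demographics (age group,
sex, height, weight, pregnancy status) with substantial missingness
(~13% in the real training cohort). The package estimates, per patient, the
probability that a murmur is present (grouping Present with Unknown as the
screening-positive class, configurable) or that the clinical outcome is
abnormal — the two tasks share the identical pipeline and differ only in
the target label.

## Pipeline

1. **Preprocessing.** Every recording is resampled to 4 kHz (polyphase
   FIR), peak-normalised per recording to $[-1, 1]$, and cut into
   overlapping segments of 4 s with a 1 s stride; a recording shorter than
   4 s yields one zero-padded segment rather than being dropped. Each
   segment becomes a log-mel spectrogram: STFT with a 25 ms periodic Hann
   window and 10 ms hop, no centering (so a 4 s segment at 4 kHz has
   exactly $1 + \lfloor(16000-100)/40\rfloor = 398$ frames), FFT length
   equal to the next power of two above the window length, triangular mel
   filterbank spanning 10–2000 Hz, and $10\log_{10}$ compression with a
   $10^{-10}$ power floor. The number of mel bands is not pinned down by
   the source pipeline; the default is 128 (the usual audio-classification
   resolution) and the desk-scale test configuration uses 32. Each window
   is min–max scaled to $[0,1]$ before entering the network (configurable;
   without scaling the log image is amplitude-shift-equivariant, which the
   tests assert).

   Whether normalisation is per recording or per window is not stated by
   the source work; we normalise per recording, matching its description
   of dataset-level signal normalisation, and expose the window-level
   min–max as a separate, documented step.

2. **Window classifier.** A residual convolutional network maps each
   window image to a murmur probability. Dropout layers sit after each
   intra-block activation of every residual block; keeping them active at
   inference and averaging $T$ stochastic forward passes is the standard
   Monte Carlo dropout approximation to a Bayesian predictive
   distribution: the pass mean is the predictive probability, the pass
   standard deviation the uncertainty. With the dropout rate at zero the
   model collapses exactly to the plain ("Res") baseline — the tests
   assert numerical identity — and $T = 1$ has zero spread by definition
   (the spread uses the $1/T$ population form).

   Two backbones share one code path: `resnet18-lite`, a width- and
   depth-reduced basic-block network (stem 7×7 stride 4 into two stages
   of two blocks, 12 and 24 channels) intended for desk-scale work, and
   `resnet50` with the canonical bottleneck 3-4-6-3 layout. The network
   engine is implemented natively in R (im2col + GEMM convolutions,
   hand-derived gradients verified against finite differences, Adam,
   weighted binary cross-entropy). Batch normalisation is omitted; at the
   scales this package trains at, He initialisation with Adam converges
   without it, and its absence keeps MC-dropout inference free of
   train/eval statistics mismatches. The published pipeline initialised
   its backbone from ImageNet weights; no such checkpoint ships here, so
   initialisation is He-normal by default and a `pretrained_weights`
   checkpoint path is accepted. Dropout rate (0.2), epochs, learning rate
   and batch size are this package's defaults — the source work does not
   report its winning configuration — and are all config-exposed.

   Windows inherit their patient's label (weak labelling): every systole
   of a murmur-positive patient is assumed to carry the murmur. Training
   holds out a patient-grouped, label-stratified validation slice for
   checkpoint selection on validation loss; patient leakage between the
   slices is a hard error, as is a single-class training set.

3. **Aggregation.** Window probabilities are aggregated by arithmetic
   means in two stages: windows within a recording, then recordings
   within a patient. The source work states only "arithmetic mean"; the
   two-stage form is the default so that a patient with many windows at
   one site is not over-weighted, and pooled-window averaging is
   implemented as an alternative mode. The MC spread propagates as the
   mean of window standard deviations.

4. **Multimodal fusion.** The aggregated deep score joins a tabular
   feature row: demographics (age group mapped to approximate months —
   Neonate 0.5, Infant 6, Child 72, Adolescent 180, the challenge
   baseline convention; one-hot sex; binary pregnancy) with mean
   imputation of numeric fields fitted on training patients only, plus
   audio summary features per recording averaged per patient (time-domain
   moments, RMS, zero-crossing rate; framewise spectral centroid,
   85%-energy roll-off and energy-weighted bandwidth, each as mean and
   SD; dominant frequency). A gradient-boosted tree classifier (xgboost,
   shallow trees of depth 3, up to 200 rounds with early stopping on the
   network's validation patients, single-threaded for reproducibility)
   produces the fused probability; "weighted" mode applies
   inverse-class-frequency sample weights. The deep score's MC spread can
   be added as a fusion input behind a flag, off by default, since the
   source pipeline's use of it is unstated. Fusion rows for training are
   produced by the already-trained network on its own training patients;
   no out-of-fold machinery is used, and the held-out evaluation patients
   never contribute rows.

## Evaluation protocol

Metrics follow the screening convention: per-class accuracies
(sensitivity for the positive class, specificity for the negative),
overall accuracy, ROC AUC via the Mann–Whitney midrank statistic (ties
count one half; equal to the exhaustive pairwise oracle, which the tests
enumerate), FNR/FPR, and a weighted accuracy
$\sum_i w_i c_{ii} / \sum_i w_i n_i$ over true classes that reduces to
plain accuracy under equal weights; the three-class challenge murmur
weights (5/3/1) ship as a constant credited to the challenge definition.
A score equal to the decision threshold counts as positive — threshold
sweeps need a fixed tie policy and the source figures do not state one.
Rates whose class is empty are reported as `NaN` with a flag, never as a
silent zero.

Cross-validation is stratified and grouped at patient granularity (fold
assignment by round-robin within label strata after a seeded shuffle), so
no subject's windows span train and test; fold summaries report
across-fold mean and standard deviation. Utilities cover the balanced
subsampling of an imbalanced site to its minority count, a seeded 70/30
patient split for fine-tuning protocols, and zero-shot transfer: a fitted
pipeline applied to a foreign catalog through the identical preprocessing
with a guard that verifies — by exact comparison of serialised parameters
— that nothing was updated. Transfer reports carry the (overall,
positive-class, negative-class) accuracy triple in that order.

Patients with zero usable recordings (or a missing task label, in
training) are excluded with a warning; the evaluation behaviour for such
patients is not specified by the source work, and silent guessing seemed
worse than an explicit exclusion list.

## Synthetic cohorts

The generator exists to make the pipeline testable without downloads; it
emulates the data *layout* and *label statistics* of the public cohorts,
not their acoustics. A recording is a periodic train of S1/S2
damped-sinusoid transients (centre frequency 50–150 Hz, 30–50 ms,
heart rate 70–140 bpm) plus ambient white noise at −25 dB relative to the
unit S1 peak. A murmur is band-limited Gaussian noise (150–400 Hz) gated
to systole at a configurable SNR over the ambient floor in that band
(+10 dB default); "Unknown"-label patients receive the same construction
12 dB quieter, so the Present∪Unknown binary grouping remains meaningful
while Unknown cases are genuinely hard. Labels and demographics are drawn
from the published joint distribution: murmur prevalence 73.8/7.2/19.0%,
outcome conditionals P(Abnormal|Present) = 150/179,
P(Abnormal|Absent) = 263/695, P(Abnormal|Unknown) = 43/68, age-group
frequencies 6/126/664/72/74 of 942, and 13% joint missingness of age,
height and weight. Defaults reproduce the real cohort's conditions
(recording lengths 5–80 s, 1–6 locations per patient).

What passing tests on these cohorts shows: the pipeline can recover a
planted, physiologically plausible spectral class difference under the
real label imbalance, and its protocol machinery (grouping, balancing,
transfer guards) is correct. What it does not show: performance on real
phonocardiograms, whose murmurs vary in band, timing and morphology, and
whose noise is structured (ambient speech, stethoscope handling, sensor
detachment). No claim about real-data accuracy follows from the synthetic
results.

## Desk-scale problem sizes and numerical choices

The test suite and the acceptance script run everything at sizes chosen
once for desk-scale work: cohorts of 200 training-site and 300
control-site patients, recordings of 6–9 s, 1–2 locations per patient,
32 mel bands, the lite backbone trained 8 epochs with Adam at
$2\times10^{-3}$, batch 32, $T = 10$ MC passes at prediction. Under these
conditions the end-to-end pipeline reaches held-out murmur AUC above 0.9
at +10 dB murmur SNR, while two null controls — training labels shuffled
at patient level, and cohorts whose murmur band is numerically absent
(−100 dB) in both classes — stay at chance. The null-control AUCs are
evaluated on the larger control site so that their sampling scatter
(±~0.04) sits well inside the documented chance band of [0.4, 0.6].

Numerical conventions worth stating: the MC-mean stability check across
dropout seeds is asserted in aggregate (mean absolute difference within
$3\,\bar\sigma/\sqrt{T}$ over the fixed inputs, individually within
$6\sigma/\sqrt T$), because a per-input 3σ bound over 20 inputs would fail
a quarter of runs by construction; all-zero signals are flagged and
propagated as zero feature vectors rather than NaNs; the all-zero
spectrogram window maps to the log floor and, under min–max scaling, to
the zero image; unparseable numeric header fields map to missing rather
than erroring, since missingness is an expected state of the real data;
and every stage derives its RNG stream from one global seed with fixed
offsets (simulate +0, network +1, MC passes +2, fusion +3, fold $f$
+10·f), so any stage can be reproduced in isolation.

## Known limitations

The network engine is plain-R and single-threaded: the full `resnet50`
path is constructible and runs, but training it at the published scale is
not practical here — the lite backbone is the supported training
configuration, and the `resnet50` configuration exists for structural
fidelity and checkpoint loading. The synthetic murmur model is
deliberately crude (no S1/S2 split variation, no respiratory modulation,
no signal-quality degradation), and heart-sound segmentation into
S1/systole/S2/diastole states is out of scope, as is any denoising or
signal-quality classifier. The three-class murmur task and the
challenge's outcome *cost* metric are not reproduced; the weighted
accuracy takes its weight vector as an input, and the cost metric slot is
a pluggable callable.
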