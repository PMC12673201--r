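---
title: "Classifying coronary MRA patches with a center-weighted 3D CNN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying coronary MRA patches with a center-weighted 3D CNN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Coronary magnetic resonance angiography (CMRA) shows the coronary lumen as a
bright tubular signal on darker surroundings. A segment with *significant
stenosis* — conventionally a reduction of the luminal diameter by 50% or
more — appears as a focal drop in that signal profile. stenonet classifies
fixed-size volumes of interest (VOIs) of 21 × 21 × 21 voxels, each centered
on an annotated point of a coronary segment, into *stenosis* versus *no
stenosis*.

The classifier is a small two-block 3D convolutional network:

1. **Feature-extracting block 1**: 3D convolution (same padding), batch
   normalization, ReLU, and 2 × 2 × 2 max pooling, taking the 21³ VOI to 11³
   feature maps.
2. **Gaussian weighting layer**: every channel of the 11³ maps is multiplied
   elementwise (Hadamard product) by a fixed, non-learned Gaussian weight
   `w(v) = exp(-||v - c||² / (2σ²))` centered on the map center `c`. Because
   the VOI is *centered on the annotation*, this focuses the classifier on
   the voxels where the lesion must be, implementing a hard-coded spatial
   attention prior.
3. **Feature-extracting block 2**: the same conv–BN–ReLU–pool stack, taking
   the weighted 11³ maps to 6³ maps.
4. **Classifier head**: a fully connected layer over the flattened 6³ maps
   and a softmax, emitting `(p_no_stenosis, p_stenosis)`.

The spatial contract 21 → 11 → 6 is only satisfiable with *ceil-mode*
pooling at window 2 / stride 2 (floor mode gives 10 and 5); `network_config()`
asserts this and rejects any configuration that breaks it. Ceil-mode pooling
is implemented by padding odd-sided maps with −∞ before taking window maxima.

Training minimizes the weighted cross-entropy error

  WCEE = −(1/n) Σᵢ wᵢ ⟨tᵢ, log yᵢ⟩,

where tᵢ is the one-hot true class, yᵢ the softmax output and wᵢ the weight
of example *i*'s true class. Class weights address the heavy imbalance of
stenosis data (≈ 9% positive): the default `"auto"` sets
`w_k = n_total / (2 n_k)` on the training folds, so a random training
example has expected weight 1. Optimization is plain SGD with momentum 0.9,
and early stopping monitors the validation-fold WCEE.

## Patient-level, stenosis-balanced cross-validation

Evaluation uses four-fold cross-validation *at the patient level*: all
segments of a patient share a fold, so no information about a test patient
can reach training (augmented copies inherit their parent's patient and thus
its fold). Patients are assigned greedily — sorted by descending
positive-segment count, ties shuffled by seed, each placed into the fold
currently holding the fewest positives — which balances positives across
folds up to patient granularity. For rotation *r*, fold *r* is the test set,
fold *(r+1) mod 4* the validation set and the remaining two folds train the
network; each fold is the test set exactly once, so every retained segment
receives exactly one out-of-fold probability score. Positive training VOIs
are augmented four-fold by 90° rotations about each axis (rotations permute
voxels, so labels are unaffected); validation and test VOIs are never
augmented.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| `gaussian_sd` | 0.75 | voxels on the 11³ map | Sharply center-peaked spatial prior; see below. |
| `channels_block1/2` | 16 / 32 | – | Smallest conventional doubling pyramid; the source architecture does not pin channel counts. |
| `conv_kernel` | 3 | voxels | Standard minimal 3D kernel with same padding. |
| `batch_size` | 4 | VOIs | Training protocol default. |
| `max_epochs` | 50 | epochs | Training protocol default; early stopping usually halts far earlier. |
| `learning_rate` | 1e-4 | – | Training protocol default for SGD-momentum. |
| `momentum` | 0.9 | – | Training protocol default. |
| `patience` | 5 | epochs | Early-stopping convention; the protocol states only that validation-based early stopping was used. |
| `class_weights` | `"auto"` | – | Inverse class frequency on the training folds. |

**The Gaussian SD.** The value 0.75 is stated without units. We read it
literally as voxel units on the 11³ post-pooling map, which concentrates
the weight almost entirely on the central 3³ voxels. A plausible alternative
is a normalized-coordinate reading (a much broader bump). Because the choice
materially changes the layer's receptive emphasis, `gaussian_sd` is
configurable; the default follows the literal reading.

**Weighting position.** The weighting layer sits between the two blocks and
is applied to the 11³ *post-pooling* maps, identically across channels; the
weight matrix is fixed, never learned.

## What the phantom generator emulates — and what it does not

No CMRA dataset is bundled; `generate_phantom_dataset()` produces volumes
with the statistical and geometric structure the classifier assumes:

* bright tubes (lumen intensity 1.0) on darker background (0.1), radius 3
  voxels, with mild quadratic centerline curvature (≤ 2 voxels);
* positive segments carry a focal radius reduction over a 3–5 voxel extent,
  drawn from `[0.5, 1.0]` diameter reduction, centered at the annotation;
  negatives are annotated at a uniform centerline point, occasionally
  (5%) with a sub-significant narrowing;
* per-patient multiplicative intensity scale (log-normal, σ = 0.1), so the
  patient-mean normalization step is non-trivially exercised;
* Gaussian blur (σ = 0.5 voxel) and additive Gaussian noise (σ = 0.02, i.e.
  high SNR); Rician magnitude noise is available via `noise_model`, and
  volumes are clamped at zero as magnitude images are non-negative.

Defaults describe a cohort of 60 synthetic patients with 12 segments each at
10% stenosis prevalence — sizes chosen to mirror the prevalence regime of
clinical segment tables while remaining tractable on a single CPU.

The phantoms deliberately omit cardiac/respiratory motion, coil sensitivity
profiles, k-space artifacts, real coronary tortuosity, neighboring
structures (veins, myocardium) and calcification. A high out-of-fold AUC on
phantoms therefore demonstrates that the pipeline — extraction,
normalization, augmentation, weighting, training, patient-level scoring — is
implemented correctly and can recover a known signal; it does **not**
predict clinical performance on patient data.

## Numerical and design choices

* **Patient-mean normalization** divides by the mean over *all* voxels of
  the patient volume (the literal reading of "average signal value of the
  images"); a body-mask variant is available (`patient_volume_mean(mask=)`).
* **Border handling**: a VOI whose annotation lies within 10 voxels of a
  volume border is completed by edge replication with a warning
  (configurable to strict rejection). Phantom annotations are placed so
  this never triggers in simulated cohorts.
* **Rotation convention**: 90° counterclockwise viewed from the positive end
  of each axis, axes in index order. Labels are rotation-invariant, so the
  convention cannot affect correctness; it is fixed for reproducibility.
* **Validation fold**: the protocol does not say which subset validates each
  rotation; we fix validation = fold (r+1) mod 4.
* **Decision rule**: `score > threshold ⇒ positive`; ties at the threshold
  count negative. The Youden operating point maximizes J = sensitivity +
  specificity − 1 over the observed thresholds, ties broken toward the
  *lowest* threshold (favoring sensitivity, the screening-relevant choice).
* **AUC** is the Mann–Whitney estimator with ties counted ½, identical to
  the trapezoidal area under the empirical curve. The DeLong test uses
  placement-value covariances; a zero-variance difference returns p = 1 with
  a warning rather than an error.
* **Observer-case selection** (stated goal only, no published algorithm):
  seeded accept/reject over stratified draws — score-decile strata within
  each class, largest-remainder allocation — until the subset AUC matches
  the full-set AUC within tolerance (cap 10,000 draws, best draw returned).
* **Group-averaged ROC**: arithmetic mean of per-reader AUCs and vertical
  averaging of curves on a common false-positive-rate grid. How *average*
  reader AUCs were compared with a test defined for two correlated curves
  is not described in the source protocol; comparing per-case mean ratings
  is one reading, and we expose only the well-defined two-curve test plus
  the group average.
* **Loss clamping**: predicted probabilities of exactly 0 at the true class
  are clamped to 1e-12 (with a warning) so the loss stays finite.
* **Early stopping** restores the parameters of the best-validation epoch;
  batch-norm running statistics (momentum 0.1) travel with the parameters.
* **Initialization**: He-uniform for convolution and FC weights, zeros for
  biases, unit scale / zero shift for batch norm, all seeded; two runs with
  identical seeds are bit-identical.

## Problem sizes used by the test suite

The deep-learning stack is implemented natively in R on BLAS matrix
products (im2col convolutions), so wall-clock cost scales directly with
channel width and cohort size. The end-to-end cross-validation check runs
the full 60-patient default cohort with an 8/16-channel network, batch 8,
learning rate 1e-3 and at most 10 epochs per fold — a width and schedule
chosen as the smallest configuration that cleanly separates the phantom
classes; the architecture itself (two blocks, weighting layer, contract
21 → 11 → 6) is exactly the default one. Reproducibility checks use an
8-patient cohort and 2 epochs, where bit-identity is as informative as at
full scale. Unit tests of the layers use 2–4 channel networks, where
finite-difference gradient checks are cheap and exact.

## Known limitations

* Pure-R training is single-threaded BLAS-bound; training hundreds of
  epochs on thousands of VOIs is feasible but slow compared to GPU stacks.
* The phantom's realism limits are listed above; in particular the
  separability of the default cohort is intentionally high.
* Batch normalization uses biased batch variance for both normalization and
  running statistics; with very small batches (the default batch size is 4)
  running statistics are noisy, which is inherent to the protocol's batch
  size, mitigated by the momentum-0.1 running average.
* `select_observer_cases()` matches the subset AUC to the full-set AUC; it
  does not reproduce any particular published case list.
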