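---
title: "Multimodal DMN classification: model, synthetic world, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal DMN classification: model, synthetic world, and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

`dmnfuse` implements a complete, testable pipeline for discriminating
Alzheimer's disease (AD) from cognitively normal (CN) participants by fusing
two modalities:

* **Imaging**: four 3-D seed-correlation maps of the default-mode network
  (posterior cingulate, left and right lateral parietal, medial prefrontal
  cortices), stacked as channels of one volume per participant.
* **Clinical**: six neuropsychological scores (ADAS-Cog 13, ECog patient
  total, FAQ, MoCA, RAVLT immediate recall, RAVLT percent forgetting),
  min-max normalized to $[0,1]$:
  $x_{\mathrm{norm}} = (x - x_{\min}) / (x_{\max} - x_{\min})$.

The classifier is a split architecture. A convolutional feature extractor
(channel chain $4\to8\to16\to24\to24\to32\to64$; first kernel $6^3$
unpadded, the rest $3^3$ with padding 1, stride 1 throughout; $3^3$/stride-2
max-pools; ReLU activations) compresses the image stack to exactly 64
features. In multimodal mode the 6 normalized clinical scores are
concatenated to these features, so the linear head (70→32→1, batch-norm,
ReLU, dropout 0.2, sigmoid output) sees 70 inputs; the unimodal variant sees
64. Training uses binary cross-entropy, Adam, and random flip/quarter-turn
rotation augmentation, under leave-one-out cross-validation (LOOCV): each
participant is held out once, the final-epoch model of each fold evaluates
its held-out participant, and the pooled held-out predictions feed a full
metric suite (accuracy, sensitivity, specificity, precision, F1, MCC; AD is
the positive class, threshold 0.5).

Explanation uses **perturbation ranking**: on each fold's held-out
participant, each of the 10 input features (4 ROI channels, 6 clinical
scores) is randomized in turn — voxel permutation for a channel, a uniform
$[0,1]$ draw for a score — and the model's error under perturbation,
averaged over draws, folds, and diagnosis group, measures how much the model
relied on that feature. Within each group, features are ranked by descending
mean error and importances are normalized by the group maximum, so the top
feature scores exactly 1. The rank change (CN rank − AD rank) summarizes
group-specific reliance.

## Why the network is implemented natively

No deep-learning framework is available to the package's target
installations, so convolution, pooling, batch-norm, dropout, Adam and
backpropagation are implemented directly: convolutions are cache-blocked
im2col gathers feeding BLAS GEMMs (compiled via Rcpp/Armadillo), and each
layer carries an explicit backward pass. The backward pass is verified
against finite differences in the test suite, and the convolution and
pooling kernels against independent direct-loop oracles.

## Architectural choices the dimensional contract does not fix

The reference architecture fixes the layer widths, kernel sizes, the pool
hyperparameters (kernel $3^3$, stride 2), and the head's 70/64 input width —
which forces the extractor to collapse to exactly 64 values. It does not fix
pool placement, padding, conv activations, or how the collapse happens.
Choices made (each is a package design decision, not a reproduction):

* Max-pools follow convolutions 1–5; convolutions 2–6 use padding 1 so the
  $3^3$ kernels do not erode small grids; a final **global max-pool**
  guarantees a 64-vector for any input the first convolution accepts. A
  scheduled pool is skipped when the grid is already smaller than the pool
  window — necessary for the $16^3$ test grid, harmless at $91^3$.
* ReLU activations on conv layers, batch-norm and dropout on the head only.
* Fan-in uniform weight initialization, seeded; classification threshold
  0.5.
* Rotation augmentation is restricted to quarter turns in a random spatial
  plane, so augmentation permutes voxels without interpolation and is
  exactly measure-preserving; it therefore requires cubic grids.

## Batch-norm calibration before held-out evaluation

Training under LOOCV at these sample sizes is effectively full-batch
(51 participants at full scale, fewer in tests, always below the configured
batch size of 64), and short runs take only a handful of optimizer steps.
Batch-norm's exponentially averaged running statistics (momentum 0.1) are
then still dominated by their $\mathcal N(0,1)$ initialization, so
evaluation-mode normalization would use moments unrelated to the trained
network. After the last epoch each fold therefore runs one forward pass over
the unaugmented training batch and sets the running statistics to that
batch's exact moments — the training-population statistics that
evaluation-mode batch-norm is defined to estimate. This is standard
batch-norm recalibration, chosen on estimator-correctness grounds.

## Normalization scope and leakage

Clinical min-max parameters are fitted on the full cohort before
cross-validation by default, matching the reference procedure's order of
operations. This leaks the held-out participant's marginal extrema (not its
label) into training folds; `train_config(refit_normalization = TRUE)`
provides the strictly leakage-free per-fold refit. Bundles are atomic — all
of one participant's data travel together — so no participant can straddle
the train/validation split.

## The synthetic world

The original cohort is controlled-access, so the package ships a generator
that emulates its *shape*, not its content: balanced groups (26 + 26 at full
shape → 208 images and 520 datapoints), four co-registered correlation-like
volumes per participant (white Gaussian noise, smoothed with a 1-voxel
Gaussian kernel to mimic the spatial correlation of connectivity maps,
baseline 0.2, clipped to $[-1,1]$), and six clinical scores drawn from
truncated normals on each instrument's native range. Group effects are a
configurable mean shift inside an axis-aligned subvolume (default: the
central half-cube, shift −0.15, i.e. reduced DMN connectivity in AD) and
per-measure group means. The default clinical means/SDs are chosen once as
clinically plausible values for mild AD versus controls (e.g. MoCA 26 ± 3 vs
17 ± 3, ADAS13 9 ± 5 vs 30 ± 5); the source cohort's distributions are
unpublished, so these are placeholders, not calibrations. A null
configuration (no group differences anywhere) supports negative-control
tests.

What a green synthetic test does establish: the plumbing is leakage-safe,
training optimizes, the multimodal route exploits clinical signal the
unimodal route cannot, and perturbation ranking recovers known informative
features. What it does not establish: anything about real fMRI — no
anatomy, registration error, scanner effects, or realistic
connectivity covariance are simulated.

## Scale presets and the test-scale learning rate

`train_config(scale = "paper")` uses the reference hyperparameters: 80
epochs, batch 64, learning rate $10^{-4}$, flip/rotate probability 0.5,
dropout 0.2. `scale = "test"` (10 epochs) exists for desk-scale experiments;
a rate of $10^{-4}$ over 10 full-batch Adam steps moves weights by
$\sim10^{-3}$ and cannot train any model, so the test preset uses
$10^{-2}$ — the conventional full-batch Adam rate for optimization runs of
~10 steps. The default grid is $16^3$ for speed; $91^3$ (the full-scale
resize target) is exercised forward-only with chunked convolution to bound
memory.

## Numerical and procedural details

* Probabilities are clamped to $[10^{-7}, 1-10^{-7}]$ inside the BCE loss.
* Importance ties break by the frozen feature order, making ranks
  deterministic; the frozen order is ROIs then clinical measures, as listed
  by `feature_ids()`.
* Perturbation uses 20 draws per feature per fold by default.
* Every random stage (cohort, weights, shuffling, augmentation,
  perturbation) draws its seed from one master seed through named
  substreams (`derive_seed()`), so runs are bit-reproducible on one CPU and
  adding draws to one stage does not shift another's stream.
* NIfTI I/O is a minimal native NIfTI-1 implementation (single 3-D float32
  volumes, little-endian), present because the target installations carry
  no neuroimaging I/O package; it is cross-validated against nibabel in the
  test suite.
* Importance normalization divides by the within-group maximum over
  whichever feature set a report covers; the package reports clinical-only
  tables the same way as all-feature tables.

## Known limitations

* The original study's exact pool placement, activations, initialization
  and perturbation repeat count are unknown; only the dimensional contract
  is guaranteed to match, so headline accuracies from the original cohort
  are not reproduction targets.
* Synthetic clinical distributions are plausible but uncalibrated.
* Full-scale ($91^3$, 80-epoch) LOOCV training is computationally heavy on
  one CPU; the package is exercised and validated at reduced scale.
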