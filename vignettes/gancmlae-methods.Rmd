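---
title: "Individual atrophy mapping with an adversarially regularized multi-loss autoencoder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual atrophy mapping with an adversarially regularized multi-loss autoencoder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

Group-level contrasts (the voxelwise two-sample t-test) describe what a
patient cohort shares, not what any one patient has. Reconstruction-based
anomaly detection inverts the problem: learn a generative model of *normal*
anatomy only, reconstruct each new subject through it, and read the residual
image — reconstruction minus input — as that subject's individual deviation
map. On T1-weighted MRI, tissue loss appears darker, so atrophy relative to
the learned normal manifold shows up as reconstruction > input.

`gancmlae` implements the GANCMLAE (GAN-constrained multiple-loss
autoencoder) architecture for this task. Four networks share three losses:

* **Encoder** (used twice, with one shared parameter set): one convolution
  (16 filters by default) followed by four stride-2 residual blocks that
  double the filter count each time, so a 128 x 128 slice becomes an
  8 x 8 x 256 feature map; a fully connected layer reduces those 16,384
  features to a 128-dimensional latent code `z`.
* **Decoder**: a dense map back to the bottleneck grid, then two
  convolutions and four upsampling (transposed-convolution) residual blocks
  with filter groups 128, 128, 64, 64, 32, 32, 16, 16, 8, 1 and a tanh
  output matching the [-1, 1] input normalization.
* **Critic** (discriminator): three fully connected layers (256, 128, 1
  units) with LeakyReLU between them, scoring latent vectors.

The combined objective is

  L = L1 + mu * L2 + gamma * L3

* **L1** — Wasserstein adversarial loss on the *latent space*: the critic
  maximizes `E[D(z_q)] - E[D(z_p)]` between encoder codes `z_q` and
  standard-normal prior samples `z_p`, constrained toward 1-Lipschitz by a
  one-sided gradient penalty `lambda * max(0, |grad_z D| - 1)` evaluated at
  uniform convex combinations of paired codes and prior samples
  (`lambda = 10`). The encoder minimizes `-E[D(z_q)]`. This regularizes the
  aggregated posterior toward the prior, as in an adversarial autoencoder
  but with the earth-mover geometry.
* **L2** — pixel loss: mean absolute error `|x - x'|` between input and
  reconstruction (least absolute error preserves detail better than squared
  error here).
* **L3** — latent consistency: `|z - z'|^2`, where `z' = Encoder(x')` is the
  code of the reconstruction, computed by the *same* encoder parameters.
  This ties the latent representation of a reconstruction to that of its
  source and stabilizes what "normal" means in code space.

The weights are exposed in `loss_weights()`. `mu` defaults to 1. `gamma`
defaults to 1e-3, and the choice matters: L3 is a squared Euclidean norm
over the whole latent vector, so at initialization it is two to three
orders of magnitude larger than the pixel loss (`E|z - z'|^2` scales with
`latent_dim` times the initial code variance). With `gamma = 1` (or even
0.01) the consistency gradient dominates every other signal and training
reliably collapses into the degenerate solution that makes L3 trivially
small — a constant decoder, whose output saturates the tanh head and whose
code `z'` no longer depends on the input, dragging `z` to the same
constant; the pixel loss then plateaus near the all-background error and
never recovers. `gamma = 1e-3` makes the three terms commensurate at the
start, after which the trained consistency term settles into the mild
regularizing role it is meant to play. We verified the collapse and the
fix directly: with the consistency term unweighted the pixel loss stays
within a few percent of its initial value for thousands of steps, while at
`gamma = 1e-3` it falls by an order of magnitude.

### Training regimen

Both networks use Adam at learning rate 2e-4 with batch size 32. Updates
alternate under a two-time-scale rule realized as independently tunable
learning rates plus an update-frequency ratio: the critic is trained twice
per generator step, each time on a fresh minibatch of encoder codes and
fresh prior samples. Training runs for a fixed number of generator steps
(no early stopping); data order is reshuffled each epoch from the run seed,
and a run is bit-reproducible given its seed. Only normal-control slices
are ever seen in training — `train()` refuses datasets carrying anomalous
labels, because the method's premise is that anomalies must be
unreconstructable.

Adam moments are (0.5, 0.9), the usual choice in adversarial training where
high first-moment inertia destabilizes the critic race; they are
configurable.

### Design choices where the architecture is genuinely open

Several internals are fixed here by explicit choice:

* Residual blocks are standard pre-activation blocks (BN - ReLU - conv,
  stride-2 main path, 1 x 1 stride-2 projection shortcut); upsampling blocks
  mirror them with a transposed convolution and a nearest-neighbour +
  1 x 1-convolution shortcut.
* The transposed convolution is implemented as the exact adjoint of a
  stride-2 "same" convolution (scatter-add of weighted patches), which is
  the fractionally-strided convolution at a quarter of the cost of
  zero-insertion followed by a full-resolution convolution.
* The latent fully connected map is mirrored by a dense layer
  latent -> bottleneck grid at the decoder input; shapes do not close
  otherwise.
* The critic's output is linear by default. A sigmoid head is retained as a
  configuration flag (`final_sigmoid`) for fidelity with the
  classifier-style description of the discriminator, but the Wasserstein
  loss mathematics requires an unbounded critic, so adversarial training is
  only defined for the linear head; the sigmoid head can still score
  latents in (0, 1).
* The gradient penalty is one-sided, `max(0, |grad| - 1)`, exactly as the
  loss is written; the common squared variant `(|grad| - 1)^2` is available
  as `loss_weights(penalty = "squared")`.
* All loss reductions over a batch are means.

The networks themselves are implemented in-package (conv, transposed conv,
batch norm, dense, with hand-derived reverse-mode gradients and an analytic
second-order term for the penalty's critic-parameter gradient); every
gradient path is validated against central finite differences in the test
suite, and the penalty's input-gradient norms against a finite-difference
oracle at 1e-4.

## Preprocessing

Volumes are intensity-normalized per volume by
`x <- (x - mean(x)) / (max(x) - min(x))`, which bounds values in [-1, 1]
(per volume rather than per slice, to preserve inter-slice intensity
relations). They are then sliced along the axial (third) axis — a
91 x 109 x 91 volume yields 91 single-channel 91 x 109 images — padded
symmetrically with zeros to square (padding, not cropping, so no tissue is
discarded; the exact crop is not prescribed anywhere), and bilinearly
resampled to the model input size (128 x 128 at full scale). Reconstructed
slice stacks are restored to the source 3D geometry by the inverse resample
and un-padding; the round trip on a smooth phantom is exact to well under
5% of the dynamic range. Edge slices with no tissue are kept by default; a
minimum-foreground-fraction filter is exposed in `pool_slices()`.

## From residuals to atrophy maps, masks and scores

For each subject the signed residual is reconstruction minus input in
normalized units, restored to 3D. The analysis chain is:

1. **Effective-atrophy mask**: voxels whose residual value is *strictly
   greater than* a threshold. The reference value 0.03 is tied to the MRI
   data it was calibrated on (chosen there so that noise outside the brain
   region is just removed); for any other data, `calibrate_threshold()`
   re-derives it as a high quantile (default 0.95) of residual magnitudes
   over a reference region in normal controls. Masks default to the
   magnitude channel because the polarity convention is a choice; the
   signed channel is available (`use_signed`).
2. **Group frequency mask**: the per-voxel proportion of subjects flagged;
   voxels whose frequency *strictly exceeds* 60% form the
   group-characteristic mask.
3. **Cluster-extent filtering**: connected components (26-neighbourhood in
   3D, 8 in 2D; connectivity configurable) with fewer than 50 voxels are
   removed; components of exactly 50 survive (inclusive retention).
4. **t-test baseline**: the conventional group-level comparison — pooled-
   variance two-sample t per voxel, two-sided p < .05 uncorrected, then the
   same extent filter. No multiple-testing correction is applied, matching
   the baseline it reproduces.
5. **Subject residual score**: the mean residual magnitude within the brain
   mask (a sum of suprathreshold magnitudes is available). The scalar
   summary is not prescribed anywhere; the masked mean is the simplest
   summary consistent with reading residuals as individual atrophy.
   Scores standardize to z-scores with the sample (n - 1) standard
   deviation of a stated reference group, and discriminate groups via
   ROC/AUC computed by the rank (Mann-Whitney) formulation with ties
   counting one half.

Strict-vs-inclusive comparisons are deliberate and tested: residual
threshold strict, frequency threshold strict, cluster retention inclusive.

All of these analyses run on an *eroded* tissue support (`erode_mask()`,
three single-voxel passes by default). Slice resampling and reconstruction
concentrate residual error in a thin rind at the tissue-background
interface; because that rind is shared across subjects it sails through the
frequency rule and would otherwise dominate the group mask. Excluding a few
boundary voxels is the standard remedy for edge artifacts in voxelwise
residual analyses and is configurable (`support_erosion`).

## Reconstruction metrics

SSIM, PSNR and MSE are computed per slice and averaged per subject; slices
with infinite PSNR (identical pairs) are excluded from the PSNR average and
counted. Metrics are evaluated after affinely mapping [-1, 1] slices to
[0, 1] with unit data range — the pixel range convention is otherwise
arbitrary, and this keeps MSE magnitudes on the conventional scale. SSIM
defaults to a 7 x 7 uniform sliding window ("means of samples" is ambiguous
between local and global statistics; the windowed form is the field
standard), with the literal whole-image form available as `mode = "global"`.
Stabilization constants use k1 = 0.01, k2 = 0.03.

## The phantom generator

Real T1 cohorts cannot ship with a package, so every stage is exercised on
a seeded synthetic population (`phantom_spec()` / `make_population()`)
designed to mirror the *structure* of the problem:

* a smooth ellipsoidal "brain" on an exactly-zero background (so a
  background-noise-based threshold rationale has a synthetic analogue);
* a low-dimensional normal manifold: all subjects share base anatomy and
  `n_structures` smooth bright structures, individualized by per-subject
  jitter of structure positions, amplitudes and global intensity
  (`subject_jitter_sd = 0.05`) plus additive Gaussian noise inside the
  tissue support (`noise_sd = 0.02`);
* anomalous subjects (a quarter of the population by default) carry a
  ball-shaped lesion whose intensity is multiplied by `1 - atrophy_magnitude`
  (multiplicative darkening mirrors tissue loss on T1 and gives signed
  residuals the expected orientation), recorded in a ground-truth mask.
  The lesion site is shared across the population up to a +/-2 voxel
  per-subject jitter, emulating a group-characteristic atrophy region so
  that frequency masking has a recoverable target.

Defaults: 64 x 64 x 24 grid, 48 subjects, atrophy magnitude 0.5 (a strong
lesion — the recovery properties are only meaningful when the injected
signal clearly exceeds the reconstruction noise floor), radius 7 voxels.
The cohort proportions deliberately mirror the reference study design at
roughly 1:10 scale — many more training normals than reference normals or
patients — because the method's premise requires the training cohort to be
large enough to learn the normal-anatomy manifold rather than memorize
subjects: with only a handful of training normals, *every* held-out subject
scores high on generic reconstruction misfit and subject-level
discrimination collapses.
The full-geometry 91 x 109 x 91 fixture is available through
`make_volume_fixture()` for geometry tests.

What the phantom does *not* emulate: MRI physics, bias fields, partial
volume effects, registration error, multi-site variation, or anatomically
realistic atrophy topographies. Passing the phantom recovery tests
demonstrates that the pipeline's machinery — training, reconstruction,
thresholding, frequency masking, scoring — is correctly wired and able to
recover localized intensity anomalies; it does not certify performance on
clinical MRI.

## Desk-scale study sizes

The packaged tests and the default pipeline run at desk scale on one CPU:
model input 32 x 32, base filters 4 (bottleneck 2 x 2 x 64), latent 32,
batch 32, 2,000 generator steps (hence 4,000 critic updates) on ~576 pooled
normal slices (24 training normals x 24 axial slices). The full-scale regimen (128 x 128 inputs, 16 base filters, latent 128,
70,000 batches) is what one would run on real cohorts:
`architecture_spec()` defaults to the full-scale architecture, while
`train_config()` defaults to the desk-scale 2,000 batches (set
`max_batches = 70000` for the full regimen). The desk model keeps the
architecture's shape — four downsampling and four upsampling residual
blocks, the same loss structure — while shrinking resolution and width.

## Numerical notes and limitations

* Batch-norm running statistics use momentum 0.9 during training and are
  *finalized* at the end of `train()` by a momentum-0 pass over a
  representative slice subset under the final weights. This matters more
  than it sounds: running averages lag the moving parameters, and the
  resulting evaluation-mode affine intensity offset barely dents SSIM but
  makes absolute residuals scale with local intensity — which inverts
  residual-based subject scoring (darker lesions then *lower* the score).
  Evaluation-mode passes (all user-facing `encode`/`decode`/`reconstruct`)
  are deterministic.
* Weight initialization is He-scaled Gaussian, seeded; `build_model()`,
  `make_population()` and `train()` save and restore the caller's RNG
  state.
* Intensity normalization requires at least two distinct values; constant
  images are a degenerate-input error.
* `standardize_scores()` requires non-zero spread; the z-score denominator
  is the sample (n - 1) standard deviation.
* Voxels with zero pooled variance in the t-test baseline are never
  significant.
* Only 2D (slice-wise) modelling is implemented; 3D convolutions are out of
  scope, as is registration, segmentation, region naming, survival
  modelling and any cognition/genotype analysis.
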