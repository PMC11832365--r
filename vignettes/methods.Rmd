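---
title: "Generative synthesis of brain MRI labels and images: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generative synthesis of brain MRI labels and images: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

`mrisynth` implements a two-stage generative model of brain MRI at desk
scale. The first stage generates *probabilistic tissue label maps* — per-voxel
probabilities for CSF, grey matter (GM), white matter (WM), deep grey matter
(DGM) and brainstem, plus binary lesion channels for white-matter
hyperintensities (WMH) and the three tumour compartments (non-enhancing core,
oedema, gadolinium-enhancing rim). The second stage renders an intensity
image for a label map in a chosen MRI contrast ("style"). Around these sit a
brain-phantom generator that supplies training and validation data with
known ground truth, a statistics-derived (SD) MRI simulator, and an
evaluation suite.

All neural components run on a small tape-based reverse-mode autodiff engine
included in the package (dense R arrays, C++ convolution kernels via
RcppArmadillo). Every operation used in a training graph is verified against
central finite differences in the test suite.

# Stage 1: label generation

## Spatial VAE

`train_label_vae()` fits a spatial variational autoencoder that compresses a
`(32, 32, 9)` label slice into a latent grid of shape `(8, 8, 3)` — two
stride-2 downsamplings and three latent channels, preserving the compression
ratio of a full-scale configuration (e.g. a `(192, 256)` slice mapping to a
`(48, 64, 3)` latent). The training loss has five terms:

* **KLD** of the diagonal-Gaussian posterior against N(0, 1);
* a **perceptual loss**: L1 over features of a fixed-seed convolutional
  stack (`make_feature_extractor()`). The extractor interface is pluggable,
  so a stack with pretrained weights can be substituted; untrained random
  convolutional features are used by default and suffice to penalise
  structural mismatch at this resolution;
* a **patch-GAN adversarial loss** (hinge form) from an 8×8-patch
  discriminator, with the discriminator trained alternately;
* a **focal reconstruction loss** with focusing parameter `gamma = 0.3`.
  We use the *excess* cross-entropy form: each element contributes
  `(1 - pt)^gamma * (CE(l, p) - CE(l, l))` with
  `pt = l*p + (1 - l)*(1 - p)`. Subtracting the entropy floor `CE(l, l)`
  makes the loss exactly zero at a perfect reconstruction even for the
  fractional border probabilities that probabilistic parcellations carry;
  `gamma = 0` recovers the unweighted excess cross-entropy. The focal
  weighting matters here: lesions occupy a few dozen pixels against ~9
  mostly-empty channels;
* a **noise-robustness loss**: the focal loss between the label and the
  decoding of its latent after adding Gaussian noise (mean 0, sd 0.05),
  encouraging latent neighbourhoods that decode consistently — important
  because the diffusion stage will hand the decoder approximate latents.
  A measurable side effect: after training, the expected loss is flat (even
  very slightly dipping) for perturbations up to roughly the latent scale
  and only rises clearly beyond it — the term works as intended.

Term weights default to values that put all terms within roughly one order
of magnitude on phantom batches at initialisation
(`vae_loss_weights()`). Training uses Adam with a step-decayed learning rate
(halved after 60% of the epochs, quartered after 85%); the late low-rate
epochs are what calibrates per-channel probability mass — without decay the
thin GM ribbon systematically loses mass to its CSF/WM neighbours.

Decoded probabilities pass through a per-channel sigmoid;
`restore_label_invariants()` then renormalises voxels whose channel sum
exceeds 1, binarises lesion channels at 0.5 and zeroes healthy channels
under lesions, so any latent decodes to a valid label map.

## Conditioned latent diffusion

`train_label_diffusion()` fits an epsilon-prediction diffusion model over
the S-VAE latents (standardised by their global standard deviation, recorded
on the model). The schedule is the standard linear one, beta from 1e-4 to
0.02 over T = 1000 steps; shorter schedules rescale beta by `1000/T` to
preserve the terminal signal level. Timesteps are drawn uniformly during
training.

Conditioning is a vector of four lesion proportions — per lesion type, the
voxel count normalised by the dataset maximum — plus, for 2D models, the
relative slice number (axial index divided by the axial extent; 256 for
1 mm whole-head volumes, the phantom's own extent here). The degenerate case
of a lesion type absent from the whole dataset yields proportion 0 for all
samples rather than a division by zero.

The denoiser is a small convolutional network on the 8×8 latent with two
conditioning pathways: *cross-attention*, where each conditioning dimension
becomes a token (`base + value * scale`, both learned) attended to by every
latent position, and a *FiLM bias*, where the same conditioning vector is
embedded and added per channel alongside the time embedding. Cross-attention
carries the per-lesion detail; the global bias stabilises coarse, strongly
slice-dependent anatomy. Lesion counting (for proportions and all evaluation)
thresholds channels at 0.5.

Sampling uses a deterministic DDIM trajectory (eta = 0) over an evenly
spaced timestep subset, 200 steps by default. The predicted clean latent is
clamped to ±3 (standardised units) at each step *with the implied noise
recomputed*; this is the standard stabilisation for imperfect denoisers,
and at toy scale it is what keeps trajectories on the data manifold.
Sampling is bit-reproducible given the seed.

# Stage 2: image generation

`train_image_generator()` fits a semantic-synthesis VAE-GAN. A convolutional
style encoder maps an image to a 16-dimensional code (posterior mean used in
eval mode). The decoder starts from the style code and builds the image
through spatially-adaptive normalisation blocks: at each resolution the
label map (average-pooled to that resolution) predicts per-pixel scale and
shift applied to the instance-normalised activations. Each block
additionally modulates its channels globally from the style code (a
FiLM-style gain/bias); without this the per-block instance normalisations
strip the global contrast information the style pathway is supposed to
carry. Exact replication of any reference architecture is out of scope —
widths and depths are configuration.

The generator loss combines the hinge GAN loss from a 2-scale patch
discriminator, KLD on the style posterior, a perceptual loss (extractor as
above, with the raw image prepended as an identity layer so a pixel-level
L1 term is included), discriminator feature matching, and a contrastive
style loss `1 - cos(E(i), E(augment(i)))` with a contrast-preserving random
affine augmentation (rotation ≤ 10°, translation ≤ 5%, scale 0.95–1.05).
When styles are unpaired (the default), the contrastive term also ties the
codes of the style slice and the paired ground-truth slice — two slices of
the same volume and contrast — which is precisely the cross-slice style
consistency the code should express. A modality/dataset discrimination loss
against a pluggable auxiliary classifier is implemented but disabled by
default (weights 0): the contrastive loss and unpaired styles carry the
clustering benefit, and the classifier interface is a black-box function,
so when enabled the term is reported without a gradient path.

Training pairs are built by `make_training_triplet()`: a label slice with
its paired image, and a style image drawn from a *different* slice of the
same volume and modality, which forces the style pathway to carry contrast
rather than content. Images are normalised per volume (1st/99th percentile);
per-slice normalisation would rescale contrast by slice content and destroy
the modality signal.

The discriminator sees the image concatenated with the label channels and a
broadcast one-hot modality encoding. Updates are gated by the adversarial
scheduler: discriminator accuracy (fraction of patches on the correct side
of 0, averaged over patches and scales) is averaged over the last 20
iterations; means strictly above 0.75 train the generator only, strictly
below 0.60 the discriminator only, and both in between (boundary values
train both). The discriminator uses a faster learning rate than the
generator (defaults 2e-3 vs 5e-4); a weaker discriminator otherwise pins
the scheduler below the lower threshold and starves the generator of
updates.

# Phantom data and the SD simulator

`generate_phantom_label()` builds nested super-ellipsoid anatomy — outer CSF
shell, GM ribbon, WM interior, two DGM blobs, inferior brainstem stalk —
with per-subject jitter of axes and centres, smoothed by a Gaussian
(sd 1.5 voxels) and normalised so channel sums stay at or below 1. The
smoothing produces genuinely fractional border probabilities, emulating
probabilistic parcellation output. WMH lesions are several small spherical
blobs placed in a dilated band around the DGM (a periventricular surrogate);
tumours are three concentric disjoint layers centred in WM. Expected lesion
volume is non-decreasing in the size parameter. Lesion channels are binary;
`fuse_lesion()` zeroes healthy probabilities exactly where a lesion layer is
1 and leaves every other voxel untouched. 3D volumes are sliced axially;
slices with less than 1% brain pixels are dropped and the integer axial
index is recorded.

The SD simulator (`sd_image()`) draws per-voxel intensities as
`bias_field * sum_i L_i * N(mu_i, sigma_i / K)` per region channel, with a
modality-dependent contrast factor K (default 6, keeping GM/WM
contrast-to-noise at 3 or more), clips negatives to zero (MRI magnitude
images are non-negative), and applies a random multiplicative bias field
with probability 0.4 — the exponential of a heavily smoothed white-noise
field whose maximum log-deviation is drawn uniformly from [0.05, 0.15].
Whether the Gaussian is drawn per voxel or once per region is ambiguous in
the statistics-derived formulation; per voxel is the minimal-assumption
default and `per_region = TRUE` offers the alternative. Default region
means emulate T1/FLAIR/T2 contrast ordering (e.g. WM bright on T1, WMH and
oedema bright on FLAIR, CSF bright on T2).

What the phantoms do *not* emulate: cortical folding, registration error,
scanner artefacts beyond the bias field, and population-level anatomical
variability beyond ellipsoid jitter. Passing the toy-scale checks therefore
demonstrates that the pipeline's machinery is correct and that conditioning,
style separation and extrapolation behave as designed — not that the models
reach real-data fidelity.

# Evaluation suite

* `tissue_proportion_profile()` — region mass over total brain mass, per
  slice or volume, with mean and sd; `profile_coverage()` scores a sampled
  profile against a reference as the fraction of (region, slice) bins within
  `k` sd (default 3, with a 1e-3 sd floor for degenerate bins).
* `lesion_size_curve()` — thresholded lesion voxel counts as a function of
  the conditioning value.
* `fp_tum()` — tumour voxels mislabelled as WMH over tumour size.
* `image_fidelity()` — single-scale SSIM (11×11 Gaussian window, sd 1.5,
  K1 = 0.01, K2 = 0.03) and MSE.
* `fid_score()` — Fréchet distance between Gaussian fits, covariance square
  root by eigendecomposition with 1e-6 jitter.
* `nn_dice_retrieval()` — memorisation check: nearest training neighbours by
  mean per-channel Dice (channels thresholded at 0.5, unweighted mean over
  channels present in either map; the variant is a documented choice).
* `style_code_clustering()` — seeded k-means (300 iterations) with an
  optional pluggable 2-D embedding (default none), scored by adjusted Rand
  index. Style codes are evaluated on slices with at least 30% brain pixels:
  near-apex slices carry almost no tissue and are poor style references.

# Problem sizes and numerical choices

The packaged study runs on one CPU: 44 phantom subjects of shape
32×32×16 (about 520 usable slices, 40 held out), S-VAE widths (16, 32) for
28 epochs, diffusion for 140 epochs, image generator for 800 iterations at
batch 8 on two SD modalities (T1/T2, the most contrast-distinct pair).
These sizes are the package's chosen toy conditions; they complete in tens
of minutes while leaving measurable margins on the property checks.

Degenerate inputs are handled explicitly: empty datasets, all-zero lesion
types, indivisible spatial shapes, empty tumour masks in `fp_tum()`,
singular covariances in `fid_score()`, single-slice volumes in triplet
construction (fall back with a warning), and zero-size lesions (a
one-voxel minimum by default, an error when `min_one_voxel = FALSE`).

Seeding is hierarchical: one master seed fans out per-component seeds via
`derive_seed()` (a fixed affine map modulo 2^31 - 1), so every stage is
independently reproducible and two identically-seeded runs are
bit-identical.

# Known limitations

* The 3D pipeline path assembles volumes from the slice-conditioned 2D
  label generator with a constant style code; a native 3D S-VAE/diffusion
  stack (three downsamplings, 8 latent channels) is not implemented at desk
  scale.
* The autodiff engine is eager and single-threaded; it is sized for the toy
  problems here, not for full-resolution training.
* Untrained perceptual features are a weaker signal than pretrained
  backbones; the extractor interface accepts externally supplied weights.
* The adversarial scheduler can leave the generator under-trained if the
  discriminator is configured too weak; the default learning-rate split
  avoids this at the packaged scale.
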