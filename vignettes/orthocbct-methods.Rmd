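---
title: "OrthoCBCT: model, phantom and evaluation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{OrthoCBCT: model, phantom and evaluation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The synthesis problem and its assumptions

OrthoCBCT reconstructs a volumetric CBCT-like image of the day's anatomy
from two orthogonal parallel-beam projections (gantry 0° anterior, 270°
left lateral) plus the patient's planning CT. The central assumption is
that the pCT supplies a dense anatomical prior while the projections carry
enough information about the day's deviations (bladder filling, rectal
gas, small target shifts) for a learned decoder to localize them in 3D.
Two orthogonal views cannot resolve arbitrary 3D changes; the method is
aimed at the pelvic setting where inter-fraction variation is dominated by
a few low-dimensional modes.

All volumes are assumed rigidly pre-aligned on a common grid (phantoms are
generated that way; for clinical data this would be an upstream
registration step, which is out of scope here, as are DICOM ingestion,
cone-beam physics and dosimetric evaluation).

## The network family

One implementation realizes four variants by flags:

* `drrs_only` — 2D encoder only; the decoder is seeded from the reshaped
  2D latent.
* `fusion` — adds a 3D pCT encoder; the two latents are concatenated and
  mapped by a 1×1×1 transform convolution.
* `fusion_skip` — adds encoder-to-decoder skip concatenations.
* `fusion_skip_res` — adds residual connections around the decoder conv
  stacks.

Encoder blocks are conv(3×3[,×3], stride 2, pad 1) → instance norm → ReLU
→ conv(stride 1); channels double per level from `baseChannels`. Design
points that were genuinely open and decided here:

* **Channel schedule**: doubling per level from `baseChannels` in both
  branches — the standard U-Net/VGG convention.
* **DRR entry**: the two projections enter as two input channels of one 2D
  encoder rather than through separate branches; they share low-level
  statistics and the fusion happens anyway at the latent.
* **2D→3D reshape**: the 2D latent's channel axis is split into
  (depth, channels) to match the 3D latent's depth. This conserves every
  element (e.g. 512 channels at 8×8 become 128 channels at 8×8×4) instead
  of replicating along depth; the build errors out, naming both shapes,
  whenever the counts are incompatible.
* **Output activation**: a 1-channel 1×1×1 convolution plus sigmoid, since
  targets are min–max normalized to [0, 1].
* **Residual identity path**: a 1×1×1 projection whenever channel counts
  differ (they always do after a skip concatenation); zeroing the conv
  stack makes a decoder block exactly the projected trilinear upsample,
  which the tests assert.
* **Decoder depth equals encoder depth**, so skips pair one-to-one; the
  first (outermost) decoder level has no same-resolution encoder partner
  and takes no skip.

Instance normalization uses population variance with ε = 1e-5 and no
learned affine. The trilinear ×2 upsampling and the DRR raster resize use
separable linear interpolation with half-pixel centres (so a resize to the
native shape is exactly the identity).

### Why an own autodiff core

No deep-learning runtime is available to this package, and the network,
loss and training loop are its contribution, so the package carries a
compact reverse-mode tape over R arrays with C++ kernels for the
convolutions and pooling. The tape is a linked chain in creation order
(parents precede children, so walking it backwards is a valid reverse
topological order). Correctness is established against central-difference
gradient checks (projection operator, relative error ≤ 1e-4 at desk size)
and against analytic identities (instance-norm scale invariance, residual
identity, conservation laws) rather than against another framework.

## Losses

The training loss is the weighted sum α·MAE + β·PL + γ·PL_DRR +
ω·PL_structures, with the four published configurations as pure weight
presets. Decisions taken where the formulation left room:

* **2.5D slice set**: all axial plus all sagittal slices, unweighted mean
  over slices and layers. Each slice is triplicated to pseudo-RGB.
* **Feature backbone**: a VGG19-layout CNN (feature indices follow the
  torchvision numbering, so the default capture ids 3, 8, 15, 22 are the
  ReLU outputs of the second conv in blocks 1–4) with seeded
  Kaiming-uniform random weights and a reduced channel schedule.
  Random-feature perceptual losses are a recognized, fully deterministic
  choice, and every structural property asserted by the tests (zero on
  identical inputs, symmetry, mask locality, monotone degradation under
  noise) holds for any backbone; pretrained weights would require a
  network download and are deliberately not a dependency. Backbone inputs
  pass through unchanged (no channel statistics normalization) since the
  weights are not tied to a training corpus.
* **PL_DRR** averages the two projection angles; the rendering inside the
  loss shares its numerics with `renderPair()` and differentiates through
  the per-image min–max normalization by treating the extremes as
  selection nodes.
* **PL_structures** multiplies both volumes by the unified mask (union of
  PTV, bladder, rectum dilated 3×, by an iterated 26-connected 3×3×3
  element — so the reach is exactly a Chebyshev ball, which the
  brute-force oracle in the tests exploits) and then applies the same
  2.5D scheme.
* A note on slice-permutation symmetry: the mean over axial slices is
  invariant to a common permutation of axial slice order, but the sagittal
  half of the 2.5D set sees axial order as in-slice structure, so the loss
  as a whole is not permutation invariant; the tests therefore assert the
  symmetry that does hold exactly (exchanging the two volumes).

## Training protocol

AdamW (β₁ = 0.9, β₂ = 0.999, ε = 1e-8, decoupled weight decay 1e-2),
initial learning rate 1e-3, batch size one, Kaiming-He uniform
initialization (gain √2; biases uniform ±1/√fan_in), default 40 epochs.
The plateau scheduler divides the rate by 10 when the validation loss has
not improved by a relative 1e-4 for 5 consecutive epochs, floored at 1e-6;
"for 5 consecutive epochs" is read as *reduce on the fifth flat epoch*
(the hand-simulated oracle in the tests encodes exactly this). An epoch is
one seeded-shuffled pass over all (fraction, pCT) pairs; augmentation
(integer translations ±5 voxels, axial rotations ±4°, applied identically
to volume and masks, bilinear/nearest interpolation, air fill) is
resampled online each epoch and applied to the training split only.
Validation is un-augmented; the checkpoint with the lowest validation loss
is retained and reproduces that loss exactly on reload. A non-finite loss
aborts immediately with the offending component named — at desk scale,
reproducibility beats robustness.

Rotation is about the axial (slice-normal) axis only, the standard
setup-error analogue; mask dilation is in voxels, not millimetres.

## The phantom generator

Organs are analytic primitives rasterized on the grid: an elliptic-cylinder
body, a bone annulus, ellipsoidal bladder and prostate (PTV), and a
rectal tube, with sizes proportional to the grid extent and painted in a
fixed priority order (soft organs over bone, target over everything);
the exported masks are the painted regions, so mask and intensity are
exactly consistent and voxel counts are analytically checkable (a bladder
volume scale *s* scales each ellipsoid axis by *s*^(1/3), so the mask
voxel count scales by *s* up to discretization).

Inter-fraction variation has no quantitative characterization to import,
so defaults were fixed once at clinically plausible ranges and not
revisited: bladder volume scale 0.7–1.5, rectal gas present in half the
fractions at 10–50% of the tube, target offsets within ±5 mm, CBCT domain
gap modelled as a +10 HU global offset plus additive Gaussian noise of
σ = 20 HU inside the body. Voxel spacing defaults to 1.98 × 1.98 × 3.0 mm.
What the phantom deliberately does **not** emulate: scatter, beam
hardening, truncation artifacts, deformable organ interplay, couch
structures. Passing tests therefore demonstrate that the pipeline learns
and measures what it claims on data with the assumed statistical
structure — not clinical-grade image quality.

The identity anatomy state with zero noise reproduces the planning volume
bit-for-bit, which anchors the fraction generator's correctness.

## Evaluation

Masked metrics are computed on the HU scale: model outputs in [0, 1] are
mapped back through the ground-truth volume's recorded (min, max) from the
per-case normalization. mMAE and mPSNR average only over body voxels.
mSSIM uses a uniform 7×7×7 window with c₁ = (0.01 L)², c₂ = (0.03 L)²
(the only self-consistent reading of the metric's printed form), population
moments, symmetric reflection padding at the volume boundary, the window
value attributed to its centre voxel, and L defaulting to max(y) − min(y).
cLPIPS works on the centrally cropped normalized volumes, axial slice by
slice, with per-position unit-normalized features and uniform layer
weights. The central region defaults to (X, Y/2, Z): full left–right and
superior–inferior extent, central half anterior–posterior.

Degenerate inputs: a volume constant after truncation normalizes to zeros
with a warning (rather than NaN); a constant projection renders as zeros
with a warning; a zero masked MSE reports mPSNR = ∞.

The ablation comparison uses Shapiro–Wilk per group as a normality screen,
Kruskal–Wallis as the omnibus test, and Dunn's pairwise rank test (normal
approximation with tie correction, implemented directly from the rank
sums) with Bonferroni adjustment and the usual star coding. Groups with
tied-constant values are rejected, as the rank tests are undefined there.

## Problem sizes

The package's own test and reproduction runs use desk-scale settings: a
32×32×16 voxel grid (64×64×32 for the architecture contracts),
`baseChannels` 8 with 3 levels for trained models, a backbone channel
schedule of 4–8–16–32, cohorts of 3–4 patients, 3 training epochs for the
ablation and 300 steps for the single-case overfit run. The paper-scale
geometry (128×128×64 crops, 64 base channels, 4 levels, 40 epochs) is
reachable through the same configuration objects.

## Known limitations

* Parallel-beam DRRs are an idealization of kV radiographs (no divergence,
  scatter or noise); the DRR operator is a mean along the ray axis, which
  is observationally equivalent to a sum after the per-image min–max
  normalization.
* The random-feature backbone makes perceptual quantities internally
  consistent but not comparable in absolute value to pretrained-backbone
  numbers.
* Two orthogonal views fundamentally under-determine complex 3D changes;
  the phantom's variation modes are low-dimensional by design.
* The desk-scale training runs demonstrate optimization behaviour
  (overfit capacity, loss algebra, protocol determinism), not clinical
  reconstruction quality.
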