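---
title: "Methods: organelle segmentation and cell extraction for serial block-face volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle segmentation and cell extraction for serial block-face volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

A FIB-SEM acquires a serial block-face (SBF) image: the ion beam mills the
sample surface in steps of tens of nanometres and the electron beam images
each newly exposed face. The result is a stack of single-channel
cross-sections forming a 3D volume. For a unicellular alga with one
organelle of each kind — plastid, mitochondrion, peroxisome, nucleus —
every voxel belongs to one of six classes (those four, cytoplasm, or
background). Manual voxel labelling by experts is the accuracy reference
but takes days per cell; `sbfseg` automates it, including the upstream
problem of isolating single cells from a field of many.

Two properties of this data drive all the design choices below. First, the
voxels are anisotropic: the milling step (dz) is usually coarser than the
in-plane pixel size, so off-axis views are geometrically distorted until
resampled. Second, contrast is weak and ambiguous: the mitochondrion,
nucleus and peroxisome have mean brightness close to the background, so
they can only be recognized from context (they sit inside the cytoplasm),
not from intensity alone.

# Preprocessing

`preprocess_chain()` applies, in order:

1. **Anisotropy correction** (`correct_anisotropy()`): nearest-neighbour
   resampling of every axis to the finest of the three spacings. The
   output index maps to input index `floor(i_out * d_out / d_in)`
   (0-based). Nearest-neighbour is used deliberately — it creates no new
   intensity values, so the identical operator is safe on label volumes.
2. **Bilateral denoising** (`denoise_bilateral()`): a 2D filter per
   acquired section, weights `exp(-d²/2σ_s²)·exp(-ΔI²/2σ_r²)`, window
   truncated at 2σ_s, border-renormalized. Defaults σ_s = 2 voxels,
   σ_r = 10% of the intensity range; these are our defaults — the
   upstream processing chain this mirrors does not pin them. Each output
   is a convex combination of inputs, so the intensity range can only
   contract. Applied slice-wise along z (it denoises the acquired
   sections) and therefore before any reslicing.
3. **Cube resize** (`resize_to_cube()`): nearest-neighbour resample to a
   fixed side (256 at acquisition scale; 64 in the desk-scale
   experiments), giving the network a constant input size.
4. **Normalization** (`normalize_volume()`): division of the 8-bit values
   by 255.

The order — geometry first, then denoising, then size and scale
normalization — follows the acquisition-pipeline narrative; the chain is a
package decision where the upstream description is silent (it names the
steps but neither the filter parameters nor the cube-resize interpolator).

`reslice()`/`unreslice()` convert between a volume and its stack of 2D
sections along any of the three axes by pure re-indexing; the round trip is
bit-identical, which the tests assert. Reslicing demands isotropic voxels.
`augment_training_set()` emits paired intensity/label sections along all
three axes — a cube of side S yields 3S pairs — implementing the
lateral/anterior-view augmentation; the three axes are mixed uniformly
into one training stream.

Indexing note: volumes are indexed `(z, y, x)` with z the milling
direction. Being R, indices are 1-based; the index-mapping formulas above
are stated 0-based because that is how they are naturally written.

# The scanning attention U-Net

`build_network()` constructs a 2D encoder–decoder applied section by
section ("scanning") through the volume:

* Encoder: `depth` stages of paired 3×3 same-padding convolutions with
  batch normalization and ReLU, channel counts doubling from
  `base_channels` (64, 128, 256, 512, 1024 at acquisition scale), 2×2 max
  pooling between stages.
* Decoder: mirrored stages; upsampling by 2×2 transposed convolution (the
  default; nearest-neighbour + 3×3 convolution is available as
  `upsample = "nearest"`); skip connections from the matching encoder
  stage, gated by an additive attention gate; then paired 3×3
  convolutions.
* Head: a 1×1 convolution to 6 channels and a per-pixel softmax, with no
  batch normalization.

The attention gate follows the standard additive formulation: with the
upsampled decoder feature g and the skip feature x (same resolution, same
channel count here), `a = W_g g + W_x x + b`, `ψ = sigmoid(w_ψ ReLU(a) +
b_ψ)`, and the gated skip is `x ⊙ ψ`. The gate's intermediate width is
half the stage width. The source architecture names attention gates but
does not define them, so this is our reading of the cited formulation.

`network_shapes()` gives the per-layer output shape schedule from the
configuration alone; the tests assert it (and the constructed kernel
shapes) against the published full-scale table row by row. At full scale
our construction has ≈31 million parameters. The published description
reports ≈130 million, which is not derivable from its own convolution
table (≈28 M); the excess presumably sits in unspecified gate/upsampling
choices, so we report our count rather than target theirs.

Everything — forward pass, backward pass, AdamW — is implemented in the
package (R orchestration over GEMM-based C++ convolution kernels). The
backward pass is verified against central finite differences for every
parameter tensor in every architectural variant; the numerical check
jitters biases first because freshly initialized networks have exact-zero
pre-activations sitting on the ReLU kink.

## Loss

`tversky_loss()` computes, per class on soft predictions,

TI_c = (TP_c + s) / (TP_c + α FP_c + β FN_c + s),

with TP/FP/FN the soft true/false positive/negative masses, smoothing
s = 1e-6 (a class absent from both prediction and truth scores TI = 1),
and loss `mean_c (1 − TI_c)`. With α = β = 0.5 this is algebraically the
soft Dice loss, which the tests assert to 1e-12 against an independent
implementation. Defaults α = 0.3, β = 0.7 penalize false negatives, which
favours recall of the small organelles; the source names the loss but not
its weights.

## Optimization

`train_network()` runs AdamW (β₁ = 0.9, β₂ = 0.999, decoupled weight decay
0.01 on convolution kernels only) with the learning rate of epoch e equal
to `base_lr · decay^(e−1)`. The acquisition-scale defaults in
`train_config()` are base 1e-5, decay 0.95, 5 epochs, batch 8 — appropriate
for tens of thousands of optimizer steps on 256² sections. The desk-scale
experiments (below) run only a few hundred steps, where a base rate of
1e-5 cannot move He-initialized weights appreciably; they therefore pass
`base_lr = 3e-3` explicitly, a deliberate scale adaptation and not a
change to the defaults. Determinism: weight initialization is seeded in
`build_network()`, data order in `train_config()`; two runs with the same
seeds agree to floating-point reproducibility.

# Multi-directional inference and fusion

`infer_direction()` reslices the volume along one axis, predicts each
section, and reassembles the per-class probabilities into the common
`(z, y, x)` frame, so the three directional volumes are voxel-aligned.
`fuse_directions()` selects, per voxel, the class holding the single
largest of the 3 × 6 probabilities. An alternative reading — majority vote
of the three per-direction argmaxes, falling back to confidence on
disagreement — coincides with the global argmax whenever two directions
agree on the winning class; we implement the global argmax and expose the
per-voxel disagreement fraction as an attribute. Exact ties resolve to
the lowest class index, then to direction order z, y, x, making fusion
deterministic.

The post-fusion "median" cleanup is ill-defined on categorical labels
(the median of class codes depends on their arbitrary numbering), so
`denoise_labels()` uses the categorical analogue: the neighbourhood mode
over the (2r+1)³ box, keeping the centre label on ties when it is among
the modes, else taking the lowest class index. Radius defaults to 1.

# Evaluation

`iou()` is exactly `|A ∩ B| / |A ∪ B|` on hard labels (inference output is
fused to hard labels before scoring). When a class is absent from both
volumes the union is empty and the score is **undefined**: it is returned
as `NA` and excluded from averages, never counted as 0 — counting it as 0
would punish e.g. single-body stages for not containing a second
component. `make_split_plan()` reproduces the stage-stratified
cross-validation layout: each case holds out one cell per division stage,
validation cells never repeat across cases, and the plan is deterministic
given its seed.

# Cell extraction from multi-cell scenes

`mask_foreground()` separates cells from background. The default masker
computes one global Otsu threshold from the whole volume — per-section
thresholds would hallucinate foreground on sections containing no cell —
binarizes each z section, removes speckle by a 3-pixel morphological
opening, and fills enclosed holes (dark organelles inside the cytoplasm
ring) along all three axes in turn, since a hole at a cell pole need not
be enclosed in every sectioning plane. Degenerate volumes without
intensity bimodality yield an empty mask, with a message. Any external
per-section masker — such as an adapter around a promptable segmentation
model — plugs in as `function(section) -> logical mask`; such models are
deliberately not a dependency: the pipeline treats 2D foreground masking
as a replaceable component, and the classical default is sufficient on
phantom scenes.

`watershed_cells()` separates touching or nearby cells: Euclidean distance
transform of the mask (exact, separable lower-envelope algorithm), seed
detection, then flooding of the negated distance map from the seeds with
26-connectivity and lexicographic tie-breaking (the labelling is
deterministic). Seed detection is the critical choice. The discrete
distance transform of a smooth body is a staircase whose medial ridge
carries many spurious local maxima, so naive peak picking oversegments
badly; seeds are therefore the **h-maxima** of the distance map —
morphological reconstruction of `dist − h` under `dist` flattens each
peak's top slab into one connected plateau, so each peak with prominence
at least `h` yields exactly one seed — followed by greedy suppression to a
minimum pairwise separation. `min_seed_distance` defaults to about the
expected cell radius and `h` to a quarter of it. The prominence rule also
sets the biology-facing behaviour: a strongly pinched late-division
dumbbell has two distance peaks of prominence ≈ lobe radius − neck radius,
so small `h` splits it into its two daughter cells and large `h` keeps it
whole. Mask components too shallow to host any seed (debris) stay
unlabelled.

`crop_cells()` cuts one volume per instance: the instance bounding box
dilated by a margin, clamped to the scene, with other instances' voxels
inside the box blanked to the scene's median background intensity, so each
crop centrally contains exactly one cell, ready for single-cell
segmentation.

# The synthetic phantom generator

No public FIB-SEM dataset accompanies the workflow this package
implements, so `generate_phantom()`/`generate_scene()` produce the study
material. A phantom emulates the structural essentials of a dividing
unicellular alga:

* **Cell body**: an ellipsoid (lobes elongated 1.15× along a random major
  axis) that pinches into a dumbbell as division progresses. The
  constriction parameter is `(stage − 1)/4`: 0 at stage 1 (interphase),
  1 at stage 5 (end of mitosis). Lobe separation grows and the mid-plane
  waist narrows monotonically with stage, which the tests assert.
* **Organelles**: balls placed inside the cell by rejection sampling with
  clearance margins, so bodies never touch each other or the cell surface
  (component counts are exact by construction): one body per organelle at
  stages 1–3, one per daughter lobe at stages 4–5 — organelles are
  distributed equally to the daughters. Target volume fractions default
  to plastid 0.08, nucleus 0.04, mitochondrion 0.02, peroxisome 0.008 of
  the cell; in crowded late-stage lobes a body that cannot be placed at
  full size is shrunk stepwise rather than dropped.
* **Intensity**: per-voxel Gaussian noise (sd 10 grey levels) around class
  means — background 40, cytoplasm 95, plastid 200, mitochondrion 65,
  peroxisome 70, nucleus 52, on the 8-bit scale — clipped to 0..255.
  The mitochondrion, nucleus and peroxisome means sit deliberately close
  to the background mean, reproducing the real data's central confound;
  the plastid is large and bright, reproducing why it is easy. The real
  images report these overlaps only qualitatively, so the numbers are free
  parameters of the generator, chosen once. Optional per-slice
  multiplicative gain jitter emulates section-to-section SEM gain
  variation (off by default).
* **Scenes**: several cells placed by rejection sampling with a minimum
  background gap between any two cells; ground truth is emitted both as
  per-cell instances and as merged class labels. Scene cells default to
  stages 1–3 because a stage-4/5 dumbbell is morphologically two daughter
  cells and instance separation is expected to split it.

All randomness flows through the spec seed (no hidden global RNG state);
the same spec reproduces the same volume bit for bit.
`degrade_anisotropic()` (keep every k-th z section, scale dz) and
`degrade_blur()` (1D Gaussian along one axis) produce the controlled
degradations used to exercise anisotropy correction and directional
fusion.

What the phantoms do **not** model: SEM image formation (charging,
curtaining, shot-noise statistics), starch granules and other unlabelled
confounders, textured organelle interiors, irregular organelle shapes, and
membrane contrast. Passing the phantom experiments therefore demonstrates
that the machinery — geometry, training, fusion, scoring, extraction — is
correct and learns context-dependent brightness classes; it does not
certify accuracy values on real microscope material.

# Desk-scale experiments

`segmentation_experiment()` is the package's standard end-to-end run,
sized for CPU minutes: 20 training phantoms spanning the five stages in
64-voxel cubes, tri-axial augmentation keeping every 8th section (24
sections per phantom), a base-8, depth-4 network (≈123k parameters),
5 epochs of AdamW at base rate 3e-3 with 0.95 decay, batch 8 (≈300
optimizer steps), and 5 held-out phantoms (one per stage) scored by
per-class IoU with z-direction inference. Typical outcome: background
≈ 1.00 and plastid ≈ 0.85–0.98; nucleus and mitochondrion partially
recovered (≈ 0–0.75 depending on seed); peroxisome near 0 — the same
difficulty ordering reported for real material, emerging here from the
brightness-overlap confound and organelle size alone.

`fusion_experiment()` blurs phantoms along one axis and compares each
single inference direction against the three-direction fusion (10 seeds by
default): fused accuracy tracks the best single direction to within about
a hundredth of IoU — fusion helps or costs little, which is its point,
since the orientation of a real cell relative to the milling direction
cannot be chosen in advance. `extraction_experiment()` runs 2–5-cell
scenes (20 each by default) through the full extraction pipeline and
scores exact instance-count recovery and one-cell-per-crop correctness;
both sit at or near 100% under the default scene conditions.

# Numerical and degenerate-input policies

* Geometric resampling is nearest-neighbour everywhere; label volumes are
  never interpolated.
* Softmax is computed with per-pixel max subtraction; probabilities sum to
  1 within 1e-5 and the tests assert it.
* Batch-norm inference uses running statistics (momentum 0.1); variance is
  floored at 0 and stabilized with eps = 1e-5.
* Fusion and watershed tie-breaks are fixed (lowest class / lexicographic
  voxel order), so all pipeline outputs are deterministic given seeds.
* Empty masks yield zero instances (not an error); empty scenes yield
  empty crop lists; all-constant volumes yield empty foreground masks with
  a message.
* The exact distance transform uses a large finite sentinel rather than
  infinity: the parabola-intersection arithmetic of the separable
  algorithm is undefined for infinite samples. A brute-force oracle in the
  test suite guards this.

# Known limitations

* The phantom realism gap above: results on phantoms bound machinery
  correctness, not real-data accuracy.
* The scanning network is 2D per section; 3D context enters only through
  multi-directional fusion, not through 3D convolutions.
* The watershed assumes roughly convex cells of comparable size; strongly
  elongated or nested cell arrangements would need retuned
  `min_seed_distance`/`h`.
* Training at acquisition scale (256³ volumes, base-64 network) is
  supported by the architecture but not practical on a single CPU; the
  package's own experiments run at desk scale by design.
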