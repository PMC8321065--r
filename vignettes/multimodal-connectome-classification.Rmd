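---
title: "Multimodal connectome classification: models, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal connectome classification: models, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem and the two activation maps

Resting-state fMRI measures a blood-oxygen-level-dependent (BOLD) signal on
a voxel grid over time: a 4D volume with dimensions $(H, W, D, T)$. The
BOLD level itself is not a direct readout of neural activity, so
classification works on *co-activation* structure instead: Pearson
correlations between time series. Given a parcellation atlas with $N$
regions (116 for an AAL-style atlas), `fmrifusion` builds the two standard
connectomic representations per subject:

* **Voxel-by-region connectivity fingerprint** — the correlation of every
  voxel's series with every region-mean series, an $(H, W, D, N)$ volume
  (`compute_fingerprint()`). It retains the full spatial layout of the
  connectome and is the input to a 3D convolutional encoder, with the $N$
  region correlations of a voxel treated as its channels.
* **Region-pair connectivity vector** — the upper triangle (diagonal
  removed) of the $N \times N$ region correlation matrix, vectorized in
  row-major pair order, length $N(N-1)/2$ (6670 for $N = 116$;
  `compute_connectivity_vector()`). It is compact but discards spatial
  structure, and feeds a multilayer perceptron.

The claim the package operationalizes is that the two maps carry
complementary information, so a classifier fusing both should not be worse
than either branch alone.

Conventions worth stating because they are invisible in the outputs:

* Regions are always ordered by ascending atlas label; the pair order of
  the connectivity vector is $(1,2), (1,3), \dots, (1,N), (2,3), \dots$ in
  that region order.
* A zero-variance series (a constant background voxel, say) correlates 0
  with everything, never `NA`: "no co-activation" keeps downstream
  networks finite. Correlations are clamped to $[-1, 1]$ against floating
  point drift.
* No Fisher z-transform is applied; the networks consume raw correlation
  coefficients.
* The atlas and the functional volumes must share one voxel grid; the
  package never resamples. Registration belongs upstream.

# The three networks

**Fingerprint encoder.** An 18-layer residual network with every 2D
convolution replaced by its 3D equivalent. The fingerprint is permuted to
$(N, H, W, D)$ so the region axis becomes the input channel axis. The stem
is a $5^3$ convolution, 64 channels, stride 2; then $1\times3\times3$ max
pooling with stride $(1,2,2)$; then four stages of two residual blocks with
channel widths 64/128/256/512, $1\times3\times3$ kernels in the first two
stages and $3\times3\times3$ in the last two, downsampling by stride
$(1,2,2)$ at the head of stages 2–4; finally a global average pool to a
512-dimensional feature vector and a linear layer to 2 logits. At full
scale (input $116\times61\times73\times61$) the stage outputs are
$(64,32,38,32)$, $(64,32,19,16)$, $(64,32,19,16)$, $(128,32,10,8)$,
$(256,32,5,4)$, $(512,32,3,2)$, then 512, then 2 —
`resnet_shape_table()` computes the chain analytically and the test suite
verifies a live forward pass against it.

Paddings are not free parameters: they are the unique smallest solutions of
the shape equations $\lfloor (L + 2p - k)/s \rfloor + 1$ that reproduce the
stage sizes above — 3 per axis for the stem, $(0,1,1)$ for the max pool and
the $1\times3\times3$ convolutions, $(1,1,1)$ for the $3\times3\times3$
convolutions. Batch normalization follows every convolution and projection
shortcuts ($1\times1\times1$ convolution, matching stride) carry the
identity path where shape changes, the standard residual design. Weights
are He-normal initialized from the caller's RNG state.

**Connectivity encoder.** A three-hidden-layer perceptron,
$6670 \to 100 \to 100 \to 100 \to 2$ at full scale, rectified-linear
activations after each hidden layer (687,502 trainable parameters at full
scale).

**Fusion.** Both encoders are truncated to feature mode — the ResNet's
512-to-2 output layer and the MLP's final 2-unit layer are bypassed — and
their features concatenated into a 612-vector feeding four fully-connected
layers. Only the final width (2) is architecturally fixed; the package
defaults to a monotone taper $612 \to 256 \to 64 \to 16 \to 2$, exposed in
`fusion_config()` because the interior widths are a free design choice.
Encoder weights are carried into the fused network bit-exactly; the head is
freshly initialized.

Because no deep-learning framework is available to R in this package's
dependency footprint — and because the architecture is the point — the
network stack is implemented in the package itself: explicit
forward/backward passes for 3D convolution (im2col + BLAS GEMM in C++,
chunked so full-scale inputs stay within memory), batch normalization, max
and global-average pooling, and linear layers, with SGD-with-momentum
updates. Every gradient path is tested against central finite differences,
and the convolution against a direct triple-loop oracle.

# Two-phase training

Phase I trains each encoder independently from scratch with softmax
cross-entropy, minibatch SGD (batch size 8, momentum 0.9, weight decay 0),
and a stepped learning-rate schedule
`lr_at_epoch(base, epoch, step, gamma) = base * gamma^floor(epoch/step)`.
Phase II builds the fused network from the Phase I weights and trains all
layers end to end. The train/test split is drawn once, persisted, and
reused by both phases, so no held-out subject ever contributes a gradient.
There is no validation split or early stopping: epoch counts are fixed.

`training_profile("full")` is the full-scale recipe: ResNet $10^{-2}$ for
30 epochs decaying $\times 0.1$ every 6; MLP $10^{-2}$ for 50 epochs
decaying every 5; fused network $10^{-5}$ for 30 epochs decaying every 8.
`training_profile("desk")` is the package default for synthetic cohorts of
a few dozen subjects: the same Phase I base rates with fewer epochs (ResNet
12, MLP 30), and a Phase II base rate of $10^{-3}$ over 15 epochs. The
Phase II change is deliberate: with only four or five minibatches per
epoch, a $10^{-5}$ rate leaves the freshly initialized fusion head
essentially at its random initialization, which defeats the purpose of the
fusion stage at this scale.

Class balance of the random split is not enforced by default (a stratified
option exists). Shuffling is seeded per epoch; with a fixed seed the split,
batch order, and final weights are identical across repeated runs, which
the test suite asserts at the level of the serialized metrics file.

# The synthetic cohort generator

Real multi-site fMRI is not redistributable with the package, so
`simulate_cohort()` generates desk-scale cohorts carrying exactly the
statistical structure the method assumes:

* Each region $r$ has a latent zero-mean unit-variance series drawn from a
  multivariate normal whose correlation matrix is `base_corr` (default
  0.2, a typical resting-state mean coupling) off the diagonal, with
  selected *effect pairs* shifted by $\pm$`effect_delta`$/2$ — up for the
  ASD group, down for controls. The shifted matrices are projected to the
  nearest positive semidefinite correlation matrix (eigenvalue clipping,
  then re-normalization to unit diagonal).
* Every voxel's series is its region latent plus independent Gaussian
  noise (`voxel_noise_sd`, default 0.5, i.e. noise at half the latent
  scale).
* A `modality_split` fraction of effect pairs is expressed only at voxel
  scale: voxels of region $i$ receive a sign-balanced component
  proportional to region $j$'s latent (and vice versa), present in ASD
  subjects only. The signs sum to zero within each region, so region means
  — and hence the connectivity vector — are untouched, while
  voxel-by-region fingerprint correlations shift. This is what makes the
  two modalities demonstrably complementary: "fine" pairs are invisible to
  the MLP branch by construction.
* The atlas is a deterministic tiling of the grid into `n_regions`
  near-cubic blocks; cohorts are byte-reproducible from one seed, with
  ground truth (effect pairs and regions) persisted for explanation
  studies.

What the generator does *not* emulate: hemodynamic response dynamics,
spatial autocorrelation of noise, multi-site batch effects, motion
artifacts, or realistic brain geometry. Passing tests on synthetic cohorts
therefore demonstrate that the pipeline recovers the kind of structure it
is designed for — not that it attains any particular accuracy on real
cohort data.

## Study conditions used by the test suite

The packaged tests run fixed, stated conditions (chosen once, at sizes a
single CPU handles in minutes):

* *Strong effect*: $16^3$ grid, 8 regions, $T = 120$, 40 subjects,
  `effect_delta` 0.6, `voxel_noise_sd` 0.5 — the pipeline must reach
  held-out accuracy $\ge 0.9$.
* *Null*: the same cohort with `effect_delta` 0 over seeds 1–3; pooled
  held-out accuracy must sit within three binomial standard errors of 0.5.
  Pooling over seeds is the point — a single 12-subject test set has an
  uninformatively wide chance band.
* *Complementary*: two effect pairs, $(1,2)$ coarse and $(3,4)$ fine
  (`modality_split` 0.5), seeds 1–5; mean fused accuracy must not fall
  below either branch.
* *Localization*: on seeds 1–3 of the complementary cohorts, mean Grad-CAM
  heat inside the ground-truth effect regions (half the volume, so
  "outside" is well defined) must exceed the mean outside.

# Grad-CAM explanations

`grad_cam()` implements gradient-weighted class activation mapping over
the ResNet branch: the target-class logit is backpropagated to a chosen
residual stage, each channel of that stage's activation is weighted by the
spatial mean of its gradient, and the rectified weighted sum is trilinearly
upsampled to the voxel grid and max-normalized. All three post-channel axes
of the activation are spatial and are upsampled jointly — at full scale the
stage-4 activation is $(512, 32, 3, 2)$, where 32 is the depthwise remnant
of the $H$ axis (the stem strides all three axes once; later downsampling
strides only $W$ and $D$), so no axis is averaged away. The default target
layer is the last residual stage, standard Grad-CAM practice; any stage can
be named, and an input-gradient mode is provided for comparison.

Two practical notes from the desk-scale localization study. First, the
saliency question is asked of the *disease* class score ("where is the
evidence of ASD?") for every subject: fine effects exist only in ASD
subjects, so explaining the control score on control subjects yields
diffuse maps. Second, at a $16^3$ grid the last stage's $W/D$ axes have
collapsed to size 1 and carry no lateral information; the localization
study therefore reads stage `block2b` (spatial $9 \times 3 \times 3$),
while the API default remains the last stage for realistically sized
inputs.

Attribution runs only through the fingerprint branch: the connectivity
vector has no spatial layout to fold a heat map onto. Overlays
(`overlay_saliency()`) blend a hot colormap over the grayscale anatomical
mid-sections with opacity proportional to heat, so zero heat reproduces
the anatomical section exactly.

# Numerical choices and degenerate inputs

* Batch normalization uses biased batch variance for normalization and
  momentum-0.1 running statistics for evaluation mode; $\epsilon = 10^{-5}$.
* SGD follows the momentum convention $v \leftarrow \mu v + g$,
  $w \leftarrow w - \eta v$.
* Max-pool ties resolve to the first element in scan order —
  deterministic.
* Softmax is computed with the max-shift for stability; cross-entropy adds
  $10^{-12}$ inside the logarithm.
* Zero-denominator precision/recall are reported as 0 with a warning
  rather than `NA`, so automated sweeps never crash on a degenerate
  confusion matrix.
* An all-zero saliency map is legal, flagged `degenerate`, and left
  unnormalized.
* Empty manifests parse to an empty table; every downstream stage rejects
  them with a typed validation error.

# Known limitations

* The networks run on CPU in R; full-scale *training* (hundreds of
  subjects at $61\times73\times61$) is out of reach here — full scale is
  exercised for architecture fidelity (a forward pass), while training
  studies run at desk scale.
* The desk-scale Phase II learning rate deviates from the full-scale
  recipe for the reason given above; users reproducing the original
  schedule should select `training_profile("full")`.
* Explanations cover the fingerprint branch only.
* The generator's latent-Gaussian model is the minimal structure the
  method assumes, not a biophysical simulator; see the caveats above.
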