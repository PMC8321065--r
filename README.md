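# fmrifusion

Multimodal functional-connectome classification for resting-state fMRI.

`fmrifusion` is an end-to-end pipeline for two-class diagnosis (ASD vs
control) from 4D BOLD volumes. From each scan and a parcellation atlas it
builds the two standard connectomic activation maps:

* the **voxel-by-region connectivity fingerprint**
  `corr(voxel series, region-mean series)`, an `(H, W, D, N)` volume that
  preserves the spatial layout of the connectome, and
* the **region-pair connectivity vector**, the row-major upper triangle of
  the `N x N` region correlation matrix — `N(N-1)/2` features, 6670 for a
  116-region AAL-style atlas.

The fingerprint feeds a 3D ResNet-18 encoder (2D convolutions replaced by
3D; region axis as input channels; stage widths 64/128/256/512; global
average pool to a 512-feature vector), the vector a three-hidden-layer MLP
(6670 → 100 → 100 → 100 → 2). Their feature vectors are concatenated
(512 + 100 = 612) into a four-layer fully-connected fusion head. Training
is two-phase: Phase I fits each encoder independently (softmax
cross-entropy, SGD with momentum 0.9, batch size 8, stepped LR decay);
Phase II initializes the fused network from the Phase I weights and trains
end to end. Grad-CAM saliency volumes explain individual predictions
through the fingerprint branch.

Because no deep-learning framework is available in the package's
dependency footprint, the network stack (3D convolution via im2col + BLAS
GEMM in C++, batch norm, pooling, backprop, SGD) is implemented in the
package and verified against finite-difference and brute-force oracles in
the test suite. A synthetic-cohort simulator with group-structured latent
covariance stands in for real cohort data, so the whole pipeline is
testable offline.

## Worked example

A desk-scale run on a simulated 40-subject cohort (16³ grid, 8 regions,
120 frames, effect size 0.6, voxel noise 0.5) — about half a minute on one
CPU:

```r
library(fmrifusion)

cfg <- run_config(
  run_dir = "runs/demo", seed = 1,
  simulate = list(grid = c(16, 16, 16), n_regions = 8, n_frames = 120,
                  n_per_group = 20, effect_delta = 0.6,
                  voxel_noise_sd = 0.5, seed = 1))
res <- run_pipeline(cfg)
str(res$metrics)
```

```
stage simulate: generating synthetic cohort
stage features: 40 subjects
stage split: 28 train / 12 test
stage phase1: training encoders on 28 subjects
stage phase2: end-to-end training
stage evaluate: 12 held-out subjects
stage explain: Grad-CAM for sub001, sub007
run complete: runs/demo/metrics.json
List of 6
 $ accuracy : num 1
 $ precision: num 1
 $ recall   : num 1
 $ f1       : num 1
 $ counts   :List of 5
  ..$ tp      : int 9
  ..$ fp      : int 0
  ..$ tn      : int 3
  ..$ fn      : int 0
  ..$ positive: chr "ASD"
 $ phase1   :List of 2
  ..$ resnet: ... accuracy 1
  ..$ mlp   : ... accuracy 1
```

The held-out metrics (accuracy, precision, recall, F1 with ASD as the
positive class) are written to `metrics.json`, alongside the resolved
config, the persisted train/test split (reused verbatim by both training
phases), per-subject fingerprints (NIfTI) and connectivity vectors (CSV),
checkpoints for each phase, and Grad-CAM saliency volumes with axial /
coronal / sagittal overlay PNGs. With this strong, low-noise effect the
cohort separates perfectly; lowering `effect_delta` toward 0 drives the
held-out accuracy to chance.

A command-line interface wraps the same stages:

```sh
inst/cli/fmrifusion run --out runs/demo --seed 1 --config run.yaml
inst/cli/fmrifusion describe --regions 116          # ResNet stage/shape table
inst/cli/fmrifusion explain --checkpoint runs/demo/checkpoints/phase2.rds \
    --features runs/demo/features --subject sub001 --out sub001
```

See the vignette (`vignettes/multimodal-connectome-classification.Rmd`)
for the model, the generator's assumptions, and every numerical design
choice.

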