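# Cached end-to-end pipeline runs shared by the acceptance-style tests.
# Each (kind, seed) combination is executed once per test session; run
# directories are kept in the session tempdir so later blocks can reread
# checkpoints, features, and ground truth.

.run_cache <- new.env(parent = emptyenv())

cohort_conditions <- function(kind, seed) {
  base <- list(grid = c(16, 16, 16), n_regions = 8, n_frames = 120,
               n_per_group = 20, voxel_noise_sd = 0.5, seed = seed)
  switch(kind,
    strong = c(base, list(effect_delta = 0.6)),
    null = c(base, list(effect_delta = 0)),
    comp = c(base, list(effect_delta = 0.6, modality_split = 0.5,
                        effect_pairs = list(c(1, 2), c(3, 4)))),
    stop("unknown cohort kind: ", kind))
}

cached_pipeline_run <- function(kind, seed) {
  key <- paste(kind, seed, sep = "_")
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  dir <- file.path(tempdir(), paste0("accrun_", key))
  cfg <- run_config(run_dir = dir, seed = seed, n_explain = 0,
                    simulate = cohort_conditions(kind, seed))
  res <- suppressWarnings(run_pipeline(cfg, resume = TRUE, quiet = TRUE))
  out <- list(metrics = res$metrics, split = res$split, dir = dir)
  .run_cache[[key]] <- out
  out
}

# Pooled test-set saliency contrast for one cached run: mean Grad-CAM heat
# (ASD class score, stage block2b) inside vs outside ground-truth regions.
saliency_contrast <- function(run) {
  gt <- jsonlite::read_json(file.path(run$dir, "cohort", "ground_truth.json"),
                            simplifyVector = TRUE)
  atlas <- read_atlas(file.path(run$dir, "cohort", "atlas.nii.gz"))
  feats <- readRDS(file.path(run$dir, "features", "features.rds"))
  net <- load_checkpoint(file.path(run$dir, "checkpoints", "phase2.rds"))
  inside <- atlas$labels %in% gt$effect_regions
  dim(inside) <- dim(atlas$labels)
  ins <- numeric(0); outs <- numeric(0)
  for (id in run$split$test_ids) {
    k <- match(id, feats$ids)
    x3d <- feats$fingerprints[, , , , k, drop = FALSE]
    dim(x3d) <- dim(x3d)[1:4]
    sal <- grad_cam(net, x3d, feats$vectors[k, ], target_class = "ASD",
                    layer = "block2b")
    ins <- c(ins, mean(sal$heat[inside]))
    outs <- c(outs, mean(sal$heat[!inside]))
  }
  c(inside = mean(ins), outside = mean(outs))
}
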