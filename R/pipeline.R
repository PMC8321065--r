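# End-to-end pipeline: simulate? -> features -> split -> phase1 -> phase2
# -> evaluate -> explain, with per-stage persistence in a run directory so
# runs are resumable and reproducible from one seed.

#' Pipeline run configuration
#'
#' All defaults are materialized here and the resolved config is written to
#' the run directory, so a run is reproducible from its `config.json`.
#'
#' @param run_dir output directory for all artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @param simulate `NULL` to use existing data, or a list of
#'   [synthetic_cohort_spec()] arguments for an on-the-fly cohort.
#' @param manifest,atlas paths to an existing manifest CSV and atlas NIfTI
#'   (ignored when simulating).
#' @param train_frac fraction of subjects used for training.
#' @param block_channels ResNet stage widths (default `c(16, 32, 64, 128)`,
#'   the desk-scale profile; use `c(64, 128, 256, 512)` for the full-scale
#'   architecture).
#' @param hidden_sizes MLP hidden widths (default `c(100, 100, 100)`).
#' @param head_sizes fusion head widths (default `c(256, 64, 16, 2)`).
#' @param profile training profile, `"desk"` or `"full"`
#'   (see [training_profile()]).
#' @param n_explain number of test subjects to explain with Grad-CAM.
#' @return a `run_config` list.
#' @export
run_config <- function(run_dir, seed = 1, simulate = NULL, manifest = NULL,
                       atlas = NULL, train_frac = 0.7,
                       block_channels = c(16, 32, 64, 128),
                       hidden_sizes = c(100, 100, 100),
                       head_sizes = c(256, 64, 16, 2),
                       profile = "desk", n_explain = 2) {
  if (is.null(simulate) && (is.null(manifest) || is.null(atlas)))
    ff_stop("validation", "either a simulate spec or manifest+atlas paths are required")
  structure(list(run_dir = run_dir, seed = as.integer(seed),
                 simulate = simulate, manifest = manifest, atlas = atlas,
                 train_frac = train_frac,
                 block_channels = as.integer(block_channels),
                 hidden_sizes = as.integer(hidden_sizes),
                 head_sizes = as.integer(head_sizes),
                 profile = profile, n_explain = as.integer(n_explain)),
            class = "run_config")
}

#' Compute and persist features for every subject in a manifest
#'
#' For each subject: region time series, voxel-by-region fingerprint
#' (written as 4D NIfTI), and region-pair connectivity vector (written as
#' CSV). A combined `features.rds` holds the stacked training arrays.
#'
#' @param manifest manifest data.frame (see [read_manifest()]).
#' @param atlas a [parcellation_atlas()].
#' @param out_dir output directory.
#' @return invisibly, list with `fingerprints` (`(N, H, W, D, B)` array,
#'   region axis first), `vectors` (`B x P` matrix), `ids`, `labels`.
#' @export
pipeline_features <- function(manifest, atlas, out_dir) {
  if (nrow(manifest) == 0) ff_stop("validation", "manifest has no subjects")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(manifest)
  nr <- length(atlas$region_ids)
  grid <- dim(atlas$labels)
  fps <- array(0, c(nr, grid, n))
  vecs <- matrix(0, n, n_connectivity_features(nr))
  for (k in seq_len(n)) {
    vol <- read_volume4d(manifest$volume_path[k])
    check_same_grid(vol, atlas)
    roits <- extract_roi_timeseries(vol, atlas)
    fp <- compute_fingerprint(vol, roits)
    cv <- compute_connectivity_vector(roits)
    id <- manifest$subject_id[k]
    write_fingerprint(fp, file.path(out_dir, paste0(id, "_fingerprint.nii.gz")))
    write_connectivity_vector(cv, file.path(out_dir, paste0(id, "_connectivity.csv")))
    fps[, , , , k] <- fingerprint_to_input(fp)
    vecs[k, ] <- cv$values
  }
  feats <- list(fingerprints = fps, vectors = vecs,
                ids = manifest$subject_id, labels = manifest$label,
                region_ids = atlas$region_ids)
  saveRDS(feats, file.path(out_dir, "features.rds"))
  invisible(feats)
}

subset_features <- function(feats, ids) {
  idx <- match(ids, feats$ids)
  if (anyNA(idx))
    ff_stop("validation", "subject id(s) missing from features: %s",
            paste(ids[is.na(idx)], collapse = ", "))
  list(fingerprints = feats$fingerprints[, , , , idx, drop = FALSE],
       vectors = feats$vectors[idx, , drop = FALSE],
       ids = feats$ids[idx], labels = feats$labels[idx])
}

stage_done <- function(paths) all(file.exists(paths))

#' Run the full pipeline
#'
#' Executes `simulate? -> features -> split -> phase1 -> phase2 ->
#' evaluate -> explain` with every artifact persisted under the run
#' directory. With `resume = TRUE` stages whose outputs already exist are
#' skipped. Two runs with identical config and seed produce identical
#' metrics.
#'
#' @param config a [run_config()].
#' @param resume logical; reuse completed stage outputs.
#' @param quiet suppress progress messages.
#' @return list with `metrics` (also written to `metrics.json`),
#'   `split`, and `run_dir`.
#' @export
run_pipeline <- function(config, resume = FALSE, quiet = FALSE) {
  rd <- config$run_dir
  dir.create(rd, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  cfg_json <- file.path(rd, "config.json")
  jsonlite::write_json(unclass(config), cfg_json, auto_unbox = TRUE,
                       null = "null", digits = NA, pretty = TRUE, force = TRUE)

  # -- simulate ----------------------------------------------------------
  if (!is.null(config$simulate)) {
    cohort_dir <- file.path(rd, "cohort")
    manifest_path <- file.path(cohort_dir, "manifest.csv")
    atlas_path <- file.path(cohort_dir, "atlas.nii.gz")
    if (!(resume && stage_done(c(manifest_path, atlas_path)))) {
      say("stage simulate: generating synthetic cohort")
      spec_args <- config$simulate
      spec_args$seed <- spec_args$seed %||% derive_seed(config$seed, 11)
      spec <- do.call(synthetic_cohort_spec, spec_args)
      simulate_cohort(spec, cohort_dir)
    } else say("stage simulate: reusing %s", cohort_dir)
    config$manifest <- manifest_path
    config$atlas <- atlas_path
  }
  manifest <- read_manifest(config$manifest)
  grid <- dim(RNifti::readNifti(config$atlas))
  atlas <- read_atlas(config$atlas, expected_grid = grid)

  # -- features ----------------------------------------------------------
  feat_dir <- file.path(rd, "features")
  feat_rds <- file.path(feat_dir, "features.rds")
  if (resume && stage_done(feat_rds)) {
    say("stage features: reusing %s", feat_rds)
    feats <- readRDS(feat_rds)
  } else {
    say("stage features: %d subjects", nrow(manifest))
    feats <- pipeline_features(manifest, atlas, feat_dir)
  }

  # -- split -------------------------------------------------------------
  split_path <- file.path(rd, "split.json")
  if (resume && stage_done(split_path)) {
    split <- read_split_plan(split_path)
  } else {
    n_train <- max(1, round(config$train_frac * nrow(manifest)))
    split <- split_dataset(manifest, n_train, derive_seed(config$seed, 21))
    write_split_plan(split, split_path)
  }
  say("stage split: %d train / %d test", length(split$train_ids),
      length(split$test_ids))
  train <- subset_features(feats, split$train_ids)
  test <- subset_features(feats, split$test_ids)

  profiles <- training_profile(config$profile, seed = derive_seed(config$seed, 31))
  ck_dir <- file.path(rd, "checkpoints")
  dir.create(ck_dir, showWarnings = FALSE)
  rck <- file.path(ck_dir, "phase1_resnet.rds")
  mck <- file.path(ck_dir, "phase1_mlp.rds")
  fck <- file.path(ck_dir, "phase2.rds")
  nr <- length(atlas$region_ids)

  # -- phase 1 -----------------------------------------------------------
  if (resume && stage_done(c(rck, mck))) {
    say("stage phase1: reusing checkpoints")
    resnet <- load_checkpoint(rck)
    mlp <- load_checkpoint(mck)
  } else {
    say("stage phase1: training encoders on %d subjects", length(train$ids))
    resnet <- with_seed(derive_seed(config$seed, 41),
      build_resnet3d(resnet_config(in_channels = nr,
                                   block_channels = config$block_channels)))
    r1 <- train_phase1_resnet(resnet, train$fingerprints, train$labels,
                              profiles$resnet)
    mlp <- with_seed(derive_seed(config$seed, 42),
      build_mlp(mlp_config(in_features = n_connectivity_features(nr),
                           hidden_sizes = config$hidden_sizes)))
    m1 <- train_phase1_mlp(mlp, train$vectors, train$labels, profiles$mlp)
    save_checkpoint(resnet, rck)
    save_checkpoint(mlp, mck)
    jsonlite::write_json(list(resnet = r1[c("loss", "accuracy")],
                              mlp = m1[c("loss", "accuracy")]),
                         file.path(ck_dir, "phase1_history.json"), digits = NA)
  }

  # -- phase 2 -----------------------------------------------------------
  fusion <- fusion_config(resnet_feature_dim = config$block_channels[4],
                          mlp_feature_dim = config$hidden_sizes[3],
                          head_sizes = config$head_sizes)
  if (resume && stage_done(fck)) {
    say("stage phase2: reusing checkpoint")
    fused <- load_checkpoint(fck)
  } else {
    say("stage phase2: end-to-end training")
    fused <- with_seed(derive_seed(config$seed, 51),
      train_phase2_multimodal(resnet, mlp, fusion, train$fingerprints,
                              train$vectors, train$labels,
                              profiles$fused))$network
    save_checkpoint(fused, fck)
  }

  # -- evaluate ----------------------------------------------------------
  # Branch metrics come from the persisted Phase I checkpoints: end-to-end
  # training fine-tunes the encoder objects in place, so the in-memory
  # encoders no longer represent Phase I after Phase II has run.
  metrics_path <- file.path(rd, "metrics.json")
  say("stage evaluate: %d held-out subjects", length(test$ids))
  ev_fused <- evaluate_network(fused, test$fingerprints, test$vectors, test$labels)
  ev_resnet <- evaluate_network(load_checkpoint(rck),
                                fingerprints = test$fingerprints,
                                labels = test$labels)
  ev_mlp <- evaluate_network(load_checkpoint(mck), vectors = test$vectors,
                             labels = test$labels)
  metrics <- list(accuracy = ev_fused$accuracy, precision = ev_fused$precision,
                  recall = ev_fused$recall, f1 = ev_fused$f1,
                  counts = unclass(ev_fused$counts),
                  phase1 = list(
                    resnet = ev_resnet[c("accuracy", "precision", "recall", "f1")],
                    mlp = ev_mlp[c("accuracy", "precision", "recall", "f1")]))
  write_metrics(metrics, metrics_path)

  # -- explain -----------------------------------------------------------
  if (config$n_explain > 0) {
    sal_dir <- file.path(rd, "saliency")
    dir.create(sal_dir, showWarnings = FALSE)
    ids <- head(test$ids, config$n_explain)
    say("stage explain: Grad-CAM for %s", paste(ids, collapse = ", "))
    for (id in ids) {
      k <- match(id, test$ids)
      x3d <- test$fingerprints[, , , , k, drop = FALSE]
      dim(x3d) <- dim(x3d)[1:4]
      sal <- grad_cam(fused, x3d, test$vectors[k, ])
      write_saliency(sal, file.path(sal_dir, paste0(id, "_saliency.nii.gz")))
      vol <- read_volume4d(manifest$volume_path[match(id, manifest$subject_id)])
      overlay_saliency(sal, vol, file.path(sal_dir, id))
    }
  }
  say("run complete: %s", metrics_path)
  list(metrics = metrics, split = split, run_dir = rd)
}
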