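# Synthetic cohort generator.  Latent-Gaussian signal model: each region
# carries a zero-mean unit-variance latent series drawn from a group
# covariance (base correlation everywhere, +/- effect_delta/2 on effect
# pairs), every voxel's series is its region latent plus independent
# Gaussian noise.  A configurable fraction of effect pairs is expressed
# only at voxel scale ("fine" pairs): sign-balanced within-region
# components that leave the region means — and hence the region-pair
# connectivity vector — untouched while shifting voxel-by-region
# fingerprint correlations. This gives the two modalities complementary
# information, mirroring what the classifier stack assumes of real data.

#' Synthetic cohort specification
#'
#' @param grid integer length-3 voxel grid `(H, W, D)`.
#' @param n_regions number of atlas regions (`<= prod(grid)`).
#' @param n_frames time series length `T`.
#' @param n_per_group subjects per diagnostic group.
#' @param base_corr baseline inter-regional correlation in `[0, 1)`.
#' @param effect_pairs two-column matrix of region-id pairs carrying the
#'   group difference, or `NULL` to sample `n_effect_pairs` pairs from the
#'   spec seed.
#' @param n_effect_pairs number of auto-selected effect pairs (default 6).
#' @param effect_delta group difference in correlation on coarse effect
#'   pairs (ASD `base + delta/2`, control `base - delta/2`); also scales the
#'   fine (voxel-only) components. Group covariances are projected to the
#'   nearest positive semidefinite correlation matrix.
#' @param voxel_noise_sd standard deviation of independent voxel noise.
#' @param modality_split fraction of effect pairs expressed only in
#'   voxel-scale structure (invisible to the region-pair vector).
#' @param seed integer seed; the cohort is byte-reproducible from it.
#' @return a `synthetic_cohort_spec` list.
#' @export
synthetic_cohort_spec <- function(grid = c(16, 16, 16), n_regions = 8,
                                  n_frames = 120, n_per_group = 20,
                                  base_corr = 0.2, effect_pairs = NULL,
                                  n_effect_pairs = 6, effect_delta = 0.6,
                                  voxel_noise_sd = 0.5, modality_split = 0,
                                  seed = 1) {
  if (n_regions > prod(grid))
    ff_stop("validation", "n_regions (%d) exceeds voxel count (%d)",
            n_regions, prod(grid))
  if (base_corr < 0 || base_corr >= 1)
    ff_stop("validation", "base_corr must be in [0, 1)")
  if (voxel_noise_sd < 0) ff_stop("validation", "voxel_noise_sd must be >= 0")
  if (modality_split < 0 || modality_split > 1)
    ff_stop("validation", "modality_split must be in [0, 1]")
  if (n_frames < 2) ff_stop("validation", "n_frames must be >= 2")
  structure(list(grid = as.integer(grid), n_regions = as.integer(n_regions),
                 n_frames = as.integer(n_frames),
                 n_per_group = as.integer(n_per_group),
                 base_corr = base_corr, effect_pairs = effect_pairs,
                 n_effect_pairs = as.integer(n_effect_pairs),
                 effect_delta = effect_delta,
                 voxel_noise_sd = voxel_noise_sd,
                 modality_split = modality_split, seed = as.integer(seed)),
            class = "synthetic_cohort_spec")
}

#' Blocky synthetic parcellation atlas
#'
#' Tiles the grid with `n_regions` contiguous rectangular blocks (no
#' background): the axis split counts are the factor triple of `n_regions`
#' whose block edge lengths are most nearly equal. Deterministic.
#'
#' @param grid integer length-3 `(H, W, D)`.
#' @param n_regions number of regions.
#' @param seed kept for interface symmetry; the tiling is deterministic.
#' @return a [parcellation_atlas()] with labels `1..n_regions`.
#' @export
make_atlas <- function(grid, n_regions, seed = 1) {
  grid <- as.integer(grid)
  best <- NULL
  best_score <- Inf
  for (a in seq_len(min(n_regions, grid[1]))) {
    if (n_regions %% a != 0) next
    rest <- n_regions / a
    for (b in seq_len(min(rest, grid[2]))) {
      if (rest %% b != 0) next
      cc <- rest / b
      if (cc > grid[3]) next
      edges <- c(grid[1] / a, grid[2] / b, grid[3] / cc)
      score <- sd(edges)
      if (score < best_score - 1e-12) {
        best <- c(a, b, cc)
        best_score <- score
      }
    }
  }
  if (is.null(best))
    ff_stop("validation",
            "cannot tile a %s grid with %d rectangular regions",
            paste(grid, collapse = "x"), n_regions)
  axis_assign <- function(L, k) {
    bounds <- round(seq(0, L, length.out = k + 1))
    rep(seq_len(k), times = diff(bounds))
  }
  ia <- axis_assign(grid[1], best[1])
  ib <- axis_assign(grid[2], best[2])
  ic <- axis_assign(grid[3], best[3])
  lab <- outer(outer(ia, best[1] * (ib - 1), "+"),
               best[1] * best[2] * (ic - 1), "+")
  parcellation_atlas(array(as.integer(lab), grid))
}

# Nearest positive semidefinite correlation matrix: eigenvalue clipping
# followed by re-normalization to unit diagonal.
nearest_psd_corr <- function(m, eig_floor = 1e-6) {
  e <- eigen(m, symmetric = TRUE)
  vals <- pmax(e$values, eig_floor)
  m2 <- e$vectors %*% (vals * t(e$vectors))
  d <- sqrt(diag(m2))
  m2 <- m2 / outer(d, d)
  (m2 + t(m2)) / 2
}

# Group correlation matrices plus the coarse/fine routing of effect pairs.
# Pair selection and routing are deterministic from the spec seed.
build_group_structure <- function(spec) {
  n <- spec$n_regions
  pairs <- spec$effect_pairs
  if (is.null(pairs)) {
    all_pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    k <- min(spec$n_effect_pairs, nrow(all_pairs))
    sel <- with_seed(derive_seed(spec$seed, 1), sample.int(nrow(all_pairs), k))
    pairs <- cbind(all_pairs[sel, 2], all_pairs[sel, 1])  # (i, j), i < j
  }
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- matrix(as.integer(pairs), ncol = 2)
  pairs <- t(apply(pairs, 1, sort))
  n_fine <- round(spec$modality_split * nrow(pairs))
  fine_sel <- if (n_fine > 0)
    with_seed(derive_seed(spec$seed, 2), sample.int(nrow(pairs), n_fine))
  else integer(0)
  coarse <- pairs[setdiff(seq_len(nrow(pairs)), fine_sel), , drop = FALSE]
  fine <- pairs[fine_sel, , drop = FALSE]
  base <- matrix(spec$base_corr, n, n)
  diag(base) <- 1
  sig <- list(ASD = base, control = base)
  for (r in seq_len(nrow(coarse))) {
    i <- coarse[r, 1]; j <- coarse[r, 2]
    sig$ASD[i, j] <- sig$ASD[j, i] <- spec$base_corr + spec$effect_delta / 2
    sig$control[i, j] <- sig$control[j, i] <- spec$base_corr - spec$effect_delta / 2
  }
  sig <- lapply(sig, nearest_psd_corr)
  for (g in names(sig)) {
    ev <- eigen(sig[[g]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      ff_stop("validation", "group covariance not PSD after projection (min eig %.3g)",
              min(ev))
  }
  list(sigma = sig, coarse_pairs = coarse, fine_pairs = fine)
}

# Sign vector over a region's voxels that sums exactly to zero so fine
# components cancel in the region mean (odd counts get one zero entry).
balanced_signs <- function(nv) {
  s <- rep_len(c(1, -1), nv)
  if (nv %% 2 == 1) s[nv] <- 0
  s
}

#' Simulate one subject's BOLD volume
#'
#' Draws the region latents from the group's multivariate normal, adds the
#' fine (voxel-only) effect components for ASD subjects, and adds
#' independent voxel noise. Consumes the current RNG state; seed
#' externally (as [simulate_cohort()] does) for reproducibility.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param atlas a [parcellation_atlas()] consistent with the spec.
#' @param group `"ASD"` or `"control"`.
#' @param structure_ precomputed result of the internal group-structure
#'   builder; `NULL` to compute it from the spec.
#' @return a [volume4d()] of dims `(H, W, D, T)`.
#' @export
simulate_subject <- function(spec, atlas, group, structure_ = NULL) {
  group <- normalize_labels(group)
  if (is.null(structure_)) structure_ <- build_group_structure(spec)
  n <- spec$n_regions
  if (length(atlas$region_ids) != n)
    ff_stop("validation", "atlas has %d regions, spec expects %d",
            length(atlas$region_ids), n)
  nt <- spec$n_frames
  lat <- MASS::mvrnorm(nt, mu = numeric(n), Sigma = structure_$sigma[[group]])
  lab <- as.vector(atlas$labels)
  reg_index <- match(lab, atlas$region_ids)
  x <- lat[, reg_index, drop = FALSE]            # T x voxels
  if (group == "ASD" && nrow(structure_$fine_pairs) > 0) {
    for (r in seq_len(nrow(structure_$fine_pairs))) {
      i <- structure_$fine_pairs[r, 1]
      j <- structure_$fine_pairs[r, 2]
      vi <- which(reg_index == i)
      vj <- which(reg_index == j)
      x[, vi] <- x[, vi] + spec$effect_delta *
        (lat[, j] %o% balanced_signs(length(vi)))
      x[, vj] <- x[, vj] + spec$effect_delta *
        (lat[, i] %o% balanced_signs(length(vj)))
    }
  }
  if (spec$voxel_noise_sd > 0)
    x <- x + spec$voxel_noise_sd * matrix(rnorm(length(x)), nrow = nt)
  volume4d(array(t(x), c(spec$grid, nt)))
}

#' Simulate and persist a synthetic cohort
#'
#' Writes `2 * n_per_group` subjects (balanced, alternating labels) in the
#' package's standard formats: NIfTI volumes under `volumes/`, the atlas,
#' a manifest CSV, and a ground-truth JSON recording which region pairs
#' (and regions) carry the group effect. Byte-reproducible from the spec
#' seed; each subject is drawn under its own derived seed.
#'
#' @param spec a [synthetic_cohort_spec()].
#' @param dir output directory (created if needed).
#' @return list with `manifest` (data.frame), `atlas`, `ground_truth`,
#'   `dir`.
#' @export
simulate_cohort <- function(spec, dir) {
  dir.create(file.path(dir, "volumes"), recursive = TRUE, showWarnings = FALSE)
  atlas <- make_atlas(spec$grid, spec$n_regions, spec$seed)
  structure_ <- build_group_structure(spec)
  n_total <- 2 * spec$n_per_group
  ids <- sprintf("sub%03d", seq_len(n_total))
  labels <- rep(c("ASD", "control"), spec$n_per_group)
  paths <- file.path(dir, "volumes", paste0(ids, ".nii.gz"))
  for (k in seq_len(n_total)) {
    vol <- with_seed(derive_seed(spec$seed, 100 + k),
                     simulate_subject(spec, atlas, labels[k], structure_))
    write_volume4d(vol, paths[k])
  }
  manifest <- data.frame(subject_id = ids, volume_path = paths,
                         label = labels, stringsAsFactors = FALSE)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  write_atlas(atlas, file.path(dir, "atlas.nii.gz"))
  ground_truth <- list(
    coarse_pairs = structure_$coarse_pairs,
    fine_pairs = structure_$fine_pairs,
    effect_regions = sort(unique(as.vector(rbind(structure_$coarse_pairs,
                                                 structure_$fine_pairs)))))
  jsonlite::write_json(ground_truth, file.path(dir, "ground_truth.json"))
  list(manifest = manifest, atlas = atlas, ground_truth = ground_truth,
       dir = dir)
}
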