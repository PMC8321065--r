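ff <- asNamespace("fmrifusion")

test_that("atlas tiling partitions the grid into equal blocks when possible", {
  at <- make_atlas(c(4, 4, 4), 8)
  expect_identical(sort(unique(as.vector(at$labels))), 1:8)
  expect_true(all(table(at$labels) == 8))
  expect_identical(make_atlas(c(4, 4, 4), 8)$labels, at$labels)
  # uneven counts still tile with every region nonempty
  at2 <- make_atlas(c(5, 4, 3), 6)
  expect_identical(sort(unique(as.vector(at2$labels))), 1:6)
  expect_true(all(table(at2$labels) >= 1))
  expect_error(make_atlas(c(4, 4, 4), 13), class = "ff_validation_error")
  expect_error(synthetic_cohort_spec(grid = c(2, 2, 2), n_regions = 9),
               class = "ff_validation_error")
})

test_that("group covariances are symmetric PSD with unit diagonal", {
  spec <- synthetic_cohort_spec(n_regions = 8, base_corr = 0.2,
                                effect_delta = 0.6, seed = 3)
  st <- ff$build_group_structure(spec)
  for (g in c("ASD", "control")) {
    s <- st$sigma[[g]]
    expect_equal(s, t(s))
    expect_equal(diag(s), rep(1, 8))
    expect_gte(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  }
  # an extreme delta still yields a valid correlation matrix via projection
  spec2 <- synthetic_cohort_spec(n_regions = 6, base_corr = 0,
                                 effect_delta = 1.9, n_effect_pairs = 10,
                                 seed = 4)
  st2 <- ff$build_group_structure(spec2)
  expect_gte(min(eigen(st2$sigma$ASD, symmetric = TRUE,
                       only.values = TRUE)$values), -1e-10)
  expect_true(all(abs(st2$sigma$ASD) <= 1 + 1e-12))
})

test_that("noise-free subjects reproduce their latents exactly", {
  spec <- synthetic_cohort_spec(grid = c(4, 4, 4), n_regions = 8,
                                n_frames = 30, voxel_noise_sd = 0,
                                modality_split = 0, seed = 5)
  at <- make_atlas(spec$grid, spec$n_regions)
  vol <- ff$with_seed(5, simulate_subject(spec, at, "control"))
  rt <- extract_roi_timeseries(vol, at)
  # every voxel equals its region mean, so the region series equals any
  # member voxel's series and within-region fingerprint correlations are 1
  v1 <- vol$data[1, 1, 1, ]
  expect_equal(rt$series[at$labels[1, 1, 1], ], v1, ignore_attr = TRUE)
  fp <- compute_fingerprint(vol, rt)
  lab <- as.vector(at$labels)
  cc <- matrix(fp$corr, ncol = 8)
  expect_true(all(abs(cc[cbind(seq_along(lab), lab)] - 1) < 1e-10))
})

test_that("sample latent correlations converge to the group matrix", {
  spec <- synthetic_cohort_spec(grid = c(4, 4, 4), n_regions = 8,
                                n_frames = 400, voxel_noise_sd = 0,
                                modality_split = 0, effect_delta = 0.6,
                                seed = 6)
  at <- make_atlas(spec$grid, spec$n_regions)
  st <- ff$build_group_structure(spec)
  bound <- 3 / sqrt(spec$n_frames)
  for (seed in 1:3) {
    vol <- ff$with_seed(seed, simulate_subject(spec, at, "ASD", st))
    rt <- extract_roi_timeseries(vol, at)
    emp <- suppressWarnings(cor(t(rt$series)))
    i <- st$coarse_pairs[1, 1]; j <- st$coarse_pairs[1, 2]
    expect_lt(abs(emp[i, j] - st$sigma$ASD[i, j]), bound)
  }
})

test_that("fine effect pairs shift fingerprints but not the region vector", {
  base <- list(grid = c(6, 6, 6), n_regions = 8, n_frames = 300,
               voxel_noise_sd = 0.2, effect_delta = 0.8,
               effect_pairs = rbind(c(1, 2)), seed = 7)
  spec_fine <- do.call(synthetic_cohort_spec, c(base, modality_split = 1))
  at <- make_atlas(c(6, 6, 6), 8)
  st <- ff$build_group_structure(spec_fine)
  # fine routing leaves both group covariances identical
  expect_equal(st$sigma$ASD, st$sigma$control)
  asd <- ff$with_seed(8, simulate_subject(spec_fine, at, "ASD", st))
  ctl <- ff$with_seed(8, simulate_subject(spec_fine, at, "control", st))
  rt_a <- extract_roi_timeseries(asd, at)
  rt_c <- extract_roi_timeseries(ctl, at)
  cv_a <- compute_connectivity_vector(rt_a)$values
  cv_c <- compute_connectivity_vector(rt_c)$values
  # region-pair correlations carry (almost) no group signal...
  expect_lt(max(abs(cv_a - cv_c)), 0.15)
  # ...but voxel-level fingerprint correlations to the partner region differ
  fp_a <- compute_fingerprint(asd, rt_a)$corr
  fp_c <- compute_fingerprint(ctl, rt_c)$corr
  m1 <- at$labels == 1
  spread_a <- sd(fp_a[, , , 2][m1])
  spread_c <- sd(fp_c[, , , 2][m1])
  expect_gt(spread_a, 2 * spread_c)
})

test_that("cohorts are balanced, valid, and byte-reproducible", {
  spec <- synthetic_cohort_spec(grid = c(4, 4, 4), n_regions = 8,
                                n_frames = 12, n_per_group = 3, seed = 9)
  d1 <- file.path(tempfile("coh"), "a")
  d2 <- file.path(tempfile("coh"), "b")
  c1 <- simulate_cohort(spec, d1)
  c2 <- simulate_cohort(spec, d2)
  expect_identical(nrow(c1$manifest), 6L)
  expect_equal(as.vector(table(c1$manifest$label)), c(3, 3))
  for (k in seq_len(6)) {
    expect_identical(unname(tools::md5sum(c1$manifest$volume_path[k])),
                     unname(tools::md5sum(c2$manifest$volume_path[k])))
    vol <- read_volume4d(c1$manifest$volume_path[k])  # passes validation
    expect_identical(dim(vol$data), c(4L, 4L, 4L, 12L))
  }
  expect_true(file.exists(file.path(d1, "ground_truth.json")))
  m <- read_manifest(file.path(d1, "manifest.csv"))
  expect_identical(m$subject_id, c1$manifest$subject_id)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("held-out MLP accuracy grows with the effect size", {
  accs <- vapply(c(0, 0.8), function(delta) {
    out <- numeric(2)
    for (seed in 1:2) {
      spec <- synthetic_cohort_spec(grid = c(4, 4, 4), n_regions = 8,
                                    n_frames = 100, n_per_group = 12,
                                    effect_delta = delta,
                                    voxel_noise_sd = 0.5, seed = seed)
      at <- make_atlas(spec$grid, spec$n_regions)
      st <- ff$build_group_structure(spec)
      labs <- rep(c("ASD", "control"), 12)
      vecs <- t(vapply(seq_len(24), function(k) {
        vol <- ff$with_seed(seed * 100 + k,
                            simulate_subject(spec, at, labs[k], st))
        compute_connectivity_vector(extract_roi_timeseries(vol, at))$values
      }, numeric(28)))
      sp <- split_dataset(sprintf("s%d", 1:24), 16, seed = seed)
      tr <- as.integer(sub("s", "", sp$train_ids))
      te <- as.integer(sub("s", "", sp$test_ids))
      net <- ff$with_seed(seed, build_mlp(
        mlp_config(in_features = 28, hidden_sizes = c(16, 16, 16))))
      train_phase1_mlp(net, vecs[tr, ], labs[tr],
                       train_config(1e-2, epochs = 20, lr_step = 5, seed = seed))
      out[seed] <- evaluate_network(net, vectors = vecs[te, ],
                                    labels = labs[te])$accuracy
    }
    mean(out)
  }, numeric(1))
  expect_gt(accs[2], accs[1])
})
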