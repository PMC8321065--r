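test_that("pearson matches hand-computed values and conventions", {
  expect_equal(pearson(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(pearson(c(1, 2, 3), c(3, 2, 1)), -1)
  expect_equal(pearson(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_identical(pearson(c(2, 2, 2), c(1, 5, 9)), 0)
  expect_error(pearson(1:3, 1:4), class = "ff_validation_error")
  expect_error(pearson(1, 2), class = "ff_validation_error")
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(7); y <- rnorm(7)
    expect_equal(pearson(x, y), naive_pearson(x, y), tolerance = 1e-12)
  }
})

test_that("region time series are per-frame voxel means in label order", {
  # region 1: constant value 5; region 2: two voxels with series (1,2,..) / (3,4,..)
  lab <- array(c(1L, 1L, 2L, 2L), c(4, 1, 1))
  vol <- array(0, c(4, 1, 1, 2))
  vol[1, 1, 1, ] <- c(5, 5); vol[2, 1, 1, ] <- c(5, 5)
  vol[3, 1, 1, ] <- c(1, 2); vol[4, 1, 1, ] <- c(3, 4)
  rt <- extract_roi_timeseries(volume4d(vol), parcellation_atlas(lab))
  expect_equal(rt$series[1, ], c(5, 5), ignore_attr = TRUE)
  expect_equal(rt$series[2, ], c(2, 3), ignore_attr = TRUE)
  # one-voxel region reproduces that voxel's series exactly
  lab2 <- array(c(1L, 2L, 2L, 2L), c(4, 1, 1))
  rt2 <- extract_roi_timeseries(volume4d(vol), parcellation_atlas(lab2))
  expect_equal(rt2$series[1, ], vol[1, 1, 1, ], ignore_attr = TRUE)
})

test_that("grid mismatch between volume and atlas is a geometry error", {
  vol <- make_toy_volume(c(4, 4, 4), 5)
  at <- make_atlas(c(4, 4, 5), 4)
  expect_error(extract_roi_timeseries(vol, at), class = "ff_geometry_error")
})

test_that("fingerprint equals an exhaustive per-voxel pearson oracle", {
  set.seed(11)
  vol <- volume4d(array(rnorm(2 * 1 * 1 * 5), c(2, 1, 1, 5)))
  lab <- array(c(1L, 2L), c(2, 1, 1))
  at <- parcellation_atlas(lab)
  rt <- extract_roi_timeseries(vol, at)
  fp <- compute_fingerprint(vol, rt)
  expect_identical(dim(fp$corr), c(2L, 1L, 1L, 2L))
  for (v in 1:2) for (n in 1:2) {
    expect_equal(fp$corr[v, 1, 1, n],
                 naive_pearson(vol$data[v, 1, 1, ], rt$series[n, ]),
                 tolerance = 1e-10)
  }
  # a voxel identical to a region's mean series correlates 1 with it
  expect_equal(fp$corr[1, 1, 1, 1], 1, tolerance = 1e-12)
})

test_that("fingerprint zero-variance voxels and frame mismatches are handled", {
  vol <- make_toy_volume(c(3, 2, 2), 6, seed = 2)
  vol$data[1, 1, 1, ] <- 7  # constant voxel
  at <- make_atlas(c(3, 2, 2), 2)
  rt <- extract_roi_timeseries(vol, at)
  fp <- compute_fingerprint(vol, rt)
  expect_true(all(fp$corr[1, 1, 1, ] == 0))
  expect_true(all(abs(fp$corr) <= 1))
  rt_bad <- rt; rt_bad$series <- rt$series[, 1:3]
  expect_error(compute_fingerprint(vol, rt_bad), class = "ff_validation_error")
})

test_that("connectivity vector is the row-major upper triangle", {
  set.seed(3)
  s <- matrix(rnorm(3 * 8), 3, 8)
  rt <- structure(list(series = s, region_ids = c(2L, 5L, 9L)),
                  class = "roi_timeseries")
  cv <- compute_connectivity_vector(rt)
  expect_length(cv$values, 3)
  expect_equal(cv$values[1], naive_pearson(s[1, ], s[2, ]), tolerance = 1e-12)
  expect_equal(cv$values[2], naive_pearson(s[1, ], s[3, ]), tolerance = 1e-12)
  expect_equal(cv$values[3], naive_pearson(s[2, ], s[3, ]), tolerance = 1e-12)
  expect_equal(cv$pairs[, 1], c(2L, 2L, 5L), ignore_attr = TRUE)
  expect_equal(cv$pairs[, 2], c(5L, 9L, 9L), ignore_attr = TRUE)
  rt1 <- structure(list(series = s[1, , drop = FALSE], region_ids = 1L),
                   class = "roi_timeseries")
  expect_error(compute_connectivity_vector(rt1), class = "ff_validation_error")
})

test_that("N=4 ordering is row-major (not column-major upper.tri)", {
  set.seed(8)
  s <- matrix(rnorm(4 * 10), 4, 10)
  rt <- structure(list(series = s, region_ids = 1:4), class = "roi_timeseries")
  cv <- compute_connectivity_vector(rt)
  want <- c(naive_pearson(s[1, ], s[2, ]), naive_pearson(s[1, ], s[3, ]),
            naive_pearson(s[1, ], s[4, ]), naive_pearson(s[2, ], s[3, ]),
            naive_pearson(s[2, ], s[4, ]), naive_pearson(s[3, ], s[4, ]))
  expect_equal(cv$values, want, tolerance = 1e-12)
})

test_that("reconstructed correlation matrix is symmetric and matches the oracle", {
  set.seed(5)
  n <- 6; nt <- 12
  s <- matrix(rnorm(n * nt), n, nt)
  rt <- structure(list(series = s, region_ids = seq_len(n)),
                  class = "roi_timeseries")
  cv <- compute_connectivity_vector(rt)
  tm <- diag(n)
  tm[lower.tri(tm)] <- cv$values    # row-major upper triangle of t(tm)
  m <- t(tm)
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  oracle <- outer(seq_len(n), seq_len(n),
                  Vectorize(function(i, j) if (i == j) 1 else naive_pearson(s[i, ], s[j, ])))
  expect_lt(max(abs(m - t(m))), 1e-12)
  expect_lt(max(abs(m - oracle)), 1e-10)
})

test_that("maps are invariant to affine rescaling of input series", {
  vol <- make_toy_volume(c(4, 4, 2), 8, seed = 9)
  at <- make_atlas(c(4, 4, 2), 4)
  rt <- extract_roi_timeseries(vol, at)
  fp <- compute_fingerprint(vol, rt)
  cv <- compute_connectivity_vector(rt)
  vol2 <- volume4d(3.7 * vol$data + 11)
  rt2 <- extract_roi_timeseries(vol2, at)
  expect_equal(compute_fingerprint(vol2, rt2)$corr, fp$corr, tolerance = 1e-10)
  expect_equal(compute_connectivity_vector(rt2)$values, cv$values,
               tolerance = 1e-10)
})

test_that("noise-free parcellation: within-region fingerprint correlations are 1", {
  at <- make_atlas(c(4, 4, 4), 8)
  nt <- 20
  set.seed(6)
  latent <- matrix(rnorm(8 * nt), 8, nt)
  vol <- array(0, c(4, 4, 4, nt))
  vm <- matrix(vol, ncol = nt)
  vm[] <- latent[as.vector(at$labels), ]
  vol <- volume4d(array(vm, c(4, 4, 4, nt)))
  rt <- extract_roi_timeseries(vol, at)
  fp <- compute_fingerprint(vol, rt)
  lab <- as.vector(at$labels)
  cc <- matrix(fp$corr, ncol = 8)
  own <- cc[cbind(seq_along(lab), lab)]
  expect_true(all(abs(own - 1) < 1e-10))
})

test_that("fingerprints and connectivity vectors persist faithfully", {
  vol <- make_toy_volume(c(4, 4, 2), 8, seed = 10)
  at <- make_atlas(c(4, 4, 2), 4)
  rt <- extract_roi_timeseries(vol, at)
  fp <- compute_fingerprint(vol, rt)
  cv <- compute_connectivity_vector(rt)
  pf <- tempfile(fileext = ".nii.gz")
  pc <- tempfile(fileext = ".csv")
  write_fingerprint(fp, pf)
  write_connectivity_vector(cv, pc)
  expect_equal(read_fingerprint(pf, at$region_ids)$corr, fp$corr)
  expect_equal(read_connectivity_vector(pc, at$region_ids)$values, cv$values)
})
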