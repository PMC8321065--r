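ff <- asNamespace("fmrifusion")

test_that("dataset splits partition the manifest reproducibly", {
  ids <- sprintf("s%04d", 1:1035)
  sp <- split_dataset(ids, 900, seed = 42)
  expect_length(sp$train_ids, 900)
  expect_length(sp$test_ids, 135)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_setequal(c(sp$train_ids, sp$test_ids), ids)
  expect_identical(split_dataset(ids, 900, seed = 42), sp)
  expect_false(identical(split_dataset(ids, 900, seed = 43)$train_ids,
                         sp$train_ids))
  sp2 <- split_dataset(sprintf("x%d", 1:10), 8, seed = 1)
  expect_length(intersect(sp2$train_ids, sp2$test_ids), 0)
  expect_length(union(sp2$train_ids, sp2$test_ids), 10)
  expect_error(split_dataset(ids, 1035, seed = 1), class = "ff_validation_error")
})

test_that("split plans persist as JSON", {
  sp <- split_dataset(sprintf("s%d", 1:20), 15, seed = 3)
  p <- tempfile(fileext = ".json")
  write_split_plan(sp, p)
  expect_identical(read_split_plan(p), sp)
})

test_that("stratified splits keep both labels in the training set", {
  m <- data.frame(subject_id = sprintf("s%d", 1:20),
                  volume_path = "x",
                  label = rep(c("ASD", "control"), each = 10))
  sp <- split_dataset(m, 10, seed = 5, stratify = TRUE)
  lab <- m$label[match(sp$train_ids, m$subject_id)]
  expect_equal(as.vector(table(lab)), c(5, 5))
})

test_that("the stepped learning-rate schedule matches its closed form", {
  expect_equal(lr_at_epoch(1e-2, 0, 6), 1e-2)
  expect_equal(lr_at_epoch(1e-2, 6, 6), 1e-3)
  expect_equal(lr_at_epoch(1e-2, 29, 6), 1e-6)
  # full horizons of the three default schedules
  expect_equal(lr_at_epoch(1e-2, 0:29, 6),
               rep(10^-(2:6), each = 6)[1:30])
  expect_equal(lr_at_epoch(1e-2, 0:49, 5),
               rep(10^-(2:11), each = 5))
  expect_equal(lr_at_epoch(1e-5, 0:29, 8),
               rep(10^-(5:8), c(8, 8, 8, 6)))
  expect_error(lr_at_epoch(1e-2, -1, 6), class = "ff_validation_error")
})

# Small separable connectivity-vector problem used by several blocks.
separable_vectors <- function(n_per = 12, p = 10, gap = 3, seed = 31) {
  ff$with_seed(seed, {
    x <- rbind(matrix(rnorm(n_per * p, mean = gap / 2), n_per, p),
               matrix(rnorm(n_per * p, mean = -gap / 2), n_per, p))
    list(x = x, y = rep(c("ASD", "control"), each = n_per))
  })
}

test_that("the MLP fits a separable problem and logs one loss per epoch", {
  d <- separable_vectors()
  net <- ff$with_seed(32, build_mlp(mlp_config(in_features = 10,
                                               hidden_sizes = c(16, 16, 16))))
  fit <- train_phase1_mlp(net, d$x, d$y,
                          train_config(1e-2, epochs = 20, lr_step = 5, seed = 1))
  expect_length(fit$loss, 20)
  expect_length(fit$accuracy, 20)
  expect_gte(tail(fit$accuracy, 1), 0.95)
  # near-monotone loss on this convex-like problem
  expect_lte(mean(diff(fit$loss) > 1e-8), 0.3)
})

test_that("zero learning rate leaves all parameters untouched", {
  d <- separable_vectors(n_per = 6)
  net <- ff$with_seed(33, build_mlp(mlp_config(in_features = 10,
                                               hidden_sizes = c(8, 8, 8))))
  params_of <- function(n) {
    st <- ff$collect_state(n$leaves)
    st[!grepl("running_", names(st))]
  }
  before <- params_of(net)
  train_phase1_mlp(net, d$x, d$y, train_config(0, epochs = 3, lr_step = 5))
  expect_identical(params_of(net), before)
})

test_that("training is reproducible from the seed", {
  d <- separable_vectors(n_per = 8)
  run <- function() {
    net <- ff$with_seed(34, build_mlp(mlp_config(in_features = 10,
                                                 hidden_sizes = c(8, 8, 8))))
    train_phase1_mlp(net, d$x, d$y,
                     train_config(1e-2, epochs = 5, lr_step = 5, seed = 7))
    ff$collect_state(net$leaves)
  }
  expect_identical(run(), run())
})

test_that("the ResNet encoder fits a separable fingerprint problem", {
  ff$with_seed(35, {
    n_per <- 8
    x <- array(rnorm(4 * 8 * 8 * 8 * 2 * n_per), c(4, 8, 8, 8, 2 * n_per))
    x[1, , , , seq_len(n_per)] <- x[1, , , , seq_len(n_per)] + 2
  })
  y <- rep(c("ASD", "control"), each = 8)
  net <- ff$with_seed(36, build_resnet3d(
    resnet_config(in_channels = 4, block_channels = c(4, 8, 16, 32))))
  fit <- train_phase1_resnet(net, x, y,
                             train_config(1e-2, epochs = 6, lr_step = 6,
                                          seed = 2))
  expect_length(fit$loss, 6)
  expect_gte(tail(fit$accuracy, 1), 0.95)
})

test_that("phase II starts from the phase I encoder weights bit-exactly", {
  d <- separable_vectors(n_per = 6)
  ff$with_seed(37, {
    xf <- array(rnorm(4 * 8 * 8 * 8 * 12), c(4, 8, 8, 8, 12))
  })
  resnet <- ff$with_seed(38, build_resnet3d(
    resnet_config(in_channels = 4, block_channels = c(4, 8, 16, 32))))
  mlp <- ff$with_seed(39, build_mlp(mlp_config(in_features = 10,
                                               hidden_sizes = c(8, 8, 8))))
  r_before <- ff$collect_state(resnet$leaves)
  m_before <- ff$collect_state(mlp$leaves)
  # zero LR: encoder weights must come through both fusion and "training"
  fit <- train_phase2_multimodal(resnet, mlp,
    fusion_config(32, 8, c(16, 8, 4, 2)), xf, d$x, d$y,
    train_config(0, epochs = 2, lr_step = 8, seed = 3))
  after <- ff$collect_state(fit$network$leaves)
  keep <- function(st) st[!grepl("running_", names(st))]
  r_after <- after[grepl("^resnet\\.", names(after))]
  names(r_after) <- sub("^resnet\\.", "", names(r_after))
  m_after <- after[grepl("^mlp\\.", names(after))]
  names(m_after) <- sub("^mlp\\.", "", names(m_after))
  expect_identical(keep(r_after), keep(r_before))
  expect_identical(keep(m_after), keep(m_before))
  expect_error(train_phase2_multimodal(mlp, mlp,
    fusion_config(32, 8, c(16, 8, 4, 2)), xf, d$x, d$y),
    class = "ff_checkpoint_error")
})

test_that("empty training sets and label mismatches are rejected", {
  net <- ff$with_seed(40, build_mlp(mlp_config(in_features = 4,
                                               hidden_sizes = c(4, 4, 4))))
  expect_error(train_phase1_mlp(net, matrix(rnorm(12), 3, 4),
                                c("ASD", "control"),
                                train_config(1e-2, 2, 5)),
               class = "ff_validation_error")
})
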