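# Two-phase training protocol: Phase I trains the two encoders
# independently (softmax cross-entropy, minibatch SGD with momentum,
# stepped learning-rate decay); Phase II initializes the fused network from
# the Phase I weights and trains it end to end.

#' Training configuration
#'
#' @param base_lr initial learning rate (> 0, or 0 for a no-op run).
#' @param epochs number of epochs (fixed; no early stopping).
#' @param lr_step epochs between learning-rate decays.
#' @param lr_gamma multiplicative decay factor (default 0.1).
#' @param batch_size minibatch size (default 8).
#' @param momentum SGD momentum (default 0.9).
#' @param weight_decay L2 penalty (default 0).
#' @param seed integer seed controlling shuffling (and any weight
#'   initialization done under it by the caller).
#' @return a `train_config` list.
#' @export
train_config <- function(base_lr = 1e-2, epochs = 30, lr_step = 6,
                         lr_gamma = 0.1, batch_size = 8, momentum = 0.9,
                         weight_decay = 0, seed = 1) {
  if (base_lr < 0) ff_stop("validation", "base_lr must be >= 0")
  if (lr_gamma <= 0 || lr_gamma > 1)
    ff_stop("validation", "lr_gamma must be in (0, 1]")
  if (epochs < 1) ff_stop("validation", "epochs must be >= 1")
  structure(list(base_lr = base_lr, epochs = as.integer(epochs),
                 lr_step = as.integer(lr_step), lr_gamma = lr_gamma,
                 batch_size = as.integer(batch_size), momentum = momentum,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "train_config")
}

#' Canned training profiles
#'
#' `"full"` reproduces the full-scale schedules: ResNet 1e-2 for 30 epochs
#' with decay every 6; MLP 1e-2 for 50 epochs with decay every 5; fused
#' network 1e-5 for 30 epochs with decay every 8. `"desk"` is the package's
#' scaled-down default for synthetic cohorts of a few dozen subjects:
#' the same Phase I learning rates with fewer epochs (ResNet 12, MLP 30),
#' and a Phase II base rate of 1e-3 over 15 epochs — with only a handful of
#' minibatches per epoch a 1e-5 rate would leave the freshly initialized
#' fusion head effectively untrained.
#'
#' @param profile `"desk"` or `"full"`.
#' @param seed integer seed stored in each config.
#' @return list with `train_config`s `resnet`, `mlp`, `fused`.
#' @export
training_profile <- function(profile = c("desk", "full"), seed = 1) {
  profile <- match.arg(profile)
  if (profile == "full") {
    list(resnet = train_config(1e-2, 30, 6, seed = seed),
         mlp = train_config(1e-2, 50, 5, seed = seed),
         fused = train_config(1e-5, 30, 8, seed = seed))
  } else {
    list(resnet = train_config(1e-2, 12, 6, seed = seed),
         mlp = train_config(1e-2, 30, 5, seed = seed),
         fused = train_config(1e-3, 15, 8, seed = seed))
  }
}

#' Stepped learning-rate schedule
#'
#' `base_lr * lr_gamma^floor(epoch / lr_step)` for 0-based `epoch`.
#'
#' @param base_lr initial rate.
#' @param epoch 0-based epoch index.
#' @param lr_step epochs between decays.
#' @param lr_gamma decay factor.
#' @return the learning rate in effect at `epoch`.
#' @export
lr_at_epoch <- function(base_lr, epoch, lr_step, lr_gamma = 0.1) {
  if (any(epoch < 0)) ff_stop("validation", "epoch must be >= 0")
  base_lr * lr_gamma^floor(epoch / lr_step)
}

#' Random train/test split of a subject manifest
#'
#' Uniformly random without stratification (a stratified option is
#' available); reproducible from the seed. The split is fixed once and
#' reused by both training phases so no test subject ever influences a
#' training step.
#'
#' @param records a manifest data.frame (see [read_manifest()]) or a
#'   character vector of subject ids.
#' @param n_train number of training subjects (< total).
#' @param seed integer seed.
#' @param stratify logical; if `TRUE`, sample proportionally within each
#'   diagnosis label (requires a manifest with labels).
#' @return an object of class `split_plan`: list with `train_ids`,
#'   `test_ids`, `seed`.
#' @export
split_dataset <- function(records, n_train, seed, stratify = FALSE) {
  if (is.data.frame(records)) {
    ids <- records$subject_id
    labels <- records$label
  } else {
    ids <- as.character(records)
    labels <- NULL
  }
  n <- length(ids)
  if (anyDuplicated(ids))
    ff_stop("validation", "duplicate subject ids in records")
  if (n_train >= n)
    ff_stop("validation", "n_train (%d) must be smaller than the record count (%d)",
            n_train, n)
  if (n_train < 1) ff_stop("validation", "n_train must be >= 1")
  train <- with_seed(seed, {
    if (stratify && !is.null(labels)) {
      take <- unlist(lapply(split(seq_len(n), labels), function(ix) {
        k <- round(n_train * length(ix) / n)
        sample(ix, min(k, length(ix)))
      }))
      # top up / trim to exactly n_train, still seeded
      if (length(take) < n_train)
        take <- c(take, sample(setdiff(seq_len(n), take), n_train - length(take)))
      sort(take[seq_len(n_train)])
    } else {
      sort(sample.int(n, n_train))
    }
  })
  structure(list(train_ids = ids[train], test_ids = ids[-train],
                 seed = as.integer(seed)),
            class = "split_plan")
}

#' Persist / load a split plan as JSON
#' @param plan a `split_plan`.
#' @param path JSON path.
#' @return `path` (write) or the `split_plan` (read).
#' @export
write_split_plan <- function(plan, path) {
  jsonlite::write_json(list(train_ids = plan$train_ids,
                            test_ids = plan$test_ids, seed = plan$seed),
                       path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split_plan
#' @export
read_split_plan <- function(path) {
  if (!file.exists(path)) ff_stop("io", "split plan not found: %s", path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(train_ids = as.character(x$train_ids),
                 test_ids = as.character(x$test_ids),
                 seed = as.integer(x$seed)), class = "split_plan")
}

# Map labels to the logits column index (ASD = 1, control = 2).
label_index <- function(labels) match(normalize_labels(labels), .ff_label_levels)

# Slice a batch out of the inputs: 5D array -> trailing axis, matrix -> rows.
slice_input <- function(x, idx) {
  if (is.matrix(x)) return(x[idx, , drop = FALSE])
  x[, , , , idx, drop = FALSE]
}

# Shared minibatch SGD loop.  forward_fn(idx, training) must return the
# logits for that batch; backward_fn(grad) must backpropagate and leave
# gradients in the leaves.
sgd_train_loop <- function(leaves, n, yidx, config, forward_fn, backward_fn,
                           what = "network") {
  if (n < 1) ff_stop("validation", "empty training set")
  loss_hist <- numeric(config$epochs)
  acc_hist <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config$base_lr, ep - 1, config$lr_step, config$lr_gamma)
    ord <- with_seed(derive_seed(config$seed, ep), sample.int(n))
    losses <- numeric(0)
    ncorrect <- 0
    for (start in seq(1, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1, n)]
      logits <- forward_fn(idx, TRUE)
      ls <- softmax_xent(logits, yidx[idx])
      if (!is.finite(ls$loss))
        ff_stop("divergence", "non-finite loss while training %s at epoch %d",
                what, ep)
      backward_fn(ls$grad)
      sgd_step(leaves, lr, config$momentum, config$weight_decay)
      losses <- c(losses, ls$loss * length(idx))
      ncorrect <- ncorrect + sum(max.col(ls$probs, ties.method = "first") == yidx[idx])
    }
    loss_hist[ep] <- sum(losses) / n
    acc_hist[ep] <- ncorrect / n
  }
  list(loss = loss_hist, accuracy = acc_hist)
}

#' Phase I: train the 3D ResNet fingerprint encoder
#'
#' Softmax cross-entropy, minibatch SGD with momentum, stepped LR decay;
#' trained from scratch for a fixed number of epochs (no validation split
#' or early stopping). Defaults follow the full-scale recipe: base LR 1e-2,
#' 30 epochs, decay 0.1 every 6 epochs, batch size 8, momentum 0.9.
#'
#' @param net a `resnet3d` network (modified in place).
#' @param fingerprints channel-first array `(C, H, W, D, B)` of subject
#'   fingerprints.
#' @param labels diagnosis labels (length `B`).
#' @param config a [train_config()]; default `train_config(1e-2, 30, 6)`.
#' @return list with `network`, `loss` (per-epoch mean training loss), and
#'   `accuracy` (per-epoch training accuracy).
#' @export
train_phase1_resnet <- function(net, fingerprints, labels,
                                config = train_config(1e-2, 30, 6)) {
  yidx <- label_index(labels)
  n <- dim(fingerprints)[5]
  if (n != length(yidx))
    ff_stop("validation", "label count %d does not match subject count %d",
            length(yidx), n)
  hist <- sgd_train_loop(net$leaves, n, yidx, config,
    forward_fn = function(idx, training)
      resnet_forward(net, slice_input(fingerprints, idx), training),
    backward_fn = function(g) resnet_backward(net, g, from = "logits"),
    what = "resnet3d")
  c(list(network = net), hist)
}

#' Phase I: train the MLP connectivity encoder
#'
#' As [train_phase1_resnet()]; defaults follow the full-scale recipe for
#' the MLP: base LR 1e-2, 50 epochs, decay 0.1 every 5 epochs.
#'
#' @param net an `mlp` network (modified in place).
#' @param vectors `(B x P)` matrix of connectivity vectors.
#' @param labels diagnosis labels (length `B`).
#' @param config a [train_config()]; default `train_config(1e-2, 50, 5)`.
#' @return list with `network`, `loss`, `accuracy`.
#' @export
train_phase1_mlp <- function(net, vectors, labels,
                             config = train_config(1e-2, 50, 5)) {
  yidx <- label_index(labels)
  n <- nrow(vectors)
  if (n != length(yidx))
    ff_stop("validation", "label count %d does not match subject count %d",
            length(yidx), n)
  hist <- sgd_train_loop(net$leaves, n, yidx, config,
    forward_fn = function(idx, training)
      mlp_forward(net, slice_input(vectors, idx), training),
    backward_fn = function(g) mlp_backward(net, g, from = "logits"),
    what = "mlp")
  c(list(network = net), hist)
}

#' Phase II: train the fused multimodal network end to end
#'
#' Builds the fused network from the Phase I encoders (weights carried over
#' bit-exactly; the fusion head is freshly initialized) and trains all
#' layers. Full-scale defaults: base LR 1e-5, 30 epochs, decay 0.1 every 8
#' epochs.
#'
#' @param resnet the Phase I `resnet3d` (network object or checkpoint path).
#' @param mlp the Phase I `mlp` (network object or checkpoint path).
#' @param fusion a [fusion_config()].
#' @param fingerprints `(C, H, W, D, B)` fingerprint array.
#' @param vectors `(B x P)` connectivity matrix.
#' @param labels diagnosis labels.
#' @param config a [train_config()]; default `train_config(1e-5, 30, 8)`.
#' @return list with `network` (the trained `multimodal`), `loss`,
#'   `accuracy`.
#' @export
train_phase2_multimodal <- function(resnet, mlp, fusion, fingerprints,
                                    vectors, labels,
                                    config = train_config(1e-5, 30, 8)) {
  if (is.character(resnet)) resnet <- load_checkpoint(resnet)
  if (is.character(mlp)) mlp <- load_checkpoint(mlp)
  if (!inherits(resnet, "resnet3d"))
    ff_stop("checkpoint", "expected a resnet3d encoder, got '%s'", class(resnet)[1])
  if (!inherits(mlp, "mlp"))
    ff_stop("checkpoint", "expected an mlp encoder, got '%s'", class(mlp)[1])
  net <- build_multimodal(resnet, mlp, fusion)
  yidx <- label_index(labels)
  n <- dim(fingerprints)[5]
  if (n != nrow(vectors) || n != length(yidx))
    ff_stop("validation", "fingerprints (%d), vectors (%d) and labels (%d) disagree",
            n, nrow(vectors), length(yidx))
  hist <- sgd_train_loop(net$leaves, n, yidx, config,
    forward_fn = function(idx, training)
      multimodal_forward(net, slice_input(fingerprints, idx),
                         slice_input(vectors, idx), training),
    backward_fn = function(g) multimodal_backward(net, g),
    what = "multimodal")
  c(list(network = net), hist)
}

# Batched evaluation-mode prediction; returns predicted labels.
predict_labels <- function(net, fingerprints = NULL, vectors = NULL) {
  n <- if (!is.null(fingerprints)) dim(fingerprints)[5] else nrow(vectors)
  logits <- switch(class(net)[1],
    multimodal = multimodal_forward(net, fingerprints, vectors, FALSE),
    resnet3d = resnet_forward(net, fingerprints, FALSE),
    mlp = mlp_forward(net, vectors, FALSE),
    ff_stop("validation", "unsupported network class '%s'", class(net)[1]))
  stopifnot(nrow(logits) == n)
  .ff_label_levels[max.col(softmax(logits), ties.method = "first")]
}
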