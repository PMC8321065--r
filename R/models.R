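# Network architectures: the 3D ResNet-18 fingerprint encoder, the MLP
# connectivity encoder, and the fused multimodal classifier.
#
# The ResNet follows the standard 18-layer residual design with every 2D
# convolution replaced by its 3D equivalent.  Paddings are fixed by shape
# arithmetic so that the full-scale stage sizes for input (116,61,73,61)
# are: conv1 (64,32,38,32), max-pool (64,32,19,16), stage outputs
# (64,32,19,16) / (128,32,10,8) / (256,32,5,4) / (512,32,3,2), global
# average pool 512, final 2 logits.  Stages 1-2 use 1x3x3 kernels, stages
# 3-4 use 3x3x3; downsampling inside stages strides only the last two
# spatial axes (1,2,2).

#' 3D ResNet-18 configuration
#'
#' @param in_channels input channel count; at full scale the 116 atlas
#'   regions of the connectivity fingerprint.
#' @param block_channels channel widths of the four residual stages; must
#'   strictly double (default `c(64, 128, 256, 512)`).
#' @param conv1_kernel,conv1_stride,conv1_pad stem convolution geometry.
#' @param num_classes output classes (2: ASD vs control).
#' @return a `resnet_config` list.
#' @export
resnet_config <- function(in_channels = 116,
                          block_channels = c(64, 128, 256, 512),
                          conv1_kernel = c(5, 5, 5),
                          conv1_stride = c(2, 2, 2),
                          conv1_pad = c(3, 3, 3),
                          num_classes = 2) {
  if (length(block_channels) != 4L)
    ff_stop("validation", "block_channels must have 4 entries")
  if (!all(block_channels[-1] == 2 * block_channels[-4]))
    ff_stop("validation", "block_channels must strictly double: %s",
            paste(block_channels, collapse = ","))
  if (!all(conv1_stride %in% c(1, 2)))
    ff_stop("validation", "strides must be 1 or 2 per axis")
  structure(list(in_channels = as.integer(in_channels),
                 block_channels = as.integer(block_channels),
                 conv1_kernel = as.integer(conv1_kernel),
                 conv1_stride = as.integer(conv1_stride),
                 conv1_pad = as.integer(conv1_pad),
                 num_classes = as.integer(num_classes)),
            class = "resnet_config")
}

# Per-stage kernels/paddings (stages 1-2: 1x3x3; stages 3-4: 3x3x3) and
# first-block strides (stage 1 keeps size; stages 2-4 stride (1,2,2)).
.resnet_stage_plan <- function() {
  list(
    kernel = list(c(1, 3, 3), c(1, 3, 3), c(3, 3, 3), c(3, 3, 3)),
    pad    = list(c(0, 1, 1), c(0, 1, 1), c(1, 1, 1), c(1, 1, 1)),
    stride = list(c(1, 1, 1), c(1, 2, 2), c(1, 2, 2), c(1, 2, 2))
  )
}

## ---- residual basic block ---------------------------------------------

nn_basic_block <- function(in_ch, out_ch, kernel, stride, pad) {
  down <- any(stride != 1) || in_ch != out_ch
  new_module("nn_basic_block",
    conv1 = nn_conv3d(in_ch, out_ch, kernel, stride, pad),
    bn1 = nn_batchnorm3d(out_ch),
    relu1 = nn_relu(),
    conv2 = nn_conv3d(out_ch, out_ch, kernel, c(1, 1, 1), pad),
    bn2 = nn_batchnorm3d(out_ch),
    down_conv = if (down) nn_conv3d(in_ch, out_ch, c(1, 1, 1), stride, c(0, 0, 0)),
    down_bn = if (down) nn_batchnorm3d(out_ch),
    relu_out = nn_relu(),
    param_names = character(0))
}

#' @export
mod_forward.nn_basic_block <- function(mod, x, training = FALSE) {
  y <- mod_forward(mod$conv1, x, training)
  y <- mod_forward(mod$bn1, y, training)
  y <- mod_forward(mod$relu1, y, training)
  y <- mod_forward(mod$conv2, y, training)
  y <- mod_forward(mod$bn2, y, training)
  s <- if (is.null(mod$down_conv)) x else
    mod_forward(mod$down_bn, mod_forward(mod$down_conv, x, training), training)
  mod_forward(mod$relu_out, y + s, training)
}

#' @export
mod_backward.nn_basic_block <- function(mod, gout) {
  g <- mod_backward(mod$relu_out, gout)
  gm <- mod_backward(mod$bn2, g)
  gm <- mod_backward(mod$conv2, gm)
  gm <- mod_backward(mod$relu1, gm)
  gm <- mod_backward(mod$bn1, gm)
  gm <- mod_backward(mod$conv1, gm)
  gs <- if (is.null(mod$down_conv)) g else
    mod_backward(mod$down_conv, mod_backward(mod$down_bn, g))
  gm + gs
}

block_leaves <- function(block, prefix) {
  out <- list()
  out[[paste0(prefix, ".conv1")]] <- block$conv1
  out[[paste0(prefix, ".bn1")]] <- block$bn1
  out[[paste0(prefix, ".conv2")]] <- block$conv2
  out[[paste0(prefix, ".bn2")]] <- block$bn2
  if (!is.null(block$down_conv)) {
    out[[paste0(prefix, ".down_conv")]] <- block$down_conv
    out[[paste0(prefix, ".down_bn")]] <- block$down_bn
  }
  out
}

## ---- ResNet ------------------------------------------------------------

#' Build the 3D ResNet-18 fingerprint encoder
#'
#' Stem convolution, 1x3x3 max pooling, four residual stages of two basic
#' blocks each (batch normalization after every convolution, projection
#' shortcuts where shape changes), global average pooling to a feature
#' vector of `block_channels[4]` units, and a final fully-connected layer
#' to the class logits. Weight initialization draws from the current RNG
#' state (seed externally for reproducibility).
#'
#' @param config a [resnet_config()].
#' @return an object of class `resnet3d`.
#' @export
build_resnet3d <- function(config) {
  plan <- .resnet_stage_plan()
  ch <- config$block_channels
  net <- new_module("resnet3d",
    config = config,
    conv1 = nn_conv3d(config$in_channels, ch[1], config$conv1_kernel,
                      config$conv1_stride, config$conv1_pad),
    bn1 = nn_batchnorm3d(ch[1]),
    relu1 = nn_relu(),
    maxpool = nn_maxpool3d(c(1, 3, 3), c(1, 2, 2), c(0, 1, 1)),
    avgpool = nn_avgpool_global(),
    fc = nn_linear(ch[4], config$num_classes),
    param_names = character(0))
  blocks <- list()
  in_ch <- ch[1]
  for (s in 1:4) {
    for (b in c("a", "b")) {
      stride <- if (b == "a") plan$stride[[s]] else c(1, 1, 1)
      nm <- sprintf("block%d%s", s, b)
      blocks[[nm]] <- nn_basic_block(in_ch, ch[s], plan$kernel[[s]], stride,
                                     plan$pad[[s]])
      in_ch <- ch[s]
    }
  }
  net$blocks <- blocks
  leaves <- list(conv1 = net$conv1, bn1 = net$bn1)
  for (nm in names(blocks)) leaves <- c(leaves, block_leaves(blocks[[nm]], nm))
  leaves$fc <- net$fc
  net$leaves <- leaves
  net
}

ensure_5d <- function(x) {
  if (length(dim(x)) == 4L) dim(x) <- c(dim(x), 1L)
  x
}

#' Forward pass through the 3D ResNet
#'
#' @param net a `resnet3d` network.
#' @param x input array `(C, H, W, D)` or batched `(C, H, W, D, B)` —
#'   channel-first, i.e. a fingerprint reshaped so the region axis leads.
#' @param training logical; batch statistics vs running statistics in the
#'   normalization layers.
#' @param output `"logits"` (default) or `"features"` for the truncated
#'   encoder (post-average-pool vector, the fusion input).
#' @return a `(B x num_classes)` logits matrix or `(B x feature_dim)`
#'   feature matrix. The per-stage output shapes of the pass are attached
#'   to the network as `net$last_shapes`.
#' @export
resnet_forward <- function(net, x, training = FALSE, output = c("logits", "features")) {
  output <- match.arg(output)
  x <- ensure_5d(x)
  shapes <- list()
  acts <- list()
  y <- mod_forward(net$conv1, x, training)
  y <- mod_forward(net$bn1, y, training)
  y <- mod_forward(net$relu1, y, training)
  shapes$conv1 <- dim(y)
  y <- mod_forward(net$maxpool, y, training)
  shapes$maxpool <- dim(y)
  for (nm in names(net$blocks)) {
    y <- mod_forward(net$blocks[[nm]], y, training)
    shapes[[nm]] <- dim(y)
    acts[[nm]] <- y
  }
  f <- mod_forward(net$avgpool, y, training)
  shapes$avgpool <- dim(f)
  net$last_shapes <- shapes
  net$last_acts <- acts
  if (output == "features") return(f)
  mod_forward(net$fc, f, training)
}

# Backward through the ResNet.  `from` names the tensor `g` differentiates:
# the logits or the pooled features.  If `collect_at` names a residual
# block, returns the gradient at that block's *output* (used by Grad-CAM);
# otherwise returns the gradient at the network input.
resnet_backward <- function(net, g, from = c("logits", "features"),
                            collect_at = NULL) {
  from <- match.arg(from)
  if (from == "logits") g <- mod_backward(net$fc, g)
  g <- mod_backward(net$avgpool, g)
  for (nm in rev(names(net$blocks))) {
    if (!is.null(collect_at) && nm == collect_at) return(g)
    g <- mod_backward(net$blocks[[nm]], g)
  }
  if (!is.null(collect_at))
    ff_stop("validation", "unknown layer '%s'; valid layers: %s", collect_at,
            paste(names(net$blocks), collapse = ", "))
  g <- mod_backward(net$maxpool, g)
  g <- mod_backward(net$relu1, g)
  g <- mod_backward(net$bn1, g)
  mod_backward(net$conv1, g)
}

#' Expected stage-by-stage output shapes of the 3D ResNet
#'
#' Pure shape arithmetic (`floor((L + 2p - k)/s) + 1` per axis), independent
#' of any forward pass; used to validate architecture fidelity and by the
#' `model describe` command.
#'
#' @param config a [resnet_config()].
#' @param input_grid integer length-3 spatial grid `(H, W, D)`.
#' @return data.frame with columns `stage`, `channels`, `H`, `W`, `D`.
#' @export
resnet_shape_table <- function(config, input_grid) {
  co <- function(L, k, s, p) floor((L + 2 * p - k) / s) + 1
  plan <- .resnet_stage_plan()
  g <- as.integer(input_grid)
  rows <- list()
  g <- mapply(co, g, config$conv1_kernel, config$conv1_stride, config$conv1_pad)
  rows[["conv1"]] <- c(config$block_channels[1], g)
  g <- mapply(co, g, c(1, 3, 3), c(1, 2, 2), c(0, 1, 1))
  rows[["maxpool"]] <- c(config$block_channels[1], g)
  for (s in 1:4) {
    g <- mapply(co, g, plan$kernel[[s]], plan$stride[[s]], plan$pad[[s]])
    if (any(g < 1))
      ff_stop("shape", "input grid too small: stage %d output would be %s",
              s, paste(g, collapse = "x"))
    rows[[sprintf("block%da", s)]] <- c(config$block_channels[s], g)
    rows[[sprintf("block%db", s)]] <- c(config$block_channels[s], g)
  }
  rows[["avgpool"]] <- c(config$block_channels[4], 1, 1, 1)
  rows[["fc"]] <- c(config$num_classes, NA, NA, NA)
  df <- do.call(rbind, rows)
  data.frame(stage = rownames(df), channels = df[, 1], H = df[, 2],
             W = df[, 3], D = df[, 4], row.names = NULL)
}

## ---- MLP ---------------------------------------------------------------

#' MLP configuration for the connectivity-vector encoder
#'
#' @param in_features input length; `N(N-1)/2` region-pair correlations
#'   (6670 at full scale).
#' @param hidden_sizes exactly three hidden layer widths (default 100 each).
#' @param out_classes output classes.
#' @return an `mlp_config` list.
#' @export
mlp_config <- function(in_features = 6670, hidden_sizes = c(100, 100, 100),
                       out_classes = 2) {
  if (length(hidden_sizes) != 3L)
    ff_stop("validation", "the MLP has exactly 3 hidden layers, got %d",
            length(hidden_sizes))
  if (any(c(in_features, hidden_sizes, out_classes) < 1))
    ff_stop("validation", "all MLP sizes must be >= 1")
  structure(list(in_features = as.integer(in_features),
                 hidden_sizes = as.integer(hidden_sizes),
                 out_classes = as.integer(out_classes)),
            class = "mlp_config")
}

#' Build the MLP connectivity encoder
#'
#' Three hidden layers with rectified-linear activations, then a linear
#' output layer: 6670 -> 100 -> 100 -> 100 -> 2 at full scale. The
#' truncated (feature) mode exposes the final hidden activation.
#'
#' @param config an [mlp_config()].
#' @return an object of class `mlp`.
#' @export
build_mlp <- function(config) {
  sizes <- c(config$in_features, config$hidden_sizes)
  net <- new_module("mlp", config = config, param_names = character(0))
  hidden <- list()
  relus <- list()
  for (i in 1:3) {
    hidden[[i]] <- nn_linear(sizes[i], sizes[i + 1])
    relus[[i]] <- nn_relu()
  }
  net$hidden <- hidden
  net$relus <- relus
  net$out <- nn_linear(sizes[4], config$out_classes)
  net$leaves <- list(hidden1 = hidden[[1]], hidden2 = hidden[[2]],
                     hidden3 = hidden[[3]], out = net$out)
  net
}

#' Forward pass through the MLP
#'
#' @param net an `mlp` network.
#' @param x `(B x in_features)` matrix (or a single vector).
#' @param training unused (kept for interface symmetry).
#' @param output `"logits"` or `"features"` (last hidden activation).
#' @return `(B x out_classes)` or `(B x hidden)` matrix.
#' @export
mlp_forward <- function(net, x, training = FALSE, output = c("logits", "features")) {
  output <- match.arg(output)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  for (i in 1:3) {
    x <- mod_forward(net$hidden[[i]], x, training)
    x <- mod_forward(net$relus[[i]], x, training)
  }
  if (output == "features") return(x)
  mod_forward(net$out, x, training)
}

mlp_backward <- function(net, g, from = c("logits", "features")) {
  from <- match.arg(from)
  if (from == "logits") g <- mod_backward(net$out, g)
  for (i in 3:1) {
    g <- mod_backward(net$relus[[i]], g)
    g <- mod_backward(net$hidden[[i]], g)
  }
  g
}

## ---- multimodal fusion -------------------------------------------------

#' Fusion head configuration
#'
#' @param resnet_feature_dim width of the ResNet post-pool feature (512 at
#'   full scale).
#' @param mlp_feature_dim width of the MLP last hidden layer (100).
#' @param head_sizes widths of the four fully-connected fusion layers; the
#'   last must be 2. Default `c(256, 64, 16, 2)`, a monotone taper from the
#'   612-unit concatenation.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(resnet_feature_dim = 512, mlp_feature_dim = 100,
                          head_sizes = c(256, 64, 16, 2)) {
  if (length(head_sizes) != 4L)
    ff_stop("validation", "the fusion head has exactly 4 layers, got %d",
            length(head_sizes))
  if (head_sizes[4] != 2L)
    ff_stop("validation", "the final fusion layer must have 2 units")
  structure(list(resnet_feature_dim = as.integer(resnet_feature_dim),
                 mlp_feature_dim = as.integer(mlp_feature_dim),
                 head_sizes = as.integer(head_sizes)),
            class = "fusion_config")
}

#' Build the fused multimodal classifier
#'
#' Truncates both trained encoders to feature mode (the ResNet's 512-to-2
#' output layer and the MLP's final 2-unit layer are bypassed), concatenates
#' their feature vectors, and attaches a freshly initialized four-layer
#' fully-connected head with rectified-linear activations between layers.
#' Encoder weights are carried over by reference, bit-exactly.
#'
#' @param resnet a trained (or fresh) `resnet3d`.
#' @param mlp a trained (or fresh) `mlp`.
#' @param fusion a [fusion_config()].
#' @return an object of class `multimodal`.
#' @export
build_multimodal <- function(resnet, mlp, fusion = fusion_config()) {
  rdim <- resnet$config$block_channels[4]
  mdim <- mlp$config$hidden_sizes[3]
  if (rdim != fusion$resnet_feature_dim)
    ff_stop("shape", "ResNet feature dim %d does not match fusion config %d",
            rdim, fusion$resnet_feature_dim)
  if (mdim != fusion$mlp_feature_dim)
    ff_stop("shape", "MLP feature dim %d does not match fusion config %d",
            mdim, fusion$mlp_feature_dim)
  sizes <- c(rdim + mdim, fusion$head_sizes)
  head <- list()
  head_relus <- list()
  for (i in 1:4) {
    head[[i]] <- nn_linear(sizes[i], sizes[i + 1])
    if (i < 4) head_relus[[i]] <- nn_relu()
  }
  net <- new_module("multimodal",
    resnet = resnet, mlp = mlp, fusion = fusion,
    head = head, head_relus = head_relus,
    param_names = character(0))
  leaves <- list()
  for (nm in names(resnet$leaves)) leaves[[paste0("resnet.", nm)]] <- resnet$leaves[[nm]]
  for (nm in names(mlp$leaves)) leaves[[paste0("mlp.", nm)]] <- mlp$leaves[[nm]]
  for (i in 1:4) leaves[[paste0("head", i)]] <- head[[i]]
  net$leaves <- leaves
  net
}

#' Forward pass through the multimodal network
#'
#' @param net a `multimodal` network.
#' @param x3d fingerprint input `(C, H, W, D[, B])`, region axis first.
#' @param xvec connectivity input `(B x P)` matrix or single vector.
#' @param training logical.
#' @return `(B x 2)` logits matrix.
#' @export
multimodal_forward <- function(net, x3d, xvec, training = FALSE) {
  rf <- resnet_forward(net$resnet, x3d, training, output = "features")
  mf <- mlp_forward(net$mlp, xvec, training, output = "features")
  z <- cbind(rf, mf)
  for (i in 1:4) {
    z <- mod_forward(net$head[[i]], z, training)
    if (i < 4) z <- mod_forward(net$head_relus[[i]], z, training)
  }
  z
}

# Backward through head and both encoders; returns the Grad-CAM style
# gradient at `collect_at` (a ResNet block name) when requested.
multimodal_backward <- function(net, gout, collect_at = NULL) {
  g <- gout
  for (i in 4:1) {
    if (i < 4) g <- mod_backward(net$head_relus[[i]], g)
    g <- mod_backward(net$head[[i]], g)
  }
  rdim <- net$fusion$resnet_feature_dim
  gr <- g[, seq_len(rdim), drop = FALSE]
  gm <- g[, rdim + seq_len(net$fusion$mlp_feature_dim), drop = FALSE]
  res <- resnet_backward(net$resnet, gr, from = "features", collect_at = collect_at)
  mlp_backward(net$mlp, gm, from = "features")
  invisible(res)
}

#' Classify one subject
#'
#' Deterministic evaluation-mode forward pass; probabilities are the
#' softmax of the two logits and the predicted class the argmax
#' (class order: ASD, control).
#'
#' @param net a `multimodal` network (or a `resnet3d` / `mlp` encoder, in
#'   which case only the matching input is used).
#' @param fingerprint a `fingerprint_map` or a channel-first input array.
#' @param connectivity a `connectivity_vector` or numeric vector.
#' @return list with `logits`, `probabilities` (named), `predicted_class`.
#' @export
predict_subject <- function(net, fingerprint = NULL, connectivity = NULL) {
  x3d <- if (inherits(fingerprint, "fingerprint_map"))
    fingerprint_to_input(fingerprint) else fingerprint
  xv <- if (inherits(connectivity, "connectivity_vector"))
    connectivity$values else connectivity
  logits <- switch(class(net)[1],
    multimodal = multimodal_forward(net, x3d, xv, training = FALSE),
    resnet3d = resnet_forward(net, x3d, training = FALSE),
    mlp = mlp_forward(net, xv, training = FALSE),
    ff_stop("validation", "unsupported network class '%s'", class(net)[1]))
  p <- softmax(logits)[1, ]
  names(p) <- .ff_label_levels
  list(logits = logits[1, ],
       probabilities = p,
       predicted_class = .ff_label_levels[which.max(p)])
}

#' Total trainable parameter count of a network
#' @param net a network built by this package.
#' @return integer parameter count.
#' @export
count_parameters <- function(net) {
  sum(vapply(net$leaves, function(leaf)
    sum(vapply(leaf$param_names, function(p) length(leaf[[p]]), 0L)), 0))
}

## ---- checkpoints -------------------------------------------------------

#' Save a network checkpoint
#'
#' Weights, batch-norm running statistics, and the configuration needed to
#' rebuild the network are stored together.
#'
#' @param net a `resnet3d`, `mlp`, or `multimodal` network.
#' @param path output `.rds` path.
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(net, path) {
  type <- class(net)[1]
  cfg <- switch(type,
    resnet3d = list(resnet = net$config),
    mlp = list(mlp = net$config),
    multimodal = list(resnet = net$resnet$config, mlp = net$mlp$config,
                      fusion = net$fusion),
    ff_stop("validation", "unsupported network class '%s'", type))
  saveRDS(list(type = type, configs = cfg, state = collect_state(net$leaves)),
          path)
  invisible(path)
}

#' Load a network checkpoint saved by [save_checkpoint()]
#' @param path `.rds` path.
#' @return the rebuilt network with restored weights.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) ff_stop("checkpoint", "checkpoint not found: %s", path)
  ck <- readRDS(path)
  if (!is.list(ck) || is.null(ck$type))
    ff_stop("checkpoint", "file %s is not a checkpoint", path)
  net <- switch(ck$type,
    resnet3d = build_resnet3d(ck$configs$resnet),
    mlp = build_mlp(ck$configs$mlp),
    multimodal = build_multimodal(build_resnet3d(ck$configs$resnet),
                                  build_mlp(ck$configs$mlp),
                                  ck$configs$fusion),
    ff_stop("checkpoint", "unknown checkpoint type '%s'", ck$type))
  load_state(net$leaves, ck$state)
  net
}
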