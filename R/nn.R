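# Minimal neural-network stack: layer modules with explicit forward /
# backward passes and in-place SGD updates.  Modules are environments so
# parameters, momentum buffers, and forward caches live by reference.
#
# Tensor convention: spatial feature maps are channel-first 5D arrays
# (C, H, W, D, B); vector features are (B x F) matrices.  Batches are the
# trailing axis of spatial maps so a single sample is a contiguous block.

new_module <- function(cls, ...) {
  e <- new.env(parent = emptyenv())
  list2env(list(...), e)
  e$grads <- list()
  e$mom <- list()
  class(e) <- c(cls, "nn_module")
  e
}

# He-normal initialization for rectifier networks
he_init <- function(n, fan_in) rnorm(n, sd = sqrt(2 / fan_in))

## ---- layers -----------------------------------------------------------

nn_conv3d <- function(in_ch, out_ch, kernel, stride = c(1, 1, 1),
                      pad = c(0, 0, 0), bias = FALSE) {
  p <- in_ch * prod(kernel)
  m <- new_module("nn_conv3d",
    in_ch = in_ch, out_ch = out_ch,
    kernel = as.integer(kernel), stride = as.integer(stride),
    pad = as.integer(pad),
    W = matrix(he_init(p * out_ch, p), p, out_ch),
    b = if (bias) numeric(out_ch) else NULL,
    param_names = if (bias) c("W", "b") else "W")
  m
}

mod_forward <- function(mod, x, training = FALSE) UseMethod("mod_forward")
mod_backward <- function(mod, gout) UseMethod("mod_backward")

#' @export
mod_forward.nn_conv3d <- function(mod, x, training = FALSE) {
  xd <- dim(x)
  if (xd[1] != mod$in_ch)
    ff_stop("shape", "conv3d expects %d input channels, got %d", mod$in_ch, xd[1])
  y <- cpp_conv3d_forward(x, as.integer(xd), mod$W,
                          if (is.null(mod$b)) numeric(0) else mod$b,
                          mod$kernel, mod$stride, mod$pad)
  mod$cache <- list(x = x, xdim = xd)
  y
}

#' @export
mod_backward.nn_conv3d <- function(mod, gout) {
  cc <- mod$cache
  r <- cpp_conv3d_backward(cc$x, as.integer(cc$xdim), gout, mod$W,
                           !is.null(mod$b), mod$kernel, mod$stride, mod$pad)
  mod$grads <- list(W = r$gW, b = if (is.null(mod$b)) NULL else r$gb)
  r$gx
}

nn_batchnorm3d <- function(ch, eps = 1e-5, momentum = 0.1) {
  new_module("nn_batchnorm3d",
    ch = ch, eps = eps, momentum = momentum,
    gamma = rep(1, ch), beta = numeric(ch),
    running_mean = numeric(ch), running_var = rep(1, ch),
    param_names = c("gamma", "beta"))
}

#' @export
mod_forward.nn_batchnorm3d <- function(mod, x, training = FALSE) {
  xd <- dim(x)
  C <- xd[1]
  xm <- matrix(x, nrow = C)
  if (training) {
    mu <- rowMeans(xm)
    v <- rowMeans(xm * xm) - mu * mu
    v[v < 0] <- 0
    mod$running_mean <- (1 - mod$momentum) * mod$running_mean + mod$momentum * mu
    mod$running_var <- (1 - mod$momentum) * mod$running_var + mod$momentum * v
  } else {
    mu <- mod$running_mean
    v <- mod$running_var
  }
  inv_std <- 1 / sqrt(v + mod$eps)
  xhat <- (xm - mu) * inv_std
  y <- mod$gamma * xhat + mod$beta
  dim(y) <- xd
  mod$cache <- list(xhat = xhat, inv_std = inv_std, training = training, xdim = xd)
  y
}

#' @export
mod_backward.nn_batchnorm3d <- function(mod, gout) {
  cc <- mod$cache
  C <- cc$xdim[1]
  gy <- matrix(gout, nrow = C)
  mod$grads <- list(gamma = rowSums(gy * cc$xhat), beta = rowSums(gy))
  if (cc$training) {
    m_dy <- rowMeans(gy)
    m_dyx <- rowMeans(gy * cc$xhat)
    gx <- (mod$gamma * cc$inv_std) * (gy - m_dy - cc$xhat * m_dyx)
  } else {
    gx <- (mod$gamma * cc$inv_std) * gy
  }
  dim(gx) <- cc$xdim
  gx
}

nn_relu <- function() new_module("nn_relu", param_names = character(0))

#' @export
mod_forward.nn_relu <- function(mod, x, training = FALSE) {
  y <- x * (x > 0)
  mod$cache <- list(mask = x > 0)
  y
}

#' @export
mod_backward.nn_relu <- function(mod, gout) gout * mod$cache$mask

nn_maxpool3d <- function(kernel, stride, pad = c(0, 0, 0)) {
  new_module("nn_maxpool3d",
    kernel = as.integer(kernel), stride = as.integer(stride),
    pad = as.integer(pad), param_names = character(0))
}

#' @export
mod_forward.nn_maxpool3d <- function(mod, x, training = FALSE) {
  r <- cpp_maxpool3d_forward(x, as.integer(dim(x)), mod$kernel, mod$stride, mod$pad)
  mod$cache <- list(idx = r$idx, n_in = length(x), xdim = dim(x))
  r$out
}

#' @export
mod_backward.nn_maxpool3d <- function(mod, gout) {
  gx <- cpp_maxpool3d_backward(gout, mod$cache$idx, mod$cache$n_in)
  dim(gx) <- mod$cache$xdim
  gx
}

# Global average pool over all spatial positions: (C,H,W,D,B) -> (B x C)
nn_avgpool_global <- function() new_module("nn_avgpool_global",
                                           param_names = character(0))

#' @export
mod_forward.nn_avgpool_global <- function(mod, x, training = FALSE) {
  xd <- dim(x)
  C <- xd[1]; S <- prod(xd[2:4]); B <- xd[5]
  xm <- matrix(x, C * S, B)
  feats <- vapply(seq_len(B), function(b) rowMeans(matrix(xm[, b], C, S)),
                  numeric(C))
  mod$cache <- list(xdim = xd)
  t(matrix(feats, C, B))
}

#' @export
mod_backward.nn_avgpool_global <- function(mod, gout) {
  xd <- mod$cache$xdim
  C <- xd[1]; S <- prod(xd[2:4]); B <- xd[5]
  gx <- array(0, xd)
  gxm <- matrix(gx, C * S, B)
  for (b in seq_len(B))
    gxm[, b] <- rep(gout[b, ] / S, S)
  array(gxm, xd)
}

nn_linear <- function(in_features, out_features, bias = TRUE) {
  new_module("nn_linear",
    in_features = in_features, out_features = out_features,
    W = matrix(he_init(in_features * out_features, in_features),
               in_features, out_features),
    b = if (bias) numeric(out_features) else NULL,
    param_names = if (bias) c("W", "b") else "W")
}

#' @export
mod_forward.nn_linear <- function(mod, x, training = FALSE) {
  if (ncol(x) != mod$in_features)
    ff_stop("shape", "linear layer expects %d input features, got %d",
            mod$in_features, ncol(x))
  y <- x %*% mod$W
  if (!is.null(mod$b)) y <- sweep(y, 2, mod$b, "+")
  mod$cache <- list(x = x)
  y
}

#' @export
mod_backward.nn_linear <- function(mod, gout) {
  x <- mod$cache$x
  mod$grads <- list(W = crossprod(x, gout),
                    b = if (is.null(mod$b)) NULL else colSums(gout))
  gout %*% t(mod$W)
}

## ---- loss -------------------------------------------------------------

# Numerically stable softmax over rows of a logits matrix.
softmax <- function(logits) {
  z <- logits - apply(logits, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

# Softmax cross-entropy; yidx is the 1-based true-class column index.
# Returns mean loss, probabilities, and the gradient w.r.t. logits.
softmax_xent <- function(logits, yidx) {
  B <- nrow(logits)
  p <- softmax(logits)
  eps <- 1e-12
  loss <- -mean(log(p[cbind(seq_len(B), yidx)] + eps))
  g <- p
  g[cbind(seq_len(B), yidx)] <- g[cbind(seq_len(B), yidx)] - 1
  list(loss = loss, probs = p, grad = g / B)
}

## ---- parameter management ---------------------------------------------

# One SGD-with-momentum step over a flat list of leaf modules.
# PyTorch-style update: v <- momentum*v + g (+ wd*w); w <- w - lr*v.
sgd_step <- function(leaves, lr, momentum = 0.9, weight_decay = 0) {
  if (lr == 0) return(invisible(NULL))
  for (leaf in leaves) {
    for (p in leaf$param_names) {
      g <- leaf$grads[[p]]
      if (is.null(g)) next
      if (weight_decay > 0) g <- g + weight_decay * leaf[[p]]
      v <- leaf$mom[[p]]
      v <- if (is.null(v)) g else momentum * v + g
      leaf$mom[[p]] <- v
      leaf[[p]] <- leaf[[p]] - lr * v
    }
  }
  invisible(NULL)
}

# Copy all parameters (and batch-norm running statistics) of a network into
# a plain named list.
collect_state <- function(leaves) {
  out <- list()
  for (nm in names(leaves)) {
    leaf <- leaves[[nm]]
    for (p in leaf$param_names)
      out[[paste0(nm, ".", p)]] <- leaf[[p]]
    if (inherits(leaf, "nn_batchnorm3d")) {
      out[[paste0(nm, ".running_mean")]] <- leaf$running_mean
      out[[paste0(nm, ".running_var")]] <- leaf$running_var
    }
  }
  out
}

load_state <- function(leaves, state) {
  for (nm in names(leaves)) {
    leaf <- leaves[[nm]]
    slots <- leaf$param_names
    if (inherits(leaf, "nn_batchnorm3d"))
      slots <- c(slots, "running_mean", "running_var")
    for (p in slots) {
      key <- paste0(nm, ".", p)
      if (is.null(state[[key]]))
        ff_stop("checkpoint", "checkpoint is missing entry %s", key)
      cur <- leaf[[p]]
      new <- state[[key]]
      if (!is.null(cur) && !identical(dim(cur) %||% length(cur),
                                      dim(new) %||% length(new)))
        ff_stop("checkpoint", "checkpoint entry %s has incompatible shape", key)
      leaf[[p]] <- new
    }
  }
  invisible(NULL)
}
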