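# Grad-CAM visual explanations: rectified, gradient-weighted sums of a
# convolutional stage's activations, folded back to brain-volume space.
# Attribution runs through the ResNet branch only — the connectivity-vector
# branch has no spatial layout to fold a map onto (documented limitation).

#' Grad-CAM saliency for one prediction
#'
#' Runs an evaluation-mode forward pass, backpropagates the target-class
#' logit to the chosen residual stage, weights each channel of that stage's
#' activation by the spatial mean of its gradient, rectifies the weighted
#' sum, trilinearly upsamples it to the voxel grid, and normalizes the
#' maximum to 1. An identically zero map (possible when the class score
#' does not depend positively on any channel) is returned as-is and
#' flagged `degenerate`.
#'
#' @param net a `multimodal` or `resnet3d` network.
#' @param fingerprint a `fingerprint_map` (or channel-first input array with
#'   attribute-free dims `(C, H, W, D)`).
#' @param connectivity a `connectivity_vector` or numeric vector (required
#'   for multimodal networks).
#' @param target_class `"ASD"` or `"control"`; the class whose score is
#'   explained.
#' @param layer name of a residual stage (`"block1a"` ... `"block4b"`);
#'   default the last one, standard Grad-CAM practice.
#' @param mode `"layer"` (standard Grad-CAM) or `"input"` (saliency from
#'   the rectified channel-mean input gradient).
#' @return an object of class `saliency_map`: list with `heat` (`(H, W, D)`
#'   array in `[0, 1]`), `target_class`, `source_layer`, `degenerate`.
#' @export
grad_cam <- function(net, fingerprint, connectivity = NULL,
                     target_class = "ASD", layer = NULL,
                     mode = c("layer", "input")) {
  mode <- match.arg(mode)
  target_class <- normalize_labels(target_class)
  x3d <- if (inherits(fingerprint, "fingerprint_map"))
    fingerprint_to_input(fingerprint) else fingerprint
  grid <- dim(x3d)[2:4]
  xv <- if (inherits(connectivity, "connectivity_vector"))
    connectivity$values else connectivity
  resnet <- switch(class(net)[1],
    multimodal = net$resnet,
    resnet3d = net,
    ff_stop("validation", "Grad-CAM requires a multimodal or resnet3d network"))
  if (!is.null(layer) && !layer %in% names(resnet$blocks))
    ff_stop("validation", "unknown layer '%s'; valid layers: %s", layer,
            paste(names(resnet$blocks), collapse = ", "))
  if (is.null(layer)) layer <- tail(names(resnet$blocks), 1)

  logits <- switch(class(net)[1],
    multimodal = multimodal_forward(net, x3d, xv, training = FALSE),
    resnet3d = resnet_forward(net, x3d, training = FALSE))
  g <- matrix(0, 1, ncol(logits))
  g[1, match(target_class, .ff_label_levels)] <- 1

  if (mode == "input") {
    gx <- switch(class(net)[1],
      multimodal = multimodal_backward(net, g),
      resnet3d = resnet_backward(net, g, from = "logits"))
    gm <- matrix(gx, nrow = dim(gx)[1])
    cam <- array(colMeans(pmax(gm, 0)), grid)
  } else {
    gact <- switch(class(net)[1],
      multimodal = multimodal_backward(net, g, collect_at = layer),
      resnet3d = resnet_backward(net, g, from = "logits", collect_at = layer))
    act <- resnet$last_acts[[layer]]
    if (is.null(act))
      ff_stop("state", "no cached activation for layer '%s'", layer)
    C <- dim(act)[1]
    alpha <- rowMeans(matrix(gact, nrow = C))
    cam_vec <- pmax(colSums(alpha * matrix(act, nrow = C)), 0)
    cam <- trilinear_resize(array(cam_vec, dim(act)[2:4]), grid)
    cam <- pmax(cam, 0)  # interpolation cannot go negative, but be explicit
  }
  mx <- max(cam)
  degenerate <- mx <= 0
  if (!degenerate) cam <- cam / mx
  structure(list(heat = cam, target_class = target_class,
                 source_layer = if (mode == "layer") layer else "input",
                 degenerate = degenerate),
            class = "saliency_map")
}

#' Persist a saliency map as a 3D NIfTI volume
#' @param saliency a `saliency_map`.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_saliency <- function(saliency, path) {
  RNifti::writeNifti(RNifti::asNifti(saliency$heat, datatype = "double"), path)
  invisible(path)
}

# Map heat in [0,1] through a hot colormap (black-red-yellow-white).
.hot_colormap <- function(h) {
  r <- pmin(1, 3 * h)
  g <- pmin(1, pmax(0, 3 * h - 1))
  b <- pmin(1, pmax(0, 3 * h - 2))
  list(r = r, g = g, b = b)
}

blend_section <- function(bg, heat, opacity) {
  w <- opacity * heat
  cm <- .hot_colormap(heat)
  img <- array(0, c(nrow(bg), ncol(bg), 3))
  img[, , 1] <- bg * (1 - w) + cm$r * w
  img[, , 2] <- bg * (1 - w) + cm$g * w
  img[, , 3] <- bg * (1 - w) + cm$b * w
  img
}

#' Render saliency cross-sections over an anatomical background
#'
#' Writes axial, coronal, and sagittal mid-slice PNGs with the heat map
#' alpha-blended over the grayscale background. Zero heat leaves the
#' background untouched.
#'
#' @param saliency a `saliency_map`.
#' @param anatomical a [volume4d()] (averaged over time) or a 3D array on
#'   the same grid as the saliency map.
#' @param path_prefix output prefix; writes `<prefix>_axial.png`,
#'   `<prefix>_coronal.png`, `<prefix>_sagittal.png`.
#' @param opacity maximum heat opacity in `[0, 1]` (default 0.6).
#' @return character vector of the three file paths, invisibly.
#' @export
overlay_saliency <- function(saliency, anatomical, path_prefix, opacity = 0.6) {
  bg <- if (inherits(anatomical, "volume4d"))
    apply(anatomical$data, 1:3, mean) else anatomical
  if (!identical(dim(bg), dim(saliency$heat)))
    ff_stop("geometry", "anatomical grid (%s) does not match saliency grid (%s)",
            paste(dim(bg), collapse = "x"),
            paste(dim(saliency$heat), collapse = "x"))
  rng <- range(bg)
  bg <- if (diff(rng) > 0) (bg - rng[1]) / diff(rng) else bg * 0
  d <- dim(bg)
  mid <- ceiling(d / 2)
  sections <- list(
    axial = list(bg = bg[, , mid[3]], heat = saliency$heat[, , mid[3]]),
    coronal = list(bg = bg[, mid[2], ], heat = saliency$heat[, mid[2], ]),
    sagittal = list(bg = bg[mid[1], , ], heat = saliency$heat[mid[1], , ]))
  paths <- character(0)
  for (nm in names(sections)) {
    s <- sections[[nm]]
    img <- blend_section(as.matrix(s$bg), as.matrix(s$heat), opacity)
    p <- paste0(path_prefix, "_", nm, ".png")
    png::writePNG(img, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}
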