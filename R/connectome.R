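# Connectomic activation maps: region-mean time series, the voxel-by-region
# connectivity fingerprint, and the region-pair correlation vector.

#' Pearson product-moment correlation with a zero-variance convention
#'
#' Standard Pearson correlation between two equal-length series, except that
#' a series with zero variance (e.g. a constant background voxel) yields
#' exactly 0 rather than `NA`: a flat signal carries no co-activation and a
#' finite value keeps downstream networks well-defined.
#'
#' @param x,y numeric vectors of equal length `>= 2`.
#' @return a single correlation value in `[-1, 1]`.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    ff_stop("validation", "series lengths differ: %d vs %d", length(x), length(y))
  if (length(x) < 2L)
    ff_stop("validation", "correlation requires series of length >= 2, got %d",
            length(x))
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0) return(0)
  r <- suppressWarnings(cor(x, y))
  min(1, max(-1, r))
}

# Column-wise Pearson correlation between two T x * matrices with the
# zero-variance -> 0 convention and clamping to [-1, 1].
cor_zv <- function(xm, ym) {
  r <- suppressWarnings(cor(xm, ym))
  r[!is.finite(r)] <- 0
  r[r > 1] <- 1
  r[r < -1] <- -1
  r
}

#' Extract region-mean BOLD time series
#'
#' For each atlas region, averages the BOLD signal over all voxels in the
#' region at each time frame, producing the `N x T` region time-series
#' matrix. Rows follow ascending atlas label order.
#'
#' @param volume a [volume4d()].
#' @param atlas a [parcellation_atlas()] on the same voxel grid.
#' @return an object of class `roi_timeseries`: list with `series`
#'   (`N x T` matrix, rownames = region ids) and `region_ids`.
#' @export
extract_roi_timeseries <- function(volume, atlas) {
  check_same_grid(volume, atlas)
  d <- dim(volume$data)
  nt <- d[4]
  lab <- as.vector(atlas$labels)
  sel <- lab != 0L
  vm <- matrix(volume$data, ncol = nt)  # voxels x T, fixed column-major order
  counts <- table(factor(lab[sel], levels = atlas$region_ids))
  if (any(counts == 0))
    ff_stop("validation", "region(s) with zero voxels: %s",
            paste(atlas$region_ids[counts == 0], collapse = ", "))
  sums <- rowsum(vm[sel, , drop = FALSE], group = lab[sel])  # sorted by label
  series <- sums / as.numeric(counts)
  rownames(series) <- atlas$region_ids
  structure(list(series = series, region_ids = atlas$region_ids),
            class = "roi_timeseries")
}

#' Voxel-by-region connectivity fingerprint
#'
#' Correlates every voxel's BOLD series with every region-mean series,
#' producing the `(H, W, D, N)` fingerprint volume: the spatial activation
#' map fed to the 3D convolutional encoder. Zero-variance voxel or region
#' series give correlation 0.
#'
#' @param volume a [volume4d()].
#' @param roits an `roi_timeseries` whose frame count matches the volume.
#' @return an object of class `fingerprint_map`: list with `corr`
#'   (`(H, W, D, N)` array) and `region_ids`.
#' @export
compute_fingerprint <- function(volume, roits) {
  d <- dim(volume$data)
  nt <- d[4]
  if (ncol(roits$series) != nt)
    ff_stop("validation", "frame counts differ: volume has %d, series has %d",
            nt, ncol(roits$series))
  vm <- t(matrix(volume$data, ncol = nt))       # T x voxels
  rm_ <- t(roits$series)                        # T x N
  cc <- cor_zv(vm, rm_)                         # voxels x N
  fp <- array(cc, c(d[1:3], length(roits$region_ids)))
  structure(list(corr = fp, region_ids = roits$region_ids),
            class = "fingerprint_map")
}

#' Region-pair connectivity vector
#'
#' Pearson correlation between every pair of region-mean series, keeping the
#' upper triangle of the symmetric `N x N` matrix (diagonal removed) in
#' row-major pair order `(1,2), (1,3), ..., (1,N), (2,3), ...` over
#' ascending region labels. The result has `N(N-1)/2` elements (6670 for a
#' 116-region atlas).
#'
#' @param roits an `roi_timeseries` with `N >= 2` regions.
#' @return an object of class `connectivity_vector`: list with `values`
#'   (numeric vector of length `N(N-1)/2`), `region_ids`, and `pairs`
#'   (two-column integer matrix of region-id pairs, one row per element).
#' @export
compute_connectivity_vector <- function(roits) {
  n <- length(roits$region_ids)
  if (n < 2L)
    ff_stop("validation", "connectivity vector requires >= 2 regions, got %d", n)
  cm <- cor_zv(t(roits$series), t(roits$series))
  # row-major upper triangle: transpose, then column-major lower triangle
  tm <- t(cm)
  values <- tm[lower.tri(tm)]
  pi_ <- which(lower.tri(tm), arr.ind = TRUE)   # (j, i) of tm = (i, j) of cm
  pairs <- cbind(roits$region_ids[pi_[, 2]], roits$region_ids[pi_[, 1]])
  colnames(pairs) <- c("region_i", "region_j")
  structure(list(values = values, region_ids = roits$region_ids, pairs = pairs),
            class = "connectivity_vector")
}

#' Number of region-pair features
#'
#' @param n_regions region count `N`.
#' @return `N(N-1)/2`, the length of the connectivity vector.
#' @export
n_connectivity_features <- function(n_regions) {
  as.integer(n_regions * (n_regions - 1) / 2)
}

#' Persist a fingerprint map as a 4D NIfTI (region as 4th axis)
#' @param fp a `fingerprint_map`.
#' @param path output `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_fingerprint <- function(fp, path) {
  RNifti::writeNifti(RNifti::asNifti(fp$corr, datatype = "double"), path)
  invisible(path)
}

#' Read a fingerprint map written by [write_fingerprint()]
#' @param path `.nii.gz` path.
#' @param region_ids region ids for the 4th axis.
#' @return a `fingerprint_map`.
#' @export
read_fingerprint <- function(path, region_ids) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L || d[4] != length(region_ids))
    ff_stop("dimensionality", "fingerprint file %s does not match %d regions",
            path, length(region_ids))
  structure(list(corr = array(as.double(img), d), region_ids = region_ids),
            class = "fingerprint_map")
}

#' Persist a connectivity vector as CSV
#' @param cv a `connectivity_vector`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_connectivity_vector <- function(cv, path) {
  write.csv(data.frame(region_i = cv$pairs[, 1], region_j = cv$pairs[, 2],
                       value = cv$values), path, row.names = FALSE)
  invisible(path)
}

#' Read a connectivity vector written by [write_connectivity_vector()]
#' @param path CSV path.
#' @param region_ids expected region ordering.
#' @return a `connectivity_vector`.
#' @export
read_connectivity_vector <- function(path, region_ids) {
  df <- read.csv(path)
  structure(list(values = df$value, region_ids = as.integer(region_ids),
                 pairs = cbind(region_i = df$region_i, region_j = df$region_j)),
            class = "connectivity_vector")
}

# Reshape a fingerprint to channel-first network input (N, H, W, D).
fingerprint_to_input <- function(fp) aperm(fp$corr, c(4, 1, 2, 3))
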