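#' BOLD volume container
#'
#' A 4D blood-oxygen-level-dependent (BOLD) scan on a regular voxel grid.
#' Axis order is `(H, W, D, T)`: three spatial axes followed by time.
#'
#' @param data numeric 4D array `(H, W, D, T)`; all values must be finite
#'   and `T >= 2`.
#' @param voxel_dims optional numeric length-3 physical voxel spacing in mm.
#' @return an object of class `volume4d` with elements `data` and
#'   `voxel_dims`.
#' @export
volume4d <- function(data, voxel_dims = NULL) {
  d <- dim(data)
  if (length(d) != 4L)
    ff_stop("dimensionality", "volume4d requires a 4D array, got %d dimension(s)",
            length(d))
  if (d[4] < 2L)
    ff_stop("validation", "volume4d requires T >= 2 time frames, got %d", d[4])
  stopifnot_finite(data, "BOLD volume")
  structure(list(data = data, voxel_dims = voxel_dims), class = "volume4d")
}

#' @export
print.volume4d <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<volume4d> grid %dx%dx%d, %d frames\n", d[1], d[2], d[3], d[4]))
  invisible(x)
}

#' Parcellation atlas container
#'
#' An integer label volume assigning each voxel to a brain region; label 0 is
#' background. `region_ids` enumerates the distinct nonzero labels in
#' ascending order — every region-indexed structure in the package (region
#' time-series rows, fingerprint channels, connectivity-vector pairs)
#' follows this ordering.
#'
#' @param labels integer-valued 3D array `(H, W, D)`.
#' @return an object of class `parcellation_atlas` with elements `labels`
#'   and `region_ids`.
#' @export
parcellation_atlas <- function(labels) {
  d <- dim(labels)
  if (length(d) != 3L)
    ff_stop("dimensionality", "atlas requires a 3D label array, got %d dimension(s)",
            length(d))
  if (any(!is.finite(labels)) || any(labels != round(labels)) || any(labels < 0))
    ff_stop("validation", "atlas labels must be finite nonnegative integers")
  ids <- sort(unique(as.vector(labels)))
  ids <- ids[ids != 0]
  if (length(ids) < 2L)
    ff_stop("validation", "atlas must contain at least 2 nonzero region labels, found %d",
            length(ids))
  storage.mode(labels) <- "integer"
  structure(list(labels = labels, region_ids = as.integer(ids)),
            class = "parcellation_atlas")
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<parcellation_atlas> grid %dx%dx%d, %d regions\n",
              d[1], d[2], d[3], length(x$region_ids)))
  invisible(x)
}

#' Read a 4D BOLD volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file containing a 4D image.
#' @return a [volume4d()] with voxel spacing taken from the NIfTI header.
#' @export
read_volume4d <- function(path) {
  if (!file.exists(path)) ff_stop("io", "volume file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 4L)
    ff_stop("dimensionality",
            "expected a 4D NIfTI volume, %s has %d dimension(s)", path, length(d))
  pix <- attr(img, "pixdim")
  vd <- if (!is.null(pix) && length(pix) >= 3) abs(pix[1:3]) else NULL
  volume4d(array(as.double(img), d), voxel_dims = vd)
}

#' Write a 4D BOLD volume to a NIfTI file
#'
#' Values are stored as doubles so a write/read round trip is bit-exact.
#'
#' @param vol a [volume4d()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume4d <- function(vol, path) {
  arr <- vol$data
  if (!is.null(vol$voxel_dims))
    attr(arr, "pixdim") <- c(vol$voxel_dims, 1)
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
  invisible(path)
}

#' Read a parcellation atlas from a NIfTI file
#'
#' @param path path to a 3D integer-valued NIfTI label image.
#' @param expected_grid optional integer length-3 grid the atlas must match;
#'   a mismatch is a hard geometry error (no resampling is performed — the
#'   atlas and the functional volumes must share one voxel grid).
#' @return a [parcellation_atlas()].
#' @export
read_atlas <- function(path, expected_grid = NULL) {
  if (!file.exists(path)) ff_stop("io", "atlas file not found: %s", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    ff_stop("dimensionality", "expected a 3D NIfTI atlas, %s has %d dimension(s)",
            path, length(d))
  if (!is.null(expected_grid) && !identical(as.integer(d), as.integer(expected_grid)))
    ff_stop("geometry", "atlas grid (%s) does not match expected grid (%s)",
            paste(d, collapse = "x"), paste(expected_grid, collapse = "x"))
  parcellation_atlas(array(as.numeric(img), d))
}

#' Write a parcellation atlas to a NIfTI file
#'
#' @param atlas a [parcellation_atlas()].
#' @param path output `.nii` or `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_atlas <- function(atlas, path) {
  RNifti::writeNifti(RNifti::asNifti(atlas$labels, datatype = "int32"), path)
  invisible(path)
}

.ff_label_levels <- c("ASD", "control")

# Canonicalize a diagnosis label vector to {ASD, control} (case-insensitive).
normalize_labels <- function(x) {
  lx <- tolower(trimws(as.character(x)))
  out <- ifelse(lx == "asd", "ASD", ifelse(lx == "control", "control", NA))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    ff_stop("validation",
            "unknown diagnosis label(s): %s (accepted: ASD, control, case-insensitive)",
            paste(bad, collapse = ", "))
  }
  out
}

#' Read a subject manifest
#'
#' A manifest is a CSV with header columns `subject_id`, `volume_path`,
#' `label`. Labels are accepted case-insensitively as `ASD` or `control`;
#' subject ids must be unique. Row order is preserved.
#'
#' @param path CSV file path.
#' @return a data.frame with columns `subject_id`, `volume_path`, `label`
#'   (one row per subject; zero rows is valid).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) ff_stop("io", "manifest file not found: %s", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "volume_path", "label")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    ff_stop("validation", "manifest is missing column(s): %s",
            paste(missing_cols, collapse = ", "))
  df <- df[, need, drop = FALSE]
  df$subject_id <- as.character(df$subject_id)
  if (nrow(df) == 0) return(df)
  dup <- df$subject_id[duplicated(df$subject_id)]
  if (length(dup) > 0)
    ff_stop("validation", "duplicate subject_id(s) in manifest: %s",
            paste(unique(dup), collapse = ", "))
  df$label <- normalize_labels(df$label)
  df
}

#' Write a subject manifest
#'
#' @param manifest data.frame with columns `subject_id`, `volume_path`,
#'   `label`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest[, c("subject_id", "volume_path", "label")], path,
            row.names = FALSE)
  invisible(path)
}

# Check that a volume and an atlas live on the same spatial grid.
check_same_grid <- function(vol, atlas) {
  vg <- dim(vol$data)[1:3]
  ag <- dim(atlas$labels)
  if (!identical(as.integer(vg), as.integer(ag)))
    ff_stop("geometry", "volume grid (%s) does not match atlas grid (%s)",
            paste(vg, collapse = "x"), paste(ag, collapse = "x"))
  invisible(TRUE)
}
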