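#' MR intensity volume container
#'
#' A 3D array of nonnegative scanner intensities with voxel-size metadata.
#' Axis order is (z, y, x): `data[z, y, x]`, with z the slice (axial)
#' direction. Voxel centers sit at physical position `(index - 0.5) *
#' voxel_size` mm along each axis, so continuous positions are expressed in a
#' right-handed mm frame anchored at the volume corner.
#'
#' @param data 3D numeric array, dims (nz, ny, nx), all values finite, >= 0.
#' @param voxel_size mm triplet (dz, dy, dx); default 0.2 x 0.1 x 0.1 mm
#'   matching a FLASH acquisition with 0.1 x 0.1 mm in-plane resolution and
#'   0.2 mm slices.
#' @param session_time acquisition time in days (optional).
#' @return object of class `mr_volume`.
#' @export
mr_volume <- function(data, voxel_size = c(0.2, 0.1, 0.1),
                      session_time = NA_real_) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (any(!is.finite(data)) || any(data < 0))
    stop("volume intensities must be finite and nonnegative")
  stopifnot(length(voxel_size) == 3, all(voxel_size > 0))
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 session_time = session_time),
            class = "mr_volume")
}

#' @export
print.mr_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("MR volume %d x %d x %d voxels (z,y,x), voxel %g x %g x %g mm\n",
              d[1], d[2], d[3], x$voxel_size[1], x$voxel_size[2],
              x$voxel_size[3]))
  cat(sprintf("  intensity range [%.3g, %.3g]\n", min(x$data), max(x$data)))
  invisible(x)
}

#' Label volume container (fluorescence-defined regions)
#'
#' Volumetric region labels (0 = negative, 1 = positive) with an optional
#' co-registered fluorescence intensity channel, sharing the mm convention of
#' [mr_volume()].
#'
#' @param labels 3D integer array (z, y, x) of region labels.
#' @param voxel_size mm triplet (dz, dy, dx).
#' @param intensity optional 3D array of fluorescence intensities, same dims.
#' @return object of class `label_volume`.
#' @export
label_volume <- function(labels, voxel_size = c(0.2, 0.2, 0.2),
                         intensity = NULL) {
  stopifnot(is.array(labels), length(dim(labels)) == 3)
  if (!is.null(intensity)) stopifnot(all(dim(intensity) == dim(labels)))
  structure(list(labels = labels, voxel_size = as.numeric(voxel_size),
                 intensity = intensity),
            class = "label_volume")
}

# voxel index (1-based, continuous) <-> mm position, per-axis
vox_to_mm <- function(idx, voxel_size) (idx - 0.5) * voxel_size
mm_to_vox <- function(mm, voxel_size) mm / voxel_size + 0.5

# rows of a point matrix (n x 3, axis order z,y,x in mm) to voxel coords
points_mm_to_vox <- function(p, voxel_size) {
  sweep(p / matrix(voxel_size, nrow(p), 3, byrow = TRUE), 2, -0.5)
}

#' Point cloud container
#' @param points n x 3 numeric matrix of mm coordinates, axis order (z, y, x).
#' @param frame_label text tag naming the coordinate frame.
#' @return object of class `point_cloud`.
#' @export
point_cloud <- function(points, frame_label = "") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3, all(is.finite(points)))
  structure(list(points = points, frame_label = frame_label),
            class = "point_cloud")
}
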