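#' Read and write MR volumes as NIfTI
#'
#' NIfTI round trips preserve intensities bit-identically (double datatype)
#' and the voxel size through the pixdim header. Arrays are stored with
#' NIfTI's (x, y, z) axis order and converted back to the package's
#' (z, y, x) convention on read.
#'
#' @param volume an [mr_volume()].
#' @param path output file (`.nii` or `.nii.gz`).
#' @return `read_volume_nifti` returns an [mr_volume()].
#' @export
write_volume_nifti <- function(volume, path) {
  stopifnot(inherits(volume, "mr_volume"))
  arr <- aperm(volume$data, c(3, 2, 1))   # (x, y, z)
  attr(arr, "pixdim") <- volume$voxel_size[c(3, 2, 1)]
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_volume_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  vs <- RNifti::pixdim(img)[1:3]
  mr_volume(aperm(as.array(img), c(3, 2, 1)), voxel_size = vs[c(3, 2, 1)])
}

#' Read and write MR volumes as multi-page TIFF
#'
#' One page per axial slice, stored as 32-bit float samples scaled into
#' [0, 1] by a power of two; the scale and voxel size are written to a JSON
#' sidecar (`<path>.json`), so the round trip recovers intensities to float
#' precision and metadata exactly.
#'
#' @param volume an [mr_volume()].
#' @param path output `.tif` file.
#' @return `read_volume_tiff` returns an [mr_volume()].
#' @export
write_volume_tiff <- function(volume, path) {
  stopifnot(inherits(volume, "mr_volume"))
  mx <- max(volume$data)
  scale <- 2^ceiling(log2(max(mx, 1)))
  pages <- lapply(seq_len(dim(volume$data)[1]), function(z)
    volume$data[z, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  jsonlite::write_json(list(scale = scale, voxel_size = volume$voxel_size),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_volume_tiff
#' @export
read_volume_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  side <- paste0(path, ".json")
  if (!file.exists(side))
    stop(sprintf("missing metadata sidecar %s", side))
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  arr <- array(0, c(length(pages), dim(pages[[1]])))
  for (z in seq_along(pages)) arr[z, , ] <- pages[[z]] * meta$scale
  mr_volume(arr, voxel_size = meta$voxel_size)
}

#' Read and write point clouds as ASCII PLY
#'
#' Minimal PLY support: vertex elements with x/y/z float properties
#' (written in mm; the package's (z, y, x) columns map to PLY z, y, x).
#' Binary PLY and non-vertex elements are not supported.
#'
#' @param cloud a [point_cloud()].
#' @param path `.ply` file.
#' @return `read_ply` returns a [point_cloud()].
#' @export
write_ply <- function(cloud, path) {
  stopifnot(inherits(cloud, "point_cloud"))
  p <- cloud$points
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("comment frame %s", cloud$frame_label),
               sprintf("element vertex %d", nrow(p)),
               "property float x", "property float y", "property float z",
               "end_header"), con)
  writeLines(sprintf("%.9g %.9g %.9g", p[, 3], p[, 2], p[, 1]), con)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3 || lines[1] != "ply")
    stop(sprintf("%s: not a PLY file (line 1)", path))
  if (!grepl("^format ascii", lines[2]))
    stop(sprintf("%s: only ASCII PLY supported (line 2)", path))
  hdr_end <- which(lines == "end_header")[1]
  if (is.na(hdr_end)) stop(sprintf("%s: missing end_header", path))
  nv_line <- grep("^element vertex", lines[seq_len(hdr_end)], value = TRUE)
  if (length(nv_line) != 1)
    stop(sprintf("%s: expected exactly one vertex element", path))
  nv <- as.integer(sub("element vertex\\s+", "", nv_line))
  frame <- sub("^comment frame\\s*", "",
               grep("^comment frame", lines[seq_len(hdr_end)], value = TRUE)[1])
  if (is.na(frame)) frame <- ""
  body <- lines[(hdr_end + 1):(hdr_end + nv)]
  vals <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(body[i]), "\\s+")[[1]]))
    if (length(v) < 3 || any(is.na(v[1:3])))
      stop(sprintf("%s: cannot parse vertex at line %d", path, hdr_end + i))
    v[1:3]
  })
  m <- do.call(rbind, vals)
  point_cloud(m[, c(3, 2, 1), drop = FALSE], frame_label = frame)
}

#' Write and read detection tables as CSV
#'
#' Column dictionary: `id` detection index; `z_vox`/`y_vox`/`x_vox`
#' continuous 1-based voxel centroid; `z_mm`/`y_mm`/`x_mm` position in mm;
#' `roi_mean`/`background_mean` ROI intensities; `sbr` reciprocal-intensity
#' signal-to-background ratio; `dark_area_px` contiguous dark pixels in the
#' central slice; `is_aggregate` aggregation flag.
#'
#' @param detections detection data frame.
#' @param path `.csv` file.
#' @return `read_detections_csv` returns the data frame.
#' @export
write_detections_csv <- function(detections, path) {
  utils::write.csv(detections, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_detections_csv
#' @export
read_detections_csv <- function(path) {
  utils::read.csv(path)
}

#' Read a pipeline configuration from YAML
#'
#' Unknown top-level keys are rejected to catch typos; missing keys take
#' package defaults (see [default_pipeline_config()]).
#'
#' @param path YAML file.
#' @return a validated config list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_pipeline_config(cfg)
}

#' Write a (resolved) pipeline configuration as YAML
#' @param config config list.
#' @param path output file.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
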