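#' Assign registered sensor positions to fluorescence-defined regions
#'
#' Each point receives the majority label among label-volume voxels within
#' `sampling_radius` mm of its (registered) position, together with the mean
#' fluorescence intensity in that ball. Points outside the label volume are
#' flagged unassigned (`NA` label).
#'
#' @param points [point_cloud()] or n x 3 mm matrix in the label volume's
#'   frame.
#' @param labels a [label_volume()].
#' @param sampling_radius ball radius in mm (default 0.3, the particle
#'   scale).
#' @return data frame with `sensor_id`, registered position, `region_label`
#'   (0 negative / 1 positive, NA unassigned) and `local_fluorescence`.
#' @export
assign_regions <- function(points, labels, sampling_radius = 0.3) {
  stopifnot(inherits(labels, "label_volume"))
  p <- if (inherits(points, "point_cloud")) points$points else as.matrix(points)
  d <- dim(labels$labels)
  vs <- labels$voxel_size
  # ball offsets in voxel units
  half <- ceiling(sampling_radius / vs)
  offs <- expand.grid(dz = -half[1]:half[1], dy = -half[2]:half[2],
                      dx = -half[3]:half[3])
  keep <- (offs$dz * vs[1])^2 + (offs$dy * vs[2])^2 + (offs$dx * vs[3])^2 <=
    sampling_radius^2
  offs <- offs[keep, , drop = FALSE]
  res <- lapply(seq_len(nrow(p)), function(i) {
    cv <- round(mm_to_vox(p[i, ], vs))
    vz <- cv[1] + offs$dz; vy <- cv[2] + offs$dy; vx <- cv[3] + offs$dx
    ok <- vz >= 1 & vz <= d[1] & vy >= 1 & vy <= d[2] & vx >= 1 & vx <= d[3]
    if (!any(ok) || cv[1] < 1 || cv[1] > d[1] || cv[2] < 1 || cv[2] > d[2] ||
        cv[3] < 1 || cv[3] > d[3])
      return(data.frame(region_label = NA_integer_,
                        local_fluorescence = NA_real_))
    ix <- cbind(vz[ok], vy[ok], vx[ok])
    lab_vals <- labels$labels[ix]
    n1 <- sum(lab_vals == 1); n0 <- sum(lab_vals == 0)
    lab <- if (n1 > n0) 1L else if (n0 > n1) 0L else
      labels$labels[cv[1], cv[2], cv[3]]  # tie: label at the nearest voxel
    fl <- if (!is.null(labels$intensity)) mean(labels$intensity[ix])
      else mean(lab_vals)
    data.frame(region_label = lab, local_fluorescence = fl)
  })
  res <- do.call(rbind, res)
  data.frame(sensor_id = seq_len(nrow(p)),
             z_mm = p[, 1], y_mm = p[, 2], x_mm = p[, 3], res)
}

#' Region-wise stress summary statistics
#'
#' Descriptive statistics of sensor stress by region label, and the mean
#' difference (negative-region mean minus positive-region mean).
#'
#' @param assignments data frame from [assign_regions()] (column
#'   `region_label`).
#' @param stresses kPa per sensor, aligned with `assignments` rows.
#' @return list with `table` (per-group n, mean, sd) and `mean_difference`.
#' @export
region_stats <- function(assignments, stresses) {
  stopifnot(nrow(assignments) == length(stresses))
  lab <- assignments$region_label
  grp <- function(l) {
    s <- stresses[!is.na(lab) & lab == l]
    data.frame(region = if (l == 1) "vimentin_positive" else
                 "vimentin_negative",
               n = length(s),
               mean_kPa = if (length(s)) mean(s) else NA_real_,
               sd_kPa = if (length(s) > 1) stats::sd(s) else NA_real_)
  }
  tab <- rbind(grp(0L), grp(1L))
  diff <- tab$mean_kPa[tab$region == "vimentin_negative"] -
    tab$mean_kPa[tab$region == "vimentin_positive"]
  list(table = tab, mean_difference = diff,
       n_unassigned = sum(is.na(lab)))
}
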