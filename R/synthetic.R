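#' @title Synthetic scene generation
#' @description Generators emulating the study's inputs with known ground
#'   truth: calibration phantoms (sparse dark spots in a gel block), tumor
#'   time series with growing particle constellations and prescribed stress
#'   trajectories, and paired-modality registration scenes. All generators
#'   are pure functions of their configuration and seed.
#' @name synthetic
NULL

# --- particle placement --------------------------------------------------

# dart-throwing placement with a minimum pairwise separation; mm coordinates
place_particles <- function(n, box_lo, box_hi, min_sep, max_tries = 2000L) {
  if (n == 0) return(matrix(numeric(0), 0, 3))
  if (any(box_hi - box_lo <= 0))
    stop(sprintf(
      "volume too small for the placement margins (free box %.2f x %.2f x %.2f mm)",
      box_hi[1] - box_lo[1], box_hi[2] - box_lo[2], box_hi[3] - box_lo[3]))
  pos <- matrix(NA_real_, n, 3)
  placed <- 0L
  for (tries in seq_len(max_tries * n)) {
    cand <- stats::runif(3, box_lo, box_hi)
    ok <- placed == 0L ||
      min(sqrt(rowSums((pos[seq_len(placed), , drop = FALSE] -
                          matrix(cand, placed, 3, byrow = TRUE))^2))) >= min_sep
    if (ok) {
      placed <- placed + 1L
      pos[placed, ] <- cand
      if (placed == n) return(pos)
    }
  }
  stop(sprintf(
    "cannot place %d particles with %.2f mm minimum separation in a %.1f x %.1f x %.1f mm volume",
    n, min_sep, box_hi[1] - box_lo[1], box_hi[2] - box_lo[2],
    box_hi[3] - box_lo[3]))
}

# --- rendering -----------------------------------------------------------

# ROI voxel set used by compute_sbr for a continuous voxel-space centroid:
# 3x3 in-plane window on the two axial slices bracketing the centroid
roi_voxel_offsets <- function(centroid_vox) {
  z <- centroid_vox[1]; y <- centroid_vox[2]; x <- centroid_vox[3]
  zl <- floor(z); if (zl == z) zl <- z  # integer z: slices z and z+1
  zh <- zl + 1
  list(z = c(zl, zh), y = round(y) + (-1:1), x = round(x) + (-1:1))
}

# mean Gaussian-dip weight over the measurement ROI for a spot at `pos_mm`
roi_attenuation <- function(pos_mm, voxel_size, psf_sigma_mm) {
  cv <- mm_to_vox(pos_mm, voxel_size)
  off <- roi_voxel_offsets(cv)
  g <- expand.grid(z = off$z, y = off$y, x = off$x)
  d2 <- (vox_to_mm(g$z, voxel_size[1]) - pos_mm[1])^2 +
    (vox_to_mm(g$y, voxel_size[2]) - pos_mm[2])^2 +
    (vox_to_mm(g$x, voxel_size[3]) - pos_mm[3])^2
  mean(exp(-d2 / (2 * psf_sigma_mm^2)))
}

# Add one Gaussian dark spot to a clean volume array (in place semantics via
# return). `depth` is the center (peak) dip amplitude.
add_spot <- function(arr, voxel_size, pos_mm, depth, psf_sigma_mm) {
  d <- dim(arr)
  half <- ceiling(4 * psf_sigma_mm / voxel_size)
  cv <- mm_to_vox(pos_mm, voxel_size)
  zr <- max(1, floor(cv[1] - half[1])):min(d[1], ceiling(cv[1] + half[1]))
  yr <- max(1, floor(cv[2] - half[2])):min(d[2], ceiling(cv[2] + half[2]))
  xr <- max(1, floor(cv[3] - half[3])):min(d[3], ceiling(cv[3] + half[3]))
  gz <- vox_to_mm(zr, voxel_size[1]) - pos_mm[1]
  gy <- vox_to_mm(yr, voxel_size[2]) - pos_mm[2]
  gx <- vox_to_mm(xr, voxel_size[3]) - pos_mm[3]
  s2 <- 2 * psf_sigma_mm^2
  dip <- depth * outer(outer(exp(-gz^2 / s2), exp(-gy^2 / s2)),
                       exp(-gx^2 / s2))
  arr[zr, yr, xr] <- arr[zr, yr, xr] - dip
  arr
}

# Render a clean (noiseless) volume for one session of a scene. The peak dip
# of each spot is chosen so that the SBR measured by compute_sbr on the
# noiseless volume equals sbr0 * signal(S)/signal(0) exactly, where sbr0 is
# the nominal zero-stress SBR implied by the noise spec's spot_depth.
render_clean <- function(scene, session) {
  noise <- scene$noise
  B <- noise$background_mean
  arr <- array(B, scene$volume_shape)
  pos <- scene$positions[[session]]
  n <- nrow(pos)
  if (n == 0) return(arr)
  sbr0 <- noise$spot_depth / (B - noise$spot_depth)
  s0 <- forward_signal(scene$model, 0)
  for (i in seq_len(n)) {
    S <- scene$stresses[i, session]
    q <- sbr0 * forward_signal(scene$model, S, extrapolation_warning = FALSE) / s0
    C_target <- B * q / (1 + q)  # ROI-level contrast giving SBR == q
    if (scene$particles$is_aggregate[i]) {
      # a clump of sensors: two deep merged spots at sub-resolution
      # separation whose combined dip clips to near-black, inflating both
      # the SBR and the contiguous dark area past single-particle bounds
      offd <- scene$agg_offsets[i, ]
      for (sgn in c(-0.5, 0.5)) {
        p <- pos[i, ] + sgn * offd
        alpha <- roi_attenuation(p, scene$voxel_size, noise$psf_sigma_mm)
        arr <- add_spot(arr, scene$voxel_size, p,
                        8 * C_target / alpha, noise$psf_sigma_mm)
      }
    } else {
      alpha <- roi_attenuation(pos[i, ], scene$voxel_size, noise$psf_sigma_mm)
      arr <- add_spot(arr, scene$voxel_size, pos[i, ], C_target / alpha,
                      noise$psf_sigma_mm)
    }
  }
  arr[arr < 0] <- 0
  arr
}

#' Render one session of a scene as an MR volume
#'
#' @param scene an `mr_scene` from one of the generators.
#' @param session session index.
#' @param add_noise apply the scene's noise law.
#' @param noise_seed seed for the noise realization; defaults to a seed
#'   derived from the scene seed and session, so repeated calls are
#'   reproducible while distinct sessions get independent noise.
#' @return an [mr_volume()].
#' @export
render_scene_volume <- function(scene, session = 1L, add_noise = TRUE,
                                noise_seed = NULL) {
  stopifnot(inherits(scene, "mr_scene"))
  arr <- render_clean(scene, session)
  if (add_noise) {
    if (is.null(noise_seed))
      noise_seed <- derive_seed(scene$seed, paste0("noise", session))
    arr <- with_seed(noise_seed, apply_noise(arr, scene$noise))
  }
  mr_volume(arr, scene$voxel_size,
            session_time = scene$session_times[session])
}

new_scene <- function(particles, positions, stresses, session_times,
                      volume_shape, voxel_size, noise, model, seed,
                      agg_offsets = NULL, extra = list()) {
  if (is.null(agg_offsets))
    agg_offsets <- matrix(0, nrow(particles), 3)
  sc <- c(list(particles = particles, positions = positions,
               stresses = stresses, session_times = session_times,
               volume_shape = volume_shape, voxel_size = voxel_size,
               noise = noise, model = model, seed = seed,
               agg_offsets = agg_offsets), extra)
  class(sc) <- "mr_scene"
  sc
}

#' @export
print.mr_scene <- function(x, ...) {
  cat(sprintf("Synthetic scene: %d particles, %d session(s), seed %d\n",
              nrow(x$particles), length(x$session_times), x$seed))
  invisible(x)
}

# --- calibration phantom -------------------------------------------------

#' Generate a calibration-phantom MR volume with known ground truth
#'
#' Emulates a cylindrical gel block with sparsely dispersed sensors imaged at
#' known applied stresses: each sensor renders as a smooth Gaussian dark spot
#' whose measured SBR follows the stress-signal law, with scanner noise
#' applied last. Particles are placed with a minimum pairwise separation of
#' three spot widths.
#'
#' @param n_particles number of sensors.
#' @param stresses applied stress in kPa: scalar (broadcast) or one per
#'   particle; must lie within the calibration validity range.
#' @param noise a [noise_spec()].
#' @param volume_shape voxel dims (nz, ny, nx).
#' @param voxel_size mm triplet (dz, dy, dx).
#' @param seed integer seed; same seed gives a bit-identical volume.
#' @param aggregate_fraction fraction of particles rendered as aggregated
#'   (merged) clusters.
#' @param model the [calibration_model()] driving spot contrast.
#' @return list with elements `volume` ([mr_volume()]) and `scene`
#'   (`mr_scene` ground truth: exact positions, stresses, aggregate flags).
#' @export
generate_calibration_phantom <- function(n_particles, stresses = 0,
                                         noise = noise_spec(),
                                         volume_shape = c(24L, 96L, 96L),
                                         voxel_size = c(0.2, 0.1, 0.1),
                                         seed = 1L,
                                         aggregate_fraction = 0,
                                         model = calibration_model()) {
  stopifnot(n_particles >= 0)
  if (length(stresses) == 1) stresses <- rep(stresses, n_particles)
  if (n_particles > 0 && length(stresses) != n_particles)
    stop("stresses must have length 1 or n_particles")
  if (any(stresses < model$stress_range[1] - 1e-9) ||
      any(stresses > model$stress_range[2] + 1e-9))
    stop("ground-truth stresses must lie within the calibration range")
  ext <- volume_shape * voxel_size        # physical extent (z, y, x) mm
  margin <- c(3 * voxel_size[1], 0.8, 0.8)
  min_sep <- 3 * noise$psf_fwhm_mm
  scene <- with_seed(seed, {
    pos <- place_particles(n_particles, margin, ext - margin, min_sep)
    n_agg <- round(aggregate_fraction * n_particles)
    is_agg <- rep(FALSE, n_particles)
    if (n_agg > 0) is_agg[sample.int(n_particles, n_agg)] <- TRUE
    ang <- stats::runif(n_particles, 0, 2 * pi)
    agg_off <- cbind(0, 0.25 * sin(ang), 0.25 * cos(ang))
    new_scene(
      particles = data.frame(id = seq_len(max(n_particles, 0)),
                             is_aggregate = is_agg),
      positions = list(pos),
      stresses = matrix(stresses, ncol = 1),
      session_times = 0,
      volume_shape = volume_shape, voxel_size = voxel_size,
      noise = noise, model = model, seed = as.integer(seed),
      agg_offsets = agg_off)
  })
  list(volume = render_scene_volume(scene, 1L), scene = scene)
}

# --- loading profiles ----------------------------------------------------

#' Compression loading profiles
#'
#' Time-stress schedules for the spheroid compression regimens. The default
#' `gradual` profile steps the stress up every 6 hours to a 5 kPa peak at
#' 48 h; the default `acute` profile holds a 0.5 kPa baseline for 48 h and
#' then ramps rapidly (1 h) to the same 5 kPa peak, so both deliver an
#' identical peak but very different loading rates.
#'
#' @param kind `"gradual"`, `"acute"`, `"constant"` or `"custom"`.
#' @param schedule for `"custom"`: data frame with strictly increasing
#'   `time_h` and `stress_kPa` columns.
#' @param peak peak stress, kPa.
#' @param baseline acute-profile baseline stress, kPa.
#' @param duration_h time of peak, hours.
#' @param step_h gradual-profile step interval, hours.
#' @param ramp_h acute-profile ramp duration, hours.
#' @param level constant-profile stress, kPa.
#' @return object of class `loading_profile`.
#' @export
loading_profile <- function(kind = c("gradual", "acute", "constant", "custom"),
                            schedule = NULL, peak = 5, baseline = 0.5,
                            duration_h = 48, step_h = 6, ramp_h = 1,
                            level = 1) {
  kind <- match.arg(kind)
  if (kind == "gradual") {
    t <- seq(0, duration_h, by = step_h)
    schedule <- data.frame(time_h = t,
                           stress_kPa = peak * t / duration_h)
  } else if (kind == "acute") {
    schedule <- data.frame(time_h = c(0, duration_h, duration_h + ramp_h),
                           stress_kPa = c(baseline, baseline, peak))
  } else if (kind == "constant") {
    schedule <- data.frame(time_h = c(0, duration_h),
                           stress_kPa = c(level, level))
  } else {
    stopifnot(is.data.frame(schedule),
              all(c("time_h", "stress_kPa") %in% names(schedule)))
  }
  if (any(diff(schedule$time_h) <= 0))
    stop("schedule times must be strictly increasing")
  structure(list(kind = kind, schedule = schedule),
            class = "loading_profile")
}

#' Evaluate a loading profile
#' @param profile a [loading_profile()].
#' @param time_h times in hours (within the schedule range).
#' @return stress in kPa (linear interpolation between schedule points).
#' @export
profile_stress_at <- function(profile, time_h) {
  stopifnot(inherits(profile, "loading_profile"))
  s <- profile$schedule
  if (any(time_h < min(s$time_h) - 1e-9) || any(time_h > max(s$time_h) + 1e-9))
    stop(sprintf("time outside the schedule range [%g, %g] h",
                 min(s$time_h), max(s$time_h)))
  stats::approx(s$time_h, s$stress_kPa, xout = time_h, rule = 2)$y
}

#' Maximum interval loading rate of a profile
#' @param profile a [loading_profile()].
#' @return maximum schedule-interval rate in kPa/day.
#' @export
profile_max_rate <- function(profile) {
  s <- profile$schedule
  max(diff(s$stress_kPa) / diff(s$time_h)) * 24
}

# --- tumor time series ---------------------------------------------------

# resolve the many accepted trajectory forms into an n x k stress matrix
resolve_trajectories <- function(trajectories, n, times_days) {
  k <- length(times_days)
  if (inherits(trajectories, "loading_profile")) {
    s <- profile_stress_at(trajectories, times_days * 24)
    return(matrix(rep(s, each = n), n, k))
  }
  if (is.list(trajectories) && all(vapply(trajectories, inherits,
                                          logical(1), "loading_profile"))) {
    stopifnot(length(trajectories) == n)
    return(t(vapply(trajectories,
                    function(p) profile_stress_at(p, times_days * 24),
                    numeric(k))))
  }
  if (is.matrix(trajectories)) {
    stopifnot(nrow(trajectories) == n, ncol(trajectories) == k)
    return(trajectories)
  }
  if (is.numeric(trajectories)) {
    if (length(trajectories) == 1) trajectories <- rep(trajectories, n)
    stopifnot(length(trajectories) == n)
    return(matrix(trajectories, n, k))
  }
  stop("unsupported trajectory specification")
}

#' Generate a longitudinal tumor scene with growing particle constellation
#'
#' Emulates a xenograft imaged over several sessions: a fixed set of sensors
#' whose constellation expands about the tumor centroid as the tumor grows,
#' with per-session ground-truth stresses following the requested
#' trajectories, optional rendering of a fraction of particles as aggregated
#' clusters, and small random per-session motion.
#'
#' @param n_particles number of sensors (constant across sessions).
#' @param sessions imaging times in days, ascending.
#' @param trajectories a [loading_profile()] (schedule times in hours,
#'   evaluated at `sessions * 24`), a list of per-particle profiles, an
#'   `n x length(sessions)` stress matrix, or a numeric constant/vector.
#' @param growth_rate fractional constellation expansion per day about the
#'   centroid.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param aggregate_fraction fraction rendered as aggregates.
#' @param motion_sd per-session random-walk motion s.d., mm.
#' @param volume_shape,voxel_size volume geometry as in
#'   [generate_calibration_phantom()].
#' @param model the [calibration_model()].
#' @return list with `volumes` (list of [mr_volume()], one per session) and
#'   `scene` (ground truth for all sessions).
#' @export
generate_tumor_timeseries <- function(n_particles, sessions,
                                      trajectories = 0,
                                      growth_rate = 0.05,
                                      noise = noise_spec(), seed = 1L,
                                      aggregate_fraction = 0,
                                      motion_sd = 0.03,
                                      volume_shape = c(32L, 96L, 96L),
                                      voxel_size = c(0.2, 0.1, 0.1),
                                      model = calibration_model()) {
  stopifnot(n_particles > 0, length(sessions) >= 1,
            !is.unsorted(sessions, strictly = TRUE))
  k <- length(sessions)
  stresses <- resolve_trajectories(trajectories, n_particles, sessions)
  if (any(stresses < model$stress_range[1] - 1e-9) ||
      any(stresses > model$stress_range[2] + 1e-9))
    stop("trajectory stresses must lie within the calibration range")
  ext <- volume_shape * voxel_size
  margin <- c(3 * voxel_size[1], 0.8, 0.8)
  # leave headroom for growth: shrink the initial placement box
  total_growth <- (1 + growth_rate)^(max(sessions) - min(sessions))
  ctr <- ext / 2
  scene <- with_seed(seed, {
    lo <- ctr - (ctr - margin) / total_growth
    hi <- ctr + (ext - margin - ctr) / total_growth
    pos0 <- place_particles(n_particles, lo, hi, 3 * noise$psf_fwhm_mm)
    positions <- vector("list", k)
    drift <- matrix(0, n_particles, 3)
    for (j in seq_len(k)) {
      g <- (1 + growth_rate)^(sessions[j] - sessions[1])
      if (j > 1 && motion_sd > 0)
        drift <- drift + matrix(stats::rnorm(3 * n_particles, 0, motion_sd),
                                n_particles, 3)
      positions[[j]] <- sweep(sweep(pos0, 2, ctr) * g, 2, ctr, "+") + drift
    }
    n_agg <- round(aggregate_fraction * n_particles)
    is_agg <- rep(FALSE, n_particles)
    if (n_agg > 0) is_agg[sample.int(n_particles, n_agg)] <- TRUE
    ang <- stats::runif(n_particles, 0, 2 * pi)
    new_scene(
      particles = data.frame(id = seq_len(n_particles),
                             is_aggregate = is_agg),
      positions = positions, stresses = stresses,
      session_times = sessions,
      volume_shape = volume_shape, voxel_size = voxel_size,
      noise = noise, model = model, seed = as.integer(seed),
      agg_offsets = cbind(0, 0.25 * sin(ang), 0.25 * cos(ang)))
  })
  volumes <- lapply(seq_len(k), function(j) render_scene_volume(scene, j))
  list(volumes = volumes, scene = scene)
}

# --- smooth random label fields ------------------------------------------

# separable Gaussian smoothing of a 3D array (replicated edges)
gauss_smooth_3d <- function(arr, sigma_vox) {
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    kern <- exp(-((-half):half)^2 / (2 * s^2))
    kern <- kern / sum(kern)
    arr <- conv_axis(arr, kern, ax)
  }
  arr
}

conv_axis <- function(arr, kern, axis) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  m <- matrix(a, nrow = d[axis])
  half <- (length(kern) - 1L) / 2L
  n <- nrow(m)
  out <- matrix(0, n, ncol(m))
  for (i in seq_along(kern)) {
    shift <- i - 1L - half
    idx <- pmin(pmax(seq_len(n) + shift, 1L), n)  # replicate edges
    out <- out + kern[i] * m[idx, , drop = FALSE]
  }
  a <- array(out, d[perm])
  aperm(a, order(perm))
}

# --- registration scenes -------------------------------------------------

# smooth bumpy ellipsoid radius: direction-dependent radius function making
# the surface asymmetric enough for rotation to be identifiable
bumpy_radius <- function(dirs, radius, bump_dirs, bump_amp = 0.15,
                         bump_width = 0.6) {
  f <- rep(1, nrow(dirs))
  for (j in seq_len(nrow(bump_dirs))) {
    ang2 <- rowSums(sweep(dirs, 2, bump_dirs[j, ], "-")^2)
    f <- f + bump_amp * (2 * (j %% 2) - 1) * exp(-ang2 / (2 * bump_width^2))
  }
  radius * f
}

inside_tumor <- function(p, center, radius, axes, bump_dirs) {
  q <- sweep(sweep(p, 2, center), 2, axes, "/")
  r <- sqrt(rowSums(q^2))
  dirs <- q / pmax(r, 1e-12)
  r <= bumpy_radius(dirs, radius, bump_dirs)
}

#' Generate a paired-modality registration scene
#'
#' Builds an MR-frame tumor surface cloud and its CFM-frame counterpart
#' related by a known rigid + smooth non-rigid warp, a patchy
#' fluorescence-positive label volume in the CFM frame, and sensor positions
#' carried in both frames. The tumor is an asymmetric (bumpy ellipsoid)
#' surface so that rotations are identifiable by shape alone.
#'
#' @param n_surface_points surface points per cloud.
#' @param n_sensors sensors inside the tumor.
#' @param warp a [warp_spec()]; the realized warp (fixed kernel draw) is
#'   returned as ground truth.
#' @param vimentin_fraction target fraction of tumor volume labelled
#'   positive, in [0, 1).
#' @param seed integer seed.
#' @param jitter_sd target-cloud point jitter s.d., mm.
#' @param center tumor center, mm (z, y, x).
#' @param radius nominal tumor radius, mm.
#' @param label_shape,label_voxel CFM label-volume geometry.
#' @return list with `source`/`target` ([point_cloud()]s), `labels`
#'   ([label_volume()]), `warp_field` (realized ground-truth warp),
#'   `sensors_mr`/`sensors_cfm` (n x 3 mm), and `sensor_labels`
#'   (ground-truth region of each sensor).
#' @export
generate_registration_scene <- function(n_surface_points = 500L,
                                        n_sensors = 40L,
                                        warp = warp_spec(),
                                        vimentin_fraction = 0.4,
                                        seed = 1L, jitter_sd = 0.02,
                                        center = c(4.8, 4.8, 4.8),
                                        radius = 3.5,
                                        label_shape = c(48L, 48L, 48L),
                                        label_voxel = 0.2) {
  if (vimentin_fraction < 0 || vimentin_fraction >= 1)
    stop("vimentin_fraction must be in [0, 1)")
  axes <- c(1, 0.85, 0.7)
  field <- realize_warp(warp, center, radius, derive_seed(seed, "warp"))
  out <- with_seed(seed, {
    bump_dirs <- matrix(stats::rnorm(6 * 3), 6, 3)
    bump_dirs <- bump_dirs / sqrt(rowSums(bump_dirs^2))
    # surface: uniform directions, bumpy-ellipsoid radius
    u <- matrix(stats::rnorm(3 * n_surface_points), n_surface_points, 3)
    u <- u / sqrt(rowSums(u^2))
    r <- bumpy_radius(u, radius, bump_dirs)
    src <- sweep(u * r, 2, axes, "*")
    src <- sweep(src, 2, center, "+")
    # sensors: min-separation placement inside 0.8 x the surface
    sens <- matrix(NA_real_, n_sensors, 3)
    placed <- 0L
    for (tries in seq_len(40000L)) {
      cand <- center + stats::runif(3, -radius, radius) * axes
      if (!inside_tumor(matrix(cand, 1, 3), center, radius * 0.8, axes,
                        bump_dirs)) next
      ok <- placed == 0L ||
        min(sqrt(rowSums((sens[seq_len(placed), , drop = FALSE] -
                            matrix(cand, placed, 3, byrow = TRUE))^2))) >= 0.9
      if (ok) {
        placed <- placed + 1L
        sens[placed, ] <- cand
        if (placed == n_sensors) break
      }
    }
    if (placed < n_sensors)
      stop(sprintf("cannot place %d sensors in the tumor interior", n_sensors))
    list(src = src, sens = sens, bump_dirs = bump_dirs)
  })
  target <- apply_warp(field, out$src)
  if (jitter_sd > 0)
    target <- target + with_seed(derive_seed(seed, "jitter"),
                                 matrix(stats::rnorm(length(target), 0,
                                                     jitter_sd),
                                        nrow(target), 3))
  sensors_cfm <- apply_warp(field, out$sens)
  # patchy label field in the CFM frame
  lab <- with_seed(derive_seed(seed, "labels"), {
    w <- array(stats::rnorm(prod(label_shape)), label_shape)
    sm <- gauss_smooth_3d(w, rep(0.8 / label_voxel, 3))
    if (vimentin_fraction == 0) {
      labels <- array(0L, label_shape)
    } else {
      thr <- stats::quantile(sm, 1 - vimentin_fraction)
      labels <- array(as.integer(sm >= thr), label_shape)
    }
    inten <- (sm - min(sm)) / (max(sm) - min(sm))
    label_volume(labels, rep(label_voxel, 3), intensity = inten)
  })
  # ground-truth region membership of an extended (300 um) particle: the
  # majority label in a particle-sized ball around its true CFM position,
  # the same rule the assignment stage applies to registered positions
  sensor_labels <- assign_regions(sensors_cfm, lab,
                                  sampling_radius = 0.3)$region_label
  list(source = point_cloud(out$src, "MR"),
       target = point_cloud(target, "CFM"),
       labels = lab, warp_field = field,
       sensors_mr = out$sens, sensors_cfm = sensors_cfm,
       sensor_labels = sensor_labels)
}

# nearest-voxel label lookup (NA outside the volume)
sample_labels_at <- function(lab, points_mm) {
  stopifnot(inherits(lab, "label_volume"))
  d <- dim(lab$labels)
  idx <- round(sweep(points_mm, 2, lab$voxel_size, "/") + 0.5)
  out <- rep(NA_integer_, nrow(points_mm))
  ok <- idx[, 1] >= 1 & idx[, 1] <= d[1] & idx[, 2] >= 1 & idx[, 2] <= d[2] &
    idx[, 3] >= 1 & idx[, 3] <= d[3]
  out[ok] <- lab$labels[cbind(idx[ok, 1], idx[ok, 2], idx[ok, 3])]
  out
}

#' Generate the two-region stress study scene
#'
#' Full synthetic counterpart of the region-wise stress comparison: a tumor
#' with a patchy fluorescence-positive label volume in the CFM frame, sensors
#' whose ground-truth stresses are drawn from per-region normal
#' distributions (censored at zero and at the calibration ceiling), an MR
#' volume rendered in the MR frame, and the surface clouds linking the two
#' frames. Default generating distributions are 3.5 +- 2.8 kPa in
#' fluorescence-positive regions and 7.4 +- 2.8 kPa in negative regions.
#'
#' @param n_sensors total sensors.
#' @param stress_positive,stress_negative c(mean, sd) in kPa of the
#'   generating distribution per region.
#' @param min_per_region minimum sensors per region (positions are redrawn
#'   deterministically until satisfied).
#' @param vimentin_fraction target positive-label volume fraction.
#' @param warp a [warp_spec()] for the MR-to-CFM deformation.
#' @param noise a [noise_spec()].
#' @param seed integer seed.
#' @param model the [calibration_model()] driving spot contrast.
#' @return the [generate_registration_scene()] list, extended with
#'   `scene` (the renderable `mr_scene`), `volume` (the noisy
#'   [mr_volume()]), and `true_stress`.
#' @export
generate_region_study <- function(n_sensors = 50L,
                                  stress_positive = c(3.5, 2.8),
                                  stress_negative = c(7.4, 2.8),
                                  min_per_region = 20L,
                                  vimentin_fraction = 0.5,
                                  warp = warp_spec(
                                    rotation = c(0.1, -0.06, 0.08),
                                    translation = c(0.3, -0.4, 0.5),
                                    scale = 1.03,
                                    nonrigid_amplitude = 0.4,
                                    nonrigid_length_scale = 4),
                                  noise = noise_spec(), seed = 1L,
                                  model = calibration_model()) {
  reg <- NULL
  for (attempt in 0:49) {
    reg <- generate_registration_scene(
      n_surface_points = 500L, n_sensors = n_sensors, warp = warp,
      vimentin_fraction = vimentin_fraction,
      seed = derive_seed(seed, paste0("regionstudy", attempt)))
    counts <- table(factor(reg$sensor_labels, levels = c(0, 1)))
    if (all(counts >= min_per_region)) break
    reg <- NULL
  }
  if (is.null(reg))
    stop("could not realize a scene with the requested per-region counts")
  S <- with_seed(derive_seed(seed, "stressdraw"), {
    mu <- ifelse(reg$sensor_labels == 1, stress_positive[1],
                 stress_negative[1])
    sd <- ifelse(reg$sensor_labels == 1, stress_positive[2],
                 stress_negative[2])
    pmin(pmax(stats::rnorm(n_sensors, mu, sd), 0),
         model$stress_range[2] - 0.05)
  })
  scene <- new_scene(
    particles = data.frame(id = seq_len(n_sensors),
                           is_aggregate = rep(FALSE, n_sensors)),
    positions = list(reg$sensors_mr),
    stresses = matrix(S, ncol = 1), session_times = 0,
    volume_shape = c(48L, 96L, 96L), voxel_size = c(0.2, 0.1, 0.1),
    noise = noise, model = model, seed = as.integer(seed))
  volume <- render_scene_volume(scene, 1L)
  c(reg, list(scene = scene, volume = volume, true_stress = S))
}

# --- CFM observation arm -------------------------------------------------

#' Simulate confocal (CFM) strain observations of a scene's sensors
#'
#' The optical readout arm: each sensor's axial strain follows the particle
#' strain-stress model at its ground-truth stress, with multiplicative
#' optical measurement noise.
#'
#' @param scene an `mr_scene`.
#' @param material a [particle_strain_model()].
#' @param optical_noise multiplicative noise s.d. (fraction; default 0.03).
#' @param seed integer seed.
#' @return data frame with `id`, `session`, `axial_strain`.
#' @export
generate_cfm_observations <- function(scene,
                                      material = particle_strain_model(),
                                      optical_noise = 0.03, seed = 1L) {
  stopifnot(inherits(scene, "mr_scene"))
  k <- ncol(scene$stresses)
  n <- nrow(scene$particles)
  grid <- expand.grid(id = scene$particles$id, session = seq_len(k))
  S <- as.vector(scene$stresses)
  eps <- strain_from_stress(material, S)
  if (optical_noise > 0)
    eps <- eps * with_seed(derive_seed(seed, "cfm"),
                           (1 + stats::rnorm(length(eps), 0, optical_noise)))
  data.frame(id = grid$id, session = grid$session, axial_strain = eps)
}
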