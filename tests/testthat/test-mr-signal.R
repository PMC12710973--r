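test_that("SBR follows the reciprocal-intensity formula on crafted volumes", {
  v <- uniform_volume(100)
  r <- compute_sbr(v, c(4, 16, 16))
  expect_equal(r$sbr, 0)            # roi == background
  # carve the ROI down to background/2 -> SBR 1; /4 -> SBR 3
  for (target in c(2, 4)) {
    arr <- array(100, c(8, 32, 32))
    arr[4:5, 15:17, 15:17] <- 100 / target
    r <- compute_sbr(mr_volume(arr), c(4.5, 16, 16))
    expect_equal(r$roi_mean, 100 / target)
    expect_equal(r$background_mean, 100)
    expect_equal(r$sbr, target - 1)
  }
})

test_that("SBR is invariant to global intensity rescaling", {
  ph <- generate_calibration_phantom(5, 3, seed = 12)
  det <- detect_particles(ph$volume)
  v2 <- mr_volume(ph$volume$data * 7.3, ph$volume$voxel_size)
  for (i in seq_len(nrow(det))) {
    cen <- c(det$z_vox[i], det$y_vox[i], det$x_vox[i])
    expect_equal(compute_sbr(v2, cen)$sbr,
                 compute_sbr(ph$volume, cen)$sbr, tolerance = 1e-12)
  }
})

test_that("ROI windows touching the boundary raise identifying errors", {
  v <- uniform_volume(100)
  expect_error(compute_sbr(v, c(4, 2, 16)), "lateral")
  expect_error(compute_sbr(v, c(4, 16, 3)), "background")
  expect_error(compute_sbr(v, c(0.4, 16, 16)), "axial")
})

test_that("detection recovers a noiseless phantom exactly", {
  ph <- generate_calibration_phantom(30, 0, seed = 31)
  v <- render_scene_volume(ph$scene, add_noise = FALSE)
  det <- detect_particles(v)
  expect_equal(nrow(det), 30)
  m <- match_to_truth(det, ph$scene$positions[[1]])
  expect_true(all(m$dist < 0.2))            # within one voxel
  expect_equal(sort(unique(m$idx)), 1:30)   # one-to-one
})

test_that("pure-noise volumes yield no detections", {
  ns <- noise_spec()
  arr <- with(list(), {
    set.seed(44)
    array(abs(rnorm(24 * 64 * 64, ns$background_mean, ns$sigma)),
          c(24, 64, 64))
  })
  det <- detect_particles(mr_volume(arr))
  expect_equal(nrow(det), 0)
  # constant volume: empty result, not an error
  expect_equal(nrow(detect_particles(uniform_volume(50))), 0)
})

test_that("detection precision and recall reach 0.95 at default noise", {
  hits <- 0; n_det <- 0; n_true <- 0
  for (seed in c(101, 202, 303)) {
    ph <- generate_calibration_phantom(30, 0, seed = seed)
    det <- detect_particles(ph$volume)
    m <- match_to_truth(det, ph$scene$positions[[1]])
    good <- m$dist < 0.3 & !duplicated(m$idx)
    hits <- hits + sum(good)
    n_det <- n_det + nrow(det)
    n_true <- n_true + 30
  }
  expect_gte(hits / n_det, 0.95)   # precision
  expect_gte(hits / n_true, 0.95)  # recall
})

test_that("merged sub-resolution spots detect as one flagged aggregate", {
  ph <- generate_calibration_phantom(1, 0, seed = 9, aggregate_fraction = 1)
  v <- render_scene_volume(ph$scene, add_noise = FALSE)
  det <- detect_particles(v, min_separation = 1)
  expect_equal(nrow(det), 1)
  expect_gt(det$dark_area_px[1], 9)
  expect_gt(det$sbr[1], 2.5)
  expect_true(det$is_aggregate[1])
})

test_that("aggregation filter applies strict thresholds with AND/OR logic", {
  det <- data.frame(sbr = c(2.5, 2.6, 1.0, 3.0),
                    dark_area_px = c(9L, 9L, 16L, 16L))
  f_and <- filter_aggregates(det)             # default: conjunction
  expect_equal(nrow(f_and$excluded), 1)       # both symptoms required
  expect_equal(f_and$excluded$sbr, 3.0)
  # boundary values are never exceedances: sbr 2.5 / area 9 stay retained
  expect_true(all(c(2.5, 2.6) %in% f_and$retained$sbr))
  f_or <- filter_aggregates(det, logic = "or")
  expect_equal(nrow(f_or$retained), 1)        # only the boundary case stays
  expect_true(all(f_or$retained$sbr == 2.5))
  expect_equal(nrow(f_or$excluded), 3)
  # retained and excluded partition the input
  expect_equal(nrow(f_or$retained) + nrow(f_or$excluded), nrow(det))
})

test_that("counting exclusions on a mixed cohort (either-symptom rule)", {
  det <- data.frame(sbr = rep(1, 10),
                    dark_area_px = c(rep(5L, 7), rep(16L, 3)))
  f <- filter_aggregates(det, logic = "or")
  expect_equal(nrow(f$retained), 7)
})

test_that("signal normalization scales SBR to the zero-stress signal", {
  expect_equal(normalize_signal(0.111, 0.111), 0.9984)
  expect_equal(normalize_signal(0, 0.111), 0)
  expect_equal(normalize_signal(0.111 / 2, 0.111), 0.4992)
})

test_that("rendered spot contrast follows the stress-signal law", {
  m <- calibration_model()
  sbr_at <- function(S) {
    ph <- generate_calibration_phantom(12, S, seed = 77)
    v <- render_scene_volume(ph$scene, add_noise = FALSE)
    mean(detect_particles(v)$sbr)
  }
  sbr0 <- sbr_at(0)
  for (S in c(5, 10, 15)) {
    expect_equal(sbr_at(S) / sbr0,
                 forward_signal(m, S) / forward_signal(m, 0),
                 tolerance = 0.01)
  }
})

test_that("noiseless stress recovery stays within 2% across the range", {
  m <- calibration_model()
  stresses <- seq(0.5, 15, length.out = 15)
  ph <- generate_calibration_phantom(15, stresses, seed = 13)
  v <- render_scene_volume(ph$scene, add_noise = FALSE)
  det <- detect_particles(v)
  expect_equal(nrow(det), 15)
  mt <- match_to_truth(det, ph$scene$positions[[1]])
  ph0 <- generate_calibration_phantom(10, 0, seed = 14)
  v0 <- render_scene_volume(ph0$scene, add_noise = FALSE)
  sbr0 <- estimate_reference_sbr0(detect_particles(v0))
  sig <- normalize_signal(det$sbr, sbr0, m)
  S_est <- invert_signal(m, sig, clamp = TRUE)
  rel <- abs(S_est - stresses[mt$idx]) / stresses[mt$idx]
  expect_lt(max(rel), 0.02)
})
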