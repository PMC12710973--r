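# asymmetric cloud for identifiable rigid recovery
make_cloud <- function(n = 150, seed = 5) {
  set.seed(seed)
  matrix(rnorm(3 * n), n, 3) * matrix(c(3, 2.2, 1.4), n, 3, byrow = TRUE)
}

test_that("registering a cloud to itself returns the identity", {
  src <- make_cloud()
  r <- register_cpd(src, src, "rigid", w = 0)
  expect_true(r$converged)
  expect_lt(r$final_sigma2, 1e-8)
  expect_equal(r$R, diag(3), tolerance = 1e-6)
  expect_equal(r$t, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(r$s, 1, tolerance = 1e-6)
})

test_that("rigid CPD recovers a known rotation and translation", {
  src <- make_cloud()
  ang <- 10 * pi / 180
  R_true <- mechanomr:::rotation_matrix(c(ang, 0, 0))
  t_true <- c(3, -2, 1)
  tgt <- src %*% t(R_true) + matrix(t_true, nrow(src), 3, byrow = TRUE)
  r <- register_cpd(src, tgt, "rigid", w = 0)
  expect_lt(max(abs(r$R - R_true)), 1e-3)
  expect_lt(max(abs(r$t - t_true)), 1e-3)
  expect_equal(r$s, 1, tolerance = 1e-3)
  # pure translation via the synthetic scene generator
  sc <- generate_registration_scene(
    n_surface_points = 200, n_sensors = 10, jitter_sd = 0,
    warp = warp_spec(translation = c(5, -3, 2)), seed = 4)
  rt <- register_cpd(sc$source, sc$target, "rigid", w = 0)
  expect_lt(max(abs(rt$t - c(5, -3, 2))), 0.1)
})

test_that("the EM objective is non-increasing", {
  src <- make_cloud(n = 120, seed = 9)
  tgt <- src %*% t(mechanomr:::rotation_matrix(c(0.2, -0.1, 0.15))) +
    matrix(c(1, 2, -1), nrow(src), 3, byrow = TRUE)
  tgt <- tgt + matrix(rnorm(length(tgt), 0, 0.05), nrow(tgt), 3)
  for (mode in c("rigid", "nonrigid")) {
    r <- register_cpd(src, tgt, mode, w = 0.1)
    o <- r$objective
    expect_true(all(diff(o) <= 1e-6 * pmax(abs(o[-length(o)]), 1) + 1e-8),
                info = mode)
  }
})

test_that("rigid CPD is equivariant under pre-rotation of both clouds", {
  src <- make_cloud(n = 100, seed = 12)
  tgt <- src %*% t(mechanomr:::rotation_matrix(c(0.15, 0, 0))) +
    matrix(c(1, -1, 2), 100, 3, byrow = TRUE)
  r0 <- register_cpd(src, tgt, "rigid", w = 0)
  Q <- mechanomr:::rotation_matrix(c(0.3, 0.5, -0.2))
  r1 <- register_cpd(src %*% t(Q), tgt %*% t(Q), "rigid", w = 0)
  res0 <- sort(sqrt(rowSums((r0$registered - tgt)^2)))
  res1 <- sort(sqrt(rowSums((r1$registered - tgt %*% t(Q))^2)))
  expect_equal(res0, res1, tolerance = 1e-6)
})

test_that("nonrigid CPD recovers a smooth warp to sub-voxel accuracy", {
  sc <- generate_registration_scene(
    n_surface_points = 400, n_sensors = 30,
    warp = warp_spec(rotation = c(0.05, -0.04, 0.06),
                     translation = c(0.3, -0.4, 0.5), scale = 1.02,
                     nonrigid_amplitude = 0.5, nonrigid_length_scale = 5),
    jitter_sd = 0.02, seed = 7)
  r <- register_cpd(sc$source, sc$target, "nonrigid", w = 0.05)
  rmsd <- sqrt(mean(rowSums((r$registered - sc$target$points)^2)))
  expect_lt(rmsd, 0.2)
  # sensor coordinates carried through the fitted transform
  mapped <- transform_points(r, sc$sensors_mr)
  err <- sqrt(rowSums((mapped$points - sc$sensors_cfm)^2))
  expect_lt(max(err), 0.3)
})

test_that("large-lambda nonrigid degenerates towards the rigid solution", {
  src <- make_cloud(n = 100, seed = 30)
  tgt <- src + matrix(c(1.5, -0.5, 1), 100, 3, byrow = TRUE)
  r <- register_cpd(src, tgt, "nonrigid", w = 0, lambda = 1e6)
  # displacement field should be (numerically) a pure translation
  expect_lt(max(sqrt(rowSums((r$registered - tgt)^2))), 0.05)
  disp <- r$registered - src
  expect_lt(max(apply(disp, 2, function(x) diff(range(x)))), 0.05)
})

test_that("transform_points applies rigid parts exactly", {
  src <- make_cloud(n = 60, seed = 41)
  tgt <- src + matrix(c(2, 1, -3), 60, 3, byrow = TRUE)
  r <- register_cpd(src, tgt, "rigid", w = 0)
  p <- matrix(c(0, 0, 0, 1, 2, 3), 2, 3, byrow = TRUE)
  out <- transform_points(r, p)
  expect_equal(out$points, p + matrix(c(2, 1, -3), 2, 3, byrow = TRUE),
               tolerance = 1e-4)
})

test_that("degenerate and undersized clouds are rejected", {
  line <- cbind(seq_len(20), 2 * seq_len(20), 3 * seq_len(20))
  expect_error(register_cpd(line, line, "rigid"), "degenerate")
  expect_error(register_cpd(make_cloud(3), make_cloud(3), "rigid"),
               "at least 4")
  expect_error(register_cpd(make_cloud(8), make_cloud(8), "nonrigid"),
               "at least 10")
})

test_that("region assignment recovers ground-truth labels", {
  sc <- generate_registration_scene(
    n_surface_points = 300, n_sensors = 40,
    warp = warp_spec(translation = c(0.5, -0.3, 0.4),
                     nonrigid_amplitude = 0.3),
    vimentin_fraction = 0.45, seed = 19)
  r <- register_cpd(sc$source, sc$target, "nonrigid", w = 0.05)
  mapped <- transform_points(r, sc$sensors_mr)
  asg <- assign_regions(mapped, sc$labels)
  agree <- mean(asg$region_label == sc$sensor_labels, na.rm = TRUE)
  expect_gte(agree, 0.95)
  # a point far outside the volume is flagged unassigned
  far <- assign_regions(matrix(c(100, 100, 100), 1, 3), sc$labels)
  expect_true(is.na(far$region_label))
})

test_that("region statistics summarise groups and their difference", {
  asg <- data.frame(region_label = c(1L, 1L, 0L, 0L))
  st <- region_stats(asg, c(2, 4, 6, 8))
  tab <- st$table
  expect_equal(tab$mean_kPa[tab$region == "vimentin_positive"], 3)
  expect_equal(tab$mean_kPa[tab$region == "vimentin_negative"], 7)
  expect_equal(st$mean_difference, 4)
  # single-group edge case: the other group is reported empty
  st1 <- region_stats(data.frame(region_label = c(1L, 1L)), c(1, 2))
  expect_equal(st1$table$n[st1$table$region == "vimentin_negative"], 0)
  expect_true(is.na(st1$table$mean_kPa[
    st1$table$region == "vimentin_negative"]))
})
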