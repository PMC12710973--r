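test_that("generators are deterministic in (config, seed)", {
  a <- generate_calibration_phantom(10, 2, seed = 5)
  b <- generate_calibration_phantom(10, 2, seed = 5)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$scene$positions, b$scene$positions)
  c <- generate_calibration_phantom(10, 2, seed = 6)
  expect_false(identical(a$volume$data, c$volume$data))
})

test_that("empty scenes render pure background", {
  ph <- generate_calibration_phantom(0, seed = 1)
  expect_equal(mean(ph$volume$data), 100, tolerance = 0.01)
  expect_equal(nrow(ph$scene$particles), 0)
})

test_that("particle placement respects capacity limits", {
  expect_error(
    generate_calibration_phantom(400, 0, volume_shape = c(12L, 40L, 40L),
                                 seed = 1),
    "cannot place")
})

test_that("default noise gives the documented single-particle SNR", {
  ph <- generate_calibration_phantom(30, 0, seed = 11)
  det <- detect_particles(ph$volume)
  snr <- detection_snr(ph$volume, det)
  expect_equal(mean(snr), 9.5, tolerance = 0.15)
})

test_that("tumor series: constant stress and zero growth are static", {
  ts <- generate_tumor_timeseries(10, sessions = c(0, 2, 4),
                                  trajectories = 3, growth_rate = 0,
                                  motion_sd = 0, seed = 8)
  expect_equal(ts$scene$positions[[1]], ts$scene$positions[[3]])
  expect_true(all(ts$scene$stresses == 3))
  # ground-truth delta-stress is zero on every interval
  expect_true(all(diff(t(ts$scene$stresses)) == 0))
})

test_that("growth scales the constellation about its centroid", {
  ts <- generate_tumor_timeseries(12, sessions = c(0, 1), trajectories = 1,
                                  growth_rate = 0.1, motion_sd = 0, seed = 3)
  p0 <- ts$scene$positions[[1]]; p1 <- ts$scene$positions[[2]]
  ctr <- ts$scene$volume_shape * ts$scene$voxel_size / 2
  r0 <- sqrt(rowSums(sweep(p0, 2, ctr)^2))
  r1 <- sqrt(rowSums(sweep(p1, 2, ctr)^2))
  expect_equal(r1 / r0, rep(1.1, 12), tolerance = 1e-10)
})

test_that("loading profiles encode the two regimens' rate contrast", {
  g <- loading_profile("gradual")
  a <- loading_profile("acute")
  expect_equal(profile_stress_at(g, 48), 5)
  expect_equal(profile_stress_at(a, 48), 0.5)
  expect_equal(profile_stress_at(a, 49), 5)
  expect_equal(profile_stress_at(a, 24), 0.5)
  # acute ramp rate exceeds the gradual profile's maximum interval rate
  expect_gt(profile_max_rate(a), profile_max_rate(g))
  expect_equal(profile_max_rate(g), 2.5)    # 0.625 kPa / 6 h in kPa/day
  expect_equal(profile_max_rate(a), 108)    # 4.5 kPa / 1 h in kPa/day
  expect_error(profile_stress_at(g, 50), "schedule range")
  expect_error(loading_profile("custom",
                               schedule = data.frame(time_h = c(0, 0),
                                                     stress_kPa = c(1, 2))),
               "strictly increasing")
})

test_that("registration scene honours identity and zero-fraction cases", {
  sc <- generate_registration_scene(n_surface_points = 100, n_sensors = 10,
                                    warp = warp_spec(), jitter_sd = 0,
                                    vimentin_fraction = 0.3, seed = 2)
  expect_equal(sc$source$points, sc$target$points)       # identity warp
  expect_equal(sc$sensors_mr, sc$sensors_cfm)
  sc0 <- generate_registration_scene(n_surface_points = 100, n_sensors = 10,
                                     vimentin_fraction = 0, seed = 2)
  expect_true(all(sc0$sensor_labels == 0))
  expect_error(generate_registration_scene(vimentin_fraction = 1.2, seed = 1),
               "vimentin_fraction")
})

test_that("label fields occupy roughly the requested volume fraction", {
  sc <- generate_registration_scene(n_surface_points = 100, n_sensors = 10,
                                    vimentin_fraction = 0.4, seed = 6)
  expect_equal(mean(sc$labels$labels), 0.4, tolerance = 0.02)
})

test_that("CFM observations follow the strain model with zero-stress zeros", {
  ph <- generate_calibration_phantom(8, 0, seed = 4)
  obs <- generate_cfm_observations(ph$scene, optical_noise = 0)
  expect_true(all(obs$axial_strain == 0))
  ph2 <- generate_calibration_phantom(8, 7, seed = 4)
  sm <- particle_strain_model()
  obs2 <- generate_cfm_observations(ph2$scene, material = sm,
                                    optical_noise = 0)
  expect_equal(obs2$axial_strain, rep(strain_from_stress(sm, 7), 8))
  # noiseless CFM round trip recovers stress to high precision
  expect_equal(stress_from_strain(sm, obs2$axial_strain[1]), 7,
               tolerance = 1e-8)
})

test_that("region study guarantees group sizes and censored stress draws", {
  rs <- generate_region_study(n_sensors = 45, seed = 17)
  counts <- table(rs$sensor_labels)
  expect_gte(min(counts), 20)
  expect_true(all(rs$true_stress >= 0))
  expect_true(all(rs$true_stress <= 15))
  # positive regions are generated softer than negative regions
  expect_lt(mean(rs$true_stress[rs$sensor_labels == 1]),
            mean(rs$true_stress[rs$sensor_labels == 0]))
})
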