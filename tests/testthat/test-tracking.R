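# build detection tables directly from ground-truth positions
det_from_positions <- function(p, sbr = rep(0.1, nrow(p)), signal = NULL) {
  data.frame(id = seq_len(nrow(p)), z_mm = p[, 1], y_mm = p[, 2],
             x_mm = p[, 3], sbr = sbr,
             normalized_signal = if (is.null(signal)) NA_real_ else signal)
}

test_that("a static constellation links into identity trajectories", {
  set.seed(21)
  p <- matrix(runif(30 * 3, 0, 8), 30, 3)
  sessions <- replicate(5, det_from_positions(p), simplify = FALSE)
  trajs <- link_particles(sessions, times = 0:4)
  expect_length(trajs, 30)
  expect_true(all(vapply(trajs, function(t) nrow(t$records), integer(1)) == 5))
  # positions preserved along each trajectory
  for (tr in trajs[1:5]) expect_equal(var(tr$records$z_mm), 0)
})

test_that("linking is invariant to detection order within a session", {
  set.seed(22)
  p <- matrix(runif(20 * 3, 0, 8), 20, 3)
  q <- p + matrix(rnorm(60, 0, 0.05), 20, 3)
  perm <- sample(20)
  t1 <- link_particles(list(det_from_positions(p), det_from_positions(q)),
                       times = c(0, 1))
  t2 <- link_particles(list(det_from_positions(p),
                            det_from_positions(q[perm, ])),
                       times = c(0, 1))
  key <- function(trajs) {
    df <- trajectories_to_df(trajs)
    df <- df[order(df$session, df$z_mm, df$y_mm), c("session", "z_mm", "y_mm",
                                                    "x_mm")]
    rownames(df) <- NULL
    df
  }
  expect_equal(key(t1), key(t2))
  expect_length(t1, 20)
})

test_that("growth correction yields perfect links on an expanding scene", {
  ts <- generate_tumor_timeseries(30, sessions = c(0, 1, 2), trajectories = 1,
                                  growth_rate = 0.10, motion_sd = 0.02,
                                  seed = 33)
  dets <- lapply(ts$volumes, detect_particles)
  trajs <- link_particles(dets, times = c(0, 1, 2), growth_correction = TRUE)
  lens <- vapply(trajs, function(t) nrow(t$records), integer(1))
  expect_gte(mean(lens == 3), 0.95)
  # verify against ground truth: every consecutive link joins the same particle
  tm <- lapply(1:3, function(j)
    match_to_truth(dets[[j]], ts$scene$positions[[j]])$idx)
  n_ok <- 0; n_tot <- 0
  for (tr in trajs) {
    r <- tr$records
    if (nrow(r) < 2) next
    ids <- vapply(seq_len(nrow(r)), function(i) {
      j <- r$session[i]
      k <- which(abs(dets[[j]]$z_mm - r$z_mm[i]) < 1e-9 &
                   abs(dets[[j]]$y_mm - r$y_mm[i]) < 1e-9)[1]
      tm[[j]][k]
    }, integer(1))
    n_tot <- n_tot + length(ids) - 1
    n_ok <- n_ok + sum(ids[-1] == ids[-length(ids)])
  }
  expect_gte(n_ok / n_tot, 0.95)
})

test_that("a particle lost mid-series terminates without false re-links", {
  set.seed(25)
  p <- matrix(runif(10 * 3, 0, 8), 10, 3)
  s1 <- det_from_positions(p)
  s2 <- det_from_positions(p[-4, , drop = FALSE])   # particle 4 vanishes
  s3 <- det_from_positions(p[-4, , drop = FALSE])
  trajs <- link_particles(list(s1, s2, s3), times = 0:2)
  lens <- vapply(trajs, function(t) nrow(t$records), integer(1))
  expect_equal(sum(lens == 3), 9)
  expect_equal(sum(lens == 1), 1)     # the terminated trajectory
  short <- trajs[[which(lens == 1)]]
  expect_equal(short$records$session, 1)
})

test_that("trajectory stress inversion round-trips forward signals", {
  m <- calibration_model()
  sig <- forward_signal(m, c(1, 3, 7)) / forward_signal(m, 0) *
    forward_signal(m, 0)
  tr <- structure(list(particle_id = 1L, records = data.frame(
    session = 1:3, time = c(0, 2, 4), z_mm = 0, y_mm = 0, x_mm = 0,
    sbr = NA_real_, normalized_signal = sig, stress = NA_real_)),
    class = "trajectory")
  tr <- trajectory_stress(tr, m)
  expect_equal(tr$records$stress, c(1, 3, 7), tolerance = 1e-6)
  expect_false(any(tr$records$out_of_range))
  # signal at the zero-stress value maps to zero stress
  tr$records$normalized_signal <- rep(0.9984, 3)
  tr <- trajectory_stress(tr, m)
  expect_equal(tr$records$stress, rep(0, 3), tolerance = 1e-6)
})

test_that("delta-stress and loading rate follow the window arithmetic", {
  tr <- structure(list(particle_id = 1L, records = data.frame(
    session = 1:3, time = c(1, 3, 5), z_mm = 0, y_mm = 0, x_mm = 0,
    sbr = NA, normalized_signal = NA, stress = c(1, 2, 5))),
    class = "trajectory")
  lr <- compute_loading_rate(tr, window = c(1, 3))
  expect_equal(lr$delta_stress, 1)
  expect_equal(lr$rate, 0.5)
  # default window: last two sessions
  lr2 <- compute_loading_rate(tr)
  expect_equal(lr2$delta_stress, 3)
  expect_error(compute_loading_rate(tr, window = c(0, 3)), "not covered")
  # time reversal negates delta-stress
  trr <- tr; trr$records$stress <- rev(tr$records$stress)
  expect_equal(compute_loading_rate(trr, c(1, 5))$delta_stress,
               -compute_loading_rate(tr, c(1, 5))$delta_stress)
})

test_that("constant trajectories have zero delta-stress", {
  tr <- structure(list(particle_id = 1L, records = data.frame(
    session = 1:4, time = 0:3, z_mm = 0, y_mm = 0, x_mm = 0,
    sbr = NA, normalized_signal = NA, stress = rep(2.5, 4))),
    class = "trajectory")
  expect_equal(compute_loading_rate(tr)$delta_stress, 0)
})

test_that("loading classification separates the two regimens", {
  g <- loading_profile("gradual"); a <- loading_profile("acute")
  mk <- function(profile) {
    t_h <- profile$schedule$time_h
    structure(list(particle_id = 1L, records = data.frame(
      session = seq_along(t_h), time = t_h / 24, z_mm = 0, y_mm = 0,
      x_mm = 0, sbr = NA, normalized_signal = NA,
      stress = profile$schedule$stress_kPa)), class = "trajectory")
  }
  expect_equal(classify_loading(mk(g), rate_threshold = 5), "gradual")
  expect_equal(classify_loading(mk(a), rate_threshold = 5), "acute")
  empty <- structure(list(particle_id = 1L,
                          records = data.frame(session = 1, time = 0,
                                               z_mm = 0, y_mm = 0, x_mm = 0,
                                               sbr = NA,
                                               normalized_signal = NA,
                                               stress = 1)),
                     class = "trajectory")
  expect_error(classify_loading(empty), "fewer than 2")
})
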