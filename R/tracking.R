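#' Link detections across imaging sessions into particle trajectories
#'
#' Greedy mutual-nearest-neighbor matching between consecutive sessions.
#' With `growth_correction = TRUE` a similarity transform (isotropic scale
#' about the constellation centroid plus translation) is estimated between
#' consecutive detection constellations before gating, compensating the
#' expansion of a growing tumor. Matches farther than `max_displacement` mm
#' (after alignment) are rejected; unmatched detections start or terminate
#' trajectories.
#'
#' @param sessions list of detection data frames (one per session, as from
#'   [detect_particles()]; aggregates should be pre-filtered).
#' @param times session times in days, same length as `sessions`.
#' @param max_displacement gating radius, mm.
#' @param growth_correction estimate and remove a scale + translation between
#'   consecutive constellations before matching.
#' @return list of trajectories; each is a list with `particle_id` and a
#'   `records` data frame (session, time, z_mm, y_mm, x_mm, sbr,
#'   normalized_signal, stress).
#' @export
link_particles <- function(sessions, times, max_displacement = 1,
                           growth_correction = TRUE) {
  stopifnot(is.list(sessions), length(sessions) >= 2,
            length(times) == length(sessions),
            !is.unsorted(times, strictly = TRUE))
  k <- length(sessions)
  pts <- lapply(sessions, function(s) {
    as.matrix(s[, c("z_mm", "y_mm", "x_mm"), drop = FALSE])
  })
  # trajectory bookkeeping: traj id of each detection in the current session
  traj_of <- vector("list", k)
  n1 <- nrow(pts[[1]])
  traj_of[[1]] <- seq_len(n1)
  n_traj <- n1
  links <- vector("list", k - 1)
  for (j in seq_len(k - 1)) {
    A <- pts[[j]]; B <- pts[[j + 1]]
    if (nrow(A) == 0 || nrow(B) == 0) {
      match_ab <- rep(NA_integer_, nrow(A))
    } else {
      Bal <- B
      if (growth_correction && nrow(A) >= 3 && nrow(B) >= 3) {
        cA <- colMeans(A); cB <- colMeans(B)
        rA <- sqrt(mean(rowSums(sweep(A, 2, cA)^2)))
        rB <- sqrt(mean(rowSums(sweep(B, 2, cB)^2)))
        s <- if (rB > 0) rA / rB else 1
        Bal <- sweep(sweep(B, 2, cB) * s, 2, cA, "+")
      }
      D <- outer(rowSums(A^2) * 0, rowSums(Bal^2) * 0, "+")
      for (c3 in 1:3) D <- D + outer(A[, c3], Bal[, c3], "-")^2
      D <- sqrt(D)
      nnA <- apply(D, 1, which.min)   # nearest in B for each A
      nnB <- apply(D, 2, which.min)   # nearest in A for each B
      match_ab <- rep(NA_integer_, nrow(A))
      for (a in seq_len(nrow(A))) {
        b <- nnA[a]
        if (nnB[b] == a && D[a, b] <= max_displacement) match_ab[a] <- b
      }
    }
    links[[j]] <- match_ab
    nxt <- rep(NA_integer_, nrow(pts[[j + 1]]))
    for (a in seq_along(match_ab)) if (!is.na(match_ab[a]))
      nxt[match_ab[a]] <- traj_of[[j]][a]
    for (b in seq_along(nxt)) if (is.na(nxt[b])) {
      n_traj <- n_traj + 1L
      nxt[b] <- n_traj
    }
    traj_of[[j + 1]] <- nxt
  }
  # assemble trajectories
  cols <- function(s, b) {
    data.frame(
      sbr = if ("sbr" %in% names(s)) s$sbr[b] else NA_real_,
      normalized_signal = if ("normalized_signal" %in% names(s))
        s$normalized_signal[b] else NA_real_)
  }
  trajs <- lapply(seq_len(n_traj), function(tid) {
    recs <- list()
    for (j in seq_len(k)) {
      b <- which(traj_of[[j]] == tid)
      if (length(b) == 1) {
        recs[[length(recs) + 1L]] <- cbind(
          data.frame(session = j, time = times[j],
                     z_mm = pts[[j]][b, 1], y_mm = pts[[j]][b, 2],
                     x_mm = pts[[j]][b, 3]),
          cols(sessions[[j]], b),
          data.frame(stress = NA_real_))
      }
    }
    records <- do.call(rbind, recs)
    rownames(records) <- NULL
    structure(list(particle_id = tid, records = records),
              class = "trajectory")
  })
  trajs
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory %d: %d record(s), days %s\n", x$particle_id,
              nrow(x$records), paste(x$records$time, collapse = ", ")))
  invisible(x)
}

#' Populate a trajectory with stress estimates
#'
#' Inverts the calibration for each record's normalized signal. Signals
#' outside the attainable range (noise pushing past the zero-stress signal)
#' are clamped into range and flagged in the `out_of_range` column rather
#' than dropped.
#'
#' @param traj a trajectory from [link_particles()].
#' @param model a [calibration_model()].
#' @return the trajectory with `stress` (kPa) and `out_of_range` populated.
#' @export
trajectory_stress <- function(traj, model) {
  stopifnot(inherits(traj, "trajectory"))
  sig <- traj$records$normalized_signal
  S <- invert_signal(model, sig, clamp = TRUE, clamp_slack = Inf)
  traj$records$stress <- as.numeric(S)
  traj$records$out_of_range <- attr(S, "out_of_range")
  traj
}

#' Stress change and loading rate over a time window
#'
#' @param traj a trajectory with stress populated.
#' @param window day pair `c(t_start, t_end)`; defaults to the trajectory's
#'   last two sessions. For the retrospective pre-induction statistic, pass
#'   the two sessions immediately preceding the induction day.
#' @return list with `delta_stress` (kPa, later minus earlier) and `rate`
#'   (kPa/day).
#' @export
compute_loading_rate <- function(traj, window = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  r <- traj$records
  if (nrow(r) < 2) stop("trajectory has fewer than 2 records")
  if (is.null(window)) window <- utils::tail(r$time, 2)
  stopifnot(length(window) == 2, window[2] > window[1])
  i1 <- which(abs(r$time - window[1]) < 1e-9)
  i2 <- which(abs(r$time - window[2]) < 1e-9)
  if (length(i1) != 1 || length(i2) != 1)
    stop(sprintf("window [%g, %g] days not covered by trajectory sessions (%s)",
                 window[1], window[2], paste(r$time, collapse = ", ")))
  ds <- r$stress[i2] - r$stress[i1]
  list(delta_stress = ds, rate = ds / (window[2] - window[1]))
}

#' Classify a stress trajectory as gradual or acute loading
#'
#' A trajectory is `acute` when its maximum interval loading rate exceeds
#' `rate_threshold`; otherwise `gradual`. There is no canonical threshold:
#' it must separate the regimens under study (the default profiles have
#' maximum rates of 2.5 and 108 kPa/day).
#'
#' @param traj a trajectory with stress populated (>= 2 records).
#' @param rate_threshold classification threshold, kPa/day.
#' @return `"gradual"` or `"acute"`.
#' @export
classify_loading <- function(traj, rate_threshold = 5) {
  stopifnot(inherits(traj, "trajectory"))
  r <- traj$records
  if (nrow(r) < 2) stop("cannot classify a trajectory with fewer than 2 records")
  rates <- diff(r$stress) / diff(r$time)
  if (max(rates) > rate_threshold) "acute" else "gradual"
}

#' Flatten trajectories to a long-format data frame
#' @param trajs list of trajectories.
#' @return data frame with one row per (particle, session) record.
#' @export
trajectories_to_df <- function(trajs) {
  do.call(rbind, lapply(trajs, function(tr)
    cbind(particle_id = tr$particle_id, tr$records)))
}
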