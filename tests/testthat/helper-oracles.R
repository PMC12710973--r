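# independent bisection oracle for calibration inversion
bisect_invert <- function(model, signal, lo = 0, hi = 15, tol = 1e-10) {
  f <- function(S) forward_signal(model, S, extrapolation_warning = FALSE)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > signal) lo <- mid else hi <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

# match each detection to its nearest ground-truth particle; returns index
# into the truth matrix and the distance in mm
match_to_truth <- function(detections, truth_mm) {
  D2 <- outer(detections$z_mm, truth_mm[, 1], "-")^2 +
    outer(detections$y_mm, truth_mm[, 2], "-")^2 +
    outer(detections$x_mm, truth_mm[, 3], "-")^2
  idx <- apply(D2, 1, which.min)
  list(idx = idx, dist = sqrt(D2[cbind(seq_len(nrow(D2)), idx)]))
}

# a small uniform volume with hand-placed ROI/background values
uniform_volume <- function(value = 100, dims = c(8L, 32L, 32L)) {
  mr_volume(array(value, dims))
}
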