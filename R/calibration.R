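#' Biexponential stress-signal calibration model
#'
#' Constructs the calibration object mapping local compressive stress S (kPa)
#' to the normalized T2* signal of a single hydrogel micro-sensor:
#' \deqn{signal(S) = a_1 e^{-b_1 S} + a_2 e^{-b_2 S}}
#' The default coefficients are the empirically fitted values for the sensor
#' lot characterised in the agarose phantom experiments
#' (a1 = 0.1344, b1 = 0.926, a2 = 0.864, b2 = 0.0405), valid on [0, 15] kPa.
#'
#' @param a1,b1 amplitude (unitless) and rate (1/kPa) of the fast component.
#' @param a2,b2 amplitude and rate of the slow component.
#' @param stress_range validity interval in kPa.
#' @param reference_sbr0 cohort zero-stress SBR used by
#'   [normalize_signal()]; `NA` until set from a phantom cohort.
#' @return an object of class `calibration_model`.
#' @export
calibration_model <- function(a1 = 0.1344, b1 = 0.926,
                              a2 = 0.864, b2 = 0.0405,
                              stress_range = c(0, 15),
                              reference_sbr0 = NA_real_) {
  stopifnot(a1 > 0, a2 > 0, b1 > 0, b2 > 0)
  if (b1 < b2) { # fast/slow ordering convention: b1 > b2
    tmp <- c(a1, b1); a1 <- a2; b1 <- b2; a2 <- tmp[1]; b2 <- tmp[2]
  }
  structure(
    list(a1 = a1, b1 = b1, a2 = a2, b2 = b2,
         stress_range = as.numeric(stress_range),
         reference_sbr0 = reference_sbr0),
    class = "calibration_model"
  )
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Biexponential calibration: signal = %.4g exp(-%.4g S) + %.4g exp(-%.4g S)\n",
    x$a1, x$b1, x$a2, x$b2))
  cat(sprintf("  valid for S in [%g, %g] kPa; signal(0) = %.4f\n",
              x$stress_range[1], x$stress_range[2], forward_signal(x, 0)))
  if (is.finite(x$reference_sbr0))
    cat(sprintf("  reference SBR at zero stress: %.4f\n", x$reference_sbr0))
  invisible(x)
}

#' Forward stress-to-signal evaluation
#'
#' @param model a [calibration_model()].
#' @param S stress in kPa (vectorised); must be nonnegative.
#' @param extrapolation_warning warn when S exceeds the model's validity range.
#' @return normalized T2* signal, same length as `S`.
#' @export
forward_signal <- function(model, S, extrapolation_warning = TRUE) {
  stopifnot(inherits(model, "calibration_model"))
  if (any(!is.finite(S)) || any(S < 0))
    stop("stress must be finite and nonnegative (kPa)")
  if (extrapolation_warning && any(S > model$stress_range[2]))
    warning(sprintf("stress above calibration range [%g, %g] kPa: extrapolating",
                    model$stress_range[1], model$stress_range[2]))
  model$a1 * exp(-model$b1 * S) + model$a2 * exp(-model$b2 * S)
}

forward_signal_deriv <- function(model, S) {
  -model$a1 * model$b1 * exp(-model$b1 * S) -
    model$a2 * model$b2 * exp(-model$b2 * S)
}

#' Invert the calibration: signal to stress by Newton-Raphson
#'
#' Solves `forward_signal(model, S) = signal` for S. Iteration starts from the
#' midpoint of the validity range; any iterate escaping the current bracket is
#' replaced by a bisection step, so convergence is guaranteed for signals in
#' the attainable range (the forward model is strictly decreasing).
#'
#' @param model a [calibration_model()].
#' @param signal normalized T2* signal (vectorised).
#' @param tol convergence tolerance on the signal residual.
#' @param max_iter maximum Newton iterations per value.
#' @param clamp if `TRUE`, signals outside the attainable range by at most
#'   `clamp_slack` (relative) are clamped to the range endpoint instead of
#'   erroring; the result carries an `out_of_range` attribute flagging them.
#' @param clamp_slack relative slack for clamping.
#' @return stress in kPa, same length as `signal`.
#' @export
invert_signal <- function(model, signal, tol = 1e-8, max_iter = 100L,
                          clamp = FALSE, clamp_slack = 0.25) {
  stopifnot(inherits(model, "calibration_model"))
  lo <- model$stress_range[1]; hi <- model$stress_range[2]
  s_hi <- forward_signal(model, lo)   # signal at low stress (max signal)
  s_lo <- forward_signal(model, hi)   # signal at high stress (min signal)
  out_of_range <- signal > s_hi | signal < s_lo
  if (any(out_of_range) && !clamp)
    stop(sprintf(
      "signal outside attainable range [%.6g, %.6g] for stress in [%g, %g] kPa",
      s_lo, s_hi, lo, hi))
  if (clamp) {
    too_far <- signal > s_hi * (1 + clamp_slack) |
      signal < s_lo * (1 - clamp_slack)
    if (any(too_far))
      stop(sprintf(
        "signal outside attainable range [%.6g, %.6g] by more than %.0f%%",
        s_lo, s_hi, 100 * clamp_slack))
    signal <- pmin(pmax(signal, s_lo), s_hi)
  }
  res <- vapply(signal, function(y) {
    if (y >= s_hi) return(lo)
    if (y <= s_lo) return(hi)
    a <- lo; b <- hi          # bracket: f(a) >= y >= f(b)
    S <- (lo + hi) / 2
    for (i in seq_len(max_iter)) {
      f <- forward_signal(model, S, extrapolation_warning = FALSE) - y
      if (abs(f) < tol) return(S)
      if (f > 0) a <- S else b <- S   # decreasing: f>0 means S too small
      step <- f / forward_signal_deriv(model, S)
      S_new <- S - step
      if (!is.finite(S_new) || S_new <= a || S_new >= b)
        S_new <- (a + b) / 2           # bisection safeguard
      S <- S_new
    }
    S
  }, numeric(1))
  if (clamp) attr(res, "out_of_range") <- out_of_range
  res
}

#' Fit the biexponential calibration to stress-signal points
#'
#' Nonlinear least squares with positivity constraints
#' (Levenberg-Marquardt). Initial values come from a log-linear fit of the
#' slow tail (points in the upper half of the stress range) for (a2, b2) and a
#' log-linear fit of the positive residual for (a1, b1). Component order is
#' normalized to b1 > b2 after fitting.
#'
#' @param points data frame with columns `stress_kPa` and `signal`.
#' @param stress_range validity range recorded on the fitted model.
#' @return a [calibration_model()] with fitted coefficients.
#' @export
fit_calibration <- function(points, stress_range = c(0, 15)) {
  stopifnot(is.data.frame(points),
            all(c("stress_kPa", "signal") %in% names(points)))
  S <- points$stress_kPa; y <- points$signal
  keep <- is.finite(S) & is.finite(y) & y > 0
  S <- S[keep]; y <- y[keep]
  lev <- sort(unique(S))
  if (length(lev) < 6)
    stop("need at least 6 distinct stress levels to fit a biexponential")
  if (diff(range(lev)) < diff(stress_range) / 2)
    stop("stress levels must span at least half of the validity range")

  start <- biexp_start(S, y)
  fit <- try(minpack.lm::nlsLM(
    y ~ a1 * exp(-b1 * S) + a2 * exp(-b2 * S),
    start = start,
    lower = c(a1 = 1e-8, b1 = 1e-8, a2 = 1e-8, b2 = 1e-8),
    control = minpack.lm::nls.lm.control(maxiter = 200)),
    silent = TRUE)
  if (inherits(fit, "try-error")) {
    # retry from a perturbed start
    start2 <- lapply(start, function(v) v * 1.3 + 1e-3)
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-b1 * S) + a2 * exp(-b2 * S),
      start = start2,
      lower = c(a1 = 1e-8, b1 = 1e-8, a2 = 1e-8, b2 = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 400))
  }
  cf <- stats::coef(fit)
  calibration_model(a1 = cf[["a1"]], b1 = cf[["b1"]],
                    a2 = cf[["a2"]], b2 = cf[["b2"]],
                    stress_range = stress_range)
}

# tail log-linear initialization for a biexponential decay
biexp_start <- function(S, y) {
  mid <- stats::median(range(S))
  tail_idx <- S >= mid
  if (sum(tail_idx) < 2) tail_idx <- rank(-S) <= max(3, length(S) %/% 3)
  lf <- stats::lm(log(y[tail_idx]) ~ S[tail_idx])
  a2 <- exp(stats::coef(lf)[[1]]); b2 <- max(1e-4, -stats::coef(lf)[[2]])
  resid <- y - a2 * exp(-b2 * S)
  pos <- resid > 0 & S <= mid
  if (sum(pos) >= 2) {
    lf2 <- stats::lm(log(resid[pos]) ~ S[pos])
    a1 <- exp(stats::coef(lf2)[[1]]); b1 <- max(b2 * 5, -stats::coef(lf2)[[2]])
  } else {
    a1 <- max(1e-3, max(y) - a2); b1 <- b2 * 20
  }
  list(a1 = a1, b1 = b1, a2 = a2, b2 = b2)
}

#' Serialize / deserialize a calibration model as JSON
#' @param model a [calibration_model()].
#' @param path file path.
#' @return `read_calibration_json` returns a [calibration_model()].
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_model(a1 = x$a1, b1 = x$b1, a2 = x$a2, b2 = x$b2,
                    stress_range = x$stress_range,
                    reference_sbr0 = if (is.null(x$reference_sbr0))
                      NA_real_ else x$reference_sbr0)
}
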