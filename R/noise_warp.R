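#' MR noise specification
#'
#' Noise and point-spread parameters for the synthetic volume renderer.
#' `spot_depth` is the nominal ROI-level contrast of an unstressed sensor
#' (background ROI mean minus sensor ROI mean on a noiseless volume); the
#' default noise `sigma` is calibrated so the ratio of that contrast to the
#' per-voxel noise standard deviation — the single-particle signal-to-noise
#' ratio as the detection module measures it — is 9.5, the value reported for
#' this sensor lot. The dark-spot profile is an isotropic Gaussian dip of
#' 0.3 mm full width at half maximum (the single-particle resolution scale).
#'
#' @param model noise law: `"rician"` (magnitude MR noise, default) or
#'   `"gaussian"`.
#' @param sigma per-voxel noise s.d. in intensity units; default
#'   `spot_depth / 9.5`.
#' @param background_mean mean tissue/gel intensity (arbitrary units).
#' @param spot_depth unstressed ROI-level spot contrast, intensity units;
#'   must be below `background_mean`.
#' @param psf_fwhm_mm spot full width at half maximum in mm.
#' @return object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("rician", "gaussian"), sigma = NULL,
                       background_mean = 100, spot_depth = 10,
                       psf_fwhm_mm = 0.3) {
  model <- match.arg(model)
  if (is.null(sigma)) sigma <- spot_depth / 9.5
  stopifnot(sigma > 0, spot_depth > 0, spot_depth < background_mean,
            psf_fwhm_mm > 0)
  structure(list(model = model, sigma = sigma,
                 background_mean = background_mean, spot_depth = spot_depth,
                 psf_fwhm_mm = psf_fwhm_mm,
                 psf_sigma_mm = psf_fwhm_mm / (2 * sqrt(2 * log(2)))),
            class = "noise_spec")
}

# apply the noise law to a clean intensity array
apply_noise <- function(clean, noise) {
  stopifnot(inherits(noise, "noise_spec"))
  n <- length(clean)
  if (noise$model == "gaussian") {
    out <- clean + stats::rnorm(n, 0, noise$sigma)
    out[out < 0] <- 0
  } else {
    # Rician magnitude: |signal + complex Gaussian|
    re <- clean + stats::rnorm(n, 0, noise$sigma)
    im <- stats::rnorm(n, 0, noise$sigma)
    out <- sqrt(re^2 + im^2)
  }
  array(out, dim(clean))
}

#' Warp specification for paired-modality scenes
#'
#' Parameterises the deformation between the in vivo MR frame and the
#' cleared-tissue fluorescence (CFM) frame: a similarity transform (rotation,
#' translation, isotropic scale) composed with a smooth non-rigid
#' displacement built from a Gaussian-kernel mixture. Default amplitudes keep
#' the field invertible (displacement gradient well below 1).
#'
#' @param rotation 3 Euler angles in radians (applied as Rz Ry Rx).
#' @param translation mm triplet (z, y, x).
#' @param scale isotropic scale factor.
#' @param nonrigid_amplitude peak non-rigid displacement magnitude, mm.
#' @param nonrigid_length_scale Gaussian kernel length scale, mm.
#' @param n_kernels number of random kernel centers.
#' @return object of class `warp_spec`.
#' @export
warp_spec <- function(rotation = c(0, 0, 0), translation = c(0, 0, 0),
                      scale = 1, nonrigid_amplitude = 0,
                      nonrigid_length_scale = 5, n_kernels = 10L) {
  stopifnot(length(rotation) == 3, length(translation) == 3, scale > 0,
            nonrigid_amplitude >= 0, nonrigid_length_scale > 0)
  structure(list(rotation = as.numeric(rotation),
                 translation = as.numeric(translation), scale = scale,
                 nonrigid_amplitude = nonrigid_amplitude,
                 nonrigid_length_scale = nonrigid_length_scale,
                 n_kernels = as.integer(n_kernels)),
            class = "warp_spec")
}

rotation_matrix <- function(angles) {
  cz <- cos(angles[1]); sz <- sin(angles[1])
  cy <- cos(angles[2]); sy <- sin(angles[2])
  cx <- cos(angles[3]); sx <- sin(angles[3])
  Rz <- matrix(c(1, 0, 0, 0, cz, -sz, 0, sz, cz), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rx <- matrix(c(cx, -sx, 0, sx, cx, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# Draw kernel centers/coefficients for the non-rigid part; returns a
# warp_field whose action on points is fully determined (no RNG at apply
# time). `center`/`radius` delimit the region the kernels populate.
realize_warp <- function(spec, center, radius, seed) {
  stopifnot(inherits(spec, "warp_spec"))
  field <- list(spec = spec, center = as.numeric(center),
                R = rotation_matrix(spec$rotation),
                kernels = NULL, coef = NULL)
  if (spec$nonrigid_amplitude > 0) {
    rs <- local_rng(seed)
    k <- spec$n_kernels
    centers <- matrix(stats::runif(3 * k, -radius, radius), k, 3) +
      matrix(center, k, 3, byrow = TRUE)
    coef <- matrix(stats::rnorm(3 * k), k, 3)
    restore_rng(rs)
    # scale coefficients so the peak displacement magnitude ~ amplitude
    probe <- matrix(stats::runif(3 * 200, -radius, radius), 200, 3) +
      matrix(center, 200, 3, byrow = TRUE)
    d <- gaussian_field_eval(probe, centers, coef,
                             spec$nonrigid_length_scale)
    peak <- max(sqrt(rowSums(d^2)))
    if (peak > 0) coef <- coef * spec$nonrigid_amplitude / peak
    field$kernels <- centers
    field$coef <- coef
  }
  structure(field, class = "warp_field")
}

gaussian_field_eval <- function(points, centers, coef, ell) {
  d2 <- outer(rowSums(points^2), rowSums(centers^2), "+") -
    2 * points %*% t(centers)
  K <- exp(-pmax(d2, 0) / (2 * ell^2))
  K %*% coef
}

#' Apply a realized warp to points
#' @param field a `warp_field` from the registration-scene generator.
#' @param points n x 3 mm matrix (z, y, x).
#' @return warped n x 3 matrix.
#' @export
apply_warp <- function(field, points) {
  stopifnot(inherits(field, "warp_field"))
  p <- as.matrix(points)
  ctr <- matrix(field$center, nrow(p), 3, byrow = TRUE)
  out <- field$spec$scale * (p - ctr) %*% t(field$R) + ctr +
    matrix(field$spec$translation, nrow(p), 3, byrow = TRUE)
  if (!is.null(field$kernels))
    out <- out + gaussian_field_eval(p, field$kernels, field$coef,
                                     field$spec$nonrigid_length_scale)
  out
}

# Seed scoping: run RNG-consuming code under a temporary seed and restore
# the caller's RNG state afterwards, so generators are pure in (config, seed).
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

with_seed <- function(seed, code) {
  old <- local_rng(seed)
  on.exit(restore_rng(old))
  code
}

# derive a stage seed (< 2^31) from a global seed and a stage name
derive_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) * 7919 + h * 104729) %% 2147483647L)
}
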