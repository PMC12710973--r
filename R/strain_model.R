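#' Saturating particle strain-stress model (CFM arm)
#'
#' Optical (confocal) readout of sensor deformation: axial strain as a
#' saturating function of local stress,
#' \deqn{\epsilon(S) = \epsilon_{max} \frac{S}{S + k}}
#' where k (`particle_modulus`, kPa) sets the half-saturation stress and
#' `max_strain` the asymptote. This is a phenomenological stand-in whose shape
#' mirrors the measured single-particle strain profile over 0-15 kPa; it is
#' not a constitutive fit.
#'
#' @param particle_modulus half-saturation stress k in kPa.
#' @param max_strain strain asymptote (unitless, in (0,1)).
#' @return object of class `particle_strain_model`.
#' @export
particle_strain_model <- function(particle_modulus = 7.5, max_strain = 0.5) {
  stopifnot(particle_modulus > 0, max_strain > 0, max_strain < 1)
  structure(list(particle_modulus = particle_modulus, max_strain = max_strain),
            class = "particle_strain_model")
}

#' Strain from stress and its closed-form inverse
#' @param model a [particle_strain_model()].
#' @param S stress in kPa (vectorised, nonnegative).
#' @return axial strain (unitless).
#' @export
strain_from_stress <- function(model, S) {
  stopifnot(inherits(model, "particle_strain_model"))
  if (any(S < 0)) stop("stress must be nonnegative")
  model$max_strain * S / (S + model$particle_modulus)
}

#' @rdname strain_from_stress
#' @param strain axial strain in [0, max_strain).
#' @export
stress_from_strain <- function(model, strain) {
  stopifnot(inherits(model, "particle_strain_model"))
  if (any(strain < 0)) stop("strain must be nonnegative")
  if (any(strain >= model$max_strain))
    stop(sprintf("strain must be below the asymptote %g", model$max_strain))
  model$particle_modulus * strain / (model$max_strain - strain)
}
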