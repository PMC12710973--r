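#' Compressible Neo-Hookean material
#'
#' Hyperelastic constants for the compression-device medium. The strain
#' energy used throughout is
#' \deqn{W = \frac{G}{2}(I_1 - 3) - G \ln J + \frac{\Lambda}{2} (\ln J)^2}
#' with first Lame parameter \eqn{\Lambda = 2 G \nu / (1 - 2\nu)}.
#'
#' @param G shear modulus in kPa.
#' @param nu Poisson ratio, in (0, 0.5).
#' @return object of class `neo_hookean`, with the derived Lame parameter.
#' @export
neo_hookean <- function(G, nu = 0.31) {
  stopifnot(G > 0, nu > 0, nu < 0.5)
  structure(list(G = G, nu = nu, lambda = 2 * G * nu / (1 - 2 * nu)),
            class = "neo_hookean")
}

# tabulated agarose grades: % w/v -> shear modulus kPa (nu = 0.31 throughout)
.agarose_table <- data.frame(conc = c(0.5, 1.0, 2.0), G = c(0.4, 1.5, 4.7))

#' Agarose material constants by gel concentration
#'
#' Tabulated shear moduli for 0.5, 1.0 and 2.0 % (w/v) agarose
#' (G = 0.4, 1.5, 4.7 kPa; Poisson ratio 0.31); log-log linear interpolation
#' between tabulated concentrations, with a warning outside [0.5, 2.0].
#'
#' @param concentration agarose concentration, % w/v.
#' @return a [neo_hookean()] material.
#' @export
agarose_material <- function(concentration) {
  stopifnot(length(concentration) == 1, concentration > 0)
  tab <- .agarose_table
  if (concentration < min(tab$conc) || concentration > max(tab$conc))
    warning(sprintf("concentration %g%% outside tabulated range [%g, %g]: extrapolating",
                    concentration, min(tab$conc), max(tab$conc)))
  lG <- stats::approx(log(tab$conc), log(tab$G), xout = log(concentration),
                      rule = 2)$y
  # linear extrapolation on the log-log line of the nearest segment
  if (concentration < min(tab$conc) || concentration > max(tab$conc)) {
    i <- if (concentration < min(tab$conc)) 1:2 else (nrow(tab) - 1):nrow(tab)
    sl <- diff(log(tab$G[i])) / diff(log(tab$conc[i]))
    lG <- log(tab$G[i[1]]) + sl * (log(concentration) - log(tab$conc[i[1]]))
  }
  neo_hookean(G = exp(lG), nu = 0.31)
}

#' Uniaxial Cauchy stress under frictionless compression
#'
#' Closed-path analytic surrogate for the device finite-element model:
#' homogeneous uniaxial deformation diag(mu, mu, lambda) with the lateral
#' stretch mu solved from the zero-lateral-traction condition
#' \eqn{G(\mu^2 - 1) + \Lambda \ln J = 0}, J = lambda mu^2. Returns the
#' magnitude of the axial Cauchy stress
#' \eqn{|\sigma_{zz}| = |G(\lambda^2 - 1) + \Lambda \ln J| / J}.
#'
#' @param material a [neo_hookean()] material.
#' @param axial_stretch stretch lambda in (0, 1] (compression).
#' @return Cauchy stress magnitude in kPa (same units as G).
#' @export
uniaxial_stress <- function(material, axial_stretch) {
  stopifnot(inherits(material, "neo_hookean"))
  vapply(axial_stretch, function(lam) {
    if (!is.finite(lam) || lam <= 0) stop("axial stretch must be positive")
    if (lam > 1) stop("tension (stretch > 1) not supported: compression only")
    if (lam == 1) return(0)
    G <- material$G; L <- material$lambda
    g <- function(mu) G * (mu^2 - 1) + L * log(lam * mu^2)
    # lateral stretch bracket: mu = 1 gives g = L*log(lam) < 0; expand upward
    hi <- 1.5
    while (g(hi) < 0) hi <- hi * 1.5
    mu <- stats::uniroot(g, c(1, hi), tol = 1e-12)$root
    J <- lam * mu^2
    abs(G * (lam^2 - 1) + L * log(J)) / J
  }, numeric(1))
}

# strain energy density along the uniaxial path (for consistency checks)
uniaxial_energy <- function(material, axial_stretch) {
  stopifnot(inherits(material, "neo_hookean"))
  vapply(axial_stretch, function(lam) {
    G <- material$G; L <- material$lambda
    g <- function(mu) G * (mu^2 - 1) + L * log(lam * mu^2)
    hi <- 1.5
    while (g(hi) < 0) hi <- hi * 1.5
    mu <- if (lam == 1) 1 else stats::uniroot(g, c(1, hi), tol = 1e-12)$root
    I1 <- lam^2 + 2 * mu^2; J <- lam * mu^2
    G / 2 * (I1 - 3) - G * log(J) + L / 2 * log(J)^2
  }, numeric(1))
}

#' Compression-device geometry
#' @param diameter,height cylinder dimensions in mm (default 10 x 10).
#' @return object of class `device_geometry`.
#' @export
device_geometry <- function(diameter = 10, height = 10) {
  stopifnot(diameter > 0, height > 0)
  structure(list(diameter = diameter, height = height),
            class = "device_geometry")
}

#' Plate displacement to applied stress (and back)
#'
#' The sandwich device compresses a gel cylinder by displacing its top plate
#' by `dx` mm; the axial stretch is `1 - dx/height` and the applied stress
#' follows [uniaxial_stress()]. `stress_to_displacement` inverts by
#' root-finding.
#'
#' @param material a [neo_hookean()] material.
#' @param geometry a [device_geometry()].
#' @param dx plate displacement in mm, in [0, height).
#' @return stress in kPa.
#' @export
displacement_to_stress <- function(material, geometry, dx) {
  stopifnot(inherits(geometry, "device_geometry"))
  if (any(dx < 0) || any(dx >= geometry$height))
    stop("displacement must be in [0, height)")
  uniaxial_stress(material, 1 - dx / geometry$height)
}

#' @rdname displacement_to_stress
#' @param stress target stress in kPa.
#' @export
stress_to_displacement <- function(material, geometry, stress) {
  stopifnot(inherits(geometry, "device_geometry"))
  vapply(stress, function(s) {
    if (s < 0) stop("stress must be nonnegative")
    if (s == 0) return(0)
    f <- function(dx) displacement_to_stress(material, geometry, dx) - s
    hi <- geometry$height * 0.5
    while (f(hi) < 0 && hi < geometry$height * 0.99)
      hi <- (hi + geometry$height) / 2
    stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  }, numeric(1))
}
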