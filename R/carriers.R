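#' Continuum carrier surfaces
#'
#' Constructors for the two idealized all-carbon nanocarriers. The graphene
#' sheet is an infinite flat plane fixed at z = 0 with mean atomic surface
#' density `eta_p`; the C60 fullerene is a sphere of radius `a` centered at
#' the origin with density `eta_s`. Discrete surface atoms are averaged into
#' these densities (continuum approximation); the drug molecule stays
#' atomistic, giving the hybrid discrete-continuous model.
#'
#' @param eta_p,eta_s surface density, atoms/Angstrom^2.
#' @param a sphere radius, Angstrom.
#' @param n_atoms atom count used to derive `eta_s` when it is not given.
#' @return An object of class `plane_carrier` or `sphere_carrier` (both also
#'   inherit class `carrier`).
#' @examples
#' plane_carrier()                  # graphene defaults
#' sphere_carrier()                 # C60 defaults: a = 3.55, 60 atoms
#' @name carriers
NULL

#' @rdname carriers
#' @export
plane_carrier <- function(eta_p = graphene_surface_density(1.42)) {
  if (!is.numeric(eta_p) || length(eta_p) != 1L || eta_p <= 0) {
    stop("'eta_p' must be a single positive density (atoms/A^2)")
  }
  structure(list(eta_p = eta_p), class = c("plane_carrier", "carrier"))
}

#' @rdname carriers
#' @export
sphere_carrier <- function(a = 3.55, eta_s = sphere_surface_density(n_atoms, a),
                           n_atoms = 60) {
  if (!is.numeric(a) || length(a) != 1L || a <= 0) {
    stop("'a' must be a single positive radius (Angstrom)")
  }
  if (!is.numeric(eta_s) || length(eta_s) != 1L || eta_s <= 0) {
    stop("'eta_s' must be a single positive density (atoms/A^2)")
  }
  structure(list(a = a, eta_s = eta_s), class = c("sphere_carrier", "carrier"))
}

#' @export
print.plane_carrier <- function(x, ...) {
  cat(sprintf("<plane_carrier> z = 0, eta_p = %.6g atoms/A^2\n", x$eta_p))
  invisible(x)
}

#' @export
print.sphere_carrier <- function(x, ...) {
  cat(sprintf("<sphere_carrier> a = %g A, eta_s = %.6g atoms/A^2\n",
              x$a, x$eta_s))
  invisible(x)
}

#' Interaction energy between a single atom and the infinite plane
#'
#' Closed form of the continuum surface integral of the 12-6 potential over
#' the plane z = 0: with \eqn{I_n = \pi/((n-1)\delta^{2n-2})},
#' \deqn{E(\delta) = \eta\pi\left(-\frac{A}{2\delta^4} +
#' \frac{B}{5\delta^{10}}\right).}
#' The minimum sits at \eqn{\delta^* = (B/A)^{1/6} = \sigma/2^{1/6}}.
#' Vectorized over `delta`.
#'
#' @param delta perpendicular distance(s) from the plane, Angstrom; > 0.
#' @param c `pair_constants` for the atom-carbon pair.
#' @param eta surface density, atoms/Angstrom^2.
#' @return Energy in kcal/mol.
#' @examples
#' cc <- pair_constants(load_lj_table()$C)
#' plane_point_energy(3.4, cc, graphene_surface_density())
#' @export
plane_point_energy <- function(delta, c, eta) {
  stopifnot(inherits(c, "pair_constants"))
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    stop("'delta' must be strictly positive: atom on or through the plane")
  }
  eta * pi * (-c$A / (2 * delta^4) + c$B / (5 * delta^10))
}

#' Interaction energy between a single atom and a spherical shell
#'
#' Closed form of the continuum surface integral over a sphere of radius `a`
#' centered at the origin, for a point at distance `delta` from the center:
#' \deqn{E(\delta) = \frac{a\pi\eta}{\delta}\left\{-\frac{A}{2}\left[
#' \frac{1}{(a-\delta)^4} - \frac{1}{(a+\delta)^4}\right] + \frac{B}{5}\left[
#' \frac{1}{(a-\delta)^{10}} - \frac{1}{(a+\delta)^{10}}\right]\right\}.}
#' Only exterior points (`delta > a`) are accepted: adsorption on the outside
#' of the cage is the physical regime modelled here, and `delta = a` is a
#' non-integrable singularity. Vectorized over `delta`.
#'
#' @param delta distance(s) from the sphere center, Angstrom; must exceed `a`.
#' @param a sphere radius, Angstrom.
#' @param c `pair_constants` for the atom-carbon pair.
#' @param eta surface density, atoms/Angstrom^2.
#' @return Energy in kcal/mol.
#' @examples
#' cc <- pair_constants(load_lj_table()$C)
#' sphere_point_energy(3.55 + 3.2, 3.55, cc, sphere_surface_density())
#' @export
sphere_point_energy <- function(delta, a, c, eta) {
  stopifnot(inherits(c, "pair_constants"))
  if (!is.numeric(a) || length(a) != 1L || a <= 0) stop("'a' must be positive")
  if (any(!is.finite(delta)) || any(delta <= 0)) {
    stop("'delta' must be strictly positive (Angstrom)")
  }
  if (any(abs(delta - a) < 1e-12)) {
    stop("'delta' equals the sphere radius: energy is singular on the surface")
  }
  if (any(delta < a)) {
    stop("'delta' < a: interior points are not supported (exterior adsorption only)")
  }
  dm <- a - delta
  dp <- a + delta
  (a * pi * eta / delta) *
    (-(c$A / 2) * (1 / dm^4 - 1 / dp^4) + (c$B / 5) * (1 / dm^10 - 1 / dp^10))
}
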