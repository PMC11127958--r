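#' Finite honeycomb graphene patch
#'
#' Builds a hexagonal (honeycomb) carbon lattice in the plane z = 0, centered
#' on a ring center, clipped to the disc of the given radius. Ring centers
#' (not atoms) decide the clipping, which keeps the boundary symmetric; the
#' patch is mirror-symmetric about the x and y axes. Used as the discrete
#' lattice-sum oracle against the continuum plane formula.
#'
#' @param bond_length carbon-carbon bond length, Angstrom (default 1.42).
#' @param radius patch extent, Angstrom; must be at least `2 * bond_length`.
#' @return Object of class `lattice_patch`: list with `atoms` (n x 3 matrix,
#'   z = 0), `bond_length`, `radius`.
#' @examples
#' p <- make_lattice_patch(1.42, 10)
#' nrow(p$atoms) / (pi * p$radius^2)  # approaches 4/(3*sqrt(3)*1.42^2)
#' @export
make_lattice_patch <- function(bond_length = 1.42, radius = 30) {
  if (!is.numeric(bond_length) || bond_length <= 0) {
    stop("'bond_length' must be positive")
  }
  if (!is.numeric(radius) || radius < 2 * bond_length) {
    stop("'radius' must be at least 2 * bond_length")
  }
  b <- bond_length
  lat <- sqrt(3) * b                     # center-to-center distance
  a1 <- c(lat, 0)
  a2 <- c(lat / 2, lat * sqrt(3) / 2)
  kmax <- ceiling(2 * radius / lat) + 2L   # wide enough for oblique axes
  ij <- expand.grid(i = -kmax:kmax, j = -kmax:kmax)
  ctr <- cbind(ij$i * a1[1] + ij$j * a2[1], ij$i * a1[2] + ij$j * a2[2])
  ctr <- ctr[rowSums(ctr^2) <= radius^2, , drop = FALSE]
  ang <- (30 + 60 * 0:5) * pi / 180      # hexagon vertices around each center
  vx <- as.numeric(outer(ctr[, 1], b * cos(ang), `+`))
  vy <- as.numeric(outer(ctr[, 2], b * sin(ang), `+`))
  key <- paste(round(vx, 6), round(vy, 6))
  keep <- !duplicated(key)
  atoms <- cbind(vx[keep], vy[keep], 0)
  structure(list(atoms = atoms, bond_length = b, radius = radius),
            class = "lattice_patch")
}

#' @export
print.lattice_patch <- function(x, ...) {
  cat(sprintf("<lattice_patch> %d atoms, bond %g A, radius %g A (%.4f atoms/A^2)\n",
              nrow(x$atoms), x$bond_length, x$radius,
              nrow(x$atoms) / (pi * x$radius^2)))
  invisible(x)
}

#' Quasi-uniform points on a sphere (Fibonacci lattice)
#'
#' Deterministic Fibonacci-spiral points at radius `a`, used as the
#' surface-quadrature oracle for the continuum sphere formula and as a
#' discrete stand-in for the C60 cage.
#'
#' @param n number of points (>= 12).
#' @param a sphere radius, Angstrom.
#' @return Object of class `sphere_point_set`: list with `points` (n x 3),
#'   `n`, `a`.
#' @export
make_sphere_points <- function(n, a) {
  if (!is.numeric(n) || n < 12) stop("'n' must be >= 12")
  if (!is.numeric(a) || a <= 0) stop("'a' must be positive")
  n <- as.integer(n)
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- a * cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
  structure(list(points = pts, n = n, a = a), class = "sphere_point_set")
}

#' Discrete lattice-sum oracle for the atom-plane energy
#'
#' Brute-force pairwise sum of the 12-6 potential between a probe point at
#' height `delta` above the patch center and every atom of a finite
#' honeycomb patch. As the patch radius grows this converges to
#' [plane_point_energy()] evaluated with the patch's own atom density,
#' providing an independent check of the continuum formula.
#'
#' @param delta probe height above the patch plane, Angstrom (> 0).
#' @param c `pair_constants` (same constants as the closed form, so any
#'   discrepancy isolates the analytic implementation).
#' @param patch a [make_lattice_patch()] object.
#' @return Energy, kcal/mol.
#' @export
oracle_plane_energy <- function(delta, c, patch) {
  stopifnot(inherits(c, "pair_constants"), inherits(patch, "lattice_patch"))
  if (any(delta <= 0)) stop("'delta' must be positive")
  vapply(delta, function(d) {
    rho <- sqrt(rowSums(patch$atoms[, 1:2, drop = FALSE]^2) + d^2)
    sum(pair_energy(rho, c))
  }, numeric(1))
}

#' Surface-quadrature oracle for the atom-sphere energy
#'
#' Equal-area quadrature of the 12-6 potential over a quasi-uniform point
#' set on the sphere: \eqn{\eta \sum_i w_i \Phi(\rho_i)} with
#' \eqn{w_i = 4\pi a^2/n}. With `n = 60` and the C60 radius this also
#' quantifies the continuum-approximation error for the real discrete cage.
#'
#' @param delta probe distance from the sphere center, Angstrom (> a).
#' @param c `pair_constants`.
#' @param points a [make_sphere_points()] object.
#' @param eta surface density to apply, atoms/Angstrom^2; default is the
#'   point set's own density `n/(4 pi a^2)`.
#' @return Energy, kcal/mol.
#' @export
oracle_sphere_energy <- function(delta, c, points,
                                 eta = points$n / (4 * pi * points$a^2)) {
  stopifnot(inherits(c, "pair_constants"), inherits(points, "sphere_point_set"))
  if (any(delta <= points$a)) stop("'delta' must exceed the sphere radius")
  w <- 4 * pi * points$a^2 / points$n
  vapply(delta, function(d) {
    dv <- sweep(points$points, 2, c(0, 0, d))
    rho <- sqrt(rowSums(dv^2))
    eta * w * sum(pair_energy(rho, c))
  }, numeric(1))
}

#' Two-dimensional quadrature oracle for the continuum plane integral
#'
#' Numerically evaluates the surface integrals
#' \eqn{I_n = \int\!\!\int (\delta^2 + y^2 + z^2)^{-n}\,dy\,dz} (n = 3, 6)
#' over the full plane by iterated adaptive quadrature (the inner integral
#' over z solved for each outer y node, both over infinite limits), then
#' assembles \eqn{E = \eta(-A I_3 + B I_6)}. Fully independent of the closed
#' form in [plane_point_energy()].
#'
#' @param delta probe height, Angstrom (> 0).
#' @param c `pair_constants`.
#' @param eta surface density, atoms/Angstrom^2.
#' @return Energy, kcal/mol.
#' @export
quad_plane_energy <- function(delta, c, eta) {
  stopifnot(inherits(c, "pair_constants"))
  if (any(delta <= 0)) stop("'delta' must be positive")
  vapply(delta, function(d) {
    In <- function(n) {
      inner <- function(y) {
        vapply(y, function(yi) {
          stats::integrate(function(z) 1 / (d^2 + yi^2 + z^2)^n,
                           -Inf, Inf, rel.tol = 1e-11)$value
        }, numeric(1))
      }
      stats::integrate(inner, -Inf, Inf, rel.tol = 1e-10)$value
    }
    eta * (-c$A * In(3) + c$B * In(6))
  }, numeric(1))
}

#' One-dimensional quadrature oracle for the continuum sphere integral
#'
#' Numerically integrates the spherical-surface integrand
#' \eqn{I_n = 2\pi \int_0^\pi a^2 \sin\phi\,
#' (a^2 + \delta^2 - 2 a \delta \cos\phi)^{-n}\,d\phi} and assembles
#' \eqn{E = \eta(-A I_3 + B I_6)}. Independent of the closed form in
#' [sphere_point_energy()].
#'
#' @param delta probe distance from the center, Angstrom (> a).
#' @param a sphere radius, Angstrom.
#' @param c `pair_constants`.
#' @param eta surface density, atoms/Angstrom^2.
#' @return Energy, kcal/mol.
#' @export
quad_sphere_energy <- function(delta, a, c, eta) {
  stopifnot(inherits(c, "pair_constants"))
  if (any(delta <= a)) stop("'delta' must exceed the sphere radius")
  vapply(delta, function(d) {
    In <- function(n) {
      f <- function(phi) {
        a^2 * sin(phi) / (a^2 + d^2 - 2 * a * d * cos(phi))^n
      }
      2 * pi * stats::integrate(f, 0, pi, rel.tol = 1e-12,
                                abs.tol = 0)$value
    }
    eta * (-c$A * In(3) + c$B * In(6))
  }, numeric(1))
}

#' Deterministic toy molecules for tests and validation
#'
#' Small constructed molecules used throughout the test-suite so that no
#' external structure files are ever needed:
#' \describe{
#'   \item{ring}{a regular planar hexagon of 6 carbons with side
#'     `bond_length` in the z = 0 plane; with `substituent` set (e.g. "F"),
#'     one extra atom is placed beyond the first ring vertex, giving the
#'     molecule a well-defined front vector.}
#'   \item{rod}{two atoms of `element` along x separated by `bond_length`.}
#'   \item{point}{a single atom of `element` at the origin.}
#' }
#' All kinds are deterministic (no RNG) and returned centered at their
#' center of mass except for the asymmetric substituted ring, which is
#' centered too (its COM shifts toward the substituent).
#'
#' @param kind `"ring"`, `"rod"` or `"point"`.
#' @param bond_length bond length, Angstrom.
#' @param element element for `rod`/`point` atoms (default "C").
#' @param substituent optional element symbol added to a `ring`.
#' @return A [molecule()].
#' @examples
#' make_toy_planar_molecule("ring", substituent = "F")
#' @export
make_toy_planar_molecule <- function(kind = c("ring", "rod", "point"),
                                     bond_length = 1.42, element = "C",
                                     substituent = NULL) {
  kind <- match.arg(kind)
  m <- switch(kind,
    point = molecule(element, matrix(0, 1, 3), name = "toy-point"),
    rod = molecule(rep(element, 2),
                   rbind(c(-bond_length / 2, 0, 0), c(bond_length / 2, 0, 0)),
                   name = "toy-rod"),
    ring = {
      ang <- (0:5) * pi / 3
      xyz <- cbind(bond_length * cos(ang), bond_length * sin(ang), 0)
      el <- rep("C", 6)
      if (!is.null(substituent)) {
        xyz <- rbind(xyz, c(2.7 * bond_length, 0, 0))
        el <- c(el, substituent)
      }
      molecule(el, xyz, name = "toy-ring")
    })
  center_molecule(m)
}

#' Discrete C60 cage as a point set on its mean sphere
#'
#' Synthetic stand-in for the fullerene's 60 discrete atoms: a Fibonacci
#' point set of 60 carbons at the C60 mean radius. Used only as an oracle /
#' visualization aid; the carrier model itself is the continuum sphere.
#'
#' @param a cage radius, Angstrom (default 3.55).
#' @return A [molecule()] of 60 carbons.
#' @export
make_c60_points <- function(a = 3.55) {
  pts <- make_sphere_points(60, a)
  molecule(rep("C", 60), pts$points, name = "C60-synthetic")
}
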