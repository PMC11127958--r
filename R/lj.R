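#' Lennard-Jones parameters for one atomic species
#'
#' Bundle a well depth and a van der Waals diameter into an `lj_params`
#' object. `sigma` is the separation at the potential minimum, i.e. the 12-6
#' potential is written \deqn{\Phi(\rho) = \epsilon[-2(\sigma/\rho)^6 +
#' (\sigma/\rho)^{12}],} so \eqn{\Phi(\sigma) = -\epsilon}. Parameter sets
#' quoted as zero-crossing distances must be converted by the caller
#' (multiply by \eqn{2^{1/6}}) before constructing an `lj_params`.
#'
#' @param epsilon well depth, kcal/mol; must be positive.
#' @param sigma van der Waals diameter (separation at the minimum), Angstrom;
#'   must be positive.
#' @return An object of class `lj_params` with fields `epsilon` and `sigma`.
#' @examples
#' lj_params(0.105, 3.851)  # UFF carbon
#' @export
lj_params <- function(epsilon, sigma) {
  if (!is.numeric(epsilon) || length(epsilon) != 1L || !is.finite(epsilon) ||
      epsilon <= 0) {
    stop("'epsilon' must be a single positive finite number (kcal/mol)")
  }
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0) {
    stop("'sigma' must be a single positive finite number (Angstrom)")
  }
  structure(list(epsilon = epsilon, sigma = sigma), class = "lj_params")
}

#' @export
print.lj_params <- function(x, ...) {
  cat(sprintf("<lj_params> epsilon = %g kcal/mol, sigma = %g A\n",
              x$epsilon, x$sigma))
  invisible(x)
}

#' Combine the parameters of two species with the standard mixing rule
#'
#' Geometric mean for the well depth, arithmetic mean for the diameter:
#' \eqn{\epsilon_{ij} = \sqrt{\epsilon_i \epsilon_j}}, \eqn{\sigma_{ij} =
#' (\sigma_i + \sigma_j)/2}.
#'
#' @param p_i,p_j `lj_params` objects.
#' @return An `lj_params` object for the mixed pair.
#' @export
mix_params <- function(p_i, p_j) {
  stopifnot(inherits(p_i, "lj_params"), inherits(p_j, "lj_params"))
  lj_params(sqrt(p_i$epsilon * p_j$epsilon), (p_i$sigma + p_j$sigma) / 2)
}

#' Attractive and repulsive constants of the 12-6 potential
#'
#' Converts well-depth form parameters into the constants of
#' \eqn{\Phi(\rho) = -A/\rho^6 + B/\rho^{12}} with \eqn{A = 2\epsilon\sigma^6}
#' (kcal A^6/mol) and \eqn{B = \epsilon\sigma^{12}} (kcal A^12/mol).
#'
#' @param p an `lj_params` object.
#' @return An object of class `pair_constants` with fields `A` and `B`.
#' @export
pair_constants <- function(p) {
  stopifnot(inherits(p, "lj_params"))
  structure(list(A = 2 * p$epsilon * p$sigma^6, B = p$epsilon * p$sigma^12),
            class = "pair_constants")
}

#' @export
print.pair_constants <- function(x, ...) {
  cat(sprintf("<pair_constants> A = %g kcal A^6/mol, B = %g kcal A^12/mol\n",
              x$A, x$B))
  invisible(x)
}

#' Lennard-Jones pair energy
#'
#' Evaluates \eqn{\Phi(\rho) = -A/\rho^6 + B/\rho^{12}} (kcal/mol).
#' Vectorized over `rho`.
#'
#' @param rho separation(s), Angstrom; must be strictly positive.
#' @param c a `pair_constants` object.
#' @return Energy in kcal/mol, same length as `rho`.
#' @export
pair_energy <- function(rho, c) {
  stopifnot(inherits(c, "pair_constants"))
  if (any(!is.finite(rho)) || any(rho <= 0)) {
    stop("'rho' must be strictly positive (Angstrom)")
  }
  r6 <- rho^6
  -c$A / r6 + c$B / r6^2
}

#' Mean atomic surface density of a graphene sheet
#'
#' A graphene sheet is a tessellation of hexagonal rings; each ring of area
#' \eqn{3\sqrt{3} b^2/2} carries two atoms (six vertices each shared by three
#' rings), giving \eqn{\eta_p = 4/(3\sqrt{3} b^2)} atoms per square Angstrom
#' for carbon-carbon bond length `b`.
#'
#' @param bond_length carbon-carbon bond length, Angstrom (graphene: 1.42).
#' @return Surface density, atoms/Angstrom^2.
#' @examples
#' graphene_surface_density(1.42)
#' @export
graphene_surface_density <- function(bond_length = 1.42) {
  if (!is.numeric(bond_length) || any(bond_length <= 0) ||
      any(!is.finite(bond_length))) {
    stop("'bond_length' must be positive (Angstrom)")
  }
  4 / (3 * sqrt(3) * bond_length^2)
}

#' Mean atomic surface density of a spherical shell
#'
#' `n_atoms` atoms spread over a sphere of radius `a`:
#' \eqn{\eta_s = n/(4\pi a^2)}. For C60 with `a = 3.55` this gives 0.3789
#' atoms/Angstrom^2.
#'
#' @param n_atoms number of atoms on the shell (C60: 60).
#' @param a sphere radius, Angstrom (C60: 3.55).
#' @return Surface density, atoms/Angstrom^2.
#' @examples
#' sphere_surface_density(60, 3.55)
#' @export
sphere_surface_density <- function(n_atoms = 60, a = 3.55) {
  if (!is.numeric(n_atoms) || any(n_atoms < 1) || any(!is.finite(n_atoms))) {
    stop("'n_atoms' must be >= 1")
  }
  if (!is.numeric(a) || any(a <= 0) || any(!is.finite(a))) {
    stop("'a' must be positive (Angstrom)")
  }
  n_atoms / (4 * pi * a^2)
}

#' Load a per-element Lennard-Jones parameter table
#'
#' Reads a CSV with columns `element`, `epsilon_kcal_mol`, `sigma_angstrom`
#' into a named list of [lj_params()]. The bundled default follows the UFF
#' non-bonded parameters (well depth and van der Waals minimum distance) for
#' H, C, N, O, F, S and Cl; pass `path` to substitute another set. Parameter
#' tables quoted as zero-crossing distances must be pre-converted (multiply
#' sigma by 2^(1/6)).
#'
#' @param path CSV file path; default is the table shipped with the package.
#' @return Named list of `lj_params`, one entry per element symbol, with the
#'   source path in attribute `"source"`.
#' @examples
#' tab <- load_lj_table()
#' tab$C
#' @export
load_lj_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "uff_lj.csv", package = "nanosorb",
                        mustWork = TRUE)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("element", "epsilon_kcal_mol", "sigma_angstrom")
  if (!all(need %in% names(df))) {
    stop("LJ table must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$element)) stop("duplicate element symbols in LJ table")
  tab <- lapply(seq_len(nrow(df)), function(i) {
    lj_params(df$epsilon_kcal_mol[i], df$sigma_angstrom[i])
  })
  names(tab) <- df$element
  attr(tab, "source") <- path
  tab
}

# pair constants of element `el` mixed with the carrier carbon, as a c(A, B)
# pair; used by the energy assembly.
.carbon_pair_constants <- function(el, lj_table) {
  p <- lj_table[[el]]
  if (is.null(p)) stop("no LJ parameters for element '", el, "'")
  pc <- pair_constants(mix_params(p, lj_table[["C"]]))
  c(A = pc$A, B = pc$B)
}
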