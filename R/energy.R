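# n1 x n2 matrices of pair constants A and B for all element pairs between
# two molecules, under the geometric/arithmetic mixing rule.
.pair_constant_matrices <- function(el1, el2, lj_table) {
  missing <- setdiff(unique(c(el1, el2)), names(lj_table))
  if (length(missing) > 0L) {
    stop("no LJ parameters for element(s): ", paste(missing, collapse = ", "))
  }
  eps <- vapply(lj_table, `[[`, numeric(1), "epsilon")
  sig <- vapply(lj_table, `[[`, numeric(1), "sigma")
  e_ij <- sqrt(outer(eps[el1], eps[el2]))
  s_ij <- outer(sig[el1], sig[el2], function(a, b) (a + b) / 2)
  list(A = 2 * e_ij * s_ij^6, B = e_ij * s_ij^12)
}

# per-atom constants against the all-carbon carrier surface
.carrier_constant_vectors <- function(el, lj_table) {
  ab <- .pair_constant_matrices(el, "C", lj_table)
  list(A = as.numeric(ab$A), B = as.numeric(ab$B))
}

#' Discrete drug-drug interaction energy
#'
#' Double sum of the 12-6 pair potential over all atom pairs of two posed
#' molecules, with per-pair constants from the mixing rule. No cutoff is
#' applied (molecules are tiny).
#'
#' @param m1,m2 posed `molecule` objects.
#' @param lj_table element parameter table from [load_lj_table()].
#' @return Energy, kcal/mol.
#' @export
drug_drug_energy <- function(m1, m2, lj_table = load_lj_table()) {
  stopifnot(inherits(m1, "molecule"), inherits(m2, "molecule"))
  x1 <- coords(m1)
  x2 <- coords(m2)
  d2min <- min(outer(rowSums(x1^2), rowSums(x2^2), `+`) - 2 * tcrossprod(x1, x2))
  if (d2min < 1e-12) stop("coincident atoms between molecules: pair energy undefined")
  ab <- .pair_constant_matrices(m1$atoms$element, m2$atoms$element, lj_table)
  cpp_lj_pair_sum(x1, x2, ab$A, ab$B)
}

#' Hybrid drug-plane interaction energy
#'
#' Sums the closed-form atom-plane continuum energy
#' [plane_point_energy()] over the atoms of a posed molecule, each atom mixed
#' with the carrier carbon parameters. All atoms must be strictly above the
#' plane z = 0.
#'
#' @param m a posed `molecule`.
#' @param carrier a [plane_carrier()].
#' @param lj_table element parameter table.
#' @return Energy, kcal/mol.
#' @export
drug_plane_energy <- function(m, carrier = plane_carrier(),
                              lj_table = load_lj_table()) {
  stopifnot(inherits(m, "molecule"), inherits(carrier, "plane_carrier"))
  z <- coords(m)[, 3]
  if (any(z <= 0)) {
    stop("atom on or below the graphene plane (z <= 0): energy undefined")
  }
  ab <- .carrier_constant_vectors(m$atoms$element, lj_table)
  cpp_lj_plane_sum(z, ab$A, ab$B, carrier$eta_p)
}

#' Hybrid drug-sphere interaction energy
#'
#' Sums the closed-form atom-sphere continuum energy
#' [sphere_point_energy()] over the atoms of a posed molecule. All atoms must
#' lie strictly outside the sphere.
#'
#' @param m a posed `molecule`.
#' @param carrier a [sphere_carrier()].
#' @param lj_table element parameter table.
#' @return Energy, kcal/mol.
#' @export
drug_sphere_energy <- function(m, carrier = sphere_carrier(),
                               lj_table = load_lj_table()) {
  stopifnot(inherits(m, "molecule"), inherits(carrier, "sphere_carrier"))
  r <- sqrt(rowSums(coords(m)^2))
  if (any(r <= carrier$a)) {
    stop("atom on or inside the C60 sphere (r <= a): energy undefined")
  }
  ab <- .carrier_constant_vectors(m$atoms$element, lj_table)
  cpp_lj_sphere_sum(r, ab$A, ab$B, carrier$a, carrier$eta_s)
}

#' Specify a drug-carrier system
#'
#' Bundles a carrier (or `NULL` for drug-drug-only systems), the molecules in
#' their default placements, one [rigid_pose()] per molecule, and the LJ
#' parameter table.
#'
#' @param molecules list of `molecule` objects (default placements).
#' @param poses list of `rigid_pose`, same length as `molecules`.
#' @param carrier `NULL`, a [plane_carrier()], or a [sphere_carrier()].
#' @param lj_table element parameter table.
#' @return Object of class `system_spec`.
#' @export
system_spec <- function(molecules, poses = NULL, carrier = NULL,
                        lj_table = load_lj_table()) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  stopifnot(all(vapply(molecules, inherits, logical(1), "molecule")))
  if (is.null(poses)) poses <- replicate(length(molecules), rigid_pose(),
                                         simplify = FALSE)
  if (inherits(poses, "rigid_pose")) poses <- list(poses)
  if (length(poses) != length(molecules)) {
    stop("'poses' must have one entry per molecule")
  }
  stopifnot(all(vapply(poses, inherits, logical(1), "rigid_pose")))
  if (!is.null(carrier) && !inherits(carrier, "carrier")) {
    stop("'carrier' must be NULL, a plane_carrier or a sphere_carrier")
  }
  els <- unique(unlist(lapply(molecules, function(m) m$atoms$element)))
  missing <- setdiff(els, names(lj_table))
  if (length(missing) > 0L) {
    stop("no LJ parameters for element(s): ", paste(missing, collapse = ", "))
  }
  structure(list(molecules = molecules, poses = poses, carrier = carrier,
                 lj_table = lj_table),
            class = "system_spec")
}

#' Total energy of a posed system, with its breakdown
#'
#' Applies each pose, then assembles the total interaction energy: the
#' discrete drug-drug double sum over all unordered molecule pairs plus the
#' hybrid continuum carrier term of every molecule (zero when `carrier` is
#' `NULL`). The components always sum exactly to the total.
#'
#' @param s a [system_spec()].
#' @return Object of class `energy_breakdown`: list with `total` (kcal/mol),
#'   `drug_drug` (named vector, one entry per unordered pair `"i-j"`) and
#'   `drug_carrier` (one entry per molecule).
#' @export
total_energy <- function(s) {
  stopifnot(inherits(s, "system_spec"))
  posed <- mapply(apply_pose, s$molecules, s$poses, SIMPLIFY = FALSE)
  n <- length(posed)
  dd <- numeric(0)
  if (n >= 2L) {
    pairs <- utils::combn(n, 2)
    dd <- apply(pairs, 2, function(ij) {
      drug_drug_energy(posed[[ij[1]]], posed[[ij[2]]], s$lj_table)
    })
    names(dd) <- apply(pairs, 2, paste, collapse = "-")
  }
  dc <- numeric(n)
  if (inherits(s$carrier, "plane_carrier")) {
    dc <- vapply(posed, drug_plane_energy, numeric(1), s$carrier, s$lj_table)
  } else if (inherits(s$carrier, "sphere_carrier")) {
    dc <- vapply(posed, drug_sphere_energy, numeric(1), s$carrier, s$lj_table)
  }
  names(dc) <- seq_len(n)
  structure(list(total = sum(dd) + sum(dc), drug_drug = dd, drug_carrier = dc),
            class = "energy_breakdown")
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("<energy_breakdown> total = %.4f kcal/mol\n", x$total))
  if (length(x$drug_drug)) {
    cat("  drug-drug:   ",
        paste(sprintf("%s: %.4f", names(x$drug_drug), x$drug_drug),
              collapse = ", "), "\n")
  }
  if (length(x$drug_carrier)) {
    cat("  drug-carrier:",
        paste(sprintf("%s: %.4f", names(x$drug_carrier), x$drug_carrier),
              collapse = ", "), "\n")
  }
  invisible(x)
}
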