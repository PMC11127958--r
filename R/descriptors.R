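.unit <- function(v) v / sqrt(sum(v^2))

.angle_deg <- function(u, v) {
  cu <- sum(.unit(u) * .unit(v))
  acos(min(1, max(-1, cu))) * 180 / pi
}

#' Geometric descriptors of a pair of stacked molecules
#'
#' Characterizes the relative placement of two posed planar molecules:
#' \describe{
#'   \item{xi}{center-of-mass separation, Angstrom.}
#'   \item{d}{interplanar distance: the COM offset projected on the mean of
#'     the two carbon-plane normals (normals are sign-aligned before
#'     averaging so anti-parallel stacks are handled), Angstrom.}
#'   \item{alpha}{incline angle between the two oriented plane normals,
#'     degrees in \eqn{[0, 180]}. Frames transported through the poses keep
#'     the normal attached to the molecule, so a flipped partner reports
#'     alpha near 180.}
#'   \item{beta}{rotational angle between the two front vectors after
#'     projection into the mean plane, degrees in \eqn{[0, 180]};
#'     `beta_folded = min(beta, 180 - beta)` is also reported since both
#'     conventions appear in the stacking literature.}
#' }
#'
#' @param m1,m2 posed `molecule` objects (used when frames are not supplied).
#' @param front1,front2 front-atom selectors (see [select_front_atom()]);
#'   `front2` defaults to `front1`.
#' @param frame1,frame2 optional pre-computed (e.g. pose-transported)
#'   `molecular_frame` objects; when supplied, `m1`/`m2` may be `NULL`.
#' @return Object of class `pair_descriptors`: list with `xi`, `d`, `alpha`,
#'   `beta`, `beta_folded` and `front_dot` (sign carrier of the co/anti
#'   decision).
#' @export
pair_descriptors <- function(m1 = NULL, m2 = NULL, front1 = NULL,
                             front2 = front1, frame1 = NULL, frame2 = NULL) {
  if (is.null(frame1)) frame1 <- molecular_frame(m1, front1)
  if (is.null(frame2)) frame2 <- molecular_frame(m2, front2)
  stopifnot(inherits(frame1, "molecular_frame"),
            inherits(frame2, "molecular_frame"))
  dvec <- frame2$center_of_mass - frame1$center_of_mass
  xi <- sqrt(sum(dvec^2))
  alpha <- .angle_deg(frame1$normal, frame2$normal)
  n2 <- if (sum(frame1$normal * frame2$normal) < 0) -frame2$normal else frame2$normal
  nbar <- .unit(frame1$normal + n2)
  d <- abs(sum(dvec * nbar))
  p1 <- frame1$front - sum(frame1$front * nbar) * nbar
  p2 <- frame2$front - sum(frame2$front * nbar) * nbar
  if (sqrt(sum(p1^2)) < 1e-10 || sqrt(sum(p2^2)) < 1e-10) {
    stop("front vector is parallel to the mean normal: beta undefined")
  }
  beta <- .angle_deg(p1, p2)
  structure(list(xi = xi, d = d, alpha = alpha, beta = beta,
                 beta_folded = min(beta, 180 - beta),
                 front_dot = sum(.unit(p1) * .unit(p2))),
            class = "pair_descriptors")
}

#' @export
print.pair_descriptors <- function(x, ...) {
  cat(sprintf(
    "<pair_descriptors> xi = %.3f A, d = %.3f A, alpha = %.3f deg, beta = %.3f deg\n",
    x$xi, x$d, x$alpha, x$beta))
  invisible(x)
}

#' Descriptors of a molecule adsorbed on the graphene plane
#'
#' `d_surface` is the height of the center of mass above the plane z = 0;
#' `gamma` is the tilt of the molecular carbon plane against the sheet (angle
#' between the molecular normal and the z axis, folded to \eqn{[0, 90]}
#' because only the tilt magnitude is meaningful).
#'
#' @param m posed `molecule` (used when `frame` is not supplied); must lie
#'   above the plane.
#' @param carrier a [plane_carrier()] (densities are not used; present for a
#'   uniform interface).
#' @param front front-atom selector for the frame.
#' @param frame optional pre-computed `molecular_frame`.
#' @return Object of class `carrier_descriptors` with `d_surface` and
#'   `gamma`.
#' @export
plane_carrier_descriptors <- function(m = NULL, carrier = plane_carrier(),
                                      front = NULL, frame = NULL) {
  if (is.null(frame)) frame <- molecular_frame(m, front)
  if (frame$center_of_mass[3] <= 0) {
    stop("molecule center of mass is not above the plane")
  }
  gamma <- .angle_deg(frame$normal, c(0, 0, 1))
  structure(list(d_surface = abs(frame$center_of_mass[3]),
                 gamma = min(gamma, 180 - gamma), omega = NA_real_),
            class = "carrier_descriptors")
}

#' Descriptors of one or two molecules adsorbed on the C60 sphere
#'
#' Per molecule: `d_surface` is the COM distance to the spherical surface
#' (\eqn{\|COM\| - a}) and `gamma` the angle between the molecular normal and
#' the outward radial direction at the COM, folded to \eqn{[0, 90]}. With two
#' molecules, `omega` is their angular separation seen from the sphere
#' center, degrees in \eqn{[0, 180]}.
#'
#' @param m1,m2 posed `molecule` objects (`m2` optional).
#' @param carrier a [sphere_carrier()].
#' @param front1,front2 front-atom selectors.
#' @param frame1,frame2 optional pre-computed frames.
#' @return Object of class `carrier_descriptors` with vectors `d_surface`,
#'   `gamma` (length 1 or 2) and scalar `omega` (NA without a second
#'   molecule).
#' @export
sphere_carrier_descriptors <- function(m1 = NULL, m2 = NULL,
                                       carrier = sphere_carrier(),
                                       front1 = NULL, front2 = front1,
                                       frame1 = NULL, frame2 = NULL) {
  stopifnot(inherits(carrier, "sphere_carrier"))
  if (is.null(frame1)) frame1 <- molecular_frame(m1, front1)
  frames <- list(frame1)
  if (!is.null(m2) || !is.null(frame2)) {
    if (is.null(frame2)) frame2 <- molecular_frame(m2, front2)
    frames <- c(frames, list(frame2))
  }
  d <- g <- numeric(length(frames))
  for (i in seq_along(frames)) {
    com <- frames[[i]]$center_of_mass
    rr <- sqrt(sum(com^2))
    if (rr <= carrier$a) stop("molecule center of mass is inside the sphere")
    d[i] <- rr - carrier$a
    gi <- .angle_deg(frames[[i]]$normal, com / rr)
    g[i] <- min(gi, 180 - gi)
  }
  omega <- if (length(frames) == 2L) {
    .angle_deg(frames[[1]]$center_of_mass, frames[[2]]$center_of_mass)
  } else NA_real_
  structure(list(d_surface = d, gamma = g, omega = omega),
            class = "carrier_descriptors")
}

#' @export
print.carrier_descriptors <- function(x, ...) {
  cat(sprintf("<carrier_descriptors> d_surface = %s A, gamma = %s deg",
              paste(sprintf("%.3f", x$d_surface), collapse = "/"),
              paste(sprintf("%.3f", x$gamma), collapse = "/")))
  if (!is.na(x$omega)) cat(sprintf(", omega = %.3f deg", x$omega))
  cat("\n")
  invisible(x)
}

#' Classify the mutual alignment of two stacked molecules
#'
#' Two molecules are considered plane-parallel when the folded incline angle
#' `min(alpha, 180 - alpha)` is at most `alpha_thr`. Parallel pairs are then
#' split on the rotational angle `beta` between front vectors: co-parallel
#' (same direction, `beta <= beta_thr`), anti-parallel (opposed,
#' `beta >= 180 - beta_thr`), otherwise orthogonally parallel (tilted
#' in-plane). Non-parallel planes are `unclassified`.
#'
#' @param pd a [pair_descriptors()] object.
#' @param alpha_thr plane-parallel threshold, degrees (default 20).
#' @param beta_thr front-vector threshold, degrees (default 30).
#' @return One of `"co_parallel"`, `"anti_parallel"`,
#'   `"orthogonally_parallel"`, `"unclassified"`.
#' @export
classify_alignment <- function(pd, alpha_thr = 20, beta_thr = 30) {
  stopifnot(inherits(pd, "pair_descriptors"))
  if (min(pd$alpha, 180 - pd$alpha) > alpha_thr) return("unclassified")
  if (pd$beta <= beta_thr) "co_parallel"
  else if (pd$beta >= 180 - beta_thr) "anti_parallel"
  else "orthogonally_parallel"
}

#' Full descriptor record of one optimized configuration
#'
#' Applies the poses, transports each molecule's frame, and assembles every
#' descriptor the configuration supports: per-molecule carrier descriptors
#' (`d_surface`, `gamma`), pairwise stacking descriptors (`xi`, `d`,
#' `alpha`, `beta`) with alignment classes, and angular separations `omega`
#' on the sphere. Molecules whose frame cannot be fitted (fewer than three
#' carbons) get `NA` angular descriptors but keep distances.
#'
#' @param poses list of [rigid_pose()] (or an `optimization_result`, whose
#'   poses and energy are used).
#' @param molecules list of `molecule` objects in default placement.
#' @param carrier `NULL`, [plane_carrier()] or [sphere_carrier()].
#' @param front_selectors one selector, or a list with one per molecule.
#' @param energy optional configuration energy to store (kcal/mol).
#' @return Object of class `configuration_record`: list with `energy`,
#'   data frame `per_molecule` (`d_surface`, `gamma`), data frame `pairs`
#'   (`i`, `j`, `xi`, `d`, `alpha`, `beta`, `beta_folded`, `omega`,
#'   `class`).
#' @export
configuration_record <- function(poses, molecules, carrier = NULL,
                                 front_selectors = NULL, energy = NA_real_) {
  if (inherits(poses, "optimization_result")) {
    energy <- poses$best_energy
    poses <- poses$best_poses
  }
  if (inherits(poses, "rigid_pose")) poses <- list(poses)
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  n <- length(molecules)
  stopifnot(length(poses) == n)
  if (!is.list(front_selectors) || !is.null(front_selectors$element)) {
    front_selectors <- rep(list(front_selectors), n)
  }
  frames <- vector("list", n)
  coms <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    frames[i] <- list(tryCatch({
      f0 <- molecular_frame(molecules[[i]], front_selectors[[i]])
      pose_frame(f0, poses[[i]])
    }, error = function(e) NULL))
    com0 <- center_of_mass(molecules[[i]])
    coms[i, ] <- com0 + c(poses[[i]]$x, poses[[i]]$y, poses[[i]]$z)
  }
  per_mol <- data.frame(d_surface = rep(NA_real_, n), gamma = rep(NA_real_, n))
  if (inherits(carrier, "plane_carrier")) {
    per_mol$d_surface <- abs(coms[, 3])
    for (i in seq_len(n)) {
      if (!is.null(frames[[i]])) {
        g <- .angle_deg(frames[[i]]$normal, c(0, 0, 1))
        per_mol$gamma[i] <- min(g, 180 - g)
      }
    }
  } else if (inherits(carrier, "sphere_carrier")) {
    rr <- sqrt(rowSums(coms^2))
    per_mol$d_surface <- rr - carrier$a
    for (i in seq_len(n)) {
      if (!is.null(frames[[i]])) {
        g <- .angle_deg(frames[[i]]$normal, coms[i, ] / rr[i])
        per_mol$gamma[i] <- min(g, 180 - g)
      }
    }
  }
  pairs <- data.frame(i = integer(0), j = integer(0), xi = numeric(0),
                      d = numeric(0), alpha = numeric(0), beta = numeric(0),
                      beta_folded = numeric(0), omega = numeric(0),
                      class = character(0), stringsAsFactors = FALSE)
  if (n >= 2L) {
    idx <- utils::combn(n, 2)
    for (k in seq_len(ncol(idx))) {
      i <- idx[1, k]; j <- idx[2, k]
      xi <- sqrt(sum((coms[i, ] - coms[j, ])^2))
      row <- data.frame(i = i, j = j, xi = xi, d = NA_real_,
                        alpha = NA_real_, beta = NA_real_,
                        beta_folded = NA_real_, omega = NA_real_,
                        class = NA_character_, stringsAsFactors = FALSE)
      if (!is.null(frames[[i]]) && !is.null(frames[[j]])) {
        pd <- pair_descriptors(frame1 = frames[[i]], frame2 = frames[[j]])
        row$d <- pd$d; row$alpha <- pd$alpha; row$beta <- pd$beta
        row$beta_folded <- pd$beta_folded
        row$class <- classify_alignment(pd)
      }
      if (inherits(carrier, "sphere_carrier")) {
        row$omega <- .angle_deg(coms[i, ], coms[j, ])
      }
      pairs <- rbind(pairs, row)
    }
  }
  structure(list(energy = energy, per_molecule = per_mol, pairs = pairs),
            class = "configuration_record")
}

#' @export
print.configuration_record <- function(x, ...) {
  cat(sprintf("<configuration_record> E = %.4f kcal/mol\n", x$energy))
  if (nrow(x$per_molecule) && any(!is.na(x$per_molecule$d_surface))) {
    cat("  per molecule:\n")
    print(round(x$per_molecule, 3))
  }
  if (nrow(x$pairs)) {
    cat("  pairs:\n")
    print(cbind(round(x$pairs[, c("xi", "d", "alpha", "beta", "omega")], 3),
                class = x$pairs$class))
  }
  invisible(x)
}
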