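#' Rigid-body pose of one molecule
#'
#' The five decision variables placing a rigid molecule: a translation
#' `(x, y, z)` of its center of mass (Angstrom, relative to the default
#' position) and two rotations `theta_x`, `theta_y` (degrees) about the lab
#' x- and y-axes. Rotation is applied about the molecule's default center of
#' mass, first `theta_x` then `theta_y` (combined matrix
#' \eqn{R = R_y(\theta_y) R_x(\theta_x)}); the order and pivot are fixed so
#' poses are reproducible.
#'
#' @param x,y,z translation, Angstrom.
#' @param theta_x,theta_y rotation angles, degrees in \eqn{[-180, 180]}.
#' @return Object of class `rigid_pose`.
#' @examples
#' rigid_pose(0, 0, 3.4, 0, 0)
#' @export
rigid_pose <- function(x = 0, y = 0, z = 0, theta_x = 0, theta_y = 0) {
  v <- c(x = x, y = y, z = z, theta_x = theta_x, theta_y = theta_y)
  if (any(!is.finite(v))) stop("pose variables must be finite")
  structure(as.list(v), class = "rigid_pose")
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("<rigid_pose> t = (%.3f, %.3f, %.3f) A, theta = (%.2f, %.2f) deg\n",
              x$x, x$y, x$z, x$theta_x, x$theta_y))
  invisible(x)
}

#' Rotation matrix of a pose
#'
#' @param theta_x,theta_y rotation angles, degrees.
#' @return 3x3 rotation matrix \eqn{R_y(\theta_y) R_x(\theta_x)}.
#' @export
pose_rotation <- function(theta_x, theta_y) {
  ax <- theta_x * pi / 180
  ay <- theta_y * pi / 180
  rx <- matrix(c(1, 0, 0,
                 0, cos(ax), -sin(ax),
                 0, sin(ax), cos(ax)), 3, 3, byrow = TRUE)
  ry <- matrix(c(cos(ay), 0, sin(ay),
                 0, 1, 0,
                 -sin(ay), 0, cos(ay)), 3, 3, byrow = TRUE)
  ry %*% rx
}

#' Apply a rigid pose to a molecule
#'
#' Rotates all atoms about the molecule's current (default) center of mass by
#' `theta_x` then `theta_y`, then translates the center of mass by
#' `(x, y, z)`. All interatomic distances are preserved.
#'
#' @param m a `molecule` in its default placement.
#' @param p a [rigid_pose()].
#' @return The posed `molecule`.
#' @export
apply_pose <- function(m, p) {
  stopifnot(inherits(m, "molecule"), inherits(p, "rigid_pose"))
  com <- center_of_mass(m)
  r <- pose_rotation(p$theta_x, p$theta_y)
  xyz <- sweep(coords(m), 2, com) %*% t(r)
  xyz <- sweep(xyz, 2, com + c(p$x, p$y, p$z), `+`)
  .set_coords(m, xyz)
}

#' Transport a molecular frame through a rigid pose
#'
#' Rotates the frame's direction vectors by the pose rotation and moves the
#' center of mass accordingly. Transporting the frame computed on the default
#' molecule (rather than refitting on posed coordinates) keeps the normal's
#' orientation attached to the molecule, so a flipped molecule reports a
#' flipped normal -- which is what distinguishes co-parallel from
#' anti-parallel stacks.
#'
#' @param frame a `molecular_frame` of the default molecule.
#' @param p a [rigid_pose()].
#' @return The transported `molecular_frame`.
#' @export
pose_frame <- function(frame, p) {
  stopifnot(inherits(frame, "molecular_frame"), inherits(p, "rigid_pose"))
  r <- pose_rotation(p$theta_x, p$theta_y)
  frame$front <- as.numeric(r %*% frame$front)
  frame$side <- as.numeric(r %*% frame$side)
  frame$normal <- as.numeric(r %*% frame$normal)
  frame$center_of_mass <- frame$center_of_mass + c(p$x, p$y, p$z)
  frame
}
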