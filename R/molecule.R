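# Standard atomic weights (IUPAC 2021 conventional values), amu.
.atomic_masses <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999,
  F = 18.998403, P = 30.973762, S = 32.06, Cl = 35.45, Br = 79.904,
  I = 126.90447
)

#' Standard atomic mass of an element
#'
#' @param element character vector of element symbols.
#' @return Atomic masses in amu.
#' @export
atomic_mass <- function(element) {
  m <- .atomic_masses[element]
  if (any(is.na(m))) {
    stop("unknown element symbol(s): ",
         paste(unique(element[is.na(m)]), collapse = ", "))
  }
  unname(m)
}

#' Construct a rigid molecule
#'
#' A molecule is an ordered, element-labelled 3D point set. Bonds are not
#' stored: all molecules are treated as rigid bodies with no bending or
#' twisting, so only elements, coordinates and masses enter the model.
#'
#' @param element character vector of element symbols.
#' @param xyz numeric matrix (n x 3) of coordinates, Angstrom.
#' @param name molecule label.
#' @param mass optional atomic masses (amu); defaults to the standard table.
#' @return An object of class `molecule`: list with `name` and data frame
#'   `atoms` (columns `element`, `x`, `y`, `z`, `mass`).
#' @examples
#' m <- molecule("C", matrix(0, 1, 3), name = "probe")
#' @export
molecule <- function(element, xyz, name = "molecule", mass = atomic_mass(element)) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  if (length(element) < 1L) stop("a molecule needs at least one atom")
  if (nrow(xyz) != length(element)) {
    stop("'xyz' must have one row per element symbol")
  }
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  structure(
    list(name = name,
         atoms = data.frame(element = as.character(element),
                            x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                            mass = mass, stringsAsFactors = FALSE)),
    class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  counts <- table(x$atoms$element)
  formula <- paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
  cat(sprintf("<molecule> %s: %d atoms (%s)\n", x$name, nrow(x$atoms), formula))
  invisible(x)
}

#' Atom coordinates as a matrix
#'
#' @param m a `molecule`.
#' @return n x 3 numeric matrix, Angstrom.
#' @export
coords <- function(m) {
  stopifnot(inherits(m, "molecule"))
  x <- as.matrix(m$atoms[, c("x", "y", "z")])
  dimnames(x) <- NULL
  x
}

#' Number of atoms
#' @param m a `molecule`.
#' @return Integer atom count.
#' @export
n_atoms <- function(m) nrow(m$atoms)

.set_coords <- function(m, xyz) {
  m$atoms$x <- xyz[, 1]
  m$atoms$y <- xyz[, 2]
  m$atoms$z <- xyz[, 3]
  m
}

#' Read a molecule from an SDF/MOL V2000 file
#'
#' Parses the header and atom block of a V2000 connection table. The bond
#' block is ignored: the model treats molecules as rigid point sets. Atom
#' lines are read at the fixed V2000 column positions (coordinates in columns
#' 1-30, element symbol in columns 32-34).
#'
#' @param file path to an SDF or MOL file (first record is read).
#' @param name molecule label; defaults to the SDF title line, or the file
#'   name when the title is empty.
#' @return A [molecule()].
#' @examples
#' sdf <- system.file("extdata", "fluorouracil_synthetic.sdf", package = "nanosorb")
#' read_sdf(sdf)
#' @export
read_sdf <- function(file, name = NULL) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 4L) stop("SDF parse error: fewer than 4 header lines")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  if (is.na(na) || na < 1L) {
    stop("SDF parse error at line 4: malformed counts line '", counts, "'")
  }
  if (length(lines) < 4L + na) {
    stop("SDF parse error: atom block truncated (expected ", na, " atoms)")
  }
  el <- character(na)
  xyz <- matrix(NA_real_, na, 3)
  for (i in seq_len(na)) {
    ln <- lines[4L + i]
    xyz[i, ] <- suppressWarnings(as.numeric(c(
      substr(ln, 1, 10), substr(ln, 11, 20), substr(ln, 21, 30))))
    el[i] <- trimws(substr(ln, 31, 34))
    if (any(is.na(xyz[i, ])) || el[i] == "") {
      stop("SDF parse error at line ", 4L + i, ": malformed atom line")
    }
    if (!el[i] %in% names(.atomic_masses)) {
      stop("SDF parse error at line ", 4L + i, ": unknown element symbol '",
           el[i], "'")
    }
  }
  if (is.null(name)) {
    title <- trimws(lines[1])
    name <- if (nzchar(title)) title else basename(file)
  }
  molecule(el, xyz, name = name)
}

#' Read / write XYZ files
#'
#' Standard XYZ format: atom count line, comment line, then one
#' `element x y z` row per atom. `write_xyz` followed by `read_xyz` is the
#' identity up to floating-point formatting (coordinates are written with six
#' decimals).
#'
#' @param file path.
#' @param m a `molecule` (for writing).
#' @param comment comment line content.
#' @param name molecule label for reading; defaults to the comment line.
#' @return `read_xyz` returns a [molecule()]; `write_xyz` returns `file`
#'   invisibly.
#' @export
read_xyz <- function(file, name = NULL) {
  lines <- readLines(file, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ parse error: empty or truncated file")
  na <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(na) || na < 1L) stop("XYZ parse error: bad atom count line")
  if (length(lines) < 2L + na) {
    stop("XYZ parse error: expected ", na, " atom rows, found ",
         length(lines) - 2L)
  }
  el <- character(na)
  xyz <- matrix(NA_real_, na, 3)
  for (i in seq_len(na)) {
    tok <- strsplit(trimws(lines[2L + i]), "\\s+")[[1]]
    if (length(tok) < 4L) stop("XYZ parse error at line ", 2L + i)
    el[i] <- tok[1]
    xyz[i, ] <- suppressWarnings(as.numeric(tok[2:4]))
    if (any(is.na(xyz[i, ]))) stop("XYZ parse error at line ", 2L + i)
  }
  if (is.null(name)) {
    cm <- trimws(lines[2])
    name <- if (nzchar(cm)) cm else basename(file)
  }
  molecule(el, xyz, name = name)
}

#' @rdname read_xyz
#' @export
write_xyz <- function(m, file, comment = m$name) {
  stopifnot(inherits(m, "molecule"))
  xyz <- coords(m)
  rows <- sprintf("%-3s %14.6f %14.6f %14.6f",
                  m$atoms$element, xyz[, 1], xyz[, 2], xyz[, 3])
  writeLines(c(as.character(n_atoms(m)), comment, rows), file)
  invisible(file)
}

#' Remove counterions from a molecule
#'
#' Drops all chloride atoms (and any other listed counterion elements),
#' preserving the order of the remaining atoms. Salt forms such as methylene
#' blue chloride are modelled as the bare chromophore: the counterion does
#' not participate in the adsorption energy.
#'
#' @param m a `molecule`.
#' @param ions element symbols to strip; default `"Cl"`.
#' @return The stripped `molecule`. Warns if nothing is left.
#' @export
strip_counterions <- function(m, ions = "Cl") {
  stopifnot(inherits(m, "molecule"))
  keep <- !(m$atoms$element %in% ions)
  if (!any(keep)) {
    warning("molecule '", m$name, "' consists only of counterions; ",
            "returning an empty atom set")
  }
  m$atoms <- m$atoms[keep, , drop = FALSE]
  rownames(m$atoms) <- NULL
  m
}

#' Center of mass of a molecule
#'
#' @param m a `molecule` with at least one atom.
#' @return Length-3 numeric vector, Angstrom.
#' @export
center_of_mass <- function(m) {
  stopifnot(inherits(m, "molecule"))
  if (nrow(m$atoms) < 1L) stop("empty molecule has no center of mass")
  w <- m$atoms$mass / sum(m$atoms$mass)
  as.numeric(crossprod(coords(m), w))
}

#' Translate a molecule so its center of mass sits at the origin
#'
#' This is the default position convention: molecules enter the optimizer
#' centered at (0, 0, 0), and rigid poses are measured relative to it.
#'
#' @param m a `molecule`.
#' @return The centered `molecule`.
#' @export
center_molecule <- function(m) {
  com <- center_of_mass(m)
  .set_coords(m, sweep(coords(m), 2, com))
}

#' Total-least-squares plane through the carbon atoms
#'
#' Fits the carbon skeleton only: ring planes are what stack against the
#' carrier, and out-of-plane hydrogens or substituents should not tilt the
#' fit. The normal direction is the smallest principal axis of the centered
#' carbon coordinates; its sign is fixed deterministically (positive z
#' component, falling back to positive x, then positive y).
#'
#' @param m a `molecule` with at least 3 non-collinear carbon atoms.
#' @return List with `point` (carbon centroid) and unit `normal`.
#' @export
carbon_plane_fit <- function(m) {
  stopifnot(inherits(m, "molecule"))
  xc <- coords(m)[m$atoms$element == "C", , drop = FALSE]
  if (nrow(xc) < 3L) {
    stop("carbon plane fit needs >= 3 carbon atoms (found ", nrow(xc), ")")
  }
  ctr <- colMeans(xc)
  sv <- svd(sweep(xc, 2, ctr))
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1)) {
    stop("carbon atoms are collinear: plane fit is degenerate")
  }
  n <- sv$v[, 3]
  s <- if (abs(n[3]) > 1e-12) sign(n[3])
       else if (abs(n[1]) > 1e-12) sign(n[1])
       else sign(n[2])
  list(point = as.numeric(ctr), normal = as.numeric(s * n))
}

#' Resolve a front-atom selector to one atom index
#'
#' Selectors identify the atom the front vector points toward. Accepted
#' forms: an integer atom index; an element symbol (must be unique in the
#' molecule); or a list `list(element =, rule =)` where `rule` is
#' `"unique"` (default), `"nearest_com"` or `"farthest_com"` to disambiguate
#' multiple atoms of that element by distance from the center of mass.
#'
#' @param m a `molecule`.
#' @param selector selector as described above.
#' @return Integer atom index.
#' @export
select_front_atom <- function(m, selector) {
  stopifnot(inherits(m, "molecule"))
  if (is.numeric(selector) && length(selector) == 1L) {
    i <- as.integer(selector)
    if (i < 1L || i > n_atoms(m)) stop("front-atom index out of range")
    return(i)
  }
  if (is.character(selector)) selector <- list(element = selector)
  if (!is.list(selector) || is.null(selector$element)) {
    stop("selector must be an atom index, element symbol, or list(element=, rule=)")
  }
  rule <- if (is.null(selector$rule)) "unique" else selector$rule
  cand <- which(m$atoms$element == selector$element)
  if (length(cand) == 0L) {
    stop("no '", selector$element, "' atom in molecule '", m$name, "'")
  }
  if (length(cand) == 1L) return(cand)
  if (rule == "unique") {
    stop("front-atom selector is ambiguous in '", m$name, "': element ",
         selector$element, " matches atoms ", paste(cand, collapse = ", "),
         "; use rule 'nearest_com'/'farthest_com' or an index")
  }
  com <- center_of_mass(m)
  d <- sqrt(rowSums(sweep(coords(m)[cand, , drop = FALSE], 2, com)^2))
  if (rule == "nearest_com") cand[which.min(d)]
  else if (rule == "farthest_com") cand[which.max(d)]
  else stop("unknown selector rule '", rule, "'")
}

#' Orthonormal molecular frame (front / side / normal vectors)
#'
#' The frame characterizes how a planar molecule is oriented: `normal` is
#' orthogonal to the fitted carbon plane, `front` is the in-plane unit vector
#' from the center of mass toward a designated front atom (projected onto the
#' plane), and `side = normal x front` completes the right-handed triad.
#'
#' @param m a `molecule`.
#' @param front_atom_selector see [select_front_atom()].
#' @return Object of class `molecular_frame`: list with `center_of_mass`,
#'   `front`, `side`, `normal` (all length-3; directions unit length).
#' @export
molecular_frame <- function(m, front_atom_selector) {
  fit <- carbon_plane_fit(m)
  com <- center_of_mass(m)
  idx <- select_front_atom(m, front_atom_selector)
  v <- as.numeric(coords(m)[idx, ]) - com
  v <- v - sum(v * fit$normal) * fit$normal
  nv <- sqrt(sum(v^2))
  if (nv < 1e-10) {
    stop("front atom projects onto the center of mass: front vector undefined")
  }
  front <- v / nv
  side <- .cross3(fit$normal, front)
  structure(list(center_of_mass = com, front = front, side = side,
                 normal = fit$normal),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  cat("<molecular_frame>\n")
  cat(sprintf("  com    %8.4f %8.4f %8.4f\n", x$center_of_mass[1],
              x$center_of_mass[2], x$center_of_mass[3]))
  for (f in c("front", "side", "normal")) {
    cat(sprintf("  %-6s %8.4f %8.4f %8.4f\n", f, x[[f]][1], x[[f]][2], x[[f]][3]))
  }
  invisible(x)
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
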