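#' Default decision-variable bounds for n molecules
#'
#' Each molecule contributes the five variables `(x, y, z, theta_x,
#' theta_y)`. Translations are confined to a `[-box, box]` cube and angles to
#' `[-180, 180]` degrees. For a plane carrier the z lower bound is raised to
#' `z_min` (default +1.5 Angstrom) so centers of mass stay above the sheet; a
#' symmetric box would allow unphysical crossings.
#'
#' @param n number of molecules.
#' @param carrier `NULL`, [plane_carrier()] or [sphere_carrier()].
#' @param box half-width of the translation box, Angstrom.
#' @param z_min plane-system lower bound on the z translation, Angstrom.
#' @return 2 x 5n matrix with rows `lower`, `upper`.
#' @export
default_pose_bounds <- function(n, carrier = NULL, box = 16, z_min = 1.5) {
  lo1 <- c(-box, -box, -box, -180, -180)
  hi1 <- c(box, box, box, 180, 180)
  if (inherits(carrier, "plane_carrier")) lo1[3] <- z_min
  b <- rbind(lower = rep(lo1, n), upper = rep(hi1, n))
  colnames(b) <- paste0(rep(c("x", "y", "z", "theta_x", "theta_y"), n),
                        rep(seq_len(n), each = 5))
  b
}

#' Decode a 5n decision vector into rigid poses
#'
#' Variables are taken in declaration order, `(x, y, z, theta_x, theta_y)`
#' per molecule.
#'
#' @param v numeric vector of length 5n.
#' @return List of n [rigid_pose()] objects.
#' @export
decode_poses <- function(v) {
  if (length(v) %% 5L != 0L) stop("decision vector length must be a multiple of 5")
  lapply(seq_len(length(v) / 5L), function(i) {
    p <- v[(5L * (i - 1L) + 1L):(5L * i)]
    rigid_pose(p[1], p[2], p[3], p[4], p[5])
  })
}

#' Build the pose-energy objective function
#'
#' Returns a pure, deterministic function of the 5n decision vector that
#' decodes the poses, applies them, and evaluates the total system energy
#' (drug-drug double sums plus hybrid continuum carrier terms). At any
#' feasible point the value equals [total_energy()] of the corresponding
#' [system_spec()]. Infeasible geometries -- an atom within `clearance` of
#' (or through) the carrier surface, where the continuum formulas change sign
#' and lose meaning -- return a large penalty that grows with the violation,
#' steering the search back without shaping any feasible basin (the
#' repulsive wall dominates long before the clearance is reached).
#'
#' @param molecules list of `molecule` objects in default placement.
#' @param carrier `NULL`, [plane_carrier()] or [sphere_carrier()].
#' @param lj_table element parameter table.
#' @param clearance infeasibility margin, Angstrom (default 0.2).
#' @return `function(v) -> kcal/mol` with attribute `"n_var"`.
#' @export
build_objective <- function(molecules, carrier = NULL,
                            lj_table = load_lj_table(), clearance = 0.2) {
  if (inherits(molecules, "molecule")) molecules <- list(molecules)
  n <- length(molecules)
  stopifnot(n >= 1L)
  com0 <- do.call(rbind, lapply(molecules, center_of_mass))
  counts <- vapply(molecules, n_atoms, integer(1))
  starts <- c(0L, cumsum(counts))[seq_len(n)]
  xc <- do.call(rbind, lapply(seq_len(n), function(i) {
    sweep(coords(molecules[[i]]), 2, com0[i, ])
  }))
  els <- lapply(molecules, function(m) m$atoms$element)
  pair_a <- pair_b <- numeric(0)
  pair_off <- integer(0)
  if (n >= 2L) {
    idx <- utils::combn(n, 2)
    for (k in seq_len(ncol(idx))) {
      ab <- .pair_constant_matrices(els[[idx[1, k]]], els[[idx[2, k]]], lj_table)
      pair_off <- c(pair_off, length(pair_a))
      pair_a <- c(pair_a, as.numeric(ab$A))
      pair_b <- c(pair_b, as.numeric(ab$B))
    }
  }
  carr_a <- carr_b <- numeric(sum(counts))
  carrier_type <- 0L
  eta <- 0
  radius <- 0
  if (inherits(carrier, "plane_carrier")) {
    carrier_type <- 1L
    eta <- carrier$eta_p
  } else if (inherits(carrier, "sphere_carrier")) {
    carrier_type <- 2L
    eta <- carrier$eta_s
    radius <- carrier$a
  }
  if (carrier_type > 0L) {
    ab <- .carrier_constant_vectors(unlist(els), lj_table)
    carr_a <- ab$A
    carr_b <- ab$B
  }
  nv <- 5L * n

  batch <- function(v) {
    cpp_eval_population(v, xc, starts, counts, com0, pair_a, pair_b,
                        as.integer(pair_off), carr_a, carr_b, carrier_type,
                        eta, radius, clearance)
  }
  obj <- function(v) {
    if (length(v) != nv) {
      stop("decision vector must have length ", nv, " (got ", length(v), ")")
    }
    batch(matrix(v, 1L))[1L]
  }
  attr(obj, "n_var") <- nv
  attr(obj, "batch_eval") <- batch
  obj
}

#' Settings for the evolutionary minimizer
#'
#' Configuration of the single-objective real-coded genetic algorithm
#' (tournament selection, simulated binary crossover, polynomial mutation,
#' elitist mu+lambda survival). Defaults are test-scale; use
#' [ga_settings_production()] for production-scale search matching the published
#' protocol (population 12000-15000, 8000-12000 offspring, 400-600
#' generations).
#'
#' @param bounds 2 x n_var matrix (rows lower, upper), e.g. from
#'   [default_pose_bounds()].
#' @param pop_size population size (>= 2).
#' @param n_offsprings offspring per generation; defaults to `pop_size`.
#' @param n_gen number of generations (>= 1).
#' @param seed RNG seed; every run is fully reproducible given the seed.
#' @param p_crossover per-pair SBX crossover probability.
#' @param eta_crossover SBX distribution index.
#' @param p_mutation per-variable mutation probability; default `1/n_var`.
#' @param eta_mutation polynomial-mutation distribution index.
#' @return Object of class `ga_settings`.
#' @export
ga_settings <- function(bounds, pop_size = 200, n_offsprings = pop_size,
                        n_gen = 150, seed = 1, p_crossover = 0.9,
                        eta_crossover = 15, p_mutation = NULL,
                        eta_mutation = 20) {
  bounds <- as.matrix(bounds)
  if (nrow(bounds) != 2L || any(!is.finite(bounds)) ||
      any(bounds[1, ] >= bounds[2, ])) {
    stop("'bounds' must be a finite 2 x n_var matrix with lower < upper")
  }
  if (pop_size < 2L) stop("'pop_size' must be >= 2")
  if (n_gen < 1L) stop("'n_gen' must be >= 1")
  if (n_offsprings < 2L) stop("'n_offsprings' must be >= 2")
  if (is.null(p_mutation)) p_mutation <- 1 / ncol(bounds)
  structure(list(bounds = bounds, pop_size = as.integer(pop_size),
                 n_offsprings = as.integer(n_offsprings),
                 n_gen = as.integer(n_gen), seed = as.integer(seed),
                 p_crossover = p_crossover, eta_crossover = eta_crossover,
                 p_mutation = p_mutation, eta_mutation = eta_mutation),
            class = "ga_settings")
}

#' @rdname ga_settings
#' @export
ga_settings_production <- function(bounds, seed = 1, pop_size = 12000,
                              n_offsprings = 10000, n_gen = 400) {
  ga_settings(bounds, pop_size = pop_size, n_offsprings = n_offsprings,
              n_gen = n_gen, seed = seed)
}

# simulated binary crossover on parent matrices (rows are individuals)
.sbx <- function(p1, p2, lo, hi, eta, pc) {
  n <- nrow(p1); nv <- ncol(p1)
  u <- matrix(runif(n * nv), n, nv)
  beta <- ifelse(u <= 0.5, (2 * u)^(1 / (eta + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta + 1)))
  act <- (matrix(runif(n * nv), n, nv) <= 0.5) & (runif(n) <= pc)
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  c1[!act] <- p1[!act]
  c2[!act] <- p2[!act]
  list(c1 = c1, c2 = c2)
}

# polynomial mutation on an individual matrix
.poly_mutate <- function(x, lo, hi, eta, pm) {
  n <- nrow(x); nv <- ncol(x)
  u <- matrix(runif(n * nv), n, nv)
  act <- matrix(runif(n * nv) <= pm, n, nv)
  delta <- ifelse(u < 0.5, (2 * u)^(1 / (eta + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta + 1)))
  span <- matrix(hi - lo, n, nv, byrow = TRUE)
  x[act] <- x[act] + (delta * span)[act]
  x
}

.clip_bounds <- function(x, lo, hi) {
  n <- nrow(x); nv <- ncol(x)
  pmin(pmax(x, matrix(lo, n, nv, byrow = TRUE)), matrix(hi, n, nv, byrow = TRUE))
}

.eval_pop <- function(objective, x) {
  batch <- attr(objective, "batch_eval")
  f <- if (is.function(batch)) batch(x)
       else vapply(seq_len(nrow(x)), function(i) objective(x[i, ]), numeric(1))
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1]
    stop("objective returned a non-finite value (", f[bad], ") at x = (",
         paste(signif(x[bad, ], 6), collapse = ", "), ")")
  }
  f
}

#' Minimize an objective with the genetic algorithm (one seed)
#'
#' Elitist real-coded GA: uniform random initialization within bounds, binary
#' tournament selection, simulated binary crossover, polynomial mutation, and
#' mu+lambda truncation survival. The best-so-far energy is recorded after
#' every generation (a non-increasing history), and the whole run is
#' reproducible from `settings$seed`.
#'
#' @param objective function of the decision vector (e.g. from
#'   [build_objective()]).
#' @param settings a [ga_settings()] object.
#' @return Object of class `optimization_result`: list with `best_energy`
#'   (kcal/mol), `best_x`, `best_poses` (decoded [rigid_pose()] list),
#'   `seed`, `history` (best-so-far per generation) and `n_eval`.
#' @export
minimize_single_seed <- function(objective, settings) {
  stopifnot(inherits(settings, "ga_settings"))
  lo <- settings$bounds[1, ]
  hi <- settings$bounds[2, ]
  nv <- length(lo)
  set.seed(settings$seed)
  np <- settings$pop_size
  no <- settings$n_offsprings
  pop <- matrix(runif(np * nv, rep(lo, each = np), rep(hi, each = np)), np, nv)
  f <- .eval_pop(objective, pop)
  history <- numeric(settings$n_gen)
  n_eval <- np
  for (gen in seq_len(settings$n_gen)) {
    n_pairs <- ceiling(no / 2)
    pick <- function(k) {
      i1 <- sample.int(np, k, replace = TRUE)
      i2 <- sample.int(np, k, replace = TRUE)
      ifelse(f[i1] <= f[i2], i1, i2)
    }
    pa <- pop[pick(n_pairs), , drop = FALSE]
    pb <- pop[pick(n_pairs), , drop = FALSE]
    ch <- .sbx(pa, pb, lo, hi, settings$eta_crossover, settings$p_crossover)
    off <- rbind(ch$c1, ch$c2)[seq_len(no), , drop = FALSE]
    off <- .poly_mutate(off, lo, hi, settings$eta_mutation, settings$p_mutation)
    off <- .clip_bounds(off, lo, hi)
    fo <- .eval_pop(objective, off)
    n_eval <- n_eval + no
    all_x <- rbind(pop, off)
    all_f <- c(f, fo)
    keep <- order(all_f)[seq_len(np)]
    pop <- all_x[keep, , drop = FALSE]
    f <- all_f[keep]
    history[gen] <- f[1]
  }
  best <- which.min(f)
  structure(list(best_energy = f[best], best_x = pop[best, ],
                 best_poses = decode_poses(pop[best, ]),
                 seed = settings$seed, history = history, n_eval = n_eval),
            class = "optimization_result")
}

#' @export
print.optimization_result <- function(x, ...) {
  cat(sprintf("<optimization_result> seed %d: E = %.4f kcal/mol (%d evals, %d molecules)\n",
              x$seed, x$best_energy, x$n_eval, length(x$best_poses)))
  invisible(x)
}

#' Independent GA runs over a list of seeds
#'
#' Runs [minimize_single_seed()] once per seed; results are returned in seed
#' order. The published protocol uses 5-12 seeds per system to expose
#' distinct stable configurations.
#'
#' @param objective the objective function.
#' @param settings base [ga_settings()] (its `seed` field is overridden).
#' @param seeds integer vector of seeds, length >= 1.
#' @return List of `optimization_result`, one per seed.
#' @export
multi_seed_search <- function(objective, settings, seeds) {
  stopifnot(length(seeds) >= 1L)
  lapply(seeds, function(s) {
    st <- settings
    st$seed <- as.integer(s)
    minimize_single_seed(objective, st)
  })
}

# TRUE when two configuration records agree within the grouping tolerances.
# Distances and angles are compared after sorting, which quotients both the
# carrier symmetry (descriptors are symmetry-invariant by construction) and
# the permutation of identical molecules. NA descriptors (frameless
# molecules) are skipped.
.records_match <- function(r1, r2, energy_tol, angle_tol, dist_tol) {
  cmp <- function(a, b, tol) {
    a <- sort(a[!is.na(a)]); b <- sort(b[!is.na(b)])
    if (length(a) != length(b)) return(FALSE)
    length(a) == 0L || all(abs(a - b) <= tol)
  }
  fold <- function(x) pmin(x, 180 - x)
  if (abs(r1$energy - r2$energy) > energy_tol) return(FALSE)
  cmp(r1$per_molecule$d_surface, r2$per_molecule$d_surface, dist_tol) &&
    cmp(r1$per_molecule$gamma, r2$per_molecule$gamma, angle_tol) &&
    cmp(r1$pairs$xi, r2$pairs$xi, dist_tol) &&
    cmp(r1$pairs$d, r2$pairs$d, dist_tol) &&
    cmp(fold(r1$pairs$alpha), fold(r2$pairs$alpha), angle_tol) &&
    cmp(r1$pairs$beta, r2$pairs$beta, angle_tol) &&
    cmp(r1$pairs$omega, r2$pairs$omega, angle_tol)
}

#' Group multi-seed results into distinct stable configurations
#'
#' Seeds that land in the same energy basin are merged; distinct basins
#' become separate configurations. Two results belong to the same group when
#' their energies differ by at most `energy_tol` and every geometric
#' descriptor (per-molecule `d_surface`, `gamma`; pairwise `xi`, `d`,
#' `alpha`, `beta`; `omega` on the sphere) agrees within `dist_tol` /
#' `angle_tol`. Descriptors are intrinsically invariant under the carrier
#' symmetry (in-plane motions for the plane, global rotations for the
#' sphere), so raw poses never need to be aligned. Groups are labelled
#' `A`, `B`, ... by ascending representative energy; the labelling is stable
#' under permutation of the input results.
#'
#' @param results list of `optimization_result` (e.g. from
#'   [multi_seed_search()]).
#' @param molecules,carrier,front_selectors system context passed to
#'   [configuration_record()].
#' @param energy_tol energy tolerance, kcal/mol (default 0.1).
#' @param angle_tol angular tolerance, degrees (default 15).
#' @param dist_tol distance tolerance, Angstrom (default 0.3).
#' @return List of `configuration_group` objects: each has `label`,
#'   `members` (results, best first), `representative` (lowest-energy
#'   member) and `record` (its [configuration_record()]).
#' @export
group_configurations <- function(results, molecules, carrier = NULL,
                                 front_selectors = NULL, energy_tol = 0.1,
                                 angle_tol = 15, dist_tol = 0.3) {
  if (inherits(results, "optimization_result")) results <- list(results)
  if (length(results) == 0L) stop("no optimization results to group")
  records <- lapply(results, configuration_record, molecules = molecules,
                    carrier = carrier, front_selectors = front_selectors)
  ord <- order(vapply(results, `[[`, numeric(1), "best_energy"))
  groups <- list()
  for (i in ord) {
    placed <- FALSE
    for (g in seq_along(groups)) {
      if (.records_match(records[[i]], groups[[g]]$record, energy_tol,
                         angle_tol, dist_tol)) {
        groups[[g]]$members <- c(groups[[g]]$members, results[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      groups[[length(groups) + 1L]] <- list(members = results[i],
                                            representative = results[[i]],
                                            record = records[[i]])
    }
  }
  for (g in seq_along(groups)) {
    groups[[g]]$label <- LETTERS[g]
    class(groups[[g]]) <- "configuration_group"
  }
  groups
}

#' @export
print.configuration_group <- function(x, ...) {
  cat(sprintf("<configuration_group %s> E = %.4f kcal/mol, %d seed(s)\n",
              x$label, x$representative$best_energy, length(x$members)))
  invisible(x)
}
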