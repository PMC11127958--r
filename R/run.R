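#' System nomenclature label
#'
#' Builds the `X-NY-A` style label: carrier code (`GP` graphene, `C60`
#' fullerene, omitted for drug-drug-only systems), molecule count, drug
#' code, and an optional configuration letter (omitted when a system has a
#' single stable configuration).
#'
#' @param carrier_code `"GP"`, `"C60"` or `"none"`.
#' @param n number of molecules.
#' @param drug_code e.g. `"FU"`, `"PF"`, `"MB"`.
#' @param group configuration letter, or `NULL`.
#' @return Character label, e.g. `"GP-2MB-A"`.
#' @examples
#' nomenclature("GP", 2, "MB", "A")
#' @export
nomenclature <- function(carrier_code, n, drug_code, group = NULL) {
  stem <- paste0(n, drug_code)
  if (!identical(carrier_code, "none") && nzchar(carrier_code)) {
    stem <- paste(carrier_code, stem, sep = "-")
  }
  if (!is.null(group)) stem <- paste(stem, group, sep = "-")
  stem
}

# fill defaults and validate a run configuration (list, or YAML/JSON path)
.resolve_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  sys <- config$system
  if (is.null(sys) || is.null(sys$drug)) {
    stop("config$system must give at least a drug (name or structure file)")
  }
  sys$carrier <- if (is.null(sys$carrier)) "none" else sys$carrier
  if (!sys$carrier %in% c("none", "GP", "C60")) {
    stop("system$carrier must be one of 'none', 'GP', 'C60'")
  }
  sys$n <- if (is.null(sys$n)) 1L else as.integer(sys$n)
  if (sys$n < 1L) stop("system$n must be >= 1")
  opt <- if (is.null(config$optimizer)) list() else config$optimizer
  preset <- if (is.null(opt$preset)) "test" else opt$preset
  scale <- switch(preset,
    test = list(pop_size = 200, n_offsprings = 200, n_gen = 150),
    production = list(pop_size = 12000, n_offsprings = 10000,
                 n_gen = if (sys$n > 1L) 600 else 400),
    stop("optimizer$preset must be 'test' or 'production'"))
  for (f in names(scale)) if (is.null(opt[[f]])) opt[[f]] <- scale[[f]]
  if (is.null(opt$seeds)) opt$seeds <- 1:5
  opt$preset <- preset
  grp <- if (is.null(config$grouping)) list() else config$grouping
  if (is.null(grp$energy_tol)) grp$energy_tol <- 0.1
  if (is.null(grp$angle_tol)) grp$angle_tol <- 15
  if (is.null(grp$dist_tol)) grp$dist_tol <- 0.3
  list(system = sys, optimizer = opt, grouping = grp,
       lj_table = config$lj_table, outdir = config$outdir)
}

# canonical placement of posed molecules for XYZ export: quotient the carrier
# symmetry so repeated runs are visually comparable.
.canonicalize_posed <- function(posed, carrier, frame1) {
  rot_z <- function(a) matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1),
                              3, 3, byrow = TRUE)
  if (inherits(carrier, "plane_carrier")) {
    shift <- c(frame1$center_of_mass[1], frame1$center_of_mass[2], 0)
    ang <- atan2(frame1$front[2], frame1$front[1])
    r <- rot_z(-ang)
    lapply(posed, function(m) .set_coords(m, sweep(coords(m), 2, shift) %*% t(r)))
  } else if (inherits(carrier, "sphere_carrier")) {
    v <- .unit(frame1$center_of_mass)
    ax <- .cross3(v, c(0, 0, 1))
    s <- sqrt(sum(ax^2))
    r <- if (s < 1e-12) {
      if (v[3] > 0) diag(3) else diag(c(1, -1, -1))
    } else {
      k <- ax / s
      th <- acos(min(1, max(-1, v[3])))
      kx <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3,
                   byrow = TRUE)
      diag(3) + sin(th) * kx + (1 - cos(th)) * (kx %*% kx)
    }
    lapply(posed, function(m) .set_coords(m, coords(m) %*% t(r)))
  } else {
    shift <- frame1$center_of_mass
    lapply(posed, function(m) .set_coords(m, sweep(coords(m), 2, shift)))
  }
}

# one results.csv row for a configuration group
.group_row <- function(g, label, carrier_code) {
  rec <- g$record
  n <- nrow(rec$per_molecule)
  row <- list(label = label, E = rec$energy, n_seeds = length(g$members))
  if (n == 2L) {
    row$d <- rec$pairs$d[1]
    row$xi <- rec$pairs$xi[1]
    row$alpha <- rec$pairs$alpha[1]
    row$beta <- rec$pairs$beta[1]
    row$alignment <- rec$pairs$class[1]
  } else {
    row$d <- NA_real_
    row$xi <- NA_real_
    row$alpha <- NA_real_
    row$beta <- NA_real_
    row$alignment <- NA_character_
  }
  if (carrier_code %in% c("GP", "C60")) {
    pre <- if (carrier_code == "GP") "GP" else "C60"
    for (i in seq_len(n)) {
      row[[sprintf("d_%s_%d", pre, i)]] <- rec$per_molecule$d_surface[i]
      row[[sprintf("gamma_%s_%d", pre, i)]] <- rec$per_molecule$gamma[i]
    }
    if (carrier_code == "C60" && n == 2L) row$omega_C60 <- rec$pairs$omega[1]
  }
  as.data.frame(row, stringsAsFactors = FALSE)
}

#' Run a full adsorption study from a configuration
#'
#' End-to-end driver: loads the drug structure, builds the carrier and the
#' 5n-variable objective, runs the evolutionary search over all requested
#' seeds, groups the results into distinct stable configurations, and writes
#' the run artifacts to the output directory:
#' \describe{
#'   \item{results.csv}{one row per configuration group with the energy and
#'     descriptor columns (`d`, `xi`, `alpha`, `beta`, `d_GP_i` /
#'     `gamma_GP_i` or `d_C60_i` / `gamma_C60_i`, `omega_C60`).}
#'   \item{<label>.xyz}{posed atoms of each group representative, in
#'     canonical placement (first molecule's in-plane position/orientation
#'     quotiented out; sphere systems rotated so molecule 1 sits on +z).}
#'   \item{omega.csv}{pairwise angular separations, sphere systems with
#'     more than two molecules.}
#'   \item{run.json}{resolved configuration, seeds, per-seed energies,
#'     package version.}
#'   \item{run.log}{per-seed best energies, human readable.}
#' }
#'
#' @param config a list, or path to a YAML/JSON file, with entries
#'   `system` (`carrier` = "none"/"GP"/"C60", `drug` = bundled drug name or
#'   SDF/XYZ path, `n` = molecule count), `optimizer` (`preset` =
#'   "test"/"production", optional `pop_size`, `n_offsprings`, `n_gen`,
#'   `seeds`),
#'   `grouping` (optional tolerances), optional `lj_table` path, `outdir`.
#' @param outdir output directory; overrides `config$outdir`.
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with `groups`, `results` (per seed), `table`
#'   (the results.csv data frame) and `files`.
#' @export
run_adsorption <- function(config, outdir = NULL, quiet = FALSE) {
  cfg <- .resolve_run_config(config)
  if (!is.null(outdir)) cfg$outdir <- outdir
  if (is.null(cfg$outdir)) stop("an output directory is required")
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))

  lj_table <- load_lj_table(cfg$lj_table)
  drug <- cfg$system$drug
  if (file.exists(drug)) {
    m <- if (grepl("\\.xyz$", drug, ignore.case = TRUE)) read_xyz(drug)
         else read_sdf(drug)
    m <- center_molecule(suppressWarnings(strip_counterions(m)))
    code <- toupper(tools::file_path_sans_ext(basename(drug)))
    front <- NULL
  } else {
    m <- drug_molecule(drug)
    code <- .drug_code(drug)
    front <- drug_front_selector(drug)
  }
  n <- cfg$system$n
  molecules <- replicate(n, m, simplify = FALSE)
  carrier <- switch(cfg$system$carrier,
                    none = NULL, GP = plane_carrier(), C60 = sphere_carrier())

  bounds <- default_pose_bounds(n, carrier)
  st <- ga_settings(bounds, pop_size = cfg$optimizer$pop_size,
                    n_offsprings = cfg$optimizer$n_offsprings,
                    n_gen = cfg$optimizer$n_gen)
  objective <- build_objective(molecules, carrier, lj_table)
  say("system %s: %d seed(s), pop %d, %d generations",
      nomenclature(cfg$system$carrier, n, code), length(cfg$optimizer$seeds),
      st$pop_size, st$n_gen)
  results <- multi_seed_search(objective, st, cfg$optimizer$seeds)
  for (r in results) say("  seed %d: E = %.4f kcal/mol", r$seed, r$best_energy)

  groups <- group_configurations(results, molecules, carrier, front,
                                 energy_tol = cfg$grouping$energy_tol,
                                 angle_tol = cfg$grouping$angle_tol,
                                 dist_tol = cfg$grouping$dist_tol)
  multi <- length(groups) > 1L
  files <- character(0)

  rows <- NULL
  omega_rows <- NULL
  for (g in groups) {
    label <- nomenclature(cfg$system$carrier, n, code,
                          if (multi) g$label else NULL)
    rows <- rbind(rows, .group_row(g, label, cfg$system$carrier))
    posed <- mapply(apply_pose, molecules, g$representative$best_poses,
                    SIMPLIFY = FALSE)
    f1 <- tryCatch({
      if (is.null(front)) NULL
      else pose_frame(molecular_frame(molecules[[1]], front),
                      g$representative$best_poses[[1]])
    }, error = function(e) NULL)
    if (is.null(f1)) {
      f1 <- list(center_of_mass = center_of_mass(posed[[1]]),
                 front = c(1, 0, 0))
      class(f1) <- "molecular_frame"
    }
    posed <- .canonicalize_posed(posed, carrier, f1)
    all_el <- unlist(lapply(posed, function(p) p$atoms$element))
    all_xyz <- do.call(rbind, lapply(posed, coords))
    xyz_file <- file.path(cfg$outdir, paste0(label, ".xyz"))
    write_xyz(molecule(all_el, all_xyz, name = label), xyz_file,
              comment = sprintf("%s E = %.4f kcal/mol", label,
                                g$representative$best_energy))
    files <- c(files, xyz_file)
    if (inherits(carrier, "sphere_carrier") && n > 2L) {
      pr <- g$record$pairs
      omega_rows <- rbind(omega_rows,
                          data.frame(label = label, m = pr$i, n = pr$j,
                                     omega = pr$omega))
    }
  }
  res_file <- file.path(cfg$outdir, "results.csv")
  utils::write.csv(rows, res_file, row.names = FALSE)
  files <- c(files, res_file)
  if (!is.null(omega_rows)) {
    om_file <- file.path(cfg$outdir, "omega.csv")
    utils::write.csv(omega_rows, om_file, row.names = FALSE)
    files <- c(files, om_file)
  }

  run_file <- file.path(cfg$outdir, "run.json")
  jsonlite::write_json(list(
    config = cfg[c("system", "optimizer", "grouping")],
    lj_table = attr(lj_table, "source"),
    package_version = as.character(utils::packageVersion("nanosorb")),
    seeds = vapply(results, `[[`, integer(1), "seed"),
    seed_energies = vapply(results, `[[`, numeric(1), "best_energy"),
    groups = lapply(groups, function(g) list(
      label = g$label, energy = g$representative$best_energy,
      n_seeds = length(g$members))),
    files = basename(c(files, run_file))
  ), run_file, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files <- c(files, run_file)

  log_file <- file.path(cfg$outdir, "run.log")
  writeLines(c(
    sprintf("system %s", nomenclature(cfg$system$carrier, n, code)),
    sprintf("preset %s: pop %d, offspring %d, generations %d",
            cfg$optimizer$preset, st$pop_size, st$n_offsprings, st$n_gen),
    sprintf("seed %d: E = %.4f kcal/mol",
            vapply(results, `[[`, integer(1), "seed"),
            vapply(results, `[[`, numeric(1), "best_energy")),
    sprintf("group %s: E = %.4f kcal/mol (%d seeds)",
            vapply(groups, `[[`, character(1), "label"),
            vapply(groups, function(g) g$representative$best_energy, numeric(1)),
            vapply(groups, function(g) length(g$members), integer(1)))
  ), log_file)
  files <- c(files, log_file)

  invisible(list(groups = groups, results = results, table = rows,
                 files = files))
}
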