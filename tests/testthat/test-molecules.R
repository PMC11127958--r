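test_that("SDF reader recovers a hand-written fixture exactly", {
  f <- write_tiny_sdf(tempfile(fileext = ".sdf"))
  m <- read_sdf(f)
  expect_s3_class(m, "molecule")
  expect_equal(n_atoms(m), 3L)
  expect_equal(m$atoms$element, c("O", "H", "H"))
  expect_identical(coords(m)[2, 1], 0.96)
  expect_identical(coords(m)[3, ], c(-0.24, 0.93, 0))
  expect_equal(m$atoms$mass, c(15.999, 1.008, 1.008))
})

test_that("SDF reader reports malformed input with line numbers", {
  f <- tempfile(fileext = ".sdf")
  writeLines(c("t", "", "", " xx  0", "junk"), f)
  expect_error(read_sdf(f), "line 4")
  writeLines(c("t", "", "", "  2  0",
               "    0.0000    0.0000    0.0000 C   0",
               "    bad line"), f)
  expect_error(read_sdf(f), "line 6")
  writeLines(c("t", "", "", "  1  0",
               "    0.0000    0.0000    0.0000 Xx  0"), f)
  expect_error(read_sdf(f), "unknown element")
})

test_that("bundled drug structures match the published formulas", {
  fu <- drug_molecule("fluorouracil")
  expect_equal(n_atoms(fu), 12L)
  expect_equal(sort(table(fu$atoms$element)),
               sort(table(c(rep("C", 4), rep("H", 3), "F", rep("N", 2),
                            rep("O", 2)))))
  pf <- drug_molecule("PF")
  expect_equal(n_atoms(pf), 27L)
  expect_equal(sum(pf$atoms$element == "N"), 3L)
  # methylene blue: 39 atoms with the chloride, 38 once stripped
  mb_raw <- drug_molecule("MB", strip_ions = FALSE)
  expect_equal(n_atoms(mb_raw), 39L)
  mb <- drug_molecule("MB")
  expect_equal(n_atoms(mb), 38L)
  expect_false("Cl" %in% mb$atoms$element)
  # loading convention: centered at the center of mass
  expect_equal(center_of_mass(fu), c(0, 0, 0), tolerance = 1e-9)
})

test_that("XYZ round-trips preserve structure", {
  ring <- make_toy_planar_molecule("ring")
  f <- tempfile(fileext = ".xyz")
  write_xyz(ring, f)
  back <- read_xyz(f)
  expect_equal(coords(back), coords(ring), tolerance = 1e-6)
  expect_equal(back$atoms$element, ring$atoms$element)

  fu <- drug_molecule("FU")
  write_xyz(fu, f)
  expect_equal(n_atoms(read_xyz(f)), 12L)

  writeLines(character(0), f)
  expect_error(read_xyz(f), "empty")
  writeLines(c("5", "c", "C 0 0 0"), f)
  expect_error(read_xyz(f), "expected 5")
})

test_that("counterion stripping removes chloride only, preserving order", {
  m <- molecule(c("C", "Cl", "N", "Cl"), matrix(1:12, 4, 3))
  s <- strip_counterions(m)
  expect_equal(s$atoms$element, c("C", "N"))
  expect_equal(coords(s), coords(m)[c(1, 3), ])
  # no-op without chloride
  ring <- make_toy_planar_molecule("ring")
  expect_equal(strip_counterions(ring), ring)
  # all-counterion molecule warns and empties
  expect_warning(empty <- strip_counterions(molecule("Cl", matrix(0, 1, 3))),
                 "counterions")
  expect_equal(nrow(empty$atoms), 0L)
})

test_that("center of mass is mass-weighted and translation-equivariant", {
  single <- molecule("C", matrix(c(1, 2, 3), 1, 3))
  expect_equal(center_of_mass(single), c(1, 2, 3))
  two <- molecule(c("C", "C"), rbind(c(0, 0, 0), c(2, 0, 0)))
  expect_equal(center_of_mass(two), c(1, 0, 0))
  # unequal masses pull the COM toward the heavy atom
  co <- molecule(c("C", "O"), rbind(c(0, 0, 0), c(1, 0, 0)))
  expect_equal(center_of_mass(co)[1], 15.999 / (12.011 + 15.999))
  set.seed(3)
  m <- drug_molecule("FU")
  t <- rnorm(3)
  mt <- molecule(m$atoms$element, sweep(coords(m), 2, -t), name = "t")
  expect_equal(center_of_mass(mt), center_of_mass(m) + t, tolerance = 1e-12)
})

test_that("carbon plane fit is exact, carbon-only, and equivariant", {
  ring <- make_toy_planar_molecule("ring")
  fit <- carbon_plane_fit(ring)
  expect_equal(fit$normal, c(0, 0, 1))
  # residual of an exactly planar set is ~0
  res <- abs(sweep(coords(ring), 2, fit$point) %*% fit$normal)
  expect_lt(max(res), 1e-10)

  # out-of-plane hydrogens do not perturb the fit
  withH <- molecule(c(rep("C", 6), "H", "H"),
                    rbind(coords(ring), c(0, 0, 1.1), c(0.5, 0, -0.9)))
  expect_equal(carbon_plane_fit(withH)$normal, fit$normal)

  set.seed(5)
  for (k in 1:5) {
    r <- random_rotation()
    fit_r <- carbon_plane_fit(rotate_molecule(ring, r))
    target <- as.numeric(r %*% c(0, 0, 1))
    expect_equal(abs(sum(fit_r$normal * target)), 1, tolerance = 1e-9)
  }

  expect_error(carbon_plane_fit(make_toy_planar_molecule("point")), ">= 3")
  collinear <- molecule(rep("C", 3), cbind(1:3, 0, 0))
  expect_error(carbon_plane_fit(collinear), "collinear")
})

test_that("molecular frame is orthonormal and rotates with the molecule", {
  m <- make_toy_planar_molecule("ring", substituent = "F")
  fr <- molecular_frame(m, list(element = "F"))
  g <- rbind(fr$front, fr$side, fr$normal)
  expect_equal(g %*% t(g), diag(3), tolerance = 1e-8)
  # front points from COM toward the substituent (in-plane)
  fpos <- coords(m)[m$atoms$element == "F", ]
  dirv <- fpos - fr$center_of_mass
  expect_gt(sum(fr$front * dirv / sqrt(sum(dirv^2))), 0.999)

  set.seed(9)
  for (k in 1:5) {
    r <- random_rotation()
    fr_r <- molecular_frame(rotate_molecule(m, r), list(element = "F"))
    expect_equal(fr_r$front, as.numeric(r %*% fr$front), tolerance = 1e-8)
    expect_equal(abs(sum(fr_r$normal * (r %*% fr$normal))), 1, tolerance = 1e-8)
  }
})

test_that("frame computations are invariant to atom ordering", {
  m <- drug_molecule("FU")
  set.seed(13)
  perm <- sample(n_atoms(m))
  mp <- molecule(m$atoms$element[perm], coords(m)[perm, ], name = m$name)
  expect_equal(center_of_mass(mp), center_of_mass(m), tolerance = 1e-12)
  f1 <- molecular_frame(m, list(element = "F"))
  f2 <- molecular_frame(mp, list(element = "F"))
  expect_equal(f2$front, f1$front, tolerance = 1e-9)
  expect_equal(abs(sum(f2$normal * f1$normal)), 1, tolerance = 1e-9)
})

test_that("front-atom selectors resolve or fail informatively", {
  pf <- drug_molecule("PF")
  expect_error(select_front_atom(pf, list(element = "N")), "ambiguous")
  i <- select_front_atom(pf, drug_front_selector("PF"))
  expect_equal(pf$atoms$element[i], "N")
  expect_error(select_front_atom(pf, list(element = "F")), "no 'F' atom")
  expect_equal(select_front_atom(pf, 4L), 4L)
  expect_error(select_front_atom(pf, 99L), "out of range")
})
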