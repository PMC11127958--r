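test_that("apply_pose is rigid, with the documented rotation convention", {
  m <- drug_molecule("FU")
  expect_equal(apply_pose(m, rigid_pose()), m)

  p <- rigid_pose(1.5, -2, 3, 0, 0)
  mp <- apply_pose(m, p)
  expect_equal(center_of_mass(mp), center_of_mass(m) + c(1.5, -2, 3),
               tolerance = 1e-12)
  expect_equal(coords(mp), sweep(coords(m), 2, -c(1.5, -2, 3)),
               tolerance = 1e-12)

  # theta_x = 180 flips offsets (dx, dy, dz) -> (dx, -dy, -dz) about the COM
  flip <- apply_pose(m, rigid_pose(theta_x = 180))
  off0 <- sweep(coords(m), 2, center_of_mass(m))
  off1 <- sweep(coords(flip), 2, center_of_mass(flip))
  expect_equal(off1, off0 %*% diag(c(1, -1, -1)), tolerance = 1e-9)

  # rigidity: all interatomic distances preserved
  set.seed(21)
  pr <- rigid_pose(runif(1, -5, 5), runif(1, -5, 5), runif(1, -5, 5),
                   runif(1, -180, 180), runif(1, -180, 180))
  expect_equal(as.numeric(dist(coords(apply_pose(m, pr)))),
               as.numeric(dist(coords(m))), tolerance = 1e-9)
})

test_that("pose rotation order is R_y after R_x", {
  r <- pose_rotation(90, 90)
  # (0,1,0) --Rx(90)--> (0,0,1) --Ry(90)--> (1,0,0)
  expect_equal(as.numeric(r %*% c(0, 1, 0)), c(1, 0, 0), tolerance = 1e-12)
})

test_that("drug-drug energy reduces to the pair law and is symmetric", {
  a <- molecule("C", matrix(0, 1, 3))
  s <- lj_tab$C$sigma
  b <- molecule("C", matrix(c(s, 0, 0), 1, 3))
  expect_equal(drug_drug_energy(a, b, lj_tab), -lj_tab$C$epsilon,
               tolerance = 1e-12)
  # mixed pair at the mixed minimum distance
  h <- molecule("H", matrix(c(0, 0, (lj_tab$C$sigma + lj_tab$H$sigma) / 2),
                            1, 3))
  expect_equal(drug_drug_energy(a, h, lj_tab),
               -sqrt(lj_tab$C$epsilon * lj_tab$H$epsilon), tolerance = 1e-12)

  m1 <- apply_pose(drug_molecule("FU"), rigid_pose(z = 3.4))
  m2 <- apply_pose(drug_molecule("FU"), rigid_pose(x = 1, theta_x = 30))
  expect_equal(drug_drug_energy(m1, m2, lj_tab),
               drug_drug_energy(m2, m1, lj_tab), tolerance = 1e-12)
  expect_error(drug_drug_energy(a, a, lj_tab), "coincident")
})

test_that("drug-plane energy is the per-atom continuum sum", {
  pc <- plane_carrier(eta_gp)
  one <- apply_pose(molecule("C", matrix(0, 1, 3)), rigid_pose(z = 3.4))
  expect_equal(drug_plane_energy(one, pc, lj_tab),
               plane_point_energy(3.4, cc_cc, eta_gp), tolerance = 1e-12)
  # additivity over atoms
  two <- molecule(c("C", "O"), rbind(c(0, 0, 3.0), c(1, 1, 4.2)))
  co <- pair_constants(mix_params(lj_tab$O, lj_tab$C))
  expect_equal(drug_plane_energy(two, pc, lj_tab),
               plane_point_energy(3.0, cc_cc, eta_gp) +
                 plane_point_energy(4.2, co, eta_gp), tolerance = 1e-12)
  below <- molecule("C", matrix(c(0, 0, -1), 1, 3))
  expect_error(drug_plane_energy(below, pc, lj_tab), "below the graphene")
})

test_that("drug-sphere energy is the per-atom continuum sum and decays", {
  sc <- sphere_carrier()
  one <- molecule("C", matrix(c(0, 0, sc$a + 3.2), 1, 3))
  expect_equal(drug_sphere_energy(one, sc, lj_tab),
               sphere_point_energy(sc$a + 3.2, sc$a, cc_cc, sc$eta_s),
               tolerance = 1e-12)
  far <- apply_pose(drug_molecule("FU"), rigid_pose(x = 500))
  expect_lt(abs(drug_sphere_energy(far, sc, lj_tab)), 1e-6)
  inside <- molecule("C", matrix(c(0, 0, 1), 1, 3))
  expect_error(drug_sphere_energy(inside, sc, lj_tab), "inside")
})

test_that("total energy assembles all components and they sum exactly", {
  fu <- drug_molecule("FU")
  # one molecule, no carrier: nothing interacts
  s0 <- system_spec(fu)
  expect_equal(total_energy(s0)$total, 0)

  poses <- list(rigid_pose(z = 3.4), rigid_pose(z = 6.9, theta_x = 20))
  s <- system_spec(list(fu, fu), poses, plane_carrier(eta_gp), lj_tab)
  br <- total_energy(s)
  expect_length(br$drug_drug, 1L)
  expect_length(br$drug_carrier, 2L)
  expect_equal(br$total, sum(br$drug_drug) + sum(br$drug_carrier),
               tolerance = 1e-9)
  posed <- mapply(apply_pose, list(fu, fu), poses, SIMPLIFY = FALSE)
  expect_equal(unname(br$drug_drug[1]),
               drug_drug_energy(posed[[1]], posed[[2]], lj_tab))
  expect_equal(unname(br$drug_carrier[1]),
               drug_plane_energy(posed[[1]], plane_carrier(eta_gp), lj_tab))
})

test_that("plane systems are invariant under common in-plane motions", {
  fu <- drug_molecule("FU")
  pc <- plane_carrier(eta_gp)
  poses <- list(rigid_pose(z = 3.4), rigid_pose(x = 3, z = 3.5, theta_y = 15))
  e0 <- total_energy(system_spec(list(fu, fu), poses, pc, lj_tab))$total
  # common translation in x, y
  shifted <- lapply(poses, function(p) rigid_pose(p$x + 4.2, p$y - 7.7, p$z,
                                                  p$theta_x, p$theta_y))
  e1 <- total_energy(system_spec(list(fu, fu), shifted, pc, lj_tab))$total
  expect_equal(e1, e0, tolerance = 1e-6)
  # common rotation about z: rotate the posed coordinates directly
  ang <- 37 * pi / 180
  rz <- matrix(c(cos(ang), -sin(ang), 0, sin(ang), cos(ang), 0, 0, 0, 1),
               3, 3, byrow = TRUE)
  posed <- mapply(apply_pose, list(fu, fu), poses, SIMPLIFY = FALSE)
  e2 <- sum(vapply(posed, function(m) {
    drug_plane_energy(rotate_molecule(m, rz), pc, lj_tab)
  }, numeric(1))) +
    drug_drug_energy(rotate_molecule(posed[[1]], rz),
                     rotate_molecule(posed[[2]], rz), lj_tab)
  expect_equal(e2, e0, tolerance = 1e-6)
})

test_that("sphere systems are invariant under global rotations", {
  fu <- drug_molecule("FU")
  sc <- sphere_carrier()
  poses <- list(rigid_pose(z = sc$a + 3.3), rigid_pose(x = sc$a + 3.4))
  posed <- mapply(apply_pose, list(fu, fu), poses, SIMPLIFY = FALSE)
  energy_of <- function(ms) {
    sum(vapply(ms, drug_sphere_energy, numeric(1), sc, lj_tab)) +
      drug_drug_energy(ms[[1]], ms[[2]], lj_tab)
  }
  e0 <- energy_of(posed)
  set.seed(31)
  for (k in 1:3) {
    r <- random_rotation()
    expect_equal(energy_of(lapply(posed, rotate_molecule, r = r)), e0,
                 tolerance = 1e-6)
  }
})

test_that("hybrid plane model converges to the discrete lattice sum", {
  patch <- make_lattice_patch(1.42, 30)
  patch_mol <- molecule(rep("C", nrow(patch$atoms)), patch$atoms)
  ring <- apply_pose(make_toy_planar_molecule("ring"), rigid_pose(z = 3.4))
  e_hybrid <- drug_plane_energy(ring, plane_carrier(eta_gp), lj_tab)
  e_discrete <- drug_drug_energy(ring, patch_mol, lj_tab)
  expect_lt(abs(e_discrete - e_hybrid) / abs(e_hybrid), 0.02)
})

test_that("system_spec validates its inputs", {
  fu <- drug_molecule("FU")
  expect_error(system_spec(list(fu, fu), list(rigid_pose())), "per molecule")
  expect_error(system_spec(fu, rigid_pose(), carrier = "GP"), "carrier")
  tiny_tab <- load_lj_table()[c("C")]
  attr(tiny_tab, "source") <- "subset"
  expect_error(system_spec(fu, lj_table = tiny_tab), "no LJ parameters")
})
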