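# stacked pair built from poses, frames transported through the poses
stacked_frames <- function(m, p1, p2, sel = list(element = "F")) {
  f0 <- molecular_frame(m, sel)
  list(f1 = pose_frame(f0, p1), f2 = pose_frame(f0, p2))
}

test_that("a translated copy reports xi = d = h and beta = 0", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  f0 <- molecular_frame(ring, list(element = "F"))
  h <- 3.3
  # translate along the molecule's own normal
  t <- h * f0$normal
  fr2 <- f0
  fr2$center_of_mass <- f0$center_of_mass + t
  pd <- pair_descriptors(frame1 = f0, frame2 = fr2)
  expect_equal(pd$xi, h, tolerance = 1e-10)
  expect_equal(pd$d, h, tolerance = 1e-10)
  expect_equal(pd$beta, 0, tolerance = 1e-8)
  expect_equal(pd$alpha, 0, tolerance = 1e-8)
  expect_equal(classify_alignment(pd), "co_parallel")
  expect_equal(pd$d, pd$xi, tolerance = 1e-12)  # exactly stacked: d = xi
})

test_that("pair descriptors are symmetric in their arguments", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  fs <- stacked_frames(ring, rigid_pose(z = 3), rigid_pose(x = 1, z = 6.4,
                                                           theta_x = 160))
  p12 <- pair_descriptors(frame1 = fs$f1, frame2 = fs$f2)
  p21 <- pair_descriptors(frame1 = fs$f2, frame2 = fs$f1)
  for (f in c("xi", "d", "alpha", "beta")) {
    expect_equal(p12[[f]], p21[[f]], tolerance = 1e-9)
  }
})

test_that("a flipped partner reports alpha near 180", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  fs <- stacked_frames(ring, rigid_pose(z = 3), rigid_pose(z = 6.4,
                                                           theta_x = 180))
  pd <- pair_descriptors(frame1 = fs$f1, frame2 = fs$f2)
  expect_equal(pd$alpha, 180, tolerance = 1e-8)
  expect_equal(pd$d, 3.4, tolerance = 1e-9)
})

test_that("plane carrier descriptors measure height and tilt", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  f0 <- molecular_frame(ring, list(element = "F"))
  flat <- pose_frame(f0, rigid_pose(z = 3))
  cd <- plane_carrier_descriptors(frame = flat)
  expect_equal(cd$d_surface, 3, tolerance = 1e-10)
  expect_equal(cd$gamma, 0, tolerance = 1e-8)
  tilted <- pose_frame(f0, rigid_pose(z = 3, theta_x = 30))
  expect_equal(plane_carrier_descriptors(frame = tilted)$gamma, 30,
               tolerance = 1e-8)
  below <- pose_frame(f0, rigid_pose(z = -3))
  expect_error(plane_carrier_descriptors(frame = below), "above the plane")
})

test_that("sphere carrier descriptors measure clearance, tilt and separation", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  a <- 3.55
  sc <- sphere_carrier(a)
  f0 <- molecular_frame(ring, list(element = "F"))
  top <- pose_frame(f0, rigid_pose(z = a + 3))
  cd <- sphere_carrier_descriptors(frame1 = top, carrier = sc)
  expect_equal(cd$d_surface, 3, tolerance = 1e-10)
  expect_equal(cd$gamma, 0, tolerance = 1e-8)
  expect_true(is.na(cd$omega))
  # second molecule on the same radial direction: omega = 0
  top2 <- pose_frame(f0, rigid_pose(z = a + 6.4))
  cd2 <- sphere_carrier_descriptors(frame1 = top, frame2 = top2, carrier = sc)
  expect_equal(cd2$omega, 0, tolerance = 1e-8)
  side <- pose_frame(f0, rigid_pose(x = a + 3, z = -f0$center_of_mass[3]))
  side$center_of_mass <- c(a + 3, 0, 0)
  cd3 <- sphere_carrier_descriptors(frame1 = top, frame2 = side, carrier = sc)
  expect_equal(cd3$omega, 90, tolerance = 1e-6)
  inside <- pose_frame(f0, rigid_pose(z = 1))
  expect_error(sphere_carrier_descriptors(frame1 = inside, carrier = sc),
               "inside the sphere")
})

test_that("alignment classification matches the published examples", {
  mk <- function(alpha, beta) {
    structure(list(xi = 3.5, d = 3.4, alpha = alpha, beta = beta,
                   beta_folded = min(beta, 180 - beta),
                   front_dot = cos(beta * pi / 180)),
              class = "pair_descriptors")
  }
  # two proflavines: alpha ~ 1, beta ~ 7 -> co-parallel
  expect_equal(classify_alignment(mk(1.007, 7.149)), "co_parallel")
  # two methylene blues: flipped stack, front vectors opposed -> anti-parallel
  expect_equal(classify_alignment(mk(179.867, 180 - 2.264)), "anti_parallel")
  # two fluorouracils: parallel planes, ~82 degree in-plane turn
  expect_equal(classify_alignment(mk(179.059, 82.127)), "orthogonally_parallel")
  # planes not parallel at all
  expect_equal(classify_alignment(mk(90, 10)), "unclassified")
})

test_that("descriptors are invariant under global rigid motions", {
  ring <- make_toy_planar_molecule("ring", substituent = "F")
  f0 <- molecular_frame(ring, list(element = "F"))
  f1 <- pose_frame(f0, rigid_pose(z = 3))
  f2 <- pose_frame(f0, rigid_pose(x = 2, z = 6.1, theta_x = 170))
  pd0 <- pair_descriptors(frame1 = f1, frame2 = f2)
  rot_frame <- function(fr, r) {
    fr$front <- as.numeric(r %*% fr$front)
    fr$side <- as.numeric(r %*% fr$side)
    fr$normal <- as.numeric(r %*% fr$normal)
    fr$center_of_mass <- as.numeric(r %*% fr$center_of_mass)
    fr
  }
  set.seed(41)
  for (k in 1:5) {
    r <- random_rotation()
    pdr <- pair_descriptors(frame1 = rot_frame(f1, r),
                            frame2 = rot_frame(f2, r))
    for (f in c("xi", "d", "alpha", "beta")) {
      expect_equal(pdr[[f]], pd0[[f]], tolerance = 1e-6)
    }
  }
})

test_that("configuration records assemble all applicable descriptors", {
  fu <- drug_molecule("FU")
  sel <- drug_front_selector("FU")
  sc <- sphere_carrier()
  poses <- list(rigid_pose(z = sc$a + 3.2), rigid_pose(x = sc$a + 3.2))
  rec <- configuration_record(poses, list(fu, fu), sc, sel, energy = -15)
  expect_equal(rec$energy, -15)
  expect_equal(nrow(rec$per_molecule), 2L)
  expect_equal(rec$per_molecule$d_surface, c(3.2, 3.2), tolerance = 1e-9)
  expect_equal(rec$pairs$omega[1], 90, tolerance = 1e-9)
  expect_false(is.na(rec$pairs$alpha[1]))
  # frameless molecules keep distances, angles go NA
  pt <- make_toy_planar_molecule("point")
  rec2 <- configuration_record(list(rigid_pose(z = 5), rigid_pose(z = 8)),
                               list(pt, pt), plane_carrier(eta_gp), NULL)
  expect_equal(rec2$pairs$xi[1], 3, tolerance = 1e-12)
  expect_true(is.na(rec2$pairs$alpha[1]))
  expect_true(is.na(rec2$per_molecule$gamma[1]))
})
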