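# shared fixtures: parameter table and frequently used pair constants
lj_tab <- load_lj_table()
cc_cc <- pair_constants(lj_tab$C)
eta_gp <- graphene_surface_density(1.42)
eta_c60 <- sphere_surface_density(60, 3.55)

# hand-written 3-atom V2000 fixture (water-like layout, arbitrary elements)
write_tiny_sdf <- function(path) {
  writeLines(c(
    "tiny",
    "  test",
    "",
    "  3  2  0  0  0  0  0  0  0  0999 V2000",
    "    0.0000    0.0000    0.0000 O   0  0  0  0  0  0  0  0  0  0  0  0",
    "    0.9600    0.0000    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "   -0.2400    0.9300    0.0000 H   0  0  0  0  0  0  0  0  0  0  0  0",
    "  1  2  1  0",
    "  1  3  1  0",
    "M  END",
    "$$$$"
  ), path)
  path
}

# random rigid rotation matrix (uniform via QR), seeded by caller
random_rotation <- function() {
  qr_ <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

rotate_molecule <- function(m, r) {
  xyz <- coords(m) %*% t(r)
  molecule(m$atoms$element, xyz, name = m$name, mass = m$atoms$mass)
}
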