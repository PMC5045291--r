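test_that("structure model validates atoms and assigns standard radii", {
  df <- data.frame(chain = "A", resno = 1L, resname = "ALA",
                   atom_name = c("N", "CA", "O"), element = c("N", "C", "O"),
                   x = c(0, 1.5, 3), y = 0, z = 0)
  m <- structure_model(df)
  expect_equal(m$atoms$radius, c(1.55, 1.70, 1.52))
  expect_error(structure_model(df[0, ]), "empty")
  expect_error(structure_model(rbind(df, df[1, ])), "duplicate")
  df2 <- df; df2$x[1] <- NA
  expect_error(structure_model(df2), "finite")
})

test_that("PDB reading keeps highest-occupancy altloc and drops waters", {
  pdb <- c(
    "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA AALA A   1       1.458   0.000   0.000  0.40 10.00           C",
    "ATOM      3  CA BALA A   1       1.600   0.100   0.000  0.60 10.00           C",
    "ATOM      4  C   ALA A   1       2.009   1.420   0.000  1.00 10.00           C",
    "HETATM    5  O   HOH A 101       9.000   9.000   9.000  1.00 10.00           O",
    "END")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(pdb, f)
  m <- read_structure(f)
  expect_equal(nrow(m$atoms), 3)
  ca <- m$atoms[m$atoms$atom_name == "CA", ]
  expect_equal(ca$x, 1.6)  # occupancy 0.60 conformer wins
  expect_error(read_structure(withr::local_tempfile(fileext = ".pdb")))
})

test_that("SASA matches the closed-form sphere and is additive when separated", {
  one <- structure_model(data.frame(chain = "A", resno = 1L, resname = "X",
                                    atom_name = "CA", element = "C",
                                    x = 0, y = 0, z = 0, radius = 1.7))
  s1 <- sasa(one)
  expect_equal(s1$total, 4 * pi * 3.1^2, tolerance = 1e-9)
  far <- two_atom_model(sep = 10)  # beyond 2 * (1.7 + 1.4)
  expect_equal(sasa(far)$total, 2 * s1$total, tolerance = 1e-9)
  expect_error(sasa(structure_model(one$atoms[0, ])), "empty")
})

test_that("SASA of overlapping spheres matches a dense-lattice oracle within 1%", {
  for (sep in c(2.0, 4.0, 5.5)) {
    m <- two_atom_model(sep)
    coarse <- sasa(m, n_points = 960)$total
    dense <- sasa(m, n_points = 10000)$total
    expect_equal(coarse, dense, tolerance = 0.01)
  }
  # also against the exact two-sphere cap formula: exposed area of each
  # expanded sphere of radius R at center distance d (equal spheres)
  R <- 1.7 + 1.4; d <- 4.0
  exact <- 2 * (4 * pi * R^2 - 2 * pi * R * (R - d / 2))
  expect_equal(sasa(two_atom_model(4.0), n_points = 10000)$total,
               exact, tolerance = 0.01)
})

test_that("SASA is invariant under rigid motion", {
  m <- synthetic_ca_model(25, seed = 61)
  set.seed(62)
  moved <- apply_transform(m, rigid_transform(random_rotation(), rnorm(3, 0, 30)))
  # lattice is fixed in space, so rotation changes the sampling; 1% is the
  # sampling determinism at 960 points
  expect_equal(sasa(moved)$total, sasa(m)$total, tolerance = 0.01)
})

test_that("buried surface area is symmetric and vanishes for separated bodies", {
  a <- synthetic_ca_model(15, seed = 63)
  b <- synthetic_ca_model(15, seed = 64)
  b_far <- apply_transform(b, rigid_transform(diag(3), c(500, 0, 0)))
  out <- buried_surface_area(a, b_far)
  expect_equal(out$delta_total, 0, tolerance = 1e-9)
  # contacting copies bury symmetric area
  b_near <- apply_transform(a, rigid_transform(diag(3), c(4, 0, 0)))
  ab <- buried_surface_area(a, b_near)
  ba <- buried_surface_area(b_near, a)
  expect_equal(ab$delta_total, ba$delta_total, tolerance = 1e-6)
  expect_gt(ab$delta_total, 0)
  expect_equal(ab$delta_half, ab$delta_total / 2)
})

test_that("degenerate superposed copies bury approximately their own surface", {
  a <- synthetic_ca_model(12, seed = 65)
  out <- buried_surface_area(a, a)
  expect_equal(out$delta_total, out$sasa_a, tolerance = 0.01)
})

test_that("rigid transforms validate, compose and preserve distances", {
  expect_error(rigid_transform(matrix(1:9, 3)), "orthonormal")
  refl <- diag(c(-1, 1, 1))
  expect_error(rigid_transform(refl), "determinant")
  m <- synthetic_ca_model(10, seed = 66)
  ident <- apply_transform(m, rigid_transform())
  expect_equal(ident$atoms$x, m$atoms$x)
  shifted <- apply_transform(m, rigid_transform(diag(3), c(1, 2, 3)))
  expect_equal(as.matrix(dist(shifted$atoms[, c("x", "y", "z")])),
               as.matrix(dist(m$atoms[, c("x", "y", "z")])),
               tolerance = 1e-12)
  set.seed(67)
  R <- random_rotation(); t <- rnorm(3)
  fwd <- apply_transform(m, rigid_transform(R, t))
  back <- apply_transform(fwd, rigid_transform(t(R), -as.numeric(t(R) %*% t)))
  expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-9)
})

test_that("Kabsch superposition: zero RMSD on rigid copies, agrees with bio3d", {
  m <- synthetic_ca_model(30, seed = 68)
  expect_equal(superpose_rmsd(m, m)$rmsd, 0, tolerance = 1e-12)
  set.seed(69)
  moved <- apply_transform(m, rigid_transform(random_rotation(), rnorm(3, 0, 10)))
  out <- superpose_rmsd(m, moved)
  expect_equal(out$rmsd, 0, tolerance = 1e-9)
  expect_equal(out$n_atoms, 30)
  # perturbed copy: nonzero RMSD, symmetric in argument order, and equal to
  # the bio3d fit on the same coordinates (independent implementation)
  pert <- moved
  pert$atoms$x <- pert$atoms$x + rnorm(30, 0, 0.8)
  pert$atoms$y <- pert$atoms$y + rnorm(30, 0, 0.8)
  pert$atoms$z <- pert$atoms$z + rnorm(30, 0, 0.8)
  r1 <- superpose_rmsd(m, pert)$rmsd
  r2 <- superpose_rmsd(pert, m)$rmsd
  expect_equal(r1, r2, tolerance = 1e-9)
  xyz_a <- as.numeric(t(as.matrix(m$atoms[, c("x", "y", "z")])))
  xyz_b <- as.numeric(t(as.matrix(pert$atoms[, c("x", "y", "z")])))
  r_bio3d <- bio3d::rmsd(xyz_a, xyz_b, fit = TRUE)  # rounds to 3 decimals
  expect_equal(r1, r_bio3d, tolerance = 1e-3)
  expect_error(superpose_rmsd(m, synthetic_ca_model(30, chain = "B", seed = 70)),
               "fewer than 3")
})

test_that("residue-offset matching aligns shifted numbering", {
  m <- synthetic_ca_model(20, seed = 71)
  shifted <- m
  shifted$atoms$resno <- shifted$atoms$resno + 100L
  expect_error(superpose_rmsd(m, shifted), "fewer than 3")
  expect_equal(superpose_rmsd(m, shifted, offset = -100)$rmsd, 0,
               tolerance = 1e-12)
})

test_that("symmetry mate preserves geometry and respects the operator", {
  m <- synthetic_ca_model(15, seed = 72)
  cell <- c(58.850, 58.830, 97.929, 90, 90, 90)
  # two-fold along c combined with a half-cell translation (tetragonal-type op)
  rot <- matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, byrow = TRUE)
  mate <- symmetry_mate(m, rot, c(0, 0, 0.5), cell)
  expect_equal(as.matrix(dist(mate$atoms[, c("x", "y", "z")])),
               as.matrix(dist(m$atoms[, c("x", "y", "z")])),
               tolerance = 1e-9)
  # identity operator returns the model unchanged
  same <- symmetry_mate(m, diag(3), c(0, 0, 0), cell)
  expect_equal(same$atoms$x, m$atoms$x, tolerance = 1e-12)
  # applying the two-fold twice returns to the original (mod lattice)
  back <- symmetry_mate(mate, rot, c(0, 0, 0.5), cell)
  expect_equal(back$atoms$x, m$atoms$x, tolerance = 1e-9)
  expect_equal(back$atoms$z, m$atoms$z + 97.929, tolerance = 1e-9)
})
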