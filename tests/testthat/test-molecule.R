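test_that("rotation centre is the midpoint of the flagged atoms", {
  m <- rigid_molecule(c("C", "C", "O"),
                      rbind(c(0, 0, 0), c(2, 0, 0), c(1, 1, 0)),
                      center_atoms = c(1, 2))
  expect_equal(rotation_center(m), c(1, 0, 0))

  shifted <- rigid_molecule(m$elements, sweep(m$coords, 2, c(1, -2, 3), "+"),
                            m$center_atoms)
  expect_equal(rotation_center(shifted), c(1, 0, 0) + c(1, -2, 3))

  expect_error(rigid_molecule("C", rbind(c(0, 0, 0)), c(1, 1)), "distinct")
})

test_that("posing preserves the rigid internal geometry", {
  mol <- toy_molecule()
  slab <- build_slab(slab_spec(3.632, n_layers = 1, repeats = c(1, 1)))
  d0 <- dist(mol$coords)
  set.seed(7)
  for (i in 1:10) {
    pose <- c(x = runif(1, -0.5, 0.5), y = runif(1, -0.5, 0.5),
              z = runif(1, 4, 7), alpha = runif(1, -180, 180),
              beta = runif(1, -180, 180), gamma = runif(1, -180, 180))
    cfg <- place_molecule(mol, pose, slab)
    d1 <- dist(cfg$coords[cfg$molecule_atoms, ])
    expect_lt(max(abs(d1 - d0)), 1e-9)
  }
})

test_that("identity pose leaves the molecule unrotated over the origin", {
  mol <- toy_molecule()
  slab <- build_slab(slab_spec(3.632, n_layers = 1, repeats = c(1, 1)))
  cfg <- place_molecule(mol, c(x = 0, y = 0, z = 5, alpha = 0, beta = 0,
                               gamma = 0), slab)
  expected <- sweep(mol$coords, 2, rotation_center(mol))
  expected <- sweep(expected, 2, c(0, 0, slab$top_layer_z + 5), "+")
  expect_equal(cfg$coords[cfg$molecule_atoms, ], expected, tolerance = 1e-12)
})

test_that("a full gamma turn reproduces the unrotated coordinates", {
  mol <- toy_molecule()
  slab <- build_slab(slab_spec(3.632, n_layers = 1, repeats = c(1, 1)))
  p0 <- c(x = 0.1, y = -0.2, z = 5, alpha = 20, beta = -40, gamma = 0)
  p1 <- p0; p1[["gamma"]] <- 360
  c0 <- place_molecule(mol, p0, slab)
  c1 <- place_molecule(mol, p1, slab)
  expect_lt(max(abs(c0$coords - c1$coords)), 1e-9)
})

test_that("lowest atom identifies the bonding species and flips with beta", {
  mol <- toy_molecule()
  slab <- build_slab(slab_spec(3.632, n_layers = 1, repeats = c(1, 1)))
  down <- place_molecule(mol, c(x = 0, y = 0, z = 5, alpha = 0, beta = 0,
                                gamma = 0), slab)
  la <- lowest_atom(down)
  expect_equal(la$element, "O")
  hH <- down$coords[which(down$elements[down$molecule_atoms] == "H"), 3]
  expect_true(all(la$height + down$top_layer_z < hH))

  flipped <- place_molecule(mol, c(x = 0, y = 0, z = 5, alpha = 0,
                                   beta = 180, gamma = 0), slab)
  expect_equal(lowest_atom(flipped)$element, "H")

  # tie in z resolved by lowest atom index
  tie <- rigid_molecule(c("N", "C", "O"),
                        rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 1)),
                        center_atoms = c(1, 3))
  cfg <- place_molecule(tie, c(x = 0, y = 0, z = 5, alpha = 0, beta = 0,
                               gamma = 0), slab)
  expect_equal(lowest_atom(cfg)$element, "N")
  expect_error(lowest_atom(cfg, integer(0)), "empty")
})

test_that("methyl normalization equalizes bond lengths and angles", {
  mol <- ragged_methyl()
  group <- cbind(2, 3:5)
  norm <- methyl_normalize(mol, list(group))

  lens0 <- ch_lengths(mol, 2, 3:5)
  lens1 <- ch_lengths(norm, 2, 3:5)
  expect_equal(stats::sd(lens1), 0, tolerance = 1e-12)
  expect_equal(unique(round(lens1, 12)), round(mean(lens0), 12))

  ang1 <- hch_angles(norm, 2, 3:5)
  expect_lt(diff(range(ang1)), 1e-9)

  # already-uniform group is a fixed point
  again <- methyl_normalize(norm, list(group))
  expect_lt(max(abs(again$coords - norm$coords)), 1e-9)

  expect_error(methyl_normalize(mol, list(matrix(numeric(0), 0, 2))), "empty")
})

test_that("two listed bonds of lengths 1.0 and 1.2 average to 1.1", {
  m <- rigid_molecule(c("C", "C", "H", "H"),
                      rbind(c(0, 0, 1), c(0, 0, 0),
                            c(1.0, 0, 0.0), c(-0.6, 0.971, 0.3) /
                              sqrt(sum(c(-0.6, 0.971, 0.3)^2)) * 1.2),
                      center_atoms = c(1, 2))
  norm <- methyl_normalize(m, list(cbind(2, 3:4)))
  expect_equal(unname(ch_lengths(norm, 2, 3:4)), c(1.1, 1.1), tolerance = 1e-9)
})

test_that("structure deviation metrics have their closed forms", {
  a <- matrix(rnorm(12), 4)
  expect_equal(unname(structure_deviation(a, a, rbind(c(1, 2)))), c(0, 0))

  b <- a; b[2, ] <- b[2, ] + c(0.3, 0, 0)
  expect_equal(structure_deviation(a, b)[["rmsd"]], 0.3 / sqrt(4))

  # symmetric in its arguments
  d1 <- structure_deviation(a, b, rbind(c(1, 2), c(2, 3)))
  d2 <- structure_deviation(b, a, rbind(c(1, 2), c(2, 3)))
  expect_equal(d1, d2)

  # 3-atom chain, one of two listed bonds stretched by 0.1
  c1 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  c2 <- rbind(c(0, 0, 0), c(1, 0, 0), c(2.1, 0, 0))
  d <- structure_deviation(c1, c2, rbind(c(1, 2), c(2, 3)))
  expect_equal(d[["mean_bond_dev"]], 0.05)

  expect_error(structure_deviation(a, a[1:2, ]), "matching")
})

test_that("extended XYZ files round-trip molecules and slabs", {
  mol <- toy_molecule()
  path <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(mol, path)
  back <- read_xyz(path)
  expect_s3_class(back, "rigid_molecule")
  expect_equal(back$elements, mol$elements)
  expect_equal(back$coords, mol$coords, tolerance = 1e-9)
  expect_equal(back$center_atoms, mol$center_atoms)

  slab <- build_slab(slab_spec(3.632, n_layers = 2, repeats = c(2, 1)))
  path2 <- withr::local_tempfile(fileext = ".xyz")
  write_xyz(slab, path2)
  back2 <- read_xyz(path2)
  expect_equal(back2$elements, slab$elements)
  expect_equal(back2$cell, slab$cell, tolerance = 1e-9)
  expect_equal(back2$coords, slab$coords, tolerance = 1e-9)
})
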