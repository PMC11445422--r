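test_that("distance obeys closed-form cases", {
  expect_equal(atom_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  expect_equal(atom_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_error(atom_distance(c(NaN, 0, 0), c(0, 0, 0)), "finite")
})

test_that("torsion matches constructed geometry and an independent oracle", {
  # planar cis and anti
  expect_equal(dihedral_angle(c(1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                              c(1, 0, 0)), 0)
  expect_equal(abs(dihedral_angle(c(-1, 1, 0), c(0, 1, 0), c(0, 0, 0),
                                  c(1, 0, 0))), 180)
  # four points constructed at a prescribed torsion by rotation about the
  # central bond (oracle independent of the NeRF construction)
  withr::local_seed(11)
  for (tau in c(-150, -60, -0.5, 30, 119, 180)) {
    a <- c(1.4, 0.9, 0)
    b <- c(0, 0, 0)
    c_ <- c(1.2, -1.1, 0)
    axis <- (c_ - b) / sqrt(sum((c_ - b)^2))
    # start from a point cis to a, rotate by tau about the b->c axis
    perp <- a - b - sum((a - b) * axis) * axis
    perp <- perp / sqrt(sum(perp^2))
    third <- c(axis[2] * perp[3] - axis[3] * perp[2],
               axis[3] * perp[1] - axis[1] * perp[3],
               axis[1] * perp[2] - axis[2] * perp[1])
    d <- c_ + 1.5 * (cos(tau * pi / 180) * perp + sin(tau * pi / 180) * third)
    expect_equal(dihedral_angle(a, b, c_, d), tau, tolerance = 1e-6)
  }
  # cross-check against bio3d on random quadruples
  for (i in 1:25) {
    pts <- matrix(rnorm(12), 4, 3)
    expect_equal(dihedral_angle(pts[1, ], pts[2, ], pts[3, ], pts[4, ]),
                 bio3d::torsion.xyz(as.numeric(t(pts))),
                 tolerance = 1e-6, ignore_attr = TRUE)
  }
  expect_error(dihedral_angle(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0),
                              c(3, 1, 0)), "collinear")
})

test_that("chi1 recovers the constructed side-chain torsion", {
  for (case in list(list(res = "VAL", chi = -60), list(res = "THR", chi = 60),
                    list(res = "ILE", chi = 175), list(res = "THR", chi = 180))) {
    m <- build_structure(custom_preset(pos203_residue = case$res,
                                       chi1_203 = case$chi, d_203 = 3.4))
    expect_lt(angle_diff(chi1(m, 203), case$chi), 1e-6)
  }
  m <- build_structure(structure_preset("I_like"))
  expect_error(chi1(m, 66), "lacks atom")   # chromophore has no backbone N
})

test_that("rotamer classification partitions (-180, 180] with stated bins", {
  expect_equal(classify_rotamer(-60), "gauche-")
  expect_equal(classify_rotamer(60), "gauche+")
  expect_equal(classify_rotamer(180), "trans")
  expect_equal(classify_rotamer(-120), "gauche-")   # inclusive lower edge
  expect_equal(classify_rotamer(0), "gauche+")
  expect_equal(classify_rotamer(120), "trans")
  grid <- seq(-179.9, 180, by = 0.1)
  labels <- classify_rotamer(grid)
  expect_true(all(labels %in% c("gauche-", "gauche+", "trans")))
  expect_equal(length(labels), length(grid))  # total: one label per angle
})

test_that("hydrogen-bond bins follow the strength scheme", {
  s <- hbond_scheme()
  expect_equal(classify_hbond(2.85, s), "normal")
  expect_equal(classify_hbond(3.24, s), "weak")
  expect_equal(classify_hbond(3.6, s), "none")
  expect_equal(classify_hbond(3.0, s), "normal")  # boundary to stronger class
  expect_equal(classify_hbond(3.5, s), "weak")
  expect_equal(classify_hbond(2.3, s), "clash")
  # symmetric under atom-order swap of the underlying distance
  a <- c(0.3, 1.2, -0.5); b <- c(2.1, 0.4, 0.8)
  expect_identical(classify_hbond(atom_distance(a, b), s),
                   classify_hbond(atom_distance(b, a), s))
})

test_that("Gln222 amide orientation follows the closer amide atom", {
  low_ph <- build_structure(custom_preset(gln222_orientation = "OE1"))
  high_ph <- build_structure(custom_preset(gln222_orientation = "NE2"))
  tie <- build_structure(custom_preset(gln222_orientation = "tie"))
  expect_equal(gln222_orientation(low_ph), "OE1->Ser65")
  expect_equal(gln222_orientation(high_ph), "NE2->Ser65")
  expect_equal(gln222_orientation(tie), "undetermined")
  no_gln <- build_structure(structure_preset("I_like"))
  no_gln$selected$resid[no_gln$selected$resno == 222] <- "LEU"
  expect_error(gln222_orientation(no_gln), "expected GLN or GLU")
})

test_that("distance and torsion are rigid-motion invariant", {
  withr::local_seed(7)
  m <- build_structure(structure_preset("I_like"))
  r0 <- measure_geometry(m)
  for (i in 1:10) {
    rot <- random_rotation()
    shift <- rnorm(3, sd = 5)
    mt <- transform_model(m, rot, shift)
    rt <- measure_geometry(mt)
    expect_equal(rt$d_his, r0$d_his, tolerance = 1e-9)
    expect_equal(rt$d_203, r0$d_203, tolerance = 1e-9)
    expect_lt(angle_diff(rt$chi1_203, r0$chi1_203), 1e-6)
  }
})

test_that("measure fills the full geometry report", {
  m <- build_structure(structure_preset("I_like"))
  r <- measure_geometry(m)
  expect_equal(r$d_his, 2.85, tolerance = 1e-6)
  expect_equal(r$d_203, 3.6, tolerance = 1e-6)
  expect_equal(r$d_wat3, 2.7, tolerance = 1e-6)
  expect_false(is.na(r$d_val_cz))           # Val203 fixture has the CG1-CZ contact
  expect_equal(r$rotamer_203, "gauche-")
  expect_equal(r$gln222_orientation, "NE2->Ser65")
  expect_true(all(r$hbond_list$distance > 0))
  expect_true(all(r$hbond_list$class %in%
                    c("normal", "weak", "none", "clash")))
  # every listed H bond within the no-bond threshold of its scheme
  hb <- r$hbond_list[r$hbond_list$class %in% c("normal", "weak"), ]
  expect_true(all(hb$distance <= r$scheme$weak_max))

  # no water -> d_wat3 absent, everything else present
  dry <- measure_geometry(build_structure(custom_preset(include_wat3 = FALSE)))
  expect_true(is.na(dry$d_wat3))
  expect_false(is.na(dry$d_his))

  # Thr203 -> no Val contact column
  thr <- measure_geometry(build_structure(
    custom_preset(pos203_residue = "THR", d_203 = 2.8, chi1_203 = 60)))
  expect_true(is.na(thr$d_val_cz))
  expect_equal(thr$pos203_element, "O")

  # serialization carries the descriptor columns
  tab <- geometry_table(r)
  expect_named(tab, c("structure_id", "d_his", "sigma_his", "d_203",
                      "sigma_203", "d_wat3", "d_val_cz", "chi1_203",
                      "rotamer_203", "gln222_orientation"))
})
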