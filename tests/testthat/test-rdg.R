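bohr <- 1 / 0.529177210903  # bohr per angstrom
single_exp <- function() {
  density_model(data.frame(element = "X", x = 0, y = 0, z = 0, name = "X1"),
                params = data.frame(element = "X", c = 1, zeta = 0.5))
}

test_that("promolecular density matches closed forms", {
  m <- single_exp()
  # rho at 2 bohr for c = 1, zeta = 0.5 is e^-4
  ev <- promolecular_density(m, c(2 / bohr, 0, 0))
  expect_equal(ev$rho, exp(-4), tolerance = 1e-12)
  # spherical symmetry
  ev_y <- promolecular_density(m, c(0, 2 / bohr, 0))
  expect_equal(ev_y$rho, ev$rho, tolerance = 1e-12)
  # gradient magnitude rho/zeta pointing outward
  expect_equal(ev$gradient, c(-exp(-4) / 0.5, 0, 0), tolerance = 1e-10)
  # gradient vanishes at the midpoint of two identical atoms
  pair <- density_model(
    data.frame(element = c("X", "X"), x = c(0, 2), y = 0, z = 0),
    params = data.frame(element = "X", c = 1, zeta = 0.5))
  mid <- promolecular_density(pair, c(1, 0, 0))
  expect_equal(max(abs(mid$gradient)), 0, tolerance = 1e-12)
  expect_error(density_model(data.frame(element = "ZZ", x = 0, y = 0, z = 0)),
               "no density parameters")
})

test_that("hessians agree with a finite-difference oracle", {
  m <- build_density_fixture("hbond_triplet")
  h <- 1e-5
  for (pt in list(c(1.7, 0.3, -0.2), c(0.5, 1.0, 0.4))) {
    analytic <- promolecular_density(m, pt)$hessian
    num <- matrix(0, 3, 3)
    for (i in 1:3) {
      ei <- numeric(3); ei[i] <- h
      gp <- promolecular_density(m, pt + ei)$gradient
      gm <- promolecular_density(m, pt - ei)$gradient
      num[i, ] <- (gp - gm) / (2 * h) / bohr  # d/d(angstrom) -> d/d(bohr)
    }
    expect_equal(analytic, (num + t(num)) / 2, tolerance = 1e-5)
  }
})

test_that("reduced gradient obeys its defining relations", {
  expect_equal(reduced_gradient(0.3, 0), 0)
  expect_equal(reduced_gradient(0.02, 2 * 0.014),
               2 * reduced_gradient(0.02, 0.014))
  # single-exponential closed form: s = rho^(-1/3) / (2 k zeta) with
  # |grad rho| = rho / zeta and k = (3 pi^2)^(1/3)
  k <- (3 * pi^2)^(1 / 3)
  m <- single_exp()
  ev <- promolecular_density(m, c(1.2 / bohr, 0, 0))
  s <- reduced_gradient(ev$rho, sqrt(sum(ev$gradient^2)))
  expect_equal(s, ev$rho^(-1 / 3) / (2 * k * 0.5), tolerance = 1e-10)
  expect_error(reduced_gradient(-0.1, 0.2), "positive")
})

test_that("sign(lambda2) rho follows the middle Hessian eigenvalue", {
  expect_equal(signed_density(diag(c(-2, -1, 3)), 0.01), -0.01)
  expect_equal(signed_density(diag(c(-2, 1, 3)), 0.01), 0.01)
  expect_equal(signed_density(diag(c(-1, 0, 2)), 0.01), 0.01)  # sign(0) = +1
  expect_error(signed_density(matrix(c(0, 1, 0, 0, 0, 0, 0, 0, 0), 3, 3),
                              0.01), "symmetric")
  # vectorized eigenvalues agree with base eigen and stay ordered
  withr::local_seed(8)
  for (i in 1:50) {
    a <- matrix(rnorm(9), 3, 3); sym <- (a + t(a)) / 2
    mine <- gfpstate:::eigvals_sym3(matrix(
      c(sym[1, 1], sym[2, 2], sym[3, 3], sym[1, 2], sym[1, 3], sym[2, 3]),
      1, 6))
    ref <- sort(eigen(sym, symmetric = TRUE, only.values = TRUE)$values)
    expect_equal(as.numeric(mine), ref, tolerance = 1e-9)
    expect_true(all(diff(as.numeric(mine)) >= -1e-12))
  }
  # negative signed density at an H-bond midpoint (density concentrated
  # along the bond axis), via numeric field evaluation
  m <- build_density_fixture("hbond_triplet")
  saddle <- promolecular_density(m, c(1.75, 0, 0))
  expect_lt(signed_density(saddle$hessian, saddle$rho), 0)
})

test_that("grid s values match the analytic closed form", {
  m <- single_exp()
  field <- nci_scan(m, region = rbind(c(-1.5, -1.5, -1.5), c(1.5, 1.5, 1.5)),
                    spacing = 0.25)
  k <- (3 * pi^2)^(1 / 3)
  pts <- expand.grid(x = field$axes[[1]], y = field$axes[[2]],
                     z = field$axes[[3]])
  r <- sqrt(pts$x^2 + pts$y^2 + pts$z^2)
  keep <- r > 0.05   # exclude the nuclear cusp guard zone
  rho_ref <- exp(-r / 0.5)
  s_ref <- rho_ref^(-1 / 3) / (2 * k * 0.5)
  expect_lt(max(abs(as.numeric(field$s)[keep] - s_ref[keep])), 1e-6)
  expect_true(all(field$s >= 0))
})

test_that("the field transforms correctly and ignores atom order", {
  m <- build_density_fixture("hbond_triplet")
  f1 <- nci_scan(m, spacing = 0.4)
  # permuting atoms leaves the field identical
  perm <- density_model(m$atoms[c(3, 1, 2), ], m$params)
  f2 <- nci_scan(perm, spacing = 0.4)
  expect_identical(f1$s, f2$s)
  expect_identical(f1$signed_rho, f2$signed_rho)
  # rigid rotation: s at rotated points equals s at original points
  withr::local_seed(21)
  rot <- random_rotation()
  pts <- matrix(runif(30, -1, 3), 10, 3)
  ev0 <- gfpstate:::eval_density(m, pts)
  atoms_r <- m$atoms
  xyz_r <- t(rot %*% t(as.matrix(m$atoms[, c("x", "y", "z")])))
  atoms_r$x <- xyz_r[, 1]; atoms_r$y <- xyz_r[, 2]; atoms_r$z <- xyz_r[, 3]
  mr <- density_model(atoms_r, m$params)
  ev1 <- gfpstate:::eval_density(mr, t(rot %*% t(pts)))
  s0 <- reduced_gradient(ev0$rho, sqrt(rowSums(ev0$grad^2)))
  s1 <- reduced_gradient(ev1$rho, sqrt(rowSums(ev1$grad^2)))
  expect_equal(s1, s0, tolerance = 1e-8)
})

test_that("fixtures yield the expected interaction clusters", {
  hb <- nci_scan(build_density_fixture("hbond_triplet"))
  expect_gte(nrow(hb$summary), 1L)
  expect_true("attraction" %in% hb$summary$class)
  att <- hb$summary[hb$summary$class == "attraction", ][1, ]
  expect_lt(att$signed_rho, -0.01)
  expect_true(grepl("H1", att$atom_pair) && grepl("O1", att$atom_pair))

  vdw <- nci_scan(build_density_fixture("vdw_pair"))
  expect_gte(nrow(vdw$summary), 1L)
  expect_true("weak" %in% vdw$summary$class)
  # s = 0 exactly at the midplane saddle of the symmetric pair
  expect_lt(min(vdw$summary$min_s), 1e-10)

  lone <- nci_scan(build_density_fixture("single_atom"))
  expect_equal(nrow(lone$summary), 0L)

  # resource guard
  expect_error(nci_scan(build_density_fixture("hbond_triplet"),
                        spacing = 0.01), "max_cells")
})

test_that("cube files carry the grid in standard layout", {
  f <- nci_scan(build_density_fixture("vdw_pair"), spacing = 0.5)
  path <- withr::local_tempfile(fileext = ".cube")
  write_cube(f, path, "s")
  lines <- readLines(path)
  natoms <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]][1])
  expect_equal(natoms, 2L)
  counts <- vapply(4:6, function(i) {
    as.integer(strsplit(trimws(lines[i]), "\\s+")[[1]][1])
  }, integer(1))
  expect_equal(counts, unname(f$dims))
  vals <- as.numeric(unlist(lapply(lines[-(1:(6 + natoms))], function(l) {
    regmatches(l, gregexpr("[-+0-9.Ee]+", l))[[1]]
  })))
  expect_equal(length(vals), prod(f$dims))
  # z runs fastest in cube order
  expect_equal(vals[1:f$dims[3]], as.numeric(f$s[1, 1, ]),
               tolerance = 1e-4)
})
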