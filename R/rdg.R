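# Promolecular electron densities, the reduced density gradient s(r),
# sign(lambda2)*rho, grid scans and Gaussian cube output for
# non-covalent interaction (NCI) analysis.

BOHR_PER_ANGSTROM <- 1 / 0.529177210903

#' Promolecular atomic density parameters
#'
#' Each element's spherically averaged electron density is modelled as a
#' sum of exponentials `rho(r) = sum_j c_j exp(-r / zeta_j)` in atomic
#' units (r in bohr, rho in e/bohr^3). Amplitudes are normalized so each
#' term integrates to its assigned electron count
#' (`integral = 8 pi c zeta^3`). Decay lengths: the valence term uses the
#' asymptotic density decay set by the first ionization energy,
#' `zeta = 1 / (2 sqrt(2 I))`, which reproduces the physically relevant
#' density tail in the non-covalent region; the core term uses the
#' hydrogenic `1 / (2 Z)`. Hydrogen is the exact ground-state H atom,
#' `rho = exp(-2 r) / pi`.
#'
#' @return data.frame with columns `element`, `c` (e/bohr^3), `zeta`
#'   (bohr).
#' @export
promolecular_params <- function() {
  term <- function(element, n_electrons, zeta) {
    data.frame(element = element, c = n_electrons / (8 * pi * zeta^3),
               zeta = zeta, stringsAsFactors = FALSE)
  }
  # first ionization energies in hartree
  ip <- c(C = 0.41380, N = 0.53412, O = 0.50045, S = 0.38073, NE = 0.79248)
  zval <- 1 / (2 * sqrt(2 * ip))
  rbind(
    data.frame(element = "H", c = 1 / pi, zeta = 0.5),
    term("C", 2, 1 / 12), term("C", 4, zval[["C"]]),
    term("N", 2, 1 / 14), term("N", 5, zval[["N"]]),
    term("O", 2, 1 / 16), term("O", 6, zval[["O"]]),
    term("NE", 2, 1 / 20), term("NE", 8, zval[["NE"]]),
    term("S", 10, 1 / 32), term("S", 6, zval[["S"]])
  )
}

#' Construct a promolecular density model
#'
#' @param atoms data.frame with columns `element` and `x`, `y`, `z`
#'   (angstrom). An optional `name` column labels atoms in interaction
#'   summaries.
#' @param params Radial density parameter table
#'   (default [promolecular_params()]); custom single-exponential
#'   elements may be supplied for analytic checks.
#' @return Object of class `density_model`.
#' @export
density_model <- function(atoms, params = promolecular_params()) {
  atoms <- as.data.frame(atoms)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  atoms$element <- toupper(atoms$element)
  unknown <- setdiff(unique(atoms$element), unique(params$element))
  if (length(unknown)) {
    stop("no density parameters for element(s): ",
         paste(unknown, collapse = ", "))
  }
  if (!"name" %in% names(atoms)) {
    atoms$name <- paste0(atoms$element, seq_len(nrow(atoms)))
  }
  # canonical atom order makes field evaluation (a sequential sum over
  # atoms) bit-identical under input permutation
  ord <- order(atoms$element, atoms$x, atoms$y, atoms$z, atoms$name)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(atoms = atoms, params = params), class = "density_model")
}

# Vectorized evaluation over a matrix of points (angstrom).
# Returns rho (n), grad (n x 3) and the six unique Hessian components
# (n x 6: xx, yy, zz, xy, xz, yz), all in atomic units.
eval_density <- function(model, points, want_derivatives = TRUE) {
  pts <- as.matrix(points) * BOHR_PER_ANGSTROM
  n <- nrow(pts)
  rho <- numeric(n)
  grad <- if (want_derivatives) matrix(0, n, 3) else NULL
  hess <- if (want_derivatives) matrix(0, n, 6) else NULL
  atoms <- model$atoms
  params <- model$params
  for (i in seq_len(nrow(atoms))) {
    dx <- pts[, 1] - atoms$x[i] * BOHR_PER_ANGSTROM
    dy <- pts[, 2] - atoms$y[i] * BOHR_PER_ANGSTROM
    dz <- pts[, 3] - atoms$z[i] * BOHR_PER_ANGSTROM
    r2 <- dx * dx + dy * dy + dz * dz
    r <- sqrt(r2)
    safe_r <- pmax(r, 1e-10)
    terms <- params[params$element == atoms$element[i], , drop = FALSE]
    for (j in seq_len(nrow(terms))) {
      cc <- terms$c[j]
      zz <- terms$zeta[j]
      rho_t <- cc * exp(-r / zz)
      rho <- rho + rho_t
      if (!want_derivatives) next
      # d rho / dr = -rho_t / zeta; radial 2nd derivative rho_t / zeta^2
      dr <- -rho_t / zz
      slope <- dr / safe_r                 # (1/r) d rho/dr
      grad[, 1] <- grad[, 1] + slope * dx
      grad[, 2] <- grad[, 2] + slope * dy
      grad[, 3] <- grad[, 3] + slope * dz
      a_minus_b <- rho_t / zz^2 - slope    # (rho'' - rho'/r)
      ux <- dx / safe_r; uy <- dy / safe_r; uz <- dz / safe_r
      hess[, 1] <- hess[, 1] + slope + a_minus_b * ux * ux
      hess[, 2] <- hess[, 2] + slope + a_minus_b * uy * uy
      hess[, 3] <- hess[, 3] + slope + a_minus_b * uz * uz
      hess[, 4] <- hess[, 4] + a_minus_b * ux * uy
      hess[, 5] <- hess[, 5] + a_minus_b * ux * uz
      hess[, 6] <- hess[, 6] + a_minus_b * uy * uz
    }
  }
  list(rho = rho, grad = grad, hess = hess)
}

#' Evaluate the promolecular density at one point
#'
#' @param model A `density_model`.
#' @param point Numeric 3-vector, angstrom.
#' @return List with `rho` (e/bohr^3), `gradient` (3-vector, a.u.) and
#'   `hessian` (symmetric 3x3, a.u.).
#' @export
promolecular_density <- function(model, point) {
  stopifnot(is.numeric(point), length(point) == 3L, all(is.finite(point)))
  ev <- eval_density(model, matrix(point, 1, 3))
  h <- ev$hess[1, ]
  hessian <- matrix(c(h[1], h[4], h[5],
                      h[4], h[2], h[6],
                      h[5], h[6], h[3]), 3, 3)
  list(rho = ev$rho[1], gradient = ev$grad[1, ], hessian = hessian)
}

#' Reduced density gradient
#'
#' `s = |grad rho| / (2 (3 pi^2)^(1/3) rho^(4/3))`, dimensionless.
#'
#' @param rho Density value(s), > 0 (a.u.).
#' @param gradient_norm |grad rho| (a.u.).
#' @return s value(s).
#' @export
reduced_gradient <- function(rho, gradient_norm) {
  if (any(rho <= 0)) stop("rho must be positive")
  gradient_norm / (2 * (3 * pi^2)^(1 / 3) * rho^(4 / 3))
}

# Vectorized eigenvalues of symmetric 3x3 matrices given the six unique
# components (columns xx, yy, zz, xy, xz, yz). Returns an n x 3 matrix
# sorted ascending. Analytic (trigonometric) method.
eigvals_sym3 <- function(h) {
  xx <- h[, 1]; yy <- h[, 2]; zz <- h[, 3]
  xy <- h[, 4]; xz <- h[, 5]; yz <- h[, 6]
  p1 <- xy^2 + xz^2 + yz^2
  q <- (xx + yy + zz) / 3
  p2 <- (xx - q)^2 + (yy - q)^2 + (zz - q)^2 + 2 * p1
  p <- sqrt(pmax(p2, 0) / 6)
  out <- matrix(0, length(xx), 3)
  degen <- p < 1e-300
  out[degen, ] <- cbind(xx, yy, zz)[degen, , drop = FALSE]
  if (any(degen)) {
    out[degen, ] <- t(apply(out[degen, , drop = FALSE], 1, sort))
  }
  idx <- which(!degen)
  if (length(idx)) {
    bxx <- (xx[idx] - q[idx]) / p[idx]
    byy <- (yy[idx] - q[idx]) / p[idx]
    bzz <- (zz[idx] - q[idx]) / p[idx]
    bxy <- xy[idx] / p[idx]; bxz <- xz[idx] / p[idx]; byz <- yz[idx] / p[idx]
    detb <- bxx * (byy * bzz - byz^2) -
      bxy * (bxy * bzz - byz * bxz) +
      bxz * (bxy * byz - byy * bxz)
    r <- pmin(pmax(detb / 2, -1), 1)
    phi <- acos(r) / 3
    e1 <- q[idx] + 2 * p[idx] * cos(phi)                 # largest
    e3 <- q[idx] + 2 * p[idx] * cos(phi + 2 * pi / 3)    # smallest
    e2 <- 3 * q[idx] - e1 - e3
    out[idx, ] <- cbind(e3, e2, e1)
  }
  out
}

#' Density signed by the second Hessian eigenvalue
#'
#' Sorts the eigenvalues of the density Hessian ascending
#' (lambda1 <= lambda2 <= lambda3) and returns `sign(lambda2) * rho`;
#' `sign(0)` is taken as +1. Negative values mark attractive (bonding)
#' interactions, positive values steric repulsion.
#'
#' @param hessian Symmetric 3x3 matrix (a.u.).
#' @param rho Density at the same point (a.u.).
#' @param tol Symmetry tolerance.
#' @return `sign(lambda2) * rho`.
#' @export
signed_density <- function(hessian, rho, tol = 1e-8) {
  stopifnot(is.matrix(hessian), all(dim(hessian) == c(3L, 3L)))
  if (max(abs(hessian - t(hessian))) > tol * max(1, max(abs(hessian)))) {
    stop("hessian is not symmetric within tolerance")
  }
  ev <- sort(eigen(hessian, symmetric = TRUE, only.values = TRUE)$values)
  lambda2 <- ev[2]
  s <- if (lambda2 < 0) -1 else 1
  s * rho
}

#' Scan the reduced density gradient on a grid
#'
#' Evaluates rho, s(r) and sign(lambda2)*rho on a regular grid covering
#' the model's atoms (or an explicit region), then identifies connected
#' low-s regions below the isosurface level and outside the covalent
#' density regime, the grid operation behind an NCI isosurface picture.
#' Each cluster is classified by sign(lambda2)*rho at its minimum-s
#' voxel: `attraction` below `-attract_thresh`, `repulsion` above
#' `+attract_thresh`, `weak` in between; and labelled with the two
#' nearest atoms.
#'
#' The grid is center-aligned so that the midpoint of the atom set lies
#' on a grid point (symmetric fixtures then sample their critical point
#' exactly).
#'
#' @param model A `density_model`.
#' @param region Optional 2x3 matrix (rows = min, max corner, angstrom);
#'   default is the atom bounding box padded by `pad`.
#' @param spacing Grid spacing in bohr (default 0.15).
#' @param pad Box padding in angstrom (default 2).
#' @param s_iso Reduced-gradient isosurface level (default 0.4).
#' @param rho_cutoff Density cutoff excluding covalent regions
#'   (default 0.05 a.u.).
#' @param attract_thresh Color-class threshold on sign(lambda2)*rho
#'   (default 0.01 a.u.).
#' @param max_cells Resource guard on the grid size (default 2e6).
#' @return Object of class `rdg_field`: grid geometry (`origin` in bohr,
#'   `spacing`, `dims`), arrays `rho`, `s`, `signed_rho` (3-d arrays,
#'   x fastest), the `summary` data.frame of interaction clusters, and
#'   the thresholds used.
#' @export
nci_scan <- function(model, region = NULL, spacing = 0.15, pad = 2,
                     s_iso = 0.4, rho_cutoff = 0.05, attract_thresh = 0.01,
                     max_cells = 2e6) {
  stopifnot(inherits(model, "density_model"), spacing > 0)
  atoms <- model$atoms
  if (is.null(region)) {
    region <- rbind(apply(atoms[, c("x", "y", "z")], 2, min) - pad,
                    apply(atoms[, c("x", "y", "z")], 2, max) + pad)
  }
  region <- as.matrix(region)
  if (any(region[2, ] <= region[1, ])) stop("empty scan region")
  center <- colMeans(region) * BOHR_PER_ANGSTROM
  half <- (region[2, ] - region[1, ]) / 2 * BOHR_PER_ANGSTROM
  k <- ceiling(half / spacing)
  axes <- lapply(1:3, function(d) center[d] + spacing * seq(-k[d], k[d]))
  dims <- lengths(axes)
  ncells <- prod(dims)
  if (ncells > max_cells) {
    stop("grid of ", ncells, " cells exceeds max_cells = ", max_cells,
         "; increase spacing or shrink the region")
  }
  # grid points in angstrom, x fastest
  pts <- cbind(
    rep(axes[[1]], times = dims[2] * dims[3]),
    rep(rep(axes[[2]], each = dims[1]), times = dims[3]),
    rep(axes[[3]], each = dims[1] * dims[2])
  ) / BOHR_PER_ANGSTROM

  rho <- numeric(ncells)
  s <- numeric(ncells)
  signed <- numeric(ncells)
  chunk <- 250000L
  for (start in seq(1L, ncells, by = chunk)) {
    idx <- start:min(start + chunk - 1L, ncells)
    ev <- eval_density(model, pts[idx, , drop = FALSE])
    gnorm <- sqrt(rowSums(ev$grad^2))
    rho[idx] <- ev$rho
    s[idx] <- reduced_gradient(ev$rho, gnorm)
    lam <- eigvals_sym3(ev$hess)
    signed[idx] <- ifelse(lam[, 2] < 0, -1, 1) * ev$rho
  }

  mask <- s <= s_iso & rho < rho_cutoff
  labels <- label_components(mask, dims)
  nclust <- max(labels, 0L)
  summary <- if (nclust > 0) {
    rows <- lapply(seq_len(nclust), function(cl) {
      members <- which(labels == cl)
      best <- members[which.min(s[members])]
      pt <- pts[best, ]
      dists <- sqrt((atoms$x - pt[1])^2 + (atoms$y - pt[2])^2 +
                      (atoms$z - pt[3])^2)
      near <- order(dists)[1:min(2, nrow(atoms))]
      sr <- signed[best]
      cls <- if (sr < -attract_thresh) "attraction"
             else if (sr > attract_thresh) "repulsion" else "weak"
      data.frame(cluster = cl, n_voxels = length(members),
                 min_s = s[best], signed_rho = sr, class = cls,
                 atom_pair = paste(atoms$name[near], collapse = "-"),
                 x = pt[1], y = pt[2], z = pt[3],
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  } else {
    data.frame(cluster = integer(0), n_voxels = integer(0),
               min_s = numeric(0), signed_rho = numeric(0),
               class = character(0), atom_pair = character(0),
               x = numeric(0), y = numeric(0), z = numeric(0),
               stringsAsFactors = FALSE)
  }
  structure(
    list(origin = vapply(axes, `[`, numeric(1), 1L), spacing = spacing,
         dims = dims, axes = axes,
         rho = array(rho, dims), s = array(s, dims),
         signed_rho = array(signed, dims),
         summary = summary, model = model,
         s_iso = s_iso, rho_cutoff = rho_cutoff,
         attract_thresh = attract_thresh),
    class = "rdg_field"
  )
}

#' @export
print.rdg_field <- function(x, ...) {
  cat("<rdg_field>", paste(x$dims, collapse = " x "), "grid, spacing",
      x$spacing, "bohr\n")
  cat("  ", nrow(x$summary), "low-s cluster(s) at s <=", x$s_iso,
      ", rho <", x$rho_cutoff, "\n")
  if (nrow(x$summary)) {
    print(x$summary[, c("cluster", "n_voxels", "min_s", "signed_rho",
                        "class", "atom_pair")], row.names = FALSE)
  }
  invisible(x)
}

# Connected-component labelling of a logical grid mask, 6-connectivity.
label_components <- function(mask, dims) {
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]
  labels <- integer(length(mask))
  current <- 0L
  ix <- function(i) (i - 1L) %% nx
  iy <- function(i) ((i - 1L) %/% nx) %% ny
  iz <- function(i) (i - 1L) %/% (nx * ny)
  for (seed in which(mask)) {
    if (labels[seed] != 0L) next
    current <- current + 1L
    queue <- seed
    labels[seed] <- current
    while (length(queue)) {
      i <- queue[length(queue)]
      queue <- queue[-length(queue)]
      cx <- ix(i); cy <- iy(i); cz <- iz(i)
      nbrs <- c(
        if (cx > 0L) i - 1L, if (cx < nx - 1L) i + 1L,
        if (cy > 0L) i - nx, if (cy < ny - 1L) i + nx,
        if (cz > 0L) i - nx * ny, if (cz < nz - 1L) i + nx * ny
      )
      nbrs <- nbrs[mask[nbrs] & labels[nbrs] == 0L]
      labels[nbrs] <- current
      queue <- c(queue, nbrs)
    }
  }
  labels
}

element_z <- function(el) {
  z <- c(H = 1, C = 6, N = 7, O = 8, NE = 10, S = 16)
  out <- z[toupper(el)]
  if (any(is.na(out))) stop("unknown element for cube output")
  unname(out)
}

#' Write a field as a Gaussian cube file
#'
#' Standard cube layout: two comment lines, atom count and grid origin
#' (bohr), per-axis voxel counts and vectors, atom records, then values
#' with z fastest. Readable by standard volumetric viewers.
#'
#' @param field An `rdg_field` from [nci_scan()].
#' @param path Output path.
#' @param what Which array to write: `"s"`, `"signed_rho"` or `"rho"`.
#' @return `path`, invisibly.
#' @export
write_cube <- function(field, path, what = c("s", "signed_rho", "rho")) {
  what <- match.arg(what)
  atoms <- field$model$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("gfpstate", what, "field"),
               "promolecular reduced-density-gradient scan"), con)
  fmt <- function(n, v) sprintf("%5d%12.6f%12.6f%12.6f", n, v[1], v[2], v[3])
  writeLines(fmt(nrow(atoms), field$origin), con)
  writeLines(fmt(field$dims[1], c(field$spacing, 0, 0)), con)
  writeLines(fmt(field$dims[2], c(0, field$spacing, 0)), con)
  writeLines(fmt(field$dims[3], c(0, 0, field$spacing)), con)
  for (i in seq_len(nrow(atoms))) {
    z <- element_z(atoms$element[i])
    pos <- as.numeric(atoms[i, c("x", "y", "z")]) * BOHR_PER_ANGSTROM
    writeLines(sprintf("%5d%12.6f%12.6f%12.6f%12.6f", z, z,
                       pos[1], pos[2], pos[3]), con)
  }
  vals <- field[[what]]
  for (i in seq_len(field$dims[1])) {
    for (j in seq_len(field$dims[2])) {
      row <- vals[i, j, ]
      lines <- split(row, ceiling(seq_along(row) / 6))
      writeLines(vapply(lines, function(v) {
        paste(sprintf("%13.5E", v), collapse = "")
      }, character(1)), con)
    }
  }
  invisible(path)
}
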