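# Synthetic GFP-like fixtures: minimal chromophore-environment structures
# built to prescribed distances and torsions by explicit constructive
# placement, Henderson-Hasselbalch titration datasets, and small atom
# sets for density tests.

norm3 <- function(v) v / sqrt(sum(v^2))

# Natural-extension (NeRF) placement: position D given A-B-C, the C-D
# bond length, the B-C-D angle and the A-B-C-D torsion (degrees, IUPAC
# sign convention).
place_atom <- function(a, b, c_, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- norm3(c_ - b)
  n <- norm3(cross3(b - a, bc))
  m <- cross3(n, bc)
  rot <- cbind(bc, m, n)
  as.numeric(c_ + rot %*% d2)
}

# Proper rotation taking unit vector a onto unit vector b (Rodrigues).
align_rotation <- function(a, b) {
  a <- norm3(a); b <- norm3(b)
  v <- cross3(a, b)
  s2 <- sum(v^2)
  c_ <- sum(a * b)
  if (s2 < 1e-16) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate pi about any axis perpendicular to a
    perp <- if (abs(a[1]) < 0.9) norm3(cross3(a, c(1, 0, 0))) else
      norm3(cross3(a, c(0, 1, 0)))
    return(2 * outer(perp, perp) - diag(3))
  }
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s2)
}

#' Built-in structure presets
#'
#' Five presets encode the exemplar geometries of the three states:
#' \itemize{
#'   \item `I_like`: Val203, His bond 2.85 A (ordinary strength) -- the
#'     I-state arrangement of the double variant at high pH;
#'   \item `A_like_T203V`: Val203, His bond 3.24 A (weak) -- the same
#'     protein at low pH, in the A state;
#'   \item `A_like_WT`: Thr203 with the hydroxyl out of bonding range and
#'     a weak His bond -- wild-type-like A state;
#'   \item `B_like_S65T`, `B_like_E222Q`: Thr203 hydroxyl hydrogen-bonded
#'     to the phenolate plus an ordinary His bond -- the B state.
#' }
#'
#' @param name Preset name, or `NULL` to list available names.
#' @return A `structure_preset` (or character vector of names).
#' @export
structure_preset <- function(name = NULL) {
  presets <- list(
    I_like = list(d_his = 2.85, pos203_residue = "VAL", d_203 = 3.60,
                  chi1_203 = -60, gln222_orientation = "NE2",
                  include_wat3 = TRUE, d_wat3 = 2.70),
    A_like_T203V = list(d_his = 3.24, pos203_residue = "VAL", d_203 = 3.60,
                        chi1_203 = -60, gln222_orientation = "OE1",
                        include_wat3 = TRUE, d_wat3 = 2.70),
    A_like_WT = list(d_his = 3.30, pos203_residue = "THR", d_203 = 3.80,
                     chi1_203 = -60, gln222_orientation = "OE1",
                     include_wat3 = TRUE, d_wat3 = 2.70),
    B_like_S65T = list(d_his = 2.80, pos203_residue = "THR", d_203 = 2.80,
                       chi1_203 = 60, gln222_orientation = "OE1",
                       include_wat3 = TRUE, d_wat3 = 2.70),
    B_like_E222Q = list(d_his = 2.90, pos203_residue = "THR", d_203 = 2.70,
                        chi1_203 = 60, gln222_orientation = "OE1",
                        include_wat3 = TRUE, d_wat3 = 2.70)
  )
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    stop("unknown preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  }
  p <- presets[[name]]
  p$name <- name
  p$dpi <- 0.07
  p$b_profile <- "uniform"
  validate_preset(p)
}

validate_preset <- function(p) {
  dists <- c(p$d_his, p$d_203, if (p$include_wat3) p$d_wat3)
  if (any(dists <= 2.0 | dists >= 6.0)) {
    stop("preset distances must lie in (2.0, 6.0) angstrom")
  }
  stopifnot(p$pos203_residue %in% c("THR", "VAL", "ILE"),
            p$chi1_203 > -180, p$chi1_203 <= 180,
            p$gln222_orientation %in% c("OE1", "NE2", "tie"),
            p$b_profile %in% c("uniform", "ramp"),
            p$dpi >= 0)
  structure(p, class = "structure_preset")
}

#' Custom structure preset
#'
#' @param name Label for the structure.
#' @param d_his His148 ND1 ... chromophore OH distance (angstrom).
#' @param pos203_residue `"THR"`, `"VAL"` or `"ILE"`.
#' @param d_203 Distal-203 ... chromophore OH distance (angstrom).
#' @param chi1_203 Side-chain chi1 at 203, degrees in (-180, 180].
#' @param gln222_orientation `"OE1"` (amide oxygen toward the Ser65
#'   hydroxyl, low-pH arrangement), `"NE2"` (reversed, high-pH
#'   arrangement) or `"tie"` (equidistant).
#' @param include_wat3 Place the bridging water?
#' @param d_wat3 Chromophore OH ... water distance (angstrom).
#' @param dpi Diffraction precision index carried on the model.
#' @param b_profile `"uniform"` (all B = 20) or `"ramp"` (B from 10 to 40
#'   across the atom list).
#' @return A `structure_preset`.
#' @export
custom_preset <- function(name = "custom", d_his = 2.85,
                          pos203_residue = "VAL", d_203 = 3.6,
                          chi1_203 = -60, gln222_orientation = "NE2",
                          include_wat3 = TRUE, d_wat3 = 2.7,
                          dpi = 0.07, b_profile = "uniform") {
  validate_preset(list(
    name = name, d_his = d_his, pos203_residue = pos203_residue,
    d_203 = d_203, chi1_203 = chi1_203,
    gln222_orientation = gln222_orientation,
    include_wat3 = include_wat3, d_wat3 = d_wat3,
    dpi = dpi, b_profile = b_profile
  ))
}

#' Random structure preset
#'
#' Draws geometry within the plausible crystallographic ranges for
#' property tests (distances 2.4--4.2 A, any chi1, any residue type).
#'
#' @param seed Integer seed.
#' @return A `structure_preset`.
#' @export
random_structure_preset <- function(seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  custom_preset(
    name = paste0("random_", seed),
    d_his = stats::runif(1, 2.4, 4.0),
    pos203_residue = sample(c("THR", "VAL", "ILE"), 1),
    d_203 = stats::runif(1, 2.5, 4.2),
    chi1_203 = stats::runif(1, -179.5, 180),
    gln222_orientation = sample(c("OE1", "NE2"), 1),
    include_wat3 = stats::runif(1) < 0.8,
    d_wat3 = stats::runif(1, 2.5, 3.3),
    dpi = 0.07,
    b_profile = sample(c("uniform", "ramp"), 1)
  )
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a synthetic chromophore-environment structure
#'
#' Emits a minimal but legal structure containing the chromophore
#' (residue `CRO` 66 with OH, CZ, O2, N2 and the Ser65-derived hydroxyl
#' OG1), His148 (with ND1), the requested residue at 203 built with the
#' requested chi1, Ser205, Gln222 (amide atoms placed per the orientation
#' flag) and optionally the bridging water. All prescribed distances and
#' torsions are realized exactly by constructive placement (the
#' chromophore hydroxyl sits at the origin and partners are placed along
#' prescribed directions), not by optimization. Occupancies are 1.0.
#'
#' @param preset A `structure_preset`.
#' @param path Optional path; when given the structure is also written as
#'   a PDB file (deterministic, byte-identical for identical presets).
#' @return A `structure_model` with the preset's DPI attached.
#' @export
build_structure <- function(preset, path = NULL) {
  stopifnot(inherits(preset, "structure_preset"))
  p <- preset
  rows <- list()
  add <- function(type, resid, resno, elety, pos) {
    rows[[length(rows) + 1L]] <<- data.frame(
      type = type, chain = "A", resno = resno, resid = resid, elety = elety,
      alt = "", occ = 1, b = 20,
      x = pos[1], y = pos[2], z = pos[3],
      elesy = substr(elety, 1, 1), stringsAsFactors = FALSE
    )
  }

  # chromophore, phenolic oxygen at the origin, phenol ring along +x
  og1_pos <- c(6.8, 0.8, 1.5)
  add("HETATM", "CRO", 66, "OH", c(0, 0, 0))
  add("HETATM", "CRO", 66, "CZ", c(1.36, 0, 0))
  add("HETATM", "CRO", 66, "N2", c(5.8, 1.1, 0.5))
  add("HETATM", "CRO", 66, "O2", c(7.2, -0.9, 0.3))
  add("HETATM", "CRO", 66, "OG1", og1_pos)

  # His148 approaching the phenolate from -x; ND1 at the exact distance
  nd1 <- c(-p$d_his, 0, 0)
  add("ATOM", "HIS", 148, "N", nd1 + c(-4.55, 2.30, 0.60))
  add("ATOM", "HIS", 148, "CA", nd1 + c(-3.20, 2.35, 0.10))
  add("ATOM", "HIS", 148, "CB", nd1 + c(-2.40, 1.10, 0.20))
  add("ATOM", "HIS", 148, "CG", nd1 + c(-0.77, 1.17, 0.00))
  add("ATOM", "HIS", 148, "ND1", nd1)

  # residue 203: build in a local frame with exact internal chi1, then
  # rigidly place the distal atom at the prescribed distance along -y
  res203 <- build_residue_203(p$pos203_residue, p$chi1_203)
  target <- c(0, -p$d_203, 0)
  shift <- res203$coords
  shift <- sweep(shift, 2, shift[res203$distal, ])
  rot <- align_rotation(shift["CB", ], c(0, -1, 0))
  placed <- t(rot %*% t(shift)) + rep(target, each = nrow(shift))
  for (nm in rownames(placed)) {
    add("ATOM", p$pos203_residue, 203, nm, placed[nm, ])
  }

  # Ser205 above the chromophore, positioned to receive the bridging water
  wat_pos <- c(0, 0, p$d_wat3 %||% 2.7)
  og <- wat_pos + c(0, 1.6, 2.2)
  add("ATOM", "SER", 205, "N", og + c(2.1, 2.0, 0.1))
  add("ATOM", "SER", 205, "CA", og + c(1.2, 2.0, 0.55))
  add("ATOM", "SER", 205, "CB", og + c(0.0, 1.2, 0.95))
  add("ATOM", "SER", 205, "OG", og)

  # Gln222 amide anchored to the Ser65-derived hydroxyl OG1: the closer
  # amide atom (2.70 A) defines the orientation, the farther sits 3.30 A
  near_off <- c(-0.325, -2.680, 0)
  far_off <- c(1.925, -2.680, 0)
  if (p$gln222_orientation == "OE1") {
    oe1 <- og1_pos + near_off; ne2 <- og1_pos + far_off
  } else if (p$gln222_orientation == "NE2") {
    ne2 <- og1_pos + near_off; oe1 <- og1_pos + far_off
  } else { # tie: both at 2.70 A
    oe1 <- og1_pos + c(-1.125, -2.455, 0)
    ne2 <- og1_pos + c(1.125, -2.455, 0)
  }
  cd <- (oe1 + ne2) / 2 + c(0, -0.61, 0)
  add("ATOM", "GLN", 222, "N", cd + c(2.6, -2.8, 0.4))
  add("ATOM", "GLN", 222, "CA", cd + c(1.9, -2.4, 0.2))
  add("ATOM", "GLN", 222, "CB", cd + c(1.4, -1.3, 0.5))
  add("ATOM", "GLN", 222, "CG", cd + c(0.7, -1.2, 0.4))
  add("ATOM", "GLN", 222, "CD", cd)
  add("ATOM", "GLN", 222, "OE1", oe1)
  add("ATOM", "GLN", 222, "NE2", ne2)

  if (isTRUE(p$include_wat3)) {
    add("HETATM", "HOH", 301, "O", wat_pos)
  }

  atoms <- do.call(rbind, rows)
  if (p$b_profile == "ramp") {
    atoms$b <- round(seq(10, 40, length.out = nrow(atoms)), 2)
  }
  model <- structure_model(atoms, structure_id = p$name, dpi = p$dpi)
  if (!is.null(path)) write_structure(model, path)
  model
}

# local-frame residue with exact internal chi1
build_residue_203 <- function(resid, chi1) {
  n <- c(0, 0, 0)
  ca <- c(1.458, 0, 0)
  cb <- ca + 1.53 * c(cos(69.5 * pi / 180), sin(69.5 * pi / 180), 0)
  coords <- rbind(N = n, CA = ca, CB = cb)
  if (resid == "THR") {
    coords <- rbind(coords,
                    OG1 = place_atom(n, ca, cb, 1.43, 110.5, chi1),
                    CG2 = place_atom(n, ca, cb, 1.52, 110.5, chi1 - 120))
    distal <- "OG1"
  } else if (resid == "VAL") {
    coords <- rbind(coords,
                    CG1 = place_atom(n, ca, cb, 1.527, 110.5, chi1),
                    CG2 = place_atom(n, ca, cb, 1.527, 110.5, chi1 + 122))
    distal <- "CG2"
  } else if (resid == "ILE") {
    coords <- rbind(coords,
                    CG1 = place_atom(n, ca, cb, 1.53, 110.5, chi1),
                    CG2 = place_atom(n, ca, cb, 1.53, 110.5, chi1 - 122))
    distal <- "CG2"
  } else {
    stop("unsupported residue type at 203: ", resid)
  }
  list(coords = coords, distal = distal)
}

#' Titration dataset preset
#'
#' The default preset emulates the pH titration of the I-stabilized
#' double variant: midpoint at pKa 6, three replicate samples per pH,
#' ten pH points spanning 4.0--8.5, Gaussian fraction noise with
#' sd 0.02.
#'
#' @param name Label.
#' @param pka_true Generating pKa.
#' @param noise_sd Gaussian noise sd on the fraction (0 for noise-free).
#' @param ph_grid pH sampling points.
#' @param replicates Replicates per pH value.
#' @param seed Integer seed.
#' @return A `titration_preset`.
#' @export
titration_preset <- function(name = "T203V_E222Q", pka_true = 6,
                             noise_sd = 0.02,
                             ph_grid = seq(4, 8.5, length.out = 10),
                             replicates = 3, seed = 1) {
  stopifnot(replicates >= 1, noise_sd >= 0)
  structure(list(name = name, pka_true = pka_true, noise_sd = noise_sd,
                 ph_grid = ph_grid, replicates = replicates, seed = seed),
            class = "titration_preset")
}

#' Build a synthetic titration dataset
#'
#' Fractions follow `hh_fraction(ph, pka_true)` plus Gaussian noise of
#' the preset's sd, clipped to \[0, 1\]; the per-point sd is recorded
#' for weighted fitting. Reproducible: identical presets (including
#' seed) give identical datasets.
#'
#' @param preset A [titration_preset()].
#' @return data.frame with columns `ph`, `fraction`, `sd`, `replicate`.
#' @export
build_titration <- function(preset = titration_preset()) {
  stopifnot(inherits(preset, "titration_preset"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(preset$seed)
  grid <- expand.grid(replicate = seq_len(preset$replicates),
                      ph = preset$ph_grid)
  truth <- hh_fraction(grid$ph, preset$pka_true)
  noise <- if (preset$noise_sd > 0) {
    stats::rnorm(nrow(grid), 0, preset$noise_sd)
  } else {
    0
  }
  frac <- pmin(pmax(truth + noise, 0), 1)
  data.frame(ph = grid$ph, fraction = frac,
             sd = if (preset$noise_sd > 0) preset$noise_sd else NA_real_,
             replicate = grid$replicate)
}

#' Small atom sets for density tests
#'
#' \itemize{
#'   \item `single_atom`: one hydrogen at the origin;
#'   \item `vdw_pair`: two neon atoms at 3.1 A, a van der Waals contact;
#'   \item `hbond_triplet`: N-H...O with the hydrogen on the N-O axis at
#'     1.0 A from N and the heavy atoms 2.85 A apart -- the exemplar
#'     hydrogen-bond length of the chromophore environment.
#' }
#'
#' @param kind Fixture name.
#' @return A [density_model()].
#' @export
build_density_fixture <- function(kind = c("single_atom", "vdw_pair",
                                           "hbond_triplet")) {
  kind <- match.arg(kind)
  atoms <- switch(kind,
    single_atom = data.frame(element = "H", x = 0, y = 0, z = 0,
                             name = "H1"),
    vdw_pair = data.frame(element = c("NE", "NE"),
                          x = c(0, 3.1), y = 0, z = 0,
                          name = c("Ne1", "Ne2")),
    hbond_triplet = data.frame(element = c("N", "H", "O"),
                               x = c(0, 1.0, 2.85), y = 0, z = 0,
                               name = c("N1", "H1", "O1"))
  )
  density_model(atoms)
}
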