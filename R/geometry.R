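# Distances, torsions, rotamer and hydrogen-bond classification, and the
# per-structure geometry report for the chromophore environment.

atom_xyz <- function(a) {
  if (is.data.frame(a)) {
    stopifnot(nrow(a) == 1L)
    return(c(a$x, a$y, a$z))
  }
  stopifnot(is.numeric(a), length(a) == 3L)
  as.numeric(a)
}

#' Euclidean distance between two atoms
#'
#' @param a,b Atom rows (one-row data.frames with `x`, `y`, `z`) or
#'   numeric 3-vectors, in angstrom.
#' @return Distance in angstrom.
#' @export
atom_distance <- function(a, b) {
  pa <- atom_xyz(a); pb <- atom_xyz(b)
  if (any(!is.finite(pa)) || any(!is.finite(pb))) stop("non-finite position")
  sqrt(sum((pa - pb)^2))
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion angle of four points
#'
#' Signed dihedral about the p2--p3 axis with the standard IUPAC sign
#' convention (cis = 0, anti = 180); result in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (or one-row atom data.frames).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  p1 <- atom_xyz(p1); p2 <- atom_xyz(p2); p3 <- atom_xyz(p3); p4 <- atom_xyz(p4)
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-10 || sqrt(sum(n2^2)) < 1e-10) {
    stop("degenerate torsion: three consecutive points are collinear")
  }
  b2u <- b2 / sqrt(sum(b2^2))
  ang <- atan2(sum(cross3(n1, n2) * b2u), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

chi1_gamma_atom <- function(resid) {
  switch(toupper(resid),
         THR = "OG1", SER = "OG", VAL = "CG1", ILE = "CG1", CYS = "SG",
         "CG")
}

#' Side-chain chi1 torsion of a residue
#'
#' Computes the N-CA-CB-gamma torsion, where the gamma atom is `OG1` for
#' Thr, `OG` for Ser, `CG1` for Val/Ile, `SG` for Cys and `CG` otherwise.
#'
#' @param model A `structure_model`.
#' @param resno Author residue number.
#' @return chi1 in degrees, in (-180, 180].
#' @export
chi1 <- function(model, resno) {
  res <- find_residue(model, resno)
  if (!nrow(res)) stop("no residue at position ", resno)
  gamma <- chi1_gamma_atom(res$resid[1])
  need <- c("N", "CA", "CB", gamma)
  pts <- lapply(need, function(nm) {
    hit <- res[res$elety == nm, , drop = FALSE]
    if (nrow(hit) != 1L) {
      stop("residue ", res$resid[1], resno, " lacks atom ", nm,
           " required for chi1")
    }
    atom_xyz(hit)
  })
  dihedral_angle(pts[[1]], pts[[2]], pts[[3]], pts[[4]])
}

#' Classify a chi1 angle into a canonical rotamer well
#'
#' Partition of (-180, 180]: `gauche-` on \[-120, 0), `gauche+` on
#' \[0, 120), `trans` otherwise (lower edges inclusive).
#'
#' @param chi1 Angle(s) in degrees, in (-180, 180].
#' @return Character vector of `"gauche-"`, `"gauche+"`, `"trans"`.
#' @export
classify_rotamer <- function(chi1) {
  stopifnot(all(chi1 > -180 - 1e-9 & chi1 <= 180 + 1e-9))
  ifelse(chi1 >= -120 & chi1 < 0, "gauche-",
         ifelse(chi1 >= 0 & chi1 < 120, "gauche+", "trans"))
}

#' Hydrogen-bond strength scheme
#'
#' Heavy-atom donor--acceptor distance bins: `normal` for
#' 2.5 <= d <= 3.0, `weak` for 3.0 < d <= 3.5, `none` above 3.5, and
#' distances below 2.5 flagged as `clash`. Boundary values (exactly 3.0
#' or 3.5) are resolved toward the stronger class.
#'
#' @param normal_max Upper edge of the normal bin (default 3.0).
#' @param weak_max Upper edge of the weak bin / no-bond threshold
#'   (default 3.5).
#' @param clash_min Lower edge of physically plausible contacts
#'   (default 2.5).
#' @return Object of class `hbond_scheme`.
#' @export
hbond_scheme <- function(normal_max = 3.0, weak_max = 3.5, clash_min = 2.5) {
  stopifnot(clash_min < normal_max, normal_max < weak_max)
  structure(list(clash_min = clash_min, normal_max = normal_max,
                 weak_max = weak_max),
            class = "hbond_scheme")
}

#' Classify a donor-acceptor distance into a hydrogen-bond strength class
#'
#' @param d Distance(s) in angstrom, > 0.
#' @param scheme A [hbond_scheme()].
#' @return Character vector of `"clash"`, `"normal"`, `"weak"`, `"none"`.
#' @export
classify_hbond <- function(d, scheme = hbond_scheme()) {
  stopifnot(all(d > 0))
  ifelse(d < scheme$clash_min, "clash",
         ifelse(d <= scheme$normal_max, "normal",
                ifelse(d <= scheme$weak_max, "weak", "none")))
}

#' Amide orientation of Gln222 toward the Ser65 hydroxyl
#'
#' The Gln222 side-chain amide hydrogen-bonds the Ser65-derived hydroxyl
#' with either its Oepsilon1 or its Nepsilon2 atom; which one is closer
#' distinguishes the low-pH (A-state) from the high-pH (I-state)
#' arrangement, where the partners are reversed. For a wild-type Glu at
#' 222 the same comparison uses OE1/OE2. When the two distances differ by
#' less than `tie` (default 0.2 angstrom, conservative for ~1.2-1.5
#' angstrom resolution data) the call is `"undetermined"`.
#'
#' @param model A `structure_model`.
#' @param resno Residue number of the amide residue (default 222).
#' @param tie Resolution floor in angstrom.
#' @return `"OE1->Ser65"`, `"NE2->Ser65"` (`"OE2->Ser65"` for Glu) or
#'   `"undetermined"`.
#' @export
gln222_orientation <- function(model, resno = 222, tie = 0.2) {
  res <- find_residue(model, resno)
  if (!nrow(res)) stop("no residue at position ", resno)
  resid <- toupper(res$resid[1])
  if (!resid %in% c("GLN", "GLU")) {
    stop("residue at ", resno, " is ", resid, ", expected GLN or GLU")
  }
  second <- if (resid == "GLN") "NE2" else "OE2"
  oe1 <- pick_atom(res, "OE1", paste0(resid, resno, ".OE1"))
  alt <- pick_atom(res, second, paste0(resid, resno, ".", second))
  target <- resolve_site(model, "hydroxyl65")
  d1 <- atom_distance(oe1, target)
  d2 <- atom_distance(alt, target)
  if (abs(d1 - d2) < tie) return("undetermined")
  if (d1 < d2) "OE1->Ser65" else paste0(second, "->Ser65")
}

#' Measure the chromophore-environment geometry of one structure
#'
#' Fills a geometry report with the quantities that characterize the
#' chromophore environment:
#' \itemize{
#'   \item `d_his`: His148 ND1 ... chromophore OH distance;
#'   \item `d_203`: position-203 distal atom (Thr OG1 / Val,Ile CG2) ...
#'     chromophore OH distance;
#'   \item `d_wat3`: chromophore OH ... bridging-water oxygen distance
#'     (`NA` when no water bridges OH and Ser205 OG within `water_cutoff`);
#'   \item `d_val_cz`: Val203 CG1 ... chromophore CZ van der Waals contact
#'     (`NA` unless position 203 is valine);
#'   \item `chi1_203` and its rotamer class;
#'   \item the Gln/Glu222 amide orientation;
#'   \item `hbond_list`: the named donor/acceptor pairs with distance and
#'     strength class.
#' }
#'
#' @param model A `structure_model`.
#' @param scheme Hydrogen-bond strength scheme.
#' @param pos203 Author number of the stacking residue (default 203).
#' @param water_cutoff Bridging-water distance cutoff in angstrom.
#' @return Object of class `geometry_report`.
#' @export
measure_geometry <- function(model, scheme = hbond_scheme(), pos203 = 203,
                             water_cutoff = 3.5) {
  oh <- resolve_site(model, "chromophore.OH")
  his_nd1 <- resolve_site(model, "His148.ND1")
  pos_key <- sprintf("pos%d.distal", pos203)
  distal <- resolve_site(model, pos_key)
  res203 <- find_residue(model, pos203)
  resid203 <- toupper(res203$resid[1])

  d_his <- atom_distance(his_nd1, oh)
  d_203 <- atom_distance(distal, oh)

  wat <- find_bridging_water(model, cutoff = water_cutoff)
  d_wat3 <- if (is.null(wat)) NA_real_ else atom_distance(oh, wat)

  d_val_cz <- NA_real_
  if (resid203 == "VAL") {
    cg1 <- res203[res203$elety == "CG1", , drop = FALSE]
    cz <- find_chromophore(model)
    cz <- cz[cz$elety == "CZ", , drop = FALSE]
    if (nrow(cg1) == 1L && nrow(cz) == 1L) {
      d_val_cz <- atom_distance(cg1, cz)
    }
  }

  chi <- chi1(model, pos203)
  orient <- gln222_orientation(model)

  hb <- data.frame(
    donor = c("His148.ND1", pos_key),
    acceptor = c("chromophore.OH", "chromophore.OH"),
    distance = c(d_his, d_203),
    stringsAsFactors = FALSE
  )
  # the 203 contact only counts as an H bond through a hydroxyl oxygen
  hb$hydrogen_bond <- c(TRUE, substr(distal$elesy, 1, 1) == "O")
  if (!is.na(d_wat3)) {
    ser_og <- resolve_site(model, "Ser205.OG")
    hb <- rbind(hb, data.frame(
      donor = c("Wat3.O", "Ser205.OG"),
      acceptor = c("chromophore.OH", "Wat3.O"),
      distance = c(d_wat3, atom_distance(ser_og, wat)),
      hydrogen_bond = TRUE
    ))
  }
  hb$class <- classify_hbond(hb$distance, scheme)

  structure(
    list(structure_id = model$structure_id,
         d_his = d_his, d_203 = d_203, d_wat3 = d_wat3, d_val_cz = d_val_cz,
         chi1_203 = chi, rotamer_203 = classify_rotamer(chi),
         gln222_orientation = orient,
         pos203_residue = resid203,
         pos203_element = substr(distal$elesy, 1, 1),
         hbond_list = hb, scheme = scheme),
    class = "geometry_report"
  )
}

#' @export
print.geometry_report <- function(x, ...) {
  cat("<geometry_report>", x$structure_id, "\n")
  fmt <- function(v, s = NULL) {
    if (is.na(v)) return("absent")
    out <- sprintf("%.3f", v)
    if (!is.null(s) && !is.na(s)) out <- sprintf("%s +/- %.4f", out, s)
    paste(out, "A")
  }
  cat("  d_his  (His148 ND1...OH):", fmt(x$d_his, x$sigma_his), "\n")
  cat("  d_203  (", x$pos203_residue, " distal...OH): ",
      fmt(x$d_203, x$sigma_203), "\n", sep = "")
  cat("  d_wat3 (OH...Wat3):", fmt(x$d_wat3, x$sigma_wat3), "\n")
  cat("  chi1_203:", sprintf("%.1f deg (%s)", x$chi1_203, x$rotamer_203), "\n")
  cat("  Gln222 amide:", x$gln222_orientation, "\n")
  invisible(x)
}

#' Serialize geometry reports to a one-row-per-structure data.frame
#'
#' @param reports A `geometry_report` or list of them.
#' @return data.frame with columns `structure_id`, `d_his`, `d_203`,
#'   `d_wat3`, `d_val_cz`, `chi1_203`, `rotamer_203`,
#'   `gln222_orientation` (plus `sigma_*` columns when errors have been
#'   annotated).
#' @export
geometry_table <- function(reports) {
  if (inherits(reports, "geometry_report")) reports <- list(reports)
  rows <- lapply(reports, function(r) {
    data.frame(
      structure_id = r$structure_id,
      d_his = r$d_his, sigma_his = r$sigma_his %||% NA_real_,
      d_203 = r$d_203, sigma_203 = r$sigma_203 %||% NA_real_,
      d_wat3 = r$d_wat3, d_val_cz = r$d_val_cz,
      chi1_203 = r$chi1_203, rotamer_203 = r$rotamer_203,
      gln222_orientation = r$gln222_orientation,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
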