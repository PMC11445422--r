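# DPI-based coordinate-error propagation: per-atom sigma scaled by
# B-factor, per-distance sigma by quadrature.

#' Per-atom coordinate error from the diffraction precision index
#'
#' The average coordinate error (DPI) is scaled to an individual atom by
#' its B-factor: `sigma_i = dpi * sqrt(b_i / b_average)`.
#'
#' @param dpi Average coordinate error (DPI), angstrom, >= 0.
#' @param b_i Atom B-factor(s), angstrom^2, >= 0.
#' @param b_average Mean B-factor, angstrom^2, > 0.
#' @return Per-atom sigma(s), angstrom.
#' @export
atom_sigma <- function(dpi, b_i, b_average) {
  stopifnot(dpi >= 0, all(b_i >= 0))
  if (b_average <= 0) stop("b_average must be positive")
  dpi * sqrt(b_i / b_average)
}

#' Interatomic-distance error by quadrature
#'
#' `sigma_l = sqrt(sigma_i^2 + sigma_j^2)`.
#'
#' @param sigma_i,sigma_j Per-atom coordinate errors, angstrom, >= 0.
#' @return Distance error, angstrom.
#' @export
distance_sigma <- function(sigma_i, sigma_j) {
  stopifnot(all(sigma_i >= 0), all(sigma_j >= 0))
  sqrt(sigma_i^2 + sigma_j^2)
}

pair_sigma <- function(model, atom_a, atom_b) {
  si <- atom_sigma(model$dpi, atom_a$b, model$b_average)
  sj <- atom_sigma(model$dpi, atom_b$b, model$b_average)
  distance_sigma(si, sj)
}

#' Annotate a geometry report with DPI-propagated distance errors
#'
#' Every reported distance gains a sigma computed from the two
#' participating atoms' B-factors via [atom_sigma()] and
#' [distance_sigma()]. For atoms with alternative conformations the
#' B-factor of the selected (highest-occupancy) conformer is used.
#'
#' @param model The `structure_model` the report was measured on; its
#'   `dpi` field must be set.
#' @param report A `geometry_report` from [measure_geometry()].
#' @return The report with `sigma_his`, `sigma_203`, `sigma_wat3`,
#'   `sigma_val_cz` fields and a `sigma` column on `hbond_list`.
#' @export
annotate_errors <- function(model, report) {
  if (is.null(model$dpi)) {
    stop("model has no DPI: supply one via read_structure(dpi = ...) or ",
         "structure_model(dpi = ...) to propagate coordinate errors")
  }
  oh <- resolve_site(model, "chromophore.OH")
  his_nd1 <- resolve_site(model, "His148.ND1")
  distal <- resolve_site(model, "pos203.distal")
  report$sigma_his <- pair_sigma(model, his_nd1, oh)
  report$sigma_203 <- pair_sigma(model, distal, oh)
  report$sigma_wat3 <- NA_real_
  if (!is.na(report$d_wat3)) {
    wat <- find_bridging_water(model)
    report$sigma_wat3 <- pair_sigma(model, oh, wat)
  }
  report$sigma_val_cz <- NA_real_
  if (!is.na(report$d_val_cz)) {
    res203 <- find_residue(model, 203)
    cg1 <- res203[res203$elety == "CG1", , drop = FALSE]
    cro <- find_chromophore(model)
    cz <- cro[cro$elety == "CZ", , drop = FALSE]
    report$sigma_val_cz <- pair_sigma(model, cg1, cz)
  }
  sigma_for_key <- function(key) {
    if (key == "Wat3.O") find_bridging_water(model) else resolve_site(model, key)
  }
  hb <- report$hbond_list
  hb$sigma <- vapply(seq_len(nrow(hb)), function(i) {
    pair_sigma(model, sigma_for_key(hb$donor[i]), sigma_for_key(hb$acceptor[i]))
  }, numeric(1))
  report$hbond_list <- hb
  report
}
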