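# In-code fixtures: a tiny 5-atom structure written as PDB and as mmCIF
# with identical content, plus small utilities.

pdb_line <- function(type, serial, name, alt, resn, chain, resno,
                     x, y, z, occ, b, element) {
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          type, serial, name, alt, resn, chain, resno, x, y, z, occ, b,
          element)
}

five_atom_records <- function() {
  data.frame(
    type = c("ATOM", "ATOM", "ATOM", "HETATM", "HETATM"),
    name = c("N", "CA", "ND1", "OH", "O"),
    alt = "", resn = c("HIS", "HIS", "HIS", "CRO", "HOH"),
    resno = c(148, 148, 148, 66, 301),
    x = c(1.0, 2.4, 2.85, 0.0, 0.5),
    y = c(2.0, 2.1, 0.0, 0.0, 1.0),
    z = c(3.0, 3.3, 0.0, 0.0, 2.5),
    occ = c(1, 1, 0.85, 1, 0.6), b = c(20, 21, 22, 15, 30),
    element = c("N", "C", "N", "O", "O"),
    stringsAsFactors = FALSE
  )
}

write_fixture_pdb <- function(path, records = five_atom_records()) {
  lines <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    pdb_line(r$type, i, r$name, r$alt, r$resn, "A", r$resno,
             r$x, r$y, r$z, r$occ, r$b, r$element)
  }, character(1))
  writeLines(c(lines, "END"), path)
  path
}

write_fixture_cif <- function(path, records = five_atom_records()) {
  head <- c(
    "data_fixture", "loop_",
    paste0("_atom_site.", c("group_PDB", "id", "type_symbol",
                            "label_atom_id", "label_alt_id",
                            "label_comp_id", "label_asym_id",
                            "label_entity_id", "label_seq_id",
                            "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
                            "Cartn_z", "occupancy", "B_iso_or_equiv",
                            "pdbx_formal_charge", "auth_seq_id",
                            "auth_comp_id", "auth_asym_id",
                            "auth_atom_id", "pdbx_PDB_model_num"))
  )
  body <- vapply(seq_len(nrow(records)), function(i) {
    r <- records[i, ]
    alt <- if (r$alt == "") "." else r$alt
    sprintf("%s %d %s %s %s %s A 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s A %s 1",
            r$type, i, r$element, r$name, alt, r$resn, r$resno,
            r$x, r$y, r$z, r$occ, r$b, r$resno, r$resn, r$name)
  }, character(1))
  writeLines(c(head, body), path)
  path
}

# smallest absolute angular difference in degrees
angle_diff <- function(a, b) {
  d <- (a - b + 180) %% 360 - 180
  abs(d)
}

# random proper rotation matrix
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

transform_model <- function(model, rot, shift) {
  xyz <- as.matrix(model$atoms[, c("x", "y", "z")])
  xyz <- t(rot %*% t(xyz)) + rep(shift, each = nrow(xyz))
  atoms <- model$atoms
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  structure_model(atoms, structure_id = model$structure_id, dpi = model$dpi)
}
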