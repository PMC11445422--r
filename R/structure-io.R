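# Reading crystallographic structures into a uniform atom model, and
# resolving the semantic site vocabulary (Greek atom names, chromophore
# codes, the position-203 distal atom) to concrete atoms.

#' Default chromophore residue codes
#'
#' Three-letter component codes accepted as the p-hydroxybenzylidene
#' imidazolinone chromophore. Component naming for the Ser65/Thr65
#' chromophore varies across depositions; in all of these the phenolic
#' oxygen is atom `OH` and the ring carbon bearing it is `CZ`.
#'
#' @return Character vector of residue codes.
#' @export
chromophore_codes <- function() c("CRO", "GYS", "CR2", "CSY")

#' Greek-letter to PDB atom-name vocabulary
#'
#' Maps the Greek remoteness labels used in the structural literature to
#' PDB component atom codes, so that site keys such as `"His148.Ndelta1"`
#' (or the Unicode form) resolve. `Ogamma` is residue-dependent (`OG` on
#' Ser, `OG1` on Thr) and is handled by [resolve_site()].
#'
#' @return Named character vector (names are Greek labels, values PDB codes).
#' @export
site_vocabulary <- function() {
  c(
    "Nδ1" = "ND1", "Ndelta1" = "ND1",
    "Nε2" = "NE2", "Nepsilon2" = "NE2",
    "Oη"  = "OH",  "Oeta"     = "OH",
    "Cζ"  = "CZ",  "Czeta"    = "CZ",
    "Oγ1" = "OG1", "Ogamma1"  = "OG1",
    "Cγ1" = "CG1", "Cgamma1"  = "CG1",
    "Cγ2" = "CG2", "Cgamma2"  = "CG2",
    "Oε1" = "OE1", "Oepsilon1" = "OE1",
    "Oε2" = "OE2", "Oepsilon2" = "OE2",
    "Oγ"  = "OG",  "Ogamma"   = "OG"
  )
}

required_atom_cols <- function() {
  c("type", "chain", "resno", "resid", "elety", "alt", "occ", "b",
    "x", "y", "z", "elesy")
}

#' Construct a structure model from an atom table
#'
#' Low-level constructor used by [read_structure()] and by the synthetic
#' generator. Validates invariants (finite coordinates, occupancies in
#' \[0,1\], non-negative B-factors, no insertion codes), resolves
#' alternative conformations to a single representative per atom
#' (highest occupancy, ties broken by altloc letter), and computes the
#' occupancy-weighted mean B-factor over the selected atoms.
#'
#' @param atoms data.frame with columns `type`, `chain`, `resno`, `resid`,
#'   `elety`, `alt`, `occ`, `b`, `x`, `y`, `z`, `elesy`.
#' @param structure_id Identifier used in reports.
#' @param dpi Diffraction precision index (average coordinate error, in
#'   angstrom) from refinement, or `NULL` if not supplied.
#' @return Object of class `structure_model` with elements `structure_id`,
#'   `atoms` (all records), `selected` (altloc-resolved records), `dpi`
#'   and `b_average`.
#' @export
structure_model <- function(atoms, structure_id = "structure", dpi = NULL) {
  atoms <- as.data.frame(atoms)
  missing_cols <- setdiff(required_atom_cols(), names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if ("insert" %in% names(atoms) && any(!is.na(atoms$insert) & atoms$insert != "")) {
    stop("insertion codes are not supported (author numbering without ",
         "insertion codes is assumed)")
  }
  atoms$alt[is.na(atoms$alt)] <- ""
  atoms$occ[is.na(atoms$occ)] <- 1
  atoms$b[is.na(atoms$b)] <- 0
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates")
  if (any(atoms$occ < 0 | atoms$occ > 1)) stop("occupancy outside [0, 1]")
  if (any(atoms$b < 0)) stop("negative B-factor")
  rownames(atoms) <- NULL
  selected <- select_conformers(atoms)
  b_average <- stats::weighted.mean(selected$b, selected$occ)
  if (!is.null(dpi)) {
    stopifnot(is.numeric(dpi), length(dpi) == 1L, dpi >= 0)
  }
  structure(
    list(structure_id = structure_id, atoms = atoms, selected = selected,
         dpi = dpi, b_average = b_average),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat("<structure_model>", x$structure_id, "\n")
  cat(" ", nrow(x$atoms), "atom records,", nrow(x$selected),
      "after altloc resolution\n")
  cat("  B_average:", format(x$b_average, digits = 4),
      " DPI:", if (is.null(x$dpi)) "absent" else format(x$dpi), "\n")
  invisible(x)
}

#' Resolve alternative conformations to one representative per atom
#'
#' For each (chain, residue number, residue name, atom name) the conformer
#' with the highest occupancy is kept; ties are broken by altloc letter
#' order (blank altloc sorts first). Output row order follows the first
#' occurrence of each atom in the input, so the selection is invariant
#' under record reordering at equal content.
#'
#' @param atoms Atom data.frame (see [structure_model()]).
#' @return The subset data.frame with one row per atom.
#' @export
select_conformers <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$resid, atoms$elety, sep = "|")
  # order: by key, then decreasing occupancy, then altloc letter
  ord <- order(key, -atoms$occ, atoms$alt)
  first <- !duplicated(key[ord])
  picked <- sort(ord[first])
  atoms[picked, , drop = FALSE]
}

#' Read a PDB or mmCIF structure
#'
#' Parses all ATOM/HETATM records (waters and altlocs retained) into a
#' [structure_model()]. Format is chosen from the file extension when
#' `format = "auto"` (`.cif`/`.mmcif` are mmCIF, everything else PDB).
#'
#' @param path Path to the coordinate file.
#' @param format `"auto"`, `"pdb"` or `"mmcif"`.
#' @param dpi Optional diffraction precision index (angstrom) from the
#'   structure's refinement; carried on the model for error propagation.
#' @param structure_id Identifier; defaults to the file name without
#'   extension.
#' @return A `structure_model`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           dpi = NULL, structure_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") {
      bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE)
    } else {
      suppressWarnings(bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE))
    },
    error = function(e) {
      stop("failed to parse ", path, " as ", format, ": ", conditionMessage(e))
    }
  )
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) {
    stop("failed to parse ", path, " as ", format,
         ": no ATOM/HETATM records found")
  }
  atoms <- data.frame(
    type = at$type, chain = at$chain, resno = at$resno, resid = at$resid,
    elety = at$elety, alt = ifelse(is.na(at$alt), "", at$alt),
    occ = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    x = at$x, y = at$y, z = at$z,
    elesy = ifelse(is.na(at$elesy), substr(at$elety, 1, 1), at$elesy),
    insert = if ("insert" %in% names(at)) at$insert else NA_character_,
    stringsAsFactors = FALSE
  )
  if (is.null(structure_id)) {
    structure_id <- tools::file_path_sans_ext(basename(path))
  }
  structure_model(atoms, structure_id = structure_id, dpi = dpi)
}

#' Write a structure model as PDB
#'
#' Fixed-column PDB v3.3 output via \pkg{bio3d}. Writing is deterministic:
#' identical models give byte-identical files.
#'
#' @param model A `structure_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  a <- model$atoms
  xyz <- as.numeric(t(as.matrix(a[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz, type = a$type, resno = a$resno, resid = a$resid,
    eleno = seq_len(nrow(a)), elety = a$elety, chain = a$chain,
    alt = ifelse(a$alt == "", NA, a$alt), o = a$occ, b = a$b,
    elesy = a$elesy, end = TRUE
  )
  invisible(path)
}

# distal atom at the position-203 site by residue type
pos203_distal_name <- function(resid) {
  switch(toupper(resid),
         THR = "OG1", SER = "OG", VAL = "CG2", ILE = "CG2",
         stop("no distal-atom rule for residue ", resid))
}

find_residue <- function(model, resno, resid = NULL) {
  sel <- model$selected
  hit <- sel[sel$resno == resno & sel$type %in% c("ATOM", "HETATM"), ,
             drop = FALSE]
  if (!is.null(resid)) hit <- hit[hit$resid %in% resid, , drop = FALSE]
  hit
}

find_chromophore <- function(model, codes = chromophore_codes()) {
  sel <- model$selected
  hit <- sel[sel$resid %in% codes, , drop = FALSE]
  if (!nrow(hit)) {
    stop("no chromophore residue found (accepted codes: ",
         paste(codes, collapse = ", "), ")")
  }
  rn <- unique(hit$resno)
  if (length(rn) > 1) hit <- hit[hit$resno == rn[1], , drop = FALSE]
  hit
}

#' Resolve a semantic site key to a single atom
#'
#' Site keys name atoms by their structural role rather than by record
#' index. Supported forms:
#' \itemize{
#'   \item `"His148.ND1"` -- residue name + author number, dot, atom name.
#'     Greek labels from [site_vocabulary()] are accepted for the atom
#'     (`"His148.Ndelta1"`).
#'   \item `"chromophore.OH"` (or any accepted chromophore code, e.g.
#'     `"CRO.OH"`) -- atom on the chromophore residue.
#'   \item `"pos203.distal"` (generally `"posNNN.distal"`) -- the distal
#'     side-chain atom at that position: `OG1` for Thr, `OG` for Ser,
#'     `CG2` for Val/Ile.
#'   \item `"hydroxyl65"` -- the Ser65-derived hydroxyl oxygen: `OG` if
#'     residue 65 is a free serine, otherwise `OG1` on the chromophore.
#' }
#' Altloc resolution (highest occupancy) has already been applied, so the
#' result is a single atom row.
#'
#' @param model A `structure_model`.
#' @param key Site key string.
#' @param chromophore Accepted chromophore residue codes.
#' @return One-row data.frame (the atom).
#' @export
resolve_site <- function(model, key, chromophore = chromophore_codes()) {
  stopifnot(is.character(key), length(key) == 1L)
  if (key == "hydroxyl65") {
    ser65 <- find_residue(model, 65, "SER")
    if (nrow(ser65)) return(pick_atom(ser65, "OG", key))
    cro <- find_chromophore(model, chromophore)
    return(pick_atom(cro, "OG1", key))
  }
  parts <- strsplit(key, ".", fixed = TRUE)[[1]]
  if (length(parts) != 2L) {
    stop("unresolvable site key '", key,
         "': expected '<Residue><number>.<atom>', 'chromophore.<atom>' ",
         "or 'pos<number>.distal'")
  }
  res_part <- parts[1]
  atom_part <- parts[2]
  if (grepl("^pos[0-9]+$", res_part)) {
    resno <- as.integer(sub("^pos", "", res_part))
    res <- find_residue(model, resno)
    if (!nrow(res)) stop("no residue at position ", resno)
    if (atom_part == "distal") atom_part <- pos203_distal_name(res$resid[1])
    return(pick_atom(res, translate_atom(atom_part, res$resid[1]), key))
  }
  if (res_part %in% c("chromophore", chromophore)) {
    cro <- find_chromophore(model, chromophore)
    return(pick_atom(cro, translate_atom(atom_part, cro$resid[1]), key))
  }
  m <- regmatches(res_part, regexec("^([A-Za-z]{2,3})([0-9]+)$", res_part))[[1]]
  if (length(m) != 3L) stop("unresolvable site key '", key, "'")
  resid <- toupper(m[2])
  resno <- as.integer(m[3])
  res <- find_residue(model, resno, resid)
  if (!nrow(res)) {
    stop("no ", resid, " at position ", resno, " (key '", key, "')")
  }
  pick_atom(res, translate_atom(atom_part, resid), key)
}

translate_atom <- function(atom, resid) {
  vocab <- site_vocabulary()
  if (atom %in% names(vocab)) {
    atom <- unname(vocab[atom])
    # Ogamma is OG on Ser but OG1 on Thr
    if (atom == "OG" && toupper(resid) == "THR") atom <- "OG1"
    if (atom == "OG1" && toupper(resid) == "SER") atom <- "OG"
  }
  atom
}

pick_atom <- function(res, atom_name, key) {
  hit <- res[res$elety == atom_name, , drop = FALSE]
  if (nrow(hit) != 1L) {
    stop("site key '", key, "' does not resolve to exactly one atom; ",
         "candidates in residue: ", paste(unique(res$elety), collapse = " "))
  }
  hit
}

#' Find the water bridging two sites
#'
#' Identifies the water oxygen (residue `HOH`/`WAT`) that bridges two
#' partner sites: both partner distances must be within `cutoff`, and
#' among eligible waters the one minimizing the summed distance is
#' returned. This operationalizes "Wat3", the conserved water between the
#' chromophore hydroxyl and Ser205 in the proton relay. Ties and ordering
#' are resolved by residue number, so the result does not depend on
#' record order.
#'
#' @param model A `structure_model`.
#' @param partners Character vector of two site keys
#'   (default `c("chromophore.OH", "Ser205.OG")`).
#' @param cutoff Maximum donor/acceptor distance in angstrom (default 3.5).
#' @return One-row data.frame (the water oxygen), or `NULL` when no water
#'   qualifies.
#' @export
find_bridging_water <- function(model,
                                partners = c("chromophore.OH", "Ser205.OG"),
                                cutoff = 3.5) {
  stopifnot(length(partners) == 2L)
  p1 <- resolve_site(model, partners[1])
  p2 <- resolve_site(model, partners[2])
  sel <- model$selected
  wat <- sel[sel$resid %in% c("HOH", "WAT") & sel$elesy == "O", , drop = FALSE]
  if (!nrow(wat)) return(NULL)
  d1 <- sqrt((wat$x - p1$x)^2 + (wat$y - p1$y)^2 + (wat$z - p1$z)^2)
  d2 <- sqrt((wat$x - p2$x)^2 + (wat$y - p2$y)^2 + (wat$z - p2$z)^2)
  ok <- d1 <= cutoff & d2 <= cutoff
  if (!any(ok)) return(NULL)
  wat <- wat[ok, , drop = FALSE]
  total <- (d1 + d2)[ok]
  ord <- order(total, wat$resno)
  wat[ord[1], , drop = FALSE]
}
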