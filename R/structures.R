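# Structure I/O. A protein structure is a tibble of heavy atoms (one row per
# atom) carrying residue identity, coordinates in the PDB orthogonal frame
# (Angstrom) and Van der Waals radii. Parsing is backed by bio3d; this layer
# applies the pipeline's conventions: first MODEL only, waters and hydrogens
# excluded by default, alternate locations resolved to highest occupancy.

.water_names <- c("HOH", "WAT", "DOD", "H2O")

new_protein_structure <- function(atoms) {
  structure(
    as_tibble(atoms),
    class = c("protein_structure", class(tibble())))
}

#' Parse a PDB structure
#'
#' Reads ATOM/HETATM records from a PDB file or from PDB-format text. Only
#' the first MODEL is used. By default waters and hydrogens are dropped and
#' alternate locations are resolved to the highest-occupancy conformer (ties
#' broken by altloc letter order). Heteroatoms other than selenomethionine
#' (MSE) are excluded unless `keep_hetero = TRUE`.
#'
#' @param source Path to a PDB file, or a character string of PDB text
#'   (recognized by embedded newlines).
#' @param keep_hydrogens,keep_waters,keep_hetero Retain hydrogen atoms,
#'   water molecules, or non-MSE HETATM records.
#' @return A `protein_structure`: a tibble with one row per atom and columns
#'   `chain_id`, `res_name`, `res_id`, `icode`, `serial`, `atom_name`,
#'   `element`, `x`, `y`, `z`, `occupancy`, `vdw_radius`, `is_heavy`.
#' @examples
#' pdb_txt <- paste(
#'   "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
#'   "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
#'   "END", sep = "\n")
#' read_pdb(pdb_txt)
#' @export
read_pdb <- function(source, keep_hydrogens = FALSE, keep_waters = FALSE,
                     keep_hetero = FALSE) {
  path <- source
  if (length(source) != 1 || grepl("\n", source, fixed = TRUE)) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path), add = TRUE)
    writeLines(unlist(strsplit(paste(source, collapse = "\n"), "\n")), path)
  } else if (!file.exists(path)) {
    stopf("cannot read PDB source: no file '%s'", path,
          class = "pocketlit_io_error")
  }
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                                     verbose = FALSE)),
    error = function(e) {
      stopf("failed to parse PDB '%s': %s", path, conditionMessage(e),
            class = "pocketlit_io_error")
    }
  )
  at <- pdb$atom
  if (nrow(at) == 0) {
    stopf("no ATOM/HETATM records in PDB source", class = "pocketlit_empty_structure")
  }
  element <- at$elesy
  missing_el <- is.na(element) | element == ""
  if (any(missing_el)) {
    # fall back to the first alphabetic character of the atom name
    element[missing_el] <- sub("^[^A-Za-z]*([A-Za-z]).*$", "\\1",
                               at$elety[missing_el])
  }
  atoms <- tibble(
    record = at$type,
    chain_id = ifelse(is.na(at$chain), "", at$chain),
    res_name = toupper(at$resid),
    res_id = as.integer(at$resno),
    icode = ifelse(is.na(at$insert) | at$insert == "", NA_character_, at$insert),
    serial = as.integer(at$eleno),
    atom_name = at$elety,
    altloc = ifelse(is.na(at$alt), "", at$alt),
    element = element,
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o)
  )
  if (!keep_waters) atoms <- filter(atoms, !.data$res_name %in% .water_names)
  if (!keep_hetero) {
    atoms <- filter(atoms, .data$record == "ATOM" | .data$res_name == "MSE")
  }
  atoms <- mutate(atoms, is_heavy = !toupper(.data$element) %in% c("H", "D"))
  if (!keep_hydrogens) atoms <- filter(atoms, .data$is_heavy)
  if (nrow(atoms) == 0) {
    stopf("no polymer atoms remain after filtering (waters/hetero/hydrogens)",
          class = "pocketlit_empty_structure")
  }
  # altloc: keep the highest-occupancy conformer per (residue, atom name);
  # ties broken by altloc letter order, '' sorting first
  atoms <- atoms %>%
    group_by(.data$chain_id, .data$res_id, .data$icode, .data$atom_name) %>%
    arrange(desc(.data$occupancy), .data$altloc, .by_group = TRUE) %>%
    slice(1) %>%
    ungroup() %>%
    arrange(.data$serial)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    stopf("non-finite atom coordinates in PDB source", class = "pocketlit_io_error")
  }
  atoms$vdw_radius <- suppressWarnings(vdw_radius(atoms$element))
  new_protein_structure(select(atoms, -"record", -"altloc"))
}

#' Write a structure to PDB format
#'
#' Serializes a `protein_structure` back to a PDB file, primarily for
#' debugging and fixture generation. Round-trips through [read_pdb()]
#' preserve the residue and atom inventory.
#'
#' @param structure A `protein_structure`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(structure, path) {
  bio3d::write.pdb(
    file = path,
    xyz = as.numeric(t(as_xyz_matrix(structure))),
    type = rep("ATOM", nrow(structure)),
    resno = structure$res_id,
    resid = structure$res_name,
    eleno = structure$serial,
    elety = structure$atom_name,
    chain = ifelse(structure$chain_id == "", " ", structure$chain_id),
    insert = ifelse(is.na(structure$icode), "", structure$icode),
    o = structure$occupancy,
    b = rep(0, nrow(structure)),
    elesy = structure$element
  )
  invisible(path)
}

#' Unique residues of a structure
#'
#' @param structure A `protein_structure`.
#' @param chain_id Optional chain filter.
#' @return A residue-ref tibble in order of first appearance, with an
#'   `n_heavy` column counting heavy atoms per residue.
#' @export
structure_residues <- function(structure, chain_id = NULL) {
  atoms <- structure
  cid <- chain_id
  if (!is.null(cid)) atoms <- filter(atoms, .data$chain_id %in% cid)
  atoms %>%
    group_by(.data$chain_id, .data$res_id, .data$icode) %>%
    summarise(
      res_name = first(.data$res_name),
      n_heavy = sum(.data$is_heavy),
      first_serial = min(.data$serial),
      .groups = "drop"
    ) %>%
    arrange(.data$first_serial) %>%
    select("chain_id", "res_name", "res_id", "icode", "n_heavy")
}

#' Chain identifiers of a structure
#' @param structure A `protein_structure`.
#' @return Character vector of chain ids in order of first appearance.
#' @export
structure_chains <- function(structure) {
  unique(structure$chain_id)
}

#' One-letter sequence of a chain
#'
#' Residues are emitted in order of first appearance; nonstandard residues
#' become `"X"` (MSE aliases to `"M"` by default). An empty `chain_id` on a
#' single-chain structure selects that chain.
#'
#' @param structure A `protein_structure`.
#' @param chain_id Chain identifier.
#' @param alias_mse Treat selenomethionine as methionine.
#' @return A one-letter sequence string.
#' @export
chain_sequence <- function(structure, chain_id, alias_mse = TRUE) {
  chains <- structure_chains(structure)
  if ((is.null(chain_id) || chain_id == "") && length(chains) == 1) {
    chain_id <- chains[[1]]
  }
  if (!chain_id %in% chains) {
    stopf("no chain '%s' in structure (chains: %s)", chain_id,
          paste(chains, collapse = ", "), class = "pocketlit_lookup_error")
  }
  res <- structure_residues(structure, chain_id = chain_id)
  paste(residue_one_letter(res$res_name, alias_mse = alias_mse), collapse = "")
}

# heavy-atom coordinates for a set of residue refs, resolved against the
# structure; returns one row per atom with the residue key attached
residue_heavy_atoms <- function(structure, residues) {
  keys <- res_key(residues$chain_id, residues$res_id, residues$icode)
  atoms <- filter(structure, .data$is_heavy)
  akey <- res_key(atoms$chain_id, atoms$res_id, atoms$icode)
  atoms[akey %in% keys, ]
}

# heavy-atom centroid per residue (representative point for clustering)
residue_centroids <- function(structure, residues = NULL) {
  atoms <- filter(structure, .data$is_heavy)
  if (!is.null(residues)) atoms <- residue_heavy_atoms(structure, residues)
  atoms %>%
    group_by(.data$chain_id, .data$res_id, .data$icode) %>%
    summarise(
      res_name = first(.data$res_name),
      x = mean(.data$x), y = mean(.data$y), z = mean(.data$z),
      .groups = "drop"
    )
}
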