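# Coordinate file I/O. Reading goes through bio3d (PDB and mmCIF); PDB
# writing through bio3d::write.pdb. mmCIF writing is a minimal atom_site
# loop emitter.

.element_from_name <- function(name) {
  ifelse(grepl("^FE", toupper(name)), "Fe",
         ifelse(grepl("^S", toupper(name)), "S",
                paste0(substr(toupper(name), 1, 1),
                       tolower(substr(name, 2, 2)))))
}

#' Read a macromolecular coordinate file
#'
#' Reads PDB (`.pdb`, `.ent`) or mmCIF (`.cif`, `.mmcif`) via bio3d and
#' returns the package's tidy atom table. Alternate locations are reduced
#' to the highest-occupancy conformer per atom.
#'
#' @param path Path to the coordinate file.
#' @return An atom tibble (see [atom_table()]).
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) {
    stop("file not found: ", path, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  pdb <- if (ext %in% c("cif", "mmcif")) {
    bio3d::read.cif(path, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, verbose = FALSE)
  }
  at <- pdb$atom
  elem <- trimws(as.character(at$elesy))
  bad <- is.na(elem) | elem == ""
  elem[bad] <- .element_from_name(trimws(at$elety[bad]))
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 2)))
  elem <- trimws(elem)
  out <- tibble::tibble(
    record = at$type,
    atom_name = toupper(trimws(at$elety)),
    element = elem,
    residue_name = toupper(trimws(at$resid)),
    chain_id = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    residue_number = as.integer(at$resno),
    x = at$x, y = at$y, z = at$z,
    occupancy = ifelse(is.na(at$o), 1, at$o),
    b_factor = ifelse(is.na(at$b), 0, at$b))
  # highest-occupancy conformer per (chain, residue, atom)
  out |>
    dplyr::group_by(.data$chain_id, .data$residue_number,
                    .data$residue_name, .data$atom_name) |>
    dplyr::slice_max(.data$occupancy, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$chain_id, .data$residue_number)
}

#' Write an atom table to a coordinate file
#'
#' @param model An atom tibble.
#' @param path Output path; format chosen by extension (`.cif`/`.mmcif`
#'   for mmCIF, otherwise PDB).
#' @return `path`, invisibly.
#' @export
write_structure <- function(model, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("cif", "mmcif")) {
    .write_mmcif(model, path)
  } else {
    .write_pdb(model, path)
  }
  invisible(path)
}

.write_pdb <- function(model, path) {
  xyz <- as.vector(t(.atom_xyz(model)))
  bio3d::write.pdb(
    pdb = NULL, file = path, xyz = xyz,
    type = model$record,
    resno = model$residue_number,
    resid = model$residue_name,
    chain = model$chain_id,
    elety = model$atom_name,
    o = model$occupancy,
    b = model$b_factor,
    elesy = toupper(model$element))
  invisible(path)
}

.write_mmcif <- function(model, path) {
  lines <- c(
    "data_model",
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf(paste("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f",
                  "? %d %s %s %s 1"),
            model$record, seq_len(nrow(model)), toupper(model$element),
            model$atom_name, model$residue_name, model$chain_id,
            model$residue_number, model$x, model$y, model$z,
            model$occupancy, model$b_factor, model$residue_number,
            model$residue_name, model$chain_id, model$atom_name),
    "#")
  writeLines(lines, path)
  invisible(path)
}
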