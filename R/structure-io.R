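#' Build an atom table
#'
#' Constructs the atom-level tibble used throughout the package: one row per
#' atom with identity, position, occupancy, B-factor and element columns.
#' Mostly useful for building structures programmatically (the synthetic
#' generator uses it); files are read with [read_structure()].
#'
#' @param atoms A data frame with (a subset of) columns `serial`, `atom`,
#'   `altloc`, `res_name`, `chain`, `resseq`, `icode`, `x`, `y`, `z`,
#'   `occupancy`, `b_factor`, `element`, `is_hetero`. Missing bookkeeping
#'   columns are filled with defaults.
#' @param id Structure identifier stored as an attribute.
#' @return A tibble of atoms with attribute `id`.
#' @export
as_structure <- function(atoms, id = "structure") {
  atoms <- as_tibble(atoms)
  n <- nrow(atoms)
  defaults <- list(
    serial = seq_len(n), altloc = "", icode = "", occupancy = 1,
    b_factor = 20, is_hetero = FALSE, element = NA_character_
  )
  for (nm in names(defaults)) {
    if (is.null(atoms[[nm]])) atoms[[nm]] <- rep(defaults[[nm]], length.out = n)
  }
  required <- c("atom", "res_name", "chain", "resseq", "x", "y", "z")
  missing <- setdiff(required, names(atoms))
  if (length(missing) > 0) {
    abort(paste("atom table is missing columns:", paste(missing, collapse = ", ")))
  }
  atoms$element <- ifelse(
    is.na(atoms$element) | atoms$element == "",
    guess_element(atoms$atom, atoms$is_hetero),
    toupper(atoms$element)
  )
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort("atom positions must be finite")
  }
  if (any(atoms$occupancy < 0 | atoms$occupancy > 1, na.rm = TRUE)) {
    abort("occupancy must lie in [0, 1]")
  }
  if (any(atoms$b_factor < 0, na.rm = TRUE)) abort("b_factor must be >= 0")
  atoms <- atoms[c(
    "serial", "atom", "altloc", "res_name", "chain", "resseq", "icode",
    "x", "y", "z", "occupancy", "b_factor", "element", "is_hetero"
  )]
  attr(atoms, "id") <- id
  atoms
}

# Infer the element symbol from a PDB atom name when the element columns are
# absent. Two-letter element symbols are only trusted for hetero records
# (protein atom names like "CA"/"CD2" start with the one-letter element).
guess_element <- function(name, is_hetero) {
  two_letter <- c(METAL_ELEMENTS, "CL", "BR", "SE", "SI")
  stripped <- toupper(gsub("[^A-Za-z]", "", name))
  out <- substr(stripped, 1, 1)
  het2 <- is_hetero & stripped %in% two_letter
  out[het2] <- stripped[het2]
  out
}

#' Read a macromolecular structure
#'
#' Reads a PDB or mmCIF coordinate file (or raw text in either format) into
#' a tidy atom table. All ATOM/HETATM records are kept, including alternate
#' conformers, waters and hydrogens; downstream modules decide what to
#' ignore. Elements missing from the file are inferred from atom names.
#'
#' @param source Path to a file, or a character string containing the file
#'   text.
#' @param format `"pdb"`, `"mmcif"`, or `"auto"` (sniffed from the file
#'   extension or content).
#' @return A tibble of atoms (see [as_structure()]).
#' @export
#' @examples
#' pdb <- "ATOM      1  SG  CYS A   1       0.000   0.000   2.100  1.00 10.00           S"
#' read_structure(pdb, format = "pdb")
read_structure <- function(source, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  is_path <- length(source) == 1 && !grepl("\n", source) && file.exists(source)
  if (!is_path) {
    path <- tempfile(fileext = ".coords")
    writeLines(source, path)
    on.exit(unlink(path))
    id <- "structure"
  } else {
    path <- source
    id <- sub("\\.(pdb|ent|cif|mmcif)$", "", basename(path), ignore.case = TRUE)
  }
  if (format == "auto") {
    if (is_path && grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      format <- "mmcif"
    } else if (is_path && grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
      format <- "pdb"
    } else {
      txt <- readLines(path, n = 50, warn = FALSE)
      format <- if (any(grepl("^data_|^_atom_site\\.|^loop_", txt))) "mmcif" else "pdb"
    }
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE) else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) abort(paste0("parse error reading ", format, " input: ", conditionMessage(e)))
  )
  a <- parsed$atom
  blank <- function(v) ifelse(is.na(v), "", v)
  atoms <- tibble(
    serial = as.integer(a$eleno),
    atom = a$elety,
    altloc = blank(a$alt),
    res_name = a$resid,
    chain = blank(a$chain),
    resseq = as.integer(a$resno),
    icode = blank(a$insert),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = ifelse(is.na(a$b), 0, a$b),
    element = ifelse(is.na(a$elesy) | a$elesy == "", NA_character_, toupper(a$elesy)),
    is_hetero = a$type == "HETATM"
  )
  as_structure(atoms, id = id)
}

#' Keep the primary alternate conformer
#'
#' For every atom modelled in alternate conformations, keeps the conformer
#' with the highest occupancy (ties broken by the alphabetically lowest
#' altloc). Residues that had alternates are recorded in the
#' `multi_conformer` attribute so training-set construction can exclude
#' multi-conformational sites.
#'
#' @param structure An atom tibble.
#' @return The filtered atom tibble, with attribute `multi_conformer`
#'   (a tibble of chain/resseq/icode).
#' @export
primary_conformer <- function(structure) {
  id <- attr(structure, "id")
  key <- paste(structure$chain, structure$resseq, structure$icode,
               structure$atom, sep = "\r")
  dup_keys <- unique(key[duplicated(key)])
  if (length(dup_keys) == 0) {
    attr(structure, "multi_conformer") <-
      tibble(chain = character(), resseq = integer(), icode = character())
    return(structure)
  }
  is_dup <- key %in% dup_keys
  flagged <- distinct(structure[is_dup, c("chain", "resseq", "icode")])
  keep <- !logical(nrow(structure))
  for (k in dup_keys) {
    idx <- which(key == k)
    ord <- order(-structure$occupancy[idx], structure$altloc[idx])
    keep[idx[-ord[1]]] <- FALSE
  }
  out <- structure[keep, ]
  attr(out, "id") <- id
  attr(out, "multi_conformer") <- flagged
  out
}

# Fixed-column PDB ATOM/HETATM record. Atom names shorter than 4 characters
# start in column 14 per the standard.
pdb_atom_line <- function(rec, type) {
  name <- rec$atom
  if (nchar(name) < 4) name <- paste0(" ", name)
  sprintf(
    "%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    type, rec$serial %% 100000L, name, substr(rec$altloc, 1, 1),
    rec$res_name, substr(rec$chain, 1, 1), rec$resseq %% 10000L,
    substr(rec$icode, 1, 1), rec$x, rec$y, rec$z, rec$occupancy,
    rec$b_factor, rec$element
  )
}

pdb_link_line <- function(zn, lig, dist) {
  sprintf(
    "LINK        %-4s%1s%-3s %1s%4d%1s              %-4s%1s%-3s %1s%4d%1s                %5.2f",
    "ZN", "", "ZN", substr(zn$chain, 1, 1), zn$resseq, "",
    ifelse(nchar(lig$atom) < 4, paste0(" ", lig$atom), lig$atom), "",
    lig$res_name, substr(lig$chain, 1, 1), lig$resseq,
    substr(lig$icode, 1, 1), dist
  )
}

#' Write a structure with predicted zinc sites
#'
#' Emits the original atom records unmodified (and in their original order),
#' followed by one hetero zinc record per predicted site whose occupancy
#' field carries the site's certainty (rounded to two decimals), plus one
#' connection record (PDB `LINK` / mmCIF `struct_conn`) per coordination
#' bond. Predicted zincs are placed on their own chain (`"Z"` by default) to
#' distinguish them from experimentally modelled ions.
#'
#' @param structure An atom tibble.
#' @param sites Placed-site tibble (see [place_zinc()]) with columns
#'   `zn_x`, `zn_y`, `zn_z`, `certainty` and the `ligands` list-column.
#' @param format `"pdb"` or `"mmcif"`.
#' @param path Optional output file; when `NULL` the text is returned only.
#' @param predicted_chain Chain identifier given to predicted zinc records.
#' @return Invisibly, the lines of the output file.
#' @export
write_predictions <- function(structure, sites, format = c("pdb", "mmcif"),
                              path = NULL, predicted_chain = "Z") {
  format <- match.arg(format)
  sites <- as_tibble(sites)
  if (nrow(sites) > 0) {
    if (is.null(sites[["certainty"]]) || any(is.na(sites$certainty)) ||
        any(sites$certainty < 0 | sites$certainty > 1)) {
      abort("every site must carry a certainty in [0, 1]")
    }
  }
  zn_recs <- NULL
  if (nrow(sites) > 0) {
    zn_recs <- tibble(
      serial = max(structure$serial, 0L) + seq_len(nrow(sites)),
      atom = "ZN", altloc = "", res_name = "ZN", chain = predicted_chain,
      resseq = seq_len(nrow(sites)), icode = "",
      x = sites$zn_x, y = sites$zn_y, z = sites$zn_z,
      occupancy = round(sites$certainty, 2),
      b_factor = 0, element = "ZN", is_hetero = TRUE
    )
  }
  lines <- if (format == "pdb") {
    write_pdb_lines(structure, sites, zn_recs)
  } else {
    write_mmcif_lines(structure, sites, zn_recs)
  }
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

write_pdb_lines <- function(structure, sites, zn_recs) {
  lines <- character(0)
  if (nrow(sites) > 0) {
    for (i in seq_len(nrow(sites))) {
      zn <- zn_recs[i, ]
      lig <- sites$ligands[[i]]
      for (j in seq_len(nrow(lig))) {
        d <- vdist(c(zn$x, zn$y, zn$z), c(lig$x[j], lig$y[j], lig$z[j]))
        lines <- c(lines, pdb_link_line(zn, lig[j, ], d))
      }
    }
  }
  for (i in seq_len(nrow(structure))) {
    rec <- structure[i, ]
    lines <- c(lines, pdb_atom_line(rec, if (rec$is_hetero) "HETATM" else "ATOM"))
  }
  if (!is.null(zn_recs)) {
    for (i in seq_len(nrow(zn_recs))) {
      lines <- c(lines, pdb_atom_line(zn_recs[i, ], "HETATM"))
    }
  }
  c(lines, "END")
}

write_mmcif_lines <- function(structure, sites, zn_recs) {
  all_atoms <- if (is.null(zn_recs)) structure else bind_rows(structure, zn_recs)
  hdr <- c(
    "data_znsite",
    "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id",
    "_atom_site.label_seq_id", "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  q <- function(v) ifelse(is.na(v) | v == "", "?", v)
  body <- sprintf(
    "%-6s %d %s %s %s %s %s 1 %d %s %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
    ifelse(all_atoms$is_hetero, "HETATM", "ATOM"), all_atoms$serial,
    q(all_atoms$element), q(all_atoms$atom), q(all_atoms$altloc),
    q(all_atoms$res_name), q(all_atoms$chain), all_atoms$resseq,
    q(all_atoms$icode), all_atoms$x, all_atoms$y, all_atoms$z,
    all_atoms$occupancy, all_atoms$b_factor, all_atoms$resseq,
    q(all_atoms$res_name), q(all_atoms$chain), q(all_atoms$atom)
  )
  conn <- character(0)
  if (nrow(sites) > 0) {
    conn <- c(
      "#", "loop_",
      "_struct_conn.id", "_struct_conn.conn_type_id",
      "_struct_conn.ptnr1_label_asym_id", "_struct_conn.ptnr1_label_seq_id",
      "_struct_conn.ptnr1_label_atom_id",
      "_struct_conn.ptnr2_label_asym_id", "_struct_conn.ptnr2_label_seq_id",
      "_struct_conn.ptnr2_label_atom_id",
      "_struct_conn.pdbx_dist_value"
    )
    k <- 0
    for (i in seq_len(nrow(sites))) {
      zn <- zn_recs[i, ]
      lig <- sites$ligands[[i]]
      for (j in seq_len(nrow(lig))) {
        k <- k + 1
        d <- vdist(c(zn$x, zn$y, zn$z), c(lig$x[j], lig$y[j], lig$z[j]))
        conn <- c(conn, sprintf(
          "metalc%d metalc %s %d ZN %s %d %s %.3f",
          k, zn$chain, zn$resseq, lig$chain[j], lig$resseq[j], lig$atom[j], d
        ))
      }
    }
  }
  c(hdr, body, conn, "#")
}
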