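ATOM_COLS <- c("atom_id", "record", "name", "altloc", "residue_name",
               "chain_id", "residue_number", "icode", "x", "y", "z",
               "occupancy", "b_factor", "element")

METAL_ELEMENTS <- c("MG", "K", "NA", "ZN")
WATER_RESIDUES <- c("HOH", "WAT", "DOD")

new_mg_structure <- function(atoms, provenance = list()) {
  atoms <- tibble::as_tibble(atoms)
  missing_cols <- setdiff(ATOM_COLS, names(atoms))
  if (length(missing_cols)) {
    rlang::abort(paste0("atom table lacks column(s): ",
                        paste(missing_cols, collapse = ", ")))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (nrow(atoms) && !all(is.finite(xyz))) {
    rlang::abort("non-finite coordinates in atom table")
  }
  occ <- atoms$occupancy
  if (any(!is.na(occ) & (occ < 0 | occ > 1))) {
    rlang::abort("occupancy outside [0, 1]")
  }
  structure(atoms, class = c("mg_structure", class(tibble::tibble()))) |>
    set_provenance(provenance)
}

set_provenance <- function(atoms, provenance) {
  attr(atoms, "provenance") <- provenance
  atoms
}

#' @export
print.mg_structure <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<mg_structure> ", nrow(x), " atoms",
      if (!is.null(prov$source)) paste0(" from ", prov$source), "\n", sep = "")
  if ("role" %in% names(x)) {
    n_metal <- sum(x$role == "metal")
    cat("  roles assigned; ", n_metal, " metal ion(s)\n", sep = "")
  }
  NextMethod()
}

#' Read a structure file into a typed atom table
#'
#' Parses an mmCIF (PDBx `atom_site` loop) or PDB v3.3 coordinate file into
#' one row per atom.  Waters and metals are retained; hydrogens are kept in
#' the table but are never treated as ligands downstream.  Alternate
#' conformations other than `''`/`'A'` are dropped (single-conformer
#' analysis); author chain/residue numbering is the reporting identity.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return an `mg_structure` tibble with columns `atom_id`, `record`,
#'   `name`, `altloc`, `residue_name`, `chain_id`, `residue_number`,
#'   `icode`, `x`, `y`, `z` (Angstrom), `occupancy`, `b_factor` (A^2),
#'   `element`.
#' @seealso [assign_roles()], [write_structure()]
#' @examples
#' f <- tempfile(fileext = ".cif")
#' write_structure(make_fixture("ideal_6Ow")$atoms, f)
#' read_structure(f)
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
      "pdb"
    } else {
      rlang::abort(paste0("cannot guess format from extension of ", path,
                          "; pass format = 'mmcif' or 'pdb'"))
    }
  }
  atoms <- switch(format,
    mmcif = read_mmcif_atoms(path),
    pdb = read_pdb_atoms(path)
  )
  if (nrow(atoms) == 0L) {
    rlang::abort(paste0("empty structure: no ATOM/HETATM records in ", path))
  }
  # Single-conformer policy: keep blank or 'A' alternate locations only.
  atoms <- dplyr::filter(atoms, .data$altloc %in% c("", "A"))
  atoms$atom_id <- seq_len(nrow(atoms))
  new_mg_structure(atoms, provenance = list(source = path, format = format))
}

read_pdb_atoms <- function(path) {
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                     multi = FALSE)),
    error = function(e) {
      rlang::abort(paste0("failed to parse PDB file ", path, ": ",
                          conditionMessage(e)))
    }
  )
  a <- pdb$atom
  tibble::tibble(
    atom_id = seq_len(nrow(a)),
    record = a$type,
    name = trimws(a$elety),
    altloc = dplyr::coalesce(trimws(a$alt), ""),
    residue_name = trimws(a$resid),
    chain_id = dplyr::coalesce(trimws(a$chain), ""),
    residue_number = as.integer(a$resno),
    icode = dplyr::coalesce(trimws(a$insert), ""),
    x = a$x, y = a$y, z = a$z,
    occupancy = dplyr::coalesce(a$o, 1),
    b_factor = dplyr::coalesce(a$b, 0),
    element = guess_element(trimws(dplyr::coalesce(a$elesy, "")),
                            trimws(a$elety), trimws(a$resid))
  )
}

# Minimal quote-aware PDBx/mmCIF atom_site reader.  Handles the standard
# loop_ layout with values separated by whitespace and '...'/"..." quoting
# (primed atom names such as "O2'" are quoted in PDBx files).
read_mmcif_atoms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  for (start in loop_starts) {
    i <- start + 1L
    fields <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      fields <- c(fields, trimws(lines[i]))
      i <- i + 1L
    }
    if (!any(startsWith(fields, "_atom_site."))) next
    fields <- sub("^_atom_site\\.", "", fields)
    rows <- list()
    while (i <= length(lines)) {
      line <- lines[i]
      trimmed <- trimws(line)
      if (trimmed %in% c("#", "loop_") || startsWith(trimmed, "_") ||
          startsWith(trimmed, "data_") || trimmed == "stop_") {
        break
      }
      if (nzchar(trimmed)) {
        tokens <- cif_tokens(line)
        if (length(tokens) != length(fields)) {
          rlang::abort(paste0(
            "malformed mmCIF atom_site row at line ", i, " of ", path, ": ",
            length(tokens), " values for ", length(fields), " columns"))
        }
        rows[[length(rows) + 1L]] <- tokens
      }
      i <- i + 1L
    }
    if (!length(rows)) return(empty_atom_table())
    m <- do.call(rbind, rows)
    colnames(m) <- fields
    return(atom_site_to_table(m, path))
  }
  rlang::abort(paste0("no atom_site loop found in mmCIF file ", path))
}

cif_tokens <- function(line) {
  m <- gregexpr("'[^']*'|\"[^\"]*\"|\\S+", line)[[1]]
  tokens <- regmatches(line, list(m))[[1]]
  sub("^['\"]", "", sub("['\"]$", "", tokens))
}

cif_col <- function(m, name, default = NA_character_) {
  if (name %in% colnames(m)) m[, name] else rep(default, nrow(m))
}

atom_site_to_table <- function(m, path) {
  blank_if_missing <- function(v) ifelse(v %in% c(".", "?") | is.na(v), "", v)
  name <- blank_if_missing(cif_col(m, "auth_atom_id"))
  fallback <- blank_if_missing(cif_col(m, "label_atom_id"))
  name <- ifelse(nzchar(name), name, fallback)
  resname <- blank_if_missing(cif_col(m, "auth_comp_id"))
  resname <- ifelse(nzchar(resname),
                    resname, blank_if_missing(cif_col(m, "label_comp_id")))
  chain <- blank_if_missing(cif_col(m, "auth_asym_id"))
  chain <- ifelse(nzchar(chain),
                  chain, blank_if_missing(cif_col(m, "label_asym_id")))
  resno <- blank_if_missing(cif_col(m, "auth_seq_id"))
  resno <- ifelse(nzchar(resno),
                  resno, blank_if_missing(cif_col(m, "label_seq_id")))
  num <- function(v, default) {
    out <- suppressWarnings(as.numeric(blank_if_missing(v)))
    ifelse(is.na(out), default, out)
  }
  xyz <- cbind(suppressWarnings(as.numeric(cif_col(m, "Cartn_x"))),
               suppressWarnings(as.numeric(cif_col(m, "Cartn_y"))),
               suppressWarnings(as.numeric(cif_col(m, "Cartn_z"))))
  if (anyNA(xyz)) {
    rlang::abort(paste0("non-numeric coordinates in atom_site loop of ", path))
  }
  tibble::tibble(
    atom_id = seq_len(nrow(m)),
    record = cif_col(m, "group_PDB", "ATOM"),
    name = name,
    altloc = blank_if_missing(cif_col(m, "label_alt_id")),
    residue_name = resname,
    chain_id = chain,
    residue_number = as.integer(num(resno, NA_real_)),
    icode = blank_if_missing(cif_col(m, "pdbx_PDB_ins_code")),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occupancy = num(cif_col(m, "occupancy"), 1),
    b_factor = num(cif_col(m, "B_iso_or_equiv"), 0),
    element = guess_element(blank_if_missing(cif_col(m, "type_symbol")),
                            name, resname)
  )
}

empty_atom_table <- function() {
  tibble::tibble(
    atom_id = integer(), record = character(), name = character(),
    altloc = character(), residue_name = character(), chain_id = character(),
    residue_number = integer(), icode = character(),
    x = double(), y = double(), z = double(),
    occupancy = double(), b_factor = double(), element = character()
  )
}

# Element from the type_symbol column when present, else from the atom name
# (leading letters, honouring two-letter metal/ion symbols).
guess_element <- function(symbol, name, resname) {
  symbol <- toupper(symbol)
  out <- ifelse(!is.na(symbol) & nzchar(symbol), symbol, NA_character_)
  need <- is.na(out)
  if (any(need)) {
    stripped <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", name)))
    two <- stripped %in% c(METAL_ELEMENTS, "FE", "MN", "CL", "BR", "CA", "CO",
                           "NI", "CU", "CD", "HG", "SE")
    # Two-letter ion names only when the residue is the ion itself,
    # otherwise 'CA' is an alpha carbon, 'ND1' a nitrogen, etc.
    is_ion_residue <- toupper(resname) == stripped
    out[need] <- ifelse(two[need] & is_ion_residue[need],
                        stripped[need],
                        substr(stripped[need], 1, 1))
  }
  out
}

#' Write an atom table to mmCIF or PDB
#'
#' @param atoms an `mg_structure` (or compatible tibble).
#' @param path output file path.
#' @param format `"auto"` (by extension), `"mmcif"` or `"pdb"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, format = c("auto", "mmcif", "pdb")) {
  format <- match.arg(format)
  if (nrow(atoms) == 0L) rlang::abort("refusing to write an empty structure")
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE)) {
      "mmcif"
    } else "pdb"
  }
  if (format == "pdb") {
    bio3d::write.pdb(
      file = path,
      xyz = as.numeric(t(as.matrix(atoms[, c("x", "y", "z")]))),
      type = atoms$record,
      resno = atoms$residue_number,
      resid = atoms$residue_name,
      eleno = atoms$atom_id,
      elety = atoms$name,
      chain = atoms$chain_id,
      insert = ifelse(nzchar(atoms$icode), atoms$icode, NA),
      alt = ifelse(nzchar(atoms$altloc), atoms$altloc, NA),
      o = atoms$occupancy,
      b = atoms$b_factor,
      elesy = atoms$element
    )
  } else {
    write_mmcif_atoms(atoms, path)
  }
  invisible(path)
}

write_mmcif_atoms <- function(atoms, path) {
  quote_cif <- function(v) ifelse(grepl("'", v), paste0('"', v, '"'), v)
  blank_dot <- function(v) ifelse(is.na(v) | !nzchar(as.character(v)), ".",
                                  as.character(v))
  rows <- sprintf(
    "%s %d %s %s %s %s %s %s %s %.3f %.3f %.3f %.2f %.2f %s %s %s %s 1",
    atoms$record, atoms$atom_id, blank_dot(atoms$element),
    quote_cif(atoms$name), blank_dot(atoms$altloc),
    atoms$residue_name, atoms$chain_id,
    blank_dot(atoms$residue_number), blank_dot(atoms$icode),
    atoms$x, atoms$y, atoms$z, atoms$occupancy, atoms$b_factor,
    blank_dot(atoms$residue_number), atoms$residue_name, atoms$chain_id,
    quote_cif(atoms$name)
  )
  header <- c(
    "data_mgion_fixture",
    "#",
    "loop_",
    paste0("_atom_site.", c(
      "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
      "label_comp_id", "label_asym_id", "label_seq_id", "pdbx_PDB_ins_code",
      "Cartn_x", "Cartn_y", "Cartn_z", "occupancy", "B_iso_or_equiv",
      "auth_seq_id", "auth_comp_id", "auth_asym_id", "auth_atom_id",
      "pdbx_PDB_model_num"))
  )
  writeLines(c(header, rows, "#"), path)
}
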