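# PDB coordinate records are fixed-width; columns below are 1-based
# inclusive per the wwPDB format description (v3.3):
#   record 1-6, serial 7-11, name 13-16, altLoc 17, resName 18-20,
#   chainID 22, resSeq 23-26, x 31-38, y 39-46, z 47-54, element 77-78.

#' Construct a structure model
#'
#' A flat atom table for one protein chain set: polymer (`ATOM`) and hetero
#' (`HETATM`) records with residue numbering as printed in the file
#' (1-based, strictly positive).
#'
#' @param atoms data.frame with columns `residue_number`, `residue_name`,
#'   `chain`, `atom_name`, `x`, `y`, `z`, `record_kind`
#'   (`"polymer"` or `"hetero"`), and optionally `element`.
#' @return an object of class `structure_model`.
#' @export
new_structure_model <- function(atoms) {
  req <- c("residue_number", "residue_name", "chain", "atom_name",
           "x", "y", "z", "record_kind")
  missing <- setdiff(req, names(atoms))
  if (length(missing) > 0L) {
    abort_input("atom table lacks columns: %s", paste(missing, collapse = ", "))
  }
  if (nrow(atoms) == 0L) abort_input("structure contains no atoms")
  if (!all(atoms$record_kind %in% c("polymer", "hetero"))) {
    abort_input("record_kind must be 'polymer' or 'hetero'")
  }
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z))) {
    abort_input("non-finite atom coordinates")
  }
  if (any(atoms$residue_number < 1L)) {
    abort_input("residue numbering must be strictly positive")
  }
  if (is.null(atoms$element)) atoms$element <- guess_element(atoms$atom_name)
  structure(list(atoms = atoms), class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  a <- x$atoms
  cat(sprintf(
    "Structure: %d atoms (%d polymer residues, hetero groups: %s)\n",
    nrow(a), length(unique(a$residue_number[a$record_kind == "polymer"])),
    paste(unique(a$residue_name[a$record_kind == "hetero"]), collapse = ", ")))
  invisible(x)
}

# Chemical element from the PDB atom-name convention when the element
# column is blank: skip leading digits, first letter is the element
# (adequate for C/N/O/S/H/P protein and cofactor atoms).
guess_element <- function(atom_name) {
  toupper(substr(sub("^[0-9]*", "", trimws(atom_name)), 1, 1))
}

#' Read a PDB coordinate file
#'
#' Parses `ATOM` and `HETATM` records by fixed column positions. Alternate
#' locations other than blank or `A` are skipped so the atom set is
#' deterministic. Multi-model files are not supported (only records before
#' the first `ENDMDL` are read).
#'
#' @param path path to a PDB-format file.
#' @return a [new_structure_model()] object.
#' @export
read_structure <- function(path) {
  if (!file.exists(path)) abort_input("structure file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  endmdl <- which(startsWith(lines, "ENDMDL"))
  if (length(endmdl) > 0L) lines <- lines[seq_len(endmdl[1] - 1L)]
  rec <- substr(lines, 1, 6)
  keep <- which(rec %in% c("ATOM  ", "HETATM"))
  if (length(keep) == 0L) abort_input("no ATOM/HETATM records in %s", path)
  ln <- lines[keep]
  altloc <- substr(ln, 17, 17)
  ok_alt <- altloc %in% c(" ", "", "A")
  ln <- ln[ok_alt]
  keep <- keep[ok_alt]
  num <- function(from, to, what) {
    v <- suppressWarnings(as.numeric(substr(ln, from, to)))
    bad <- which(is.na(v))
    if (length(bad) > 0L) {
      abort_input("malformed %s field at line %d of %s",
                  what, keep[bad[1]], path)
    }
    v
  }
  atoms <- data.frame(
    residue_number = as.integer(num(23, 26, "residue number")),
    residue_name = trimws(substr(ln, 18, 20)),
    chain = substr(ln, 22, 22),
    atom_name = trimws(substr(ln, 13, 16)),
    x = num(31, 38, "x coordinate"),
    y = num(39, 46, "y coordinate"),
    z = num(47, 54, "z coordinate"),
    record_kind = ifelse(substr(ln, 1, 6) == "ATOM  ", "polymer", "hetero"),
    element = toupper(trimws(substr(ln, 77, 78))),
    stringsAsFactors = FALSE
  )
  blank <- !nzchar(atoms$element)
  atoms$element[blank] <- guess_element(atoms$atom_name[blank])
  new_structure_model(atoms)
}

#' Write a structure model as PDB coordinate records
#'
#' @param structure a `structure_model`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(structure, path) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  rec <- ifelse(a$record_kind == "polymer", "ATOM  ", "HETATM")
  # atom names of length < 4 start in column 14 by convention
  nm <- ifelse(nchar(a$atom_name) < 4,
               sprintf(" %-3s", a$atom_name), sprintf("%-4s", a$atom_name))
  lines <- sprintf(
    "%s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, seq_len(nrow(a)), nm, a$residue_name, a$chain, a$residue_number,
    a$x, a$y, a$z, 1, 0, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Atoms of named hetero groups
#'
#' @param structure a `structure_model`.
#' @param residue_names 3-letter hetero residue names (e.g. `"PLP"`,
#'   `"MAE"`).
#' @return the matching rows of the atom table.
#' @export
hetero_atoms <- function(structure, residue_names) {
  stopifnot(inherits(structure, "structure_model"))
  a <- structure$atoms
  a[a$record_kind == "hetero" & a$residue_name %in% residue_names, ,
    drop = FALSE]
}
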