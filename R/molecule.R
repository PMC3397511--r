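# Molecule and MoleculeSet containers plus SDF (V2000) input/output.

#' Construct a molecule
#'
#' The package-wide light-weight molecule container: an atom table with 3D
#' coordinates in Angstrom and partial charges in elementary-charge units,
#' plus an optional bond table (needed for charge assignment, substructure
#' matching and CoMSIA atom typing; synthetic pseudo-molecules may omit it).
#'
#' @param id compound identifier (character scalar).
#' @param atoms data.frame with columns `element`, `x`, `y`, `z` and
#'   optionally `charge` (defaults to 0).
#' @param bonds optional data.frame with columns `from`, `to`, `order`
#'   (1-based atom indices).
#' @param formal_charge net formal charge of the molecule.
#' @param scaffold_map optional integer vector of atom indices realizing the
#'   shared scaffold, in scaffold-position order (used by [scaffold_align()]
#'   when no SMARTS pattern is given).
#' @param comsia optional natoms x 5 numeric matrix of CoMSIA atom weights
#'   with columns S, E, H, D, A; computed on demand by rule-based typing when
#'   absent (see [comsia_atom_weights()]).
#' @return an object of class `qsar_molecule`.
#' @export
molecule <- function(id, atoms, bonds = NULL, formal_charge = 0,
                     scaffold_map = NULL, comsia = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("element", "x", "y", "z") %in% names(atoms)))
  if (is.null(atoms$charge)) atoms$charge <- 0
  if (is.null(atoms$fcharge)) atoms$fcharge <- 0L
  coords <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(coords))) stop("molecule ", id, ": non-finite coordinates")
  if (!all(is.finite(atoms$charge))) stop("molecule ", id, ": non-finite charges")
  if (!is.null(scaffold_map)) {
    scaffold_map <- as.integer(scaffold_map)
    if (any(scaffold_map < 1L | scaffold_map > nrow(atoms)))
      stop("molecule ", id, ": scaffold_map index out of range")
  }
  structure(list(id = as.character(id), atoms = atoms, bonds = bonds,
                 formal_charge = formal_charge, scaffold_map = scaffold_map,
                 comsia = comsia),
            class = "qsar_molecule")
}

#' @export
print.qsar_molecule <- function(x, ...) {
  cat("<molecule ", x$id, ": ", nrow(x$atoms), " atoms, ",
      if (is.null(x$bonds)) 0L else nrow(x$bonds), " bonds, net charge ",
      format(sum(x$atoms$charge), digits = 3), ">\n", sep = "")
  invisible(x)
}

#' Atom coordinates as a matrix
#' @param mol a `qsar_molecule`.
#' @return natoms x 3 numeric matrix (Angstrom).
#' @export
coords <- function(mol) {
  m <- as.matrix(mol$atoms[, c("x", "y", "z")])
  dimnames(m) <- NULL
  m
}

set_coords <- function(mol, xyz) {
  mol$atoms$x <- xyz[, 1]; mol$atoms$y <- xyz[, 2]; mol$atoms$z <- xyz[, 3]
  mol
}

#' Construct a molecule set
#' @param mols list of `qsar_molecule` objects.
#' @return `qsar_molecule_set`, a named list (names = compound ids).
#' @export
molecule_set <- function(mols) {
  stopifnot(all(vapply(mols, inherits, logical(1), "qsar_molecule")))
  names(mols) <- vapply(mols, function(m) m$id, character(1))
  structure(mols, class = "qsar_molecule_set")
}

#' @export
print.qsar_molecule_set <- function(x, ...) {
  cat("<molecule set: ", length(x), " molecules>\n", sep = "")
  invisible(x)
}

#' @export
`[.qsar_molecule_set` <- function(x, i) molecule_set(unclass(x)[i])

# ---- SDF V2000 -------------------------------------------------------------

fmt_counts <- function(na, nb)
  sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb)

#' Write molecules to an SDF (V2000) file
#'
#' Partial charges are carried in a `> <PARTIAL_CHARGES>` data field (one
#' value per atom) so that charge-annotated sets round-trip.
#'
#' @param set a `qsar_molecule_set` or single `qsar_molecule`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(set, path) {
  if (inherits(set, "qsar_molecule")) set <- molecule_set(list(set))
  con <- file(path, "w")
  on.exit(close(con))
  for (mol in set) writeLines(mol_to_sdf_record(mol), con)
  invisible(path)
}

mol_to_molblock <- function(mol) {
  a <- mol$atoms
  b <- mol$bonds
  if (is.null(b)) b <- data.frame(from = integer(), to = integer(), order = numeric())
  lines <- c(
    mol$id,
    "  qsar3d",
    "",
    fmt_counts(nrow(a), nrow(b)),
    sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            a$x, a$y, a$z, a$element),
    if (nrow(b)) sprintf("%3d%3d%3d  0", b$from, b$to,
                         ifelse(b$order == 1.5, 4L, as.integer(b$order))),
    {  # formal charges (nitro etc.): M CHG lines, 8 atom/value pairs each
      chg <- which(mol$atoms$fcharge != 0L)
      if (length(chg)) vapply(split(chg, ceiling(seq_along(chg) / 8)),
        function(idx) paste0("M  CHG", sprintf("%3d", length(idx)),
                             paste0(sprintf("%4d%4d", idx,
                                            mol$atoms$fcharge[idx]),
                                    collapse = "")),
        character(1)) else character()
    },
    "M  END"
  )
  paste(lines, collapse = "\n")
}

mol_to_sdf_record <- function(mol) {
  c(strsplit(mol_to_molblock(mol), "\n", fixed = TRUE)[[1]],
    ">  <PARTIAL_CHARGES>",
    paste(sprintf("%.6f", mol$atoms$charge), collapse = " "),
    "",
    "$$$$")
}

parse_sdf_record <- function(lines, index) {
  if (length(lines) < 4L)
    stop("SDF record ", index, ": truncated header")
  counts <- lines[4]
  na <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nb <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(na) || is.na(nb) || length(lines) < 4 + na + nb)
    stop("SDF record ", index, ": malformed counts line")
  atom_lines <- lines[5:(4 + na)]
  atoms <- data.frame(
    element = trimws(substr(atom_lines, 32, 34)),
    x = as.numeric(substr(atom_lines, 1, 10)),
    y = as.numeric(substr(atom_lines, 11, 20)),
    z = as.numeric(substr(atom_lines, 21, 30)),
    stringsAsFactors = FALSE
  )
  if (anyNA(atoms$x) || anyNA(atoms$y) || anyNA(atoms$z) || any(!nzchar(atoms$element)))
    stop("SDF record ", index, ": malformed atom block")
  bonds <- NULL
  if (nb > 0) {
    bl <- lines[(5 + na):(4 + na + nb)]
    ord <- as.integer(substr(bl, 7, 9))
    bonds <- data.frame(from = as.integer(substr(bl, 1, 3)),
                        to = as.integer(substr(bl, 4, 6)),
                        order = ifelse(ord == 4L, 1.5, as.numeric(ord)))
    if (anyNA(bonds$from) || anyNA(bonds$to))
      stop("SDF record ", index, ": malformed bond block")
  }
  atoms$fcharge <- 0L
  for (chg_line in grep("^M  CHG", lines, value = TRUE)) {
    nums <- as.integer(strsplit(trimws(sub("^M  CHG", "", chg_line)),
                                "\\s+")[[1]])
    pairs <- matrix(nums[-1], ncol = 2, byrow = TRUE)
    atoms$fcharge[pairs[, 1]] <- pairs[, 2]
  }
  id <- trimws(lines[1])
  if (!nzchar(id)) id <- paste0("mol", index)
  charges <- NULL
  tag <- grep("^>.*<PARTIAL_CHARGES>", lines)
  if (length(tag) == 1L && length(lines) > tag) {
    charges <- as.numeric(strsplit(trimws(lines[tag + 1L]), "\\s+")[[1]])
    if (length(charges) != na) charges <- NULL
  }
  if (!is.null(charges)) atoms$charge <- charges
  molecule(id = id, atoms = atoms, bonds = bonds)
}

read_sdf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  breaks <- grep("^\\$\\$\\$\\$", lines)
  if (length(breaks) == 0L) {
    if (!any(nzchar(trimws(lines)))) stop("empty SDF file: ", path)
    breaks <- length(lines) + 1L  # single record without terminator
    lines <- c(lines, "$$$$")
  }
  start <- 1L
  mols <- list()
  for (i in seq_along(breaks)) {
    chunk <- lines[start:(breaks[i] - 1L)]
    if (any(nzchar(trimws(chunk))))
      mols[[length(mols) + 1L]] <- parse_sdf_record(chunk, length(mols) + 1L)
    start <- breaks[i] + 1L
  }
  if (length(mols) == 0L) stop("empty SDF file: ", path)
  molecule_set(mols)
}

# ---- loaders ---------------------------------------------------------------

#' Load molecules from SDF, MOL2 or SMILES
#'
#' SMILES inputs (one molecule per line, optional id after whitespace) are
#' embedded to a single 3D conformer (distance geometry + force-field
#' minimization) and Gasteiger-charged through the RDKit bridge. SDF is parsed
#' natively; MOL2 goes through the bridge.
#'
#' @param path input file.
#' @param format one of `"sdf"`, `"mol2"`, `"smiles"`; default guesses from
#'   the file extension.
#' @param seed embedding seed for SMILES input.
#' @return a `qsar_molecule_set`.
#' @export
load_molecules <- function(path, format = c("auto", "sdf", "mol2", "smiles"),
                           seed = 20120608L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, sdf = "sdf", sd = "sdf", mol2 = "mol2",
                     smi = "smiles", smiles = "smiles",
                     stop("cannot guess format from extension: ", ext))
  }
  switch(format,
    sdf = read_sdf(path),
    mol2 = molecule_set(bridge_molecules(
      chem_bridge(list(op = "read_mol2", path = normalizePath(path))))),
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0L) stop("empty SMILES file: ", path)
      records <- lapply(seq_along(lines), function(i) {
        parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
        list(smiles = parts[1],
             id = if (length(parts) > 1L) parts[2] else paste0("mol", i))
      })
      embed_smiles(records, seed = seed)
    })
}

#' Embed SMILES records to 3D charged molecules
#'
#' @param records list of `list(smiles=, id=)` records.
#' @param seed conformer-embedding seed.
#' @return a `qsar_molecule_set` with coordinates and Gasteiger charges.
#' @export
embed_smiles <- function(records, seed = 20120608L) {
  res <- chem_bridge(list(op = "embed_smiles", records = records, seed = seed))
  molecule_set(bridge_molecules(res))
}

#' Assign Gasteiger partial charges
#'
#' Iterative partial equalization of orbital electronegativity (plain
#' Gasteiger, via RDKit). This approximates the Gasteiger-Hueckel charges of
#' the Tripos tool chain; the difference shifts absolute field values but not
#' the downstream validation-metric layer.
#'
#' @param mol a `qsar_molecule` with a bond table and explicit hydrogens.
#' @param method currently only `"gasteiger"`.
#' @return the molecule with per-atom charges filled in.
#' @export
assign_charges <- function(mol, method = "gasteiger") {
  method <- match.arg(method, "gasteiger")
  if (is.null(mol$bonds) || nrow(mol$bonds) == 0L)
    stop("molecule ", mol$id, ": charge assignment needs a bond table")
  res <- chem_bridge(list(op = "gasteiger", molblock = mol_to_molblock(mol)))
  q <- vapply(res$charges, as.numeric, numeric(1))
  if (abs(sum(q) - res$formal_charge) > 1e-3)
    stop("molecule ", mol$id, ": charges do not sum to the formal charge")
  mol$atoms$charge <- q
  mol$formal_charge <- res$formal_charge
  mol
}

smarts_matches <- function(mol, smarts) {
  res <- chem_bridge(list(op = "smarts_match", molblock = mol_to_molblock(mol),
                          smarts = smarts))
  lapply(res$matches, function(m) vapply(m, as.integer, integer(1)) + 1L)
}
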