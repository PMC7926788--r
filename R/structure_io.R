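#' Read a PDB file into a hierarchical structure model
#'
#' Parses a PDB-format file (via [bio3d::read.pdb()]) into a `fab_structure`:
#' a flat heavy-atom table tagged by residue kind. Hydrogens are dropped,
#' waters (HOH/WAT/DOD) are routed to a `waters` slot and excluded from both
#' polymer chains and ligands, every other HETATM residue becomes a ligand
#' instance, and alternate locations are collapsed to a single conformer per
#' atom (highest occupancy; ties broken in favour of altloc `"A"`, then
#' lexicographically).
#'
#' Only one coordinate model is loaded. Residues keep their author numbering
#' and insertion codes; all downstream reporting uses `(chain, number, icode)`
#' identifiers, never sequential indices.
#'
#' @param path Path to a PDB file containing at least one ATOM/HETATM record.
#' @param model Model to load: `"first"` (default) or a 1-based model index.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @return An object of class `fab_structure`: a list with `id`, `atoms`
#'   (data frame of polymer + ligand heavy atoms: `element`, `name`, `x`,
#'   `y`, `z`, `occ`, `altloc`, `hetero`, `chain`, `resno`, `icode`,
#'   `resname`, `kind`, `vdw`), `waters` (same layout) and `model_index`.
#' @examples
#' pdb <- system.file("extdata", "toy_plm.pdb", package = "fabpocket")
#' s <- read_pdb(pdb)
#' s
#' ligand_residues(s)
#' @export
read_pdb <- function(path, model = "first", id = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  check_pdb_records(path)
  multi <- !(identical(model, "first") || identical(model, 1L) ||
               identical(model, 1))
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = multi, verbose = FALSE,
                                          rm.alt = FALSE))
  at <- pdb$atom
  if (multi) {
    midx <- as.integer(model)
    if (is.na(midx) || midx < 1 || midx > nrow(pdb$xyz))
      stop("model index ", model, " out of range (file has ",
           nrow(pdb$xyz), " models)")
    xyz <- matrix(pdb$xyz[midx, ], ncol = 3, byrow = TRUE)
    at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]
  } else midx <- 1L
  atoms <- data.frame(
    element = infer_element(at$elesy, at$elety),
    name = trimws(at$elety),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    altloc = ifelse(is.na(at$alt), "", at$alt),
    hetero = at$type == "HETATM",
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = at$resno,
    icode = ifelse(is.na(at$insert), "", at$insert),
    resname = trimws(at$resid),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[atoms$element != "H" & atoms$element != "D", , drop = FALSE]
  if (nrow(atoms) == 0) stop("zero usable heavy atoms in ", path)
  atoms <- resolve_altloc(atoms)
  water_names <- c("HOH", "WAT", "DOD")
  atoms$kind <- ifelse(atoms$resname %in% water_names, "water",
                       ifelse(atoms$hetero, "ligand", "polymer"))
  waters <- atoms[atoms$kind == "water", , drop = FALSE]
  atoms <- atoms[atoms$kind != "water", , drop = FALSE]
  rownames(atoms) <- NULL; rownames(waters) <- NULL
  atoms$vdw <- NA_real_
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(path))
  structure(list(id = id, atoms = atoms, waters = waters,
                 model_index = midx),
            class = "fab_structure")
}

# Pre-scan ATOM/HETATM records for malformed coordinate fields so parse
# errors can name the offending line.
check_pdb_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(rec)) stop("no ATOM or HETATM records in ", path)
  for (i in which(rec)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop("unparseable ATOM/HETATM record at line ", i, ": too short")
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38),
                                         substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)) || any(!is.finite(xyz)))
      stop("unparseable coordinates at line ", i)
  }
  invisible(TRUE)
}

# Element from the PDB element column when present, otherwise from the atom
# name columns (first alphabetic character, skipping leading digits).
infer_element <- function(elesy, elety) {
  el <- toupper(trimws(ifelse(is.na(elesy), "", elesy)))
  fallback <- toupper(gsub("^[0-9']*", "", trimws(elety)))
  fallback <- substr(fallback, 1, 1)
  ifelse(el == "", fallback, el)
}

# Keep one altloc per atom slot (chain, resno, icode, resname, name):
# highest occupancy, ties to altloc "A", then lexicographic. Only groups
# actually carrying altloc identifiers are collapsed; duplicate-keyed
# records without altlocs (e.g., pseudo-atom dumps) pass through, and the
# original record order is preserved.
resolve_altloc <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, atoms$icode, atoms$resname,
               atoms$name, sep = "\r")
  has_alt <- vapply(split(atoms$altloc != "", key), any, logical(1))
  candidate <- has_alt[key] & (key %in% key[duplicated(key)])
  if (!any(candidate)) return(atoms)
  pref <- ifelse(atoms$altloc == "A", 0L, 1L)
  idx <- seq_len(nrow(atoms))
  ord <- order(key, -atoms$occ, pref, atoms$altloc)
  drop_rows <- idx[ord][duplicated(key[ord]) & candidate[ord]]
  atoms[setdiff(idx, drop_rows), , drop = FALSE]
}

#' @export
print.fab_structure <- function(x, ...) {
  a <- x$atoms
  cat("fab_structure '", x$id, "' (model ", x$model_index, ")\n", sep = "")
  cat("  polymer atoms: ", sum(a$kind == "polymer"),
      " in ", length(unique(a$chain[a$kind == "polymer"])), " chain(s)\n",
      sep = "")
  lig <- ligand_residues(x)
  cat("  ligand residues: ", nrow(lig),
      if (nrow(lig)) paste0(" (", paste(unique(lig$resname), collapse = ", "),
                            ")") else "", "\n", sep = "")
  cat("  waters: ", nrow(x$waters), " atoms\n", sep = "")
  invisible(x)
}

#' Ligand residues of a structure
#'
#' @param structure A `fab_structure`.
#' @return Data frame with one row per ligand residue instance: `resname`,
#'   `chain`, `resno`, `icode`, `n_atoms`.
#' @export
ligand_residues <- function(structure) {
  a <- structure$atoms[structure$atoms$kind == "ligand", , drop = FALSE]
  if (nrow(a) == 0)
    return(data.frame(resname = character(), chain = character(),
                      resno = integer(), icode = character(),
                      n_atoms = integer(), stringsAsFactors = FALSE))
  key <- paste(a$chain, a$resno, a$icode, a$resname, sep = "\r")
  u <- !duplicated(key)
  data.frame(resname = a$resname[u], chain = a$chain[u], resno = a$resno[u],
             icode = a$icode[u], n_atoms = as.integer(table(key)[key[u]]),
             stringsAsFactors = FALSE)
}

#' Assign van der Waals radii to every atom
#'
#' Radii are looked up by element from a small element-keyed table; elements
#' absent from the table get the carbon default of 1.70 Angstrom with a
#' warning naming them. The radii feed the cavity-detection geometry, which
#' only needs coarse per-element values.
#'
#' @param structure A `fab_structure`.
#' @param radius_table Named numeric vector of radii in Angstrom, keyed by
#'   element symbol. Defaults to [fab_vdw_table()].
#' @return The structure with `atoms$vdw` (and `waters$vdw`) populated.
#' @export
assign_vdw_radii <- function(structure, radius_table = fab_vdw_table()) {
  fill <- function(a) {
    if (nrow(a) == 0) { a$vdw <- numeric(0); return(a) }
    r <- unname(radius_table[a$element])
    unknown <- is.na(r)
    if (any(unknown)) {
      warning("unknown element(s) defaulted to 1.70 A: ",
              paste(sort(unique(a$element[unknown])), collapse = ", "))
      r[unknown] <- 1.70
    }
    a$vdw <- r
    a
  }
  structure$atoms <- fill(structure$atoms)
  structure$waters <- fill(structure$waters)
  structure
}

#' Default van der Waals radius table (Angstrom)
#'
#' @return Named numeric vector: C 1.70, N 1.55, O 1.52, S 1.80, P 1.80.
#' @export
fab_vdw_table <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80)
}

# Fixed-column PDB ATOM/HETATM formatter.
format_pdb_atoms <- function(atoms, serial_start = 1L) {
  n <- nrow(atoms)
  if (n == 0) return(character(0))
  serial <- seq(serial_start, length.out = n)
  name4 <- vapply(seq_len(n), function(i) {
    nm <- atoms$name[i]
    if (nchar(nm) >= 4) substr(nm, 1, 4)
    else if (nchar(atoms$element[i]) == 2) sprintf("%-4s", nm)
    else sprintf(" %-3s", nm)
  }, character(1))
  sprintf("%-6s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ifelse(atoms$hetero, "HETATM", "ATOM"),
          serial %% 100000L, name4,
          substr(paste0(atoms$altloc, " "), 1, 1),
          atoms$resname, atoms$chain,
          ifelse(atoms$resno > 9999L, atoms$resno %% 10000L, atoms$resno),
          substr(paste0(atoms$icode, " "), 1, 1),
          atoms$x, atoms$y, atoms$z, atoms$occ,
          if (!is.null(atoms$b)) atoms$b else rep(0, n),
          atoms$element)
}

#' Write a structure (and optionally its pockets) as a PDB file
#'
#' Writes the structure's heavy atoms as standard ATOM/HETATM records. When
#' pockets are supplied, each alpha-sphere centre is appended as a HETATM
#' pseudo-atom (resname `STP`, element `C`, chain `Z`) with the pocket id as
#' residue number and the sphere radius in the B-factor column, so detected
#' pockets can be inspected in any molecular viewer. The output is
#' re-readable by [read_pdb()] (sphere centres round-trip to the 3-decimal
#' precision of the PDB coordinate format).
#'
#' @param structure A `fab_structure`.
#' @param path Output file path.
#' @param pockets Optional list of pockets from [detect_pockets()].
#' @return Invisibly, `path`.
#' @export
write_pocket_pdb <- function(structure, path, pockets = NULL) {
  a <- structure$atoms
  lines <- c(sprintf("REMARK   3 fabpocket structure %s", structure$id),
             format_pdb_atoms(a))
  serial <- nrow(a) + 1L
  for (p in pockets) {
    sp <- p$spheres
    ps <- data.frame(element = "C", name = "APS",
                     x = sp$cx, y = sp$cy, z = sp$cz,
                     occ = 1, altloc = "", hetero = TRUE, chain = "Z",
                     resno = p$id, icode = "", resname = "STP",
                     b = sp$radius, stringsAsFactors = FALSE)
    lines <- c(lines, format_pdb_atoms(ps, serial))
    serial <- serial + nrow(ps)
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' @rdname write_pocket_pdb
#' @export
write_structure_pdb <- function(structure, path) {
  write_pocket_pdb(structure, path, pockets = NULL)
}
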