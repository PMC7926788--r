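#' Load a curated training table
#'
#' Reads a TSV of training records (one structure/ligand per row) describing
#' fatty-acid-bound (label 1) or unbound (label 0) pocket examples. Columns
#' are mapped by name through `column_map`, so tables with different
#' headers can be loaded without editing. PDB identifiers are upper-cased
#' and validated (4 characters, digit first); malformed rows are skipped
#' with a message. Duplicate `(pdb_id, chain, ligand_code)` rows are
#' collapsed with a warning.
#'
#' @param path TSV file with a header row.
#' @param column_map Named character vector mapping the canonical fields
#'   `pdb_id`, `chain`, `ligand_code`, `species`, `label` to the file's
#'   column names. `chain`, `species` and `label` are optional in the file
#'   (defaults: `"*"`, `""`, `1`).
#' @return Data frame of records (`pdb_id`, `chain`, `ligand_code`,
#'   `species`, `label`) with attributes `n_records` and
#'   `n_distinct_species`.
#' @examples
#' tab <- system.file("extdata", "FA_AllSpecie_Train.synthetic.tsv",
#'                    package = "fabpocket")
#' rec <- load_training_table(tab)
#' attr(rec, "n_records"); attr(rec, "n_distinct_species")
#' @export
load_training_table <- function(path,
                                column_map = c(pdb_id = "pdb_id",
                                               chain = "chain",
                                               ligand_code = "ligand_code",
                                               species = "species",
                                               label = "label")) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  mandatory <- c("pdb_id", "ligand_code")
  for (f in mandatory) {
    cn <- column_map[[f]]
    if (is.null(cn) || !(cn %in% names(d)))
      stop("missing mandatory column '", if (is.null(cn)) f else cn,
           "' in ", path)
  }
  getcol <- function(field, default) {
    cn <- column_map[[field]]
    if (!is.null(cn) && cn %in% names(d)) d[[cn]] else rep(default, nrow(d))
  }
  rec <- data.frame(
    pdb_id = toupper(trimws(d[[column_map[["pdb_id"]]]])),
    chain = as.character(getcol("chain", "*")),
    ligand_code = toupper(trimws(d[[column_map[["ligand_code"]]]])),
    species = as.character(getcol("species", "")),
    label = as.integer(getcol("label", 1L)),
    stringsAsFactors = FALSE)
  bad <- !grepl("^[0-9][A-Z0-9]{3}$", rec$pdb_id)
  if (any(bad)) {
    message("skipped ", sum(bad), " row(s) with malformed pdb_id: ",
            paste(head(unique(rec$pdb_id[bad]), 5), collapse = ", "))
    rec <- rec[!bad, , drop = FALSE]
  }
  if (!all(rec$label %in% c(0L, 1L)))
    stop("labels must be 0 or 1 in ", path)
  key <- paste(rec$pdb_id, rec$chain, rec$ligand_code, sep = "\r")
  if (anyDuplicated(key)) {
    warning("collapsed ", sum(duplicated(key)),
            " duplicate (pdb_id, chain, ligand_code) row(s) in ",
            basename(path))
    rec <- rec[!duplicated(key), , drop = FALSE]
  }
  rownames(rec) <- NULL
  attr(rec, "n_records") <- nrow(rec)
  attr(rec, "n_distinct_species") <-
    length(unique(rec$species[rec$species != ""]))
  rec
}

#' Load a ligand exclusion list
#'
#' One 3-character chemical-component code per line (comments with `#`
#' allowed); codes are upper-cased. Used to purge fatty acids and
#' structurally similar ligands from a negative evaluation pool so that no
#' structure in the pool retains a ligand the models were trained on.
#'
#' @param path Text file, one code per line.
#' @return Character vector of unique uppercase codes.
#' @export
load_ligand_exclusion <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  x <- toupper(x[x != ""])
  if (length(x) == 0) stop("empty ligand exclusion list: ", path)
  unique(x)
}

#' Label detected pockets by ligand contact
#'
#' A pocket is labeled 1 (fatty-acid binding) when at least
#' `min_contact_spheres` of its alpha-sphere centres lie within
#' `contact_distance` of any heavy atom of the ligand, and 0 otherwise.
#' Detection must have run with the ligand's atoms excluded, so the cavity
#' is found as empty space — the same condition prediction sees on apo
#' structures.
#'
#' @param pockets List of `fab_pocket` objects.
#' @param ligand_atoms Data frame of ligand heavy atoms with columns `x`,
#'   `y`, `z` (e.g., the matching rows of `structure$atoms`).
#' @param contact_distance Contact cutoff, Angstrom (default 3).
#' @param min_contact_spheres Minimum contacting sphere centres (default 3).
#' @return Integer vector of 0/1 labels aligned to `pockets`.
#' @export
label_pockets <- function(pockets, ligand_atoms, contact_distance = 3,
                          min_contact_spheres = 3) {
  if (is.null(ligand_atoms) || nrow(ligand_atoms) == 0)
    stop("ligand has no heavy atoms")
  L <- as.matrix(ligand_atoms[, c("x", "y", "z")])
  vapply(pockets, function(p) {
    cen <- as.matrix(p$spheres[, c("cx", "cy", "cz")])
    d2 <- outer(rowSums(cen^2), rowSums(L^2), "+") - 2 * cen %*% t(L)
    hits <- sum(apply(d2, 1, min) <= contact_distance^2 + 1e-12)
    as.integer(hits >= min_contact_spheres)
  }, integer(1))
}

#' Build a labeled feature dataset from training records
#'
#' For each record: loads `<structure_dir>/<pdb_id>.pdb`, removes the
#' matching ligand instance(s) from the detection input, detects pockets,
#' assigns secondary structure, computes features, and labels pockets. For
#' positive records (label 1), pockets contacting the ligand become class-1
#' rows and the remaining pockets of that structure are discarded (they are
#' unverified, not negatives). For negative records (label 0), every
#' detected pocket becomes a class-0 row. Records whose structure file is
#' missing, or whose ligand code is absent from the structure, are skipped
#' and listed in the `skipped` report — never silently dropped.
#'
#' @param records Data frame from [load_training_table()].
#' @param structure_dir Directory of PDB files named `<pdb_id>.pdb`
#'   (case-insensitive lookup).
#' @param params [detection_params()].
#' @param contact_distance,min_contact_spheres Contact rule, see
#'   [label_pockets()].
#' @param volume_seed Seed for the Monte-Carlo volume term.
#' @return List: `X` (feature matrix, [feature_schema()] columns), `y`
#'   (integer labels), `provenance` (data frame `pdb_id`, `pocket_id`,
#'   `label`, `record_row`), `skipped` (data frame `pdb_id`, `reason`).
#' @export
build_dataset <- function(records, structure_dir,
                          params = detection_params(),
                          contact_distance = 3, min_contact_spheres = 3,
                          volume_seed = 1) {
  rows <- list(); prov <- list(); skipped <- list()
  for (r in seq_len(nrow(records))) {
    rec <- records[r, ]
    path <- file.path(structure_dir, paste0(rec$pdb_id, ".pdb"))
    if (!file.exists(path)) {
      alt <- file.path(structure_dir, paste0(tolower(rec$pdb_id), ".pdb"))
      if (file.exists(alt)) path <- alt
      else {
        skipped[[length(skipped) + 1]] <-
          data.frame(pdb_id = rec$pdb_id, reason = "structure file missing",
                     stringsAsFactors = FALSE)
        next
      }
    }
    s <- read_pdb(path, id = rec$pdb_id)
    lig <- s$atoms[s$atoms$kind == "ligand" &
                     s$atoms$resname == rec$ligand_code, , drop = FALSE]
    if (rec$label == 1 && nrow(lig) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(pdb_id = rec$pdb_id,
                   reason = paste0("ligand ", rec$ligand_code,
                                   " absent from structure"),
                   stringsAsFactors = FALSE)
      next
    }
    pockets <- detect_pockets(s, params, include_ligands = FALSE)
    if (length(pockets) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(pdb_id = rec$pdb_id, reason = "no pockets detected",
                   stringsAsFactors = FALSE)
      next
    }
    ss <- assign_ss(s)
    if (rec$label == 1) {
      lab <- label_pockets(pockets, lig, contact_distance,
                           min_contact_spheres)
      use <- which(lab == 1)
      use_lab <- rep(1L, length(use))
    } else {
      use <- seq_along(pockets)
      use_lab <- rep(0L, length(use))
    }
    for (k in seq_along(use)) {
      p <- pockets[[use[k]]]
      rows[[length(rows) + 1]] <-
        compute_features(p, s, ss, seed = volume_seed)
      prov[[length(prov) + 1]] <-
        data.frame(pdb_id = rec$pdb_id, pocket_id = p$id,
                   label = use_lab[k], record_row = r,
                   stringsAsFactors = FALSE)
    }
  }
  X <- do.call(rbind, rows)
  provenance <- if (length(prov)) do.call(rbind, prov) else
    data.frame(pdb_id = character(), pocket_id = integer(),
               label = integer(), record_row = integer())
  list(X = X, y = provenance$label, provenance = provenance,
       skipped = if (length(skipped)) do.call(rbind, skipped) else
         data.frame(pdb_id = character(), reason = character()))
}
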