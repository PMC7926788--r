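#' Cavity-detection parameters
#'
#' Controls the alpha-sphere reconstruction of protein cavities. An alpha
#' sphere is a sphere tangent to four atoms that contains no atom centre;
#' spheres of intermediate radius line clefts and buried cavities. The
#' defaults follow the fpocket convention tuned for elongated fatty-acid
#' cavities: a minimum alpha-sphere radius of 4 Angstrom (fpocket's `-m 4`)
#' and a 6 Angstrom clustering distance (fpocket's `-D 6`), with the
#' documented fpocket maximum radius of 6.2 Angstrom.
#'
#' @param min_alpha_radius Minimum alpha-sphere radius, Angstrom (default 4).
#' @param max_alpha_radius Maximum alpha-sphere radius, Angstrom
#'   (default 6.2).
#' @param cluster_distance Single-linkage clustering distance between sphere
#'   centres, Angstrom (default 6).
#' @param min_spheres_per_pocket Minimum spheres for a pocket to be reported
#'   (default 15).
#' @param apolar_probe_count A sphere is apolar when at least this many of
#'   its 4 defining atoms are carbon or sulfur (default 3).
#' @return A `fab_detection_params` list.
#' @export
detection_params <- function(min_alpha_radius = 4, max_alpha_radius = 6.2,
                             cluster_distance = 6,
                             min_spheres_per_pocket = 15,
                             apolar_probe_count = 3) {
  stopifnot(min_alpha_radius > 0, min_alpha_radius < max_alpha_radius,
            cluster_distance > 0, min_spheres_per_pocket >= 1,
            apolar_probe_count >= 0, apolar_probe_count <= 4)
  structure(list(min_alpha_radius = min_alpha_radius,
                 max_alpha_radius = max_alpha_radius,
                 cluster_distance = cluster_distance,
                 min_spheres_per_pocket = as.integer(min_spheres_per_pocket),
                 apolar_probe_count = as.integer(apolar_probe_count)),
            class = "fab_detection_params")
}

#' Circumsphere of four points
#'
#' Solves the 3x3 linear system `2 (p_i - p_4) . c = |p_i|^2 - |p_4|^2` for
#' the unique point equidistant from all four vertices.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return List with `center` (3-vector) and `radius`.
#' @examples
#' circumsphere(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
#' @export
circumsphere <- function(p1, p2, p3, p4) {
  P <- rbind(p1, p2, p3, p4)
  stopifnot(ncol(P) == 3, all(is.finite(P)))
  A <- 2 * sweep(P[1:3, , drop = FALSE], 2, P[4, ])
  vol <- abs(det(A)) / 48
  if (vol <= 1e-9)
    stop("degenerate geometry: the four points are (near-)coplanar")
  b <- rowSums(P[1:3, , drop = FALSE]^2) - sum(P[4, ]^2)
  center <- drop(solve(A, b))
  list(center = unname(center),
       radius = sqrt(sum((center - P[4, ])^2)))
}

# Atom subset a detection run operates on: heavy polymer atoms, optionally
# plus ligands. Ligands are excluded by default so cavities are detected as
# empty space, matching the apo condition at prediction time.
detection_atoms <- function(structure, include_ligands = FALSE) {
  a <- structure$atoms
  if (!include_ligands) a <- a[a$kind == "polymer", , drop = FALSE]
  a
}

#' Generate alpha spheres for a structure
#'
#' Enumerates every empty circumsphere of four heavy atoms — in general
#' position, exactly the Delaunay tetrahedra of the atom centres — and keeps
#' those with radius inside `[min_alpha_radius, max_alpha_radius]`
#' (inclusive on both ends). A sphere is empty when no atom centre lies
#' strictly inside it (distance from centre < radius - 1e-6 Angstrom). Each
#' kept sphere is tagged apolar when at least `apolar_probe_count` of its
#' four defining atoms are carbon or sulfur.
#'
#' @param structure A `fab_structure` (radii need not be assigned; only
#'   atom centres and elements are used).
#' @param params A [detection_params()] object.
#' @param include_ligands Include ligand atoms in the detection input
#'   (default `FALSE`; cavities are detected as empty space).
#' @return Data frame of spheres: `cx`, `cy`, `cz`, `radius`, atom row
#'   indices `a1`..`a4` (into the detection atom subset), and `apolar`.
#'   The detection atom subset is attached as attribute `"atoms"`.
#' @export
generate_alpha_spheres <- function(structure, params = detection_params(),
                                   include_ligands = FALSE) {
  a <- detection_atoms(structure, include_ligands)
  if (nrow(a) < 4) stop("need at least 4 heavy atoms for cavity detection")
  m <- cpp_alpha_spheres(as.matrix(a[, c("x", "y", "z")]),
                         params$min_alpha_radius, params$max_alpha_radius,
                         1e-6, 1e-9)
  sp <- data.frame(cx = m[, "cx"], cy = m[, "cy"], cz = m[, "cz"],
                   radius = m[, "radius"],
                   a1 = as.integer(m[, "i1"]), a2 = as.integer(m[, "i2"]),
                   a3 = as.integer(m[, "i3"]), a4 = as.integer(m[, "i4"]))
  apc <- (a$element %in% c("C", "S"))
  sp$apolar <- (apc[sp$a1] + apc[sp$a2] + apc[sp$a3] + apc[sp$a4]) >=
    params$apolar_probe_count
  # canonical order: by centre coordinates then radius, so output is
  # independent of atom input order
  sp <- sp[order(sp$cx, sp$cy, sp$cz, sp$radius), , drop = FALSE]
  rownames(sp) <- NULL
  attr(sp, "atoms") <- a
  sp
}

#' Cluster alpha spheres into candidate pockets
#'
#' Single-linkage clustering of sphere centres: pockets are the connected
#' components of the graph with an edge wherever two centres are at most
#' `cluster_distance` apart. Pockets are ranked by sphere count
#' (descending), ties broken by mean radius (descending).
#'
#' @param spheres Sphere data frame from [generate_alpha_spheres()].
#' @param cluster_distance Linkage distance, Angstrom.
#' @return List of pre-filter pockets, each a list with `id` (rank),
#'   `spheres` (rows of the input).
#' @export
cluster_spheres <- function(spheres, cluster_distance = 6) {
  n <- nrow(spheres)
  if (n == 0) return(list())
  if (n == 1) {
    comp <- 1L
  } else {
    hc <- hclust(dist(spheres[, c("cx", "cy", "cz")]), method = "single")
    comp <- cutree(hc, h = cluster_distance)
  }
  groups <- split(seq_len(n), comp)
  sizes <- vapply(groups, length, integer(1))
  meanr <- vapply(groups, function(i) mean(spheres$radius[i]), numeric(1))
  ord <- order(-sizes, -meanr)
  out <- vector("list", length(groups))
  for (r in seq_along(ord)) {
    idx <- groups[[ord[r]]]
    sp <- spheres[idx, , drop = FALSE]
    rownames(sp) <- NULL
    out[[r]] <- list(id = r, spheres = sp)
  }
  attr(out, "atoms") <- attr(spheres, "atoms")
  out
}

#' Finalize clustered pockets
#'
#' Drops pockets with fewer than `min_spheres_per_pocket` spheres, then
#' derives for each survivor its lining residues (the residues owning the
#' spheres' defining atoms), the per-chain author-residue-number span, the
#' apolar sphere fraction, and summary geometry. Survivors are re-ranked
#' 1..n in the original order.
#'
#' @param structure The `fab_structure` the spheres were generated on.
#' @param pockets Output of [cluster_spheres()].
#' @param params A [detection_params()] object.
#' @return List of `fab_pocket` objects: `id`, `spheres`, `lining`
#'   (data frame `chain`, `resno`, `icode`, `resname`), `span` (data frame
#'   `chain`, `start`, `end`), `apolar_fraction`, `n_spheres`,
#'   `mean_radius`, `max_radius`, `centroid`.
#' @export
finalize_pockets <- function(structure, pockets,
                             params = detection_params()) {
  atoms <- attr(pockets, "atoms")
  if (is.null(atoms)) atoms <- detection_atoms(structure)
  keep <- Filter(function(p) nrow(p$spheres) >= params$min_spheres_per_pocket,
                 pockets)
  out <- vector("list", length(keep))
  for (i in seq_along(keep)) {
    p <- keep[[i]]
    sp <- p$spheres
    aidx <- unique(c(sp$a1, sp$a2, sp$a3, sp$a4))
    lin <- atoms[aidx, c("chain", "resno", "icode", "resname"), drop = FALSE]
    lin <- lin[!duplicated(paste(lin$chain, lin$resno, lin$icode,
                                 sep = "\r")), , drop = FALSE]
    lin <- lin[order(lin$chain, lin$resno, lin$icode), , drop = FALSE]
    rownames(lin) <- NULL
    span <- do.call(rbind, lapply(split(lin, lin$chain), function(d)
      data.frame(chain = d$chain[1], start = min(d$resno),
                 end = max(d$resno), stringsAsFactors = FALSE)))
    rownames(span) <- NULL
    out[[i]] <- structure(list(
      id = i, spheres = sp, lining = lin, span = span,
      apolar_fraction = mean(sp$apolar),
      n_spheres = nrow(sp),
      mean_radius = mean(sp$radius),
      max_radius = max(sp$radius),
      centroid = c(mean(sp$cx), mean(sp$cy), mean(sp$cz))),
      class = "fab_pocket")
  }
  out
}

#' Detect pockets on a structure
#'
#' Convenience wrapper: [generate_alpha_spheres()], [cluster_spheres()] at
#' `params$cluster_distance`, then [finalize_pockets()].
#'
#' @inheritParams generate_alpha_spheres
#' @return List of `fab_pocket` objects, ranked by sphere count.
#' @export
detect_pockets <- function(structure, params = detection_params(),
                           include_ligands = FALSE) {
  sp <- generate_alpha_spheres(structure, params, include_ligands)
  finalize_pockets(structure, cluster_spheres(sp, params$cluster_distance),
                   params)
}

#' @export
print.fab_pocket <- function(x, ...) {
  cat("fab_pocket #", x$id, ": ", x$n_spheres, " spheres, mean radius ",
      round(x$mean_radius, 2), " A, apolar fraction ",
      round(x$apolar_fraction, 2), "\n", sep = "")
  for (i in seq_len(nrow(x$span)))
    cat("  chain ", x$span$chain[i], " span ", x$span$start[i], "-",
        x$span$end[i], " (", nrow(x$lining), " lining residues)\n", sep = "")
  invisible(x)
}

#' Tabular pocket report
#'
#' @param structure A `fab_structure`.
#' @param pockets List of `fab_pocket` objects.
#' @return Data frame: `structure_id`, `pocket_id`, `n_spheres`,
#'   `mean_radius`, `apolar_fraction`, `chain`, `span_start`, `span_end`,
#'   `lining_residues` (semicolon-separated `resname resno` list); one row
#'   per (pocket, chain).
#' @export
pocket_report <- function(structure, pockets) {
  rows <- lapply(pockets, function(p) {
    lining <- paste(paste0(p$lining$resname, " ", p$lining$chain,
                           p$lining$resno, p$lining$icode), collapse = ";")
    data.frame(structure_id = structure$id, pocket_id = p$id,
               n_spheres = p$n_spheres, mean_radius = p$mean_radius,
               apolar_fraction = p$apolar_fraction,
               chain = p$span$chain, span_start = p$span$start,
               span_end = p$span$end, lining_residues = lining,
               stringsAsFactors = FALSE)
  })
  if (length(rows) == 0)
    return(data.frame(structure_id = character(), pocket_id = integer(),
                      n_spheres = integer(), mean_radius = numeric(),
                      apolar_fraction = numeric(), chain = character(),
                      span_start = integer(), span_end = integer(),
                      lining_residues = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
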