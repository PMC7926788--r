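# In-memory fixture builders and independent oracles used across the suite.

# Wrap an atom data frame into the structure container.
make_structure <- function(atoms, id = "fixture") {
  defaults <- list(occ = 1, altloc = "", hetero = FALSE, chain = "A",
                   resno = 1L, icode = "", resname = "ALA",
                   kind = "polymer", vdw = NA_real_)
  for (nm in names(defaults))
    if (is.null(atoms[[nm]])) atoms[[nm]] <- defaults[[nm]]
  if (is.null(atoms$name)) atoms$name <- atoms$element
  structure(list(id = id, atoms = atoms, waters = atoms[0, , drop = FALSE],
                 model_index = 1L),
            class = "fab_structure")
}

# Bare point cloud as an all-carbon polymer (for geometry tests).
point_structure <- function(P, element = "C") {
  n <- nrow(P)
  make_structure(data.frame(
    element = element, name = "CA", x = P[, 1], y = P[, 2], z = P[, 3],
    resno = seq_len(n), stringsAsFactors = FALSE))
}

# --- Exhaustive alpha-sphere oracle -------------------------------------
# Enumerates every 4-point combination, solves the equidistance system with
# base R solve(), applies the radius band and the strict inside test by
# brute force. Independent of the compiled enumeration path.
oracle_alpha_spheres <- function(P, rmin, rmax, inside_tol = 1e-6) {
  n <- nrow(P)
  quads <- combn(n, 4)
  out <- list()
  for (q in seq_len(ncol(quads))) {
    idx <- quads[, q]
    p <- P[idx, , drop = FALSE]
    A <- 2 * sweep(p[1:3, , drop = FALSE], 2, p[4, ])
    if (abs(det(A)) / 48 <= 1e-9) next
    b <- rowSums(p[1:3, , drop = FALSE]^2) - sum(p[4, ]^2)
    cen <- drop(solve(A, b))
    r <- sqrt(sum((cen - p[4, ])^2))
    if (r < rmin || r > rmax) next
    d <- sqrt((P[, 1] - cen[1])^2 + (P[, 2] - cen[2])^2 +
                (P[, 3] - cen[3])^2)
    if (any(d < r - inside_tol)) next
    out[[length(out) + 1]] <- c(sort(idx), cen, r)
  }
  if (length(out) == 0)
    return(matrix(numeric(0), 0, 8))
  do.call(rbind, out)
}

# --- Connected-components oracle (union-find) ---------------------------
uf_components <- function(centers, D) {
  n <- nrow(centers)
  d <- as.matrix(dist(centers))
  parent <- seq_len(n)
  findr <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j > i && d[i, j] <= D) {
      ri <- findr(i); rj <- findr(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  vapply(seq_len(n), findr, integer(1))
}

# --- Ideal-geometry chain builder (NeRF) --------------------------------
# Builds an N/CA/C backbone with prescribed (phi, psi), omega = 180, using
# standard bond lengths and angles, so dihedral recovery can be tested
# against the generating values.
place_atom <- function(A, B, C, L, theta_deg, chi_deg) {
  theta <- theta_deg * pi / 180
  chi <- -chi_deg * pi / 180  # frame handedness: negate to match the
                              # IUPAC sign the assigner reports
  unit <- function(v) v / sqrt(sum(v^2))
  cross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                            a[3] * b[1] - a[1] * b[3],
                            a[1] * b[2] - a[2] * b[1])
  bc <- unit(C - B)
  nrm <- unit(cross(B - A, bc))
  m <- cross(nrm, bc)
  d <- c(-L * cos(theta), L * sin(theta) * cos(chi),
         L * sin(theta) * sin(chi))
  C + d[1] * bc + d[2] * m + d[3] * nrm
}

make_ideal_chain <- function(n_res, phi, psi, chain = "A") {
  b_nca <- 1.458; b_cac <- 1.525; b_cn <- 1.329
  a_ncac <- 111.0; a_cacn <- 116.2; a_cnca <- 121.7
  coords <- list()
  # seed triad of residue 1
  N1 <- c(0, 0, 0)
  CA1 <- c(b_nca, 0, 0)
  C1 <- CA1 + b_cac * c(-cos(a_ncac * pi / 180), sin(a_ncac * pi / 180), 0)
  coords[["1"]] <- list(N = N1, CA = CA1, C = C1)
  for (i in seq_len(n_res - 1) + 1) {
    prev <- coords[[as.character(i - 1)]]
    Ni <- place_atom(prev$N, prev$CA, prev$C, b_cn, a_cacn, psi)
    CAi <- place_atom(prev$CA, prev$C, Ni, b_nca, a_cnca, 180)  # omega
    Ci <- place_atom(prev$C, Ni, CAi, b_cac, a_ncac, phi)
    coords[[as.character(i)]] <- list(N = Ni, CA = CAi, C = Ci)
  }
  rows <- list()
  for (i in seq_len(n_res)) {
    at <- coords[[as.character(i)]]
    for (nm in c("N", "CA", "C"))
      rows[[length(rows) + 1]] <- data.frame(
        element = substr(nm, 1, 1), name = nm,
        x = at[[nm]][1], y = at[[nm]][2], z = at[[nm]][3],
        resno = i, stringsAsFactors = FALSE)
  }
  atoms <- do.call(rbind, rows)
  atoms$chain <- chain
  make_structure(atoms, id = "ideal_chain")
}

# Small PDB text fixture written to a temp file.
write_fixture_pdb <- function(lines) {
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  f
}

# Regular tetrahedron with a given circumradius, centred at `center`.
regular_tetrahedron <- function(circumradius = 5, center = c(0, 0, 0)) {
  V <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  V <- V / sqrt(3) * circumradius
  sweep(V, 2, center, "+")
}
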