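#' Specification of a synthetic cavity-bearing cage structure
#'
#' Describes a protein-like atom cloud: atoms jittered through a spherical
#' wall that leaves an empty interior cavity and an atom-free mouth cone
#' around +z, optionally with a pseudo-ligand placed inside the cavity.
#' Atoms are threaded into pseudo-alanine residues (N, CA, C, O, CB) so the
#' dihedral/secondary-structure code runs on cages, and elements are drawn
#' from `element_mix` so apolarity-dependent descriptors are controllable
#' (a fatty-acid-like cavity is carbon-rich; a polar decoy is not).
#'
#' @param n_shell_atoms Atom budget; rounded down to a multiple of 5
#'   (default 200).
#' @param shell_radius Outer wall radius, Angstrom (default 9).
#' @param cavity_radius Inner wall radius = radius of the empty interior,
#'   Angstrom (default 5). Must be below `shell_radius`.
#' @param shell_thickness Radial wall depth, Angstrom; default
#'   `shell_radius - cavity_radius`.
#' @param mouth_half_angle Half-angle of the atom-free cone around +z,
#'   degrees, below 90 (default 15).
#' @param element_mix Named fractions over C/N/O/S summing to 1 (default
#'   all carbon).
#' @param ligand `"none"`, `acyl_ligand(n)` or `ring_ligand(n)`.
#' @param seed Integer seed; with the spec it fully determines the output.
#' @return A `fab_cage_spec` list.
#' @export
cage_spec <- function(n_shell_atoms = 200, shell_radius = 9,
                      cavity_radius = 5, shell_thickness = NULL,
                      mouth_half_angle = 15,
                      element_mix = c(C = 1, N = 0, O = 0, S = 0),
                      ligand = "none", seed = 1) {
  if (is.null(shell_thickness)) shell_thickness <- shell_radius - cavity_radius
  stopifnot(cavity_radius > 0, cavity_radius < shell_radius,
            shell_thickness > 0,
            cavity_radius + shell_thickness <= shell_radius + 1e-9,
            n_shell_atoms >= 20)
  if (mouth_half_angle < 0 || mouth_half_angle >= 90)
    stop("geometrically impossible spec: mouth_half_angle must be in ",
         "[0, 90) degrees")
  mix <- element_mix[c("C", "N", "O", "S")]
  mix[is.na(mix)] <- 0
  names(mix) <- c("C", "N", "O", "S")
  if (abs(sum(mix) - 1) > 1e-9) stop("element_mix fractions must sum to 1")
  structure(list(n_shell_atoms = as.integer(n_shell_atoms),
                 shell_radius = shell_radius, cavity_radius = cavity_radius,
                 shell_thickness = shell_thickness,
                 mouth_half_angle = mouth_half_angle, element_mix = mix,
                 ligand = ligand, seed = as.integer(seed)),
            class = "fab_cage_spec")
}

#' Acyl-chain / ring pseudo-ligand specifications
#'
#' `acyl_ligand(n)` is a tetrahedral zigzag carbon chain with 1.5 Angstrom
#' bond spacing (a straight all-anti chain of that length would not fit
#' inside the default cavity; the zigzag keeps the bond spacing and the
#' acyl-tail shape while staying within `cavity_radius` of the origin).
#' `ring_ligand(n)` is a planar regular polygon with 1.4 Angstrom edges —
#' the aromatic/cyclic decoy class.
#'
#' @param n_carbons,n_members Heavy-atom count.
#' @return A ligand spec list.
#' @export
acyl_ligand <- function(n_carbons = 8) {
  stopifnot(n_carbons >= 2)
  list(type = "acyl", n = as.integer(n_carbons))
}

#' @rdname acyl_ligand
#' @export
ring_ligand <- function(n_members = 6) {
  stopifnot(n_members >= 3)
  list(type = "ring", n = as.integer(n_members))
}

# Uniform directions on the sphere excluding the mouth cone around +z.
sample_directions <- function(n, mouth_half_angle) {
  umax <- cos(mouth_half_angle * pi / 180)
  u <- runif(n, -1, umax)
  phi <- runif(n, 0, 2 * pi)
  s <- sqrt(1 - u^2)
  cbind(s * cos(phi), s * sin(phi), u)
}

# Greedy nearest-neighbour threading of points into a chain order.
thread_order <- function(P) {
  n <- nrow(P)
  left <- rep(TRUE, n)
  ord <- integer(n)
  cur <- 1L
  for (i in seq_len(n)) {
    ord[i] <- cur
    left[cur] <- FALSE
    if (i == n) break
    d2 <- (P[, 1] - P[cur, 1])^2 + (P[, 2] - P[cur, 2])^2 +
      (P[, 3] - P[cur, 3])^2
    d2[!left] <- Inf
    cur <- which.min(d2)
  }
  ord
}

random_rotation <- function() {
  repeat {
    M <- matrix(rnorm(9), 3, 3)
    qr_ <- qr(M)
    Q <- qr.Q(qr_)
    if (det(Q) < 0) Q[, 1] <- -Q[, 1]
    if (abs(det(Q) - 1) < 1e-8) return(Q)
  }
}

ligand_coords <- function(lig, cavity_radius) {
  if (identical(lig$type, "acyl")) {
    n <- lig$n
    dx <- 1.23; dy <- 0.86  # 1.5 A bonds in a tetrahedral zigzag
    x <- (seq_len(n) - (n + 1) / 2) * dx
    y <- rep_len(c(0, dy), n) - dy / 2
    P <- cbind(x, y, 0)
  } else if (identical(lig$type, "ring")) {
    n <- lig$n
    rr <- 0.7 / sin(pi / n)  # circumradius for 1.4 A edges
    th <- 2 * pi * (seq_len(n) - 1) / n
    P <- cbind(rr * cos(th), rr * sin(th), 0)
  } else stop("unknown ligand type")
  if (max(sqrt(rowSums(P^2))) >= cavity_radius)
    stop("ligand does not fit inside the cavity")
  P %*% t(random_rotation())
}

#' Generate a synthetic cavity-bearing cage structure
#'
#' Builds the structure described by a [cage_spec()]: wall atoms at radii
#' uniform in `[cavity_radius, cavity_radius + shell_thickness]`, in
#' directions excluding the mouth cone, threaded by nearest neighbour into
#' pseudo-alanine residues on one polymer chain; the optional pseudo-ligand
#' is a HETATM residue (`SAC` for acyl, `SRG` for ring) centred in the
#' cavity. Output is deterministic per seed and PDB-writable with
#' [write_structure_pdb()].
#'
#' @param spec A [cage_spec()].
#' @return A `fab_structure` whose id records the seed; the spec is
#'   attached as attribute `"spec"`.
#' @export
make_cage <- function(spec) {
  stopifnot(inherits(spec, "fab_cage_spec"))
  with_seed(spec$seed, {
    n_res <- spec$n_shell_atoms %/% 5L
    n <- 5L * n_res
    dirs <- sample_directions(n, spec$mouth_half_angle)
    rad <- runif(n, spec$cavity_radius,
                 spec$cavity_radius + spec$shell_thickness)
    P <- dirs * rad
    P <- P[thread_order(P), , drop = FALSE]
    elements <- sample(names(spec$element_mix), n, replace = TRUE,
                       prob = spec$element_mix)
    atom_names <- rep_len(c("N", "CA", "C", "O", "CB"), n)
    atoms <- data.frame(
      element = elements, name = atom_names,
      x = round(P[, 1], 3), y = round(P[, 2], 3), z = round(P[, 3], 3),
      occ = 1, altloc = "", hetero = FALSE, chain = "A",
      resno = rep(seq_len(n_res), each = 5L), icode = "",
      resname = "ALA", kind = "polymer", vdw = NA_real_,
      stringsAsFactors = FALSE)
    if (!identical(spec$ligand, "none")) {
      L <- ligand_coords(spec$ligand, spec$cavity_radius)
      resname <- if (spec$ligand$type == "acyl") "SAC" else "SRG"
      lig <- data.frame(
        element = "C", name = paste0("C", seq_len(nrow(L))),
        x = round(L[, 1], 3), y = round(L[, 2], 3), z = round(L[, 3], 3),
        occ = 1, altloc = "", hetero = TRUE, chain = "L", resno = 1L,
        icode = "", resname = resname, kind = "ligand", vdw = NA_real_,
        stringsAsFactors = FALSE)
      atoms <- rbind(atoms, lig)
    }
    out <- structure(list(id = paste0("cage_seed", spec$seed),
                          atoms = atoms,
                          waters = atoms[0, , drop = FALSE],
                          model_index = 1L),
                     class = "fab_structure")
    attr(out, "spec") <- spec
    out
  })
}

#' Specification of a simulated labeled feature matrix
#'
#' Class-conditional multivariate Gaussian features over the 14-descriptor
#' [feature_schema()], standing in for a curated structure training set.
#' The first `round(informative_fraction * 14)` schema columns carry
#' signal: the class means differ by `effect_size` pooled standard
#' deviations (shifted symmetrically about the base profile); the remaining
#' columns are identically distributed in both classes. Fraction-type
#' columns are clipped to \[0, 1\] after sampling.
#'
#' @param n_pos,n_neg Class sizes.
#' @param effect_size Separation between class means, in pooled-sd units
#'   (0 = null).
#' @param informative_fraction Fraction of the 14 features carrying signal,
#'   in (0, 1].
#' @param noise_cov `"diagonal"` or `list(type = "exchangeable", rho = r)`
#'   for a common between-feature correlation.
#' @param seed Integer seed.
#' @return A `fab_feature_sim_spec` list.
#' @export
feature_sim_spec <- function(n_pos, n_neg, effect_size = 1,
                             informative_fraction = 0.5,
                             noise_cov = "diagonal", seed = 1) {
  stopifnot(n_pos >= 0, n_neg >= 0, effect_size >= 0,
            informative_fraction > 0, informative_fraction <= 1)
  if (is.list(noise_cov))
    stopifnot(identical(noise_cov$type, "exchangeable"),
              noise_cov$rho >= 0, noise_cov$rho < 1)
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 effect_size = effect_size,
                 informative_fraction = informative_fraction,
                 noise_cov = noise_cov, seed = as.integer(seed)),
            class = "fab_feature_sim_spec")
}

# Plausible base profile (mean, sd) per descriptor; fraction columns are
# clipped to [0, 1] after sampling.
feature_base_profile <- function() {
  nm <- as.character(feature_schema())
  mean <- c(40, 5.0, 5.8, 0.55, 600, 6.0, 0.5, 0.30, 0.20, 0.12,
            0.40, 0.15, 0.45, 25)
  sd <- c(12, 0.35, 0.30, 0.15, 150, 1.5, 1.2, 0.10, 0.08, 0.07,
          0.15, 0.10, 0.15, 8)
  frac <- grepl("fraction", nm)
  list(names = nm, mean = setNames(mean, nm), sd = setNames(sd, nm),
       fraction_cols = frac)
}

#' Simulate a labeled pocket feature matrix
#'
#' @param spec A [feature_sim_spec()].
#' @return List with `X` (matrix, [feature_schema()] columns), `y` (integer
#'   labels, positives first), `informative` (names of signal-carrying
#'   columns) and `usable_for_training` (`FALSE` when a class is empty).
#' @export
simulate_features <- function(spec) {
  stopifnot(inherits(spec, "fab_feature_sim_spec"))
  prof <- feature_base_profile()
  p <- length(prof$names)
  m <- max(1L, round(spec$informative_fraction * p))
  informative <- prof$names[seq_len(m)]
  n <- spec$n_pos + spec$n_neg
  y <- rep(c(1L, 0L), c(spec$n_pos, spec$n_neg))
  X <- with_seed(spec$seed, {
    E <- matrix(rnorm(n * p), n, p)
    if (is.list(spec$noise_cov)) {
      rho <- spec$noise_cov$rho
      g <- rnorm(n)
      E <- sqrt(rho) * matrix(g, n, p) + sqrt(1 - rho) * E
    }
    Z <- sweep(E, 2, prof$sd, "*")
    Z <- sweep(Z, 2, prof$mean, "+")
    shift <- ifelse(y == 1, spec$effect_size / 2, -spec$effect_size / 2)
    for (j in seq_len(m))
      Z[, j] <- Z[, j] + shift * prof$sd[j]
    Z
  })
  colnames(X) <- prof$names
  X[, prof$fraction_cols] <- pmin(pmax(X[, prof$fraction_cols], 0), 1)
  X[, "n_spheres"] <- pmax(X[, "n_spheres"], 1)
  X[, "n_lining_residues"] <- pmax(X[, "n_lining_residues"], 1)
  list(X = X, y = y, informative = informative,
       usable_for_training = spec$n_pos > 0 && spec$n_neg > 0)
}
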