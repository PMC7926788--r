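#' Backbone phi/psi dihedrals for one chain
#'
#' Computes, per polymer residue, phi from C(i-1)-N(i)-CA(i)-C(i) and psi
#' from N(i)-CA(i)-C(i)-N(i+1), in degrees in (-180, 180]. Dihedrals are
#' marked missing (`NA`) at chain termini, across chain breaks (consecutive
#' CA-CA distance above 4.5 Angstrom), and wherever a backbone atom is
#' absent.
#'
#' @param structure A `fab_structure`.
#' @param chain Chain identifier.
#' @return Data frame: `chain`, `resno`, `icode`, `resname`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(structure, chain) {
  a <- structure$atoms
  a <- a[a$kind == "polymer" & a$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no polymer atoms in chain ", chain)
  key <- paste(a$resno, a$icode, sep = "\r")
  resid <- unique(key)
  n <- length(resid)
  getxyz <- function(ri, name) {
    hit <- which(key == resid[ri] & a$name == name)
    if (length(hit) == 0) return(NULL)
    c(a$x[hit[1]], a$y[hit[1]], a$z[hit[1]])
  }
  N <- lapply(seq_len(n), getxyz, name = "N")
  CA <- lapply(seq_len(n), getxyz, name = "CA")
  C <- lapply(seq_len(n), getxyz, name = "C")
  # chain break between i and i+1 when either CA is missing or the CA-CA
  # gap exceeds 4.5 A
  linked <- rep(FALSE, n)  # linked[i]: residue i connected to residue i+1
  if (n > 1) for (i in seq_len(n - 1))
    linked[i] <- !is.null(CA[[i]]) && !is.null(CA[[i + 1]]) &&
      sqrt(sum((CA[[i]] - CA[[i + 1]])^2)) <= 4.5
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1 && linked[i - 1] &&
        !is.null(C[[i - 1]]) && !is.null(N[[i]]) && !is.null(CA[[i]]) &&
        !is.null(C[[i]]))
      phi[i] <- dihedral_deg(C[[i - 1]], N[[i]], CA[[i]], C[[i]])
    if (i < n && linked[i] &&
        !is.null(N[[i]]) && !is.null(CA[[i]]) && !is.null(C[[i]]) &&
        !is.null(N[[i + 1]]))
      psi[i] <- dihedral_deg(N[[i]], CA[[i]], C[[i]], N[[i + 1]])
  }
  first <- match(resid, key)
  data.frame(chain = chain, resno = a$resno[first], icode = a$icode[first],
             resname = a$resname[first], phi = phi, psi = psi,
             stringsAsFactors = FALSE)
}

# Signed dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  ang <- atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Assign 3-state secondary structure from backbone dihedrals
#'
#' A dihedral-region classifier with run-length smoothing, standing in for
#' a hydrogen-bond-based assigner such as Stride: residues with phi in
#' \[-100, -30\] and psi in \[-80, -5\] are helix (H); residues with phi in
#' \[-180, -80\] and psi in \[90, 180\] or \[-180, -170\] are strand (E);
#' everything else, including residues with missing dihedrals, is coil (C).
#' Helix runs shorter than 4 and strand runs shorter than 3 are demoted to
#' coil. The downstream classifier consumes only coarse per-pocket H/E/C
#' composition fractions, for which this approximation suffices.
#'
#' @param structure A `fab_structure`.
#' @param chain Chain identifier; `NULL` (default) assigns every chain.
#' @return Data frame: `chain`, `resno`, `icode`, `resname`, `label`
#'   (one of "H", "E", "C").
#' @export
assign_ss <- function(structure, chain = NULL) {
  chains <- if (is.null(chain)) {
    pk <- structure$atoms$kind == "polymer"
    unique(structure$atoms$chain[pk])
  } else chain
  out <- lapply(chains, function(ch) {
    d <- backbone_dihedrals(structure, ch)
    lab <- rep("C", nrow(d))
    ok <- !is.na(d$phi) & !is.na(d$psi)
    h <- ok & d$phi >= -100 & d$phi <= -30 & d$psi >= -80 & d$psi <= -5
    e <- ok & d$phi >= -180 & d$phi <= -80 &
      ((d$psi >= 90 & d$psi <= 180) | (d$psi >= -180 & d$psi <= -170))
    lab[e] <- "E"
    lab[h] <- "H"   # helix box wins where the boxes could be extended
    lab <- demote_short_runs(lab, "H", 4)
    lab <- demote_short_runs(lab, "E", 3)
    d$label <- lab
    d[, c("chain", "resno", "icode", "resname", "label")]
  })
  do.call(rbind, out)
}

demote_short_runs <- function(lab, what, min_len) {
  r <- rle(lab)
  r$values[r$values == what & r$lengths < min_len] <- "C"
  inverse.rle(r)
}
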