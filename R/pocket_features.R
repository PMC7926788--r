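#' Feature schema of the pocket descriptor vector
#'
#' The fixed-order 14-descriptor contract consumed by the classifier:
#' alpha-sphere geometry (`n_spheres`, `mean_radius`, `max_radius`,
#' `apolar_fraction`, `volume`, `compactness`), lining-residue
#' physicochemistry (`hydrophobicity` as the mean Kyte-Doolittle index,
#' `polar_residue_fraction`, `charged_residue_fraction`,
#' `aromatic_residue_fraction`), lining secondary-structure composition
#' (`helix_fraction`, `strand_fraction`, `coil_fraction`) and
#' `n_lining_residues`. The order and the schema version travel with every
#' trained model; prediction refuses mismatching schemas.
#'
#' @return Character vector of the 14 feature names, with attribute
#'   `"version"`.
#' @export
feature_schema <- function() {
  structure(c("n_spheres", "mean_radius", "max_radius", "apolar_fraction",
              "volume", "compactness", "hydrophobicity",
              "polar_residue_fraction", "charged_residue_fraction",
              "aromatic_residue_fraction", "helix_fraction",
              "strand_fraction", "coil_fraction", "n_lining_residues"),
            version = "fab-features-1")
}

# Kyte-Doolittle hydropathy index by 3-letter residue code.
kd_scale <- c(ILE = 4.5, VAL = 4.2, LEU = 3.8, PHE = 2.8, CYS = 2.5,
              MET = 1.9, ALA = 1.8, GLY = -0.4, THR = -0.7, SER = -0.8,
              TRP = -0.9, TYR = -1.3, PRO = -1.6, HIS = -3.2, GLU = -3.5,
              GLN = -3.5, ASP = -3.5, ASN = -3.5, LYS = -3.9, ARG = -4.5)
polar_set <- c("SER", "THR", "ASN", "GLN", "TYR", "CYS", "HIS")
charged_set <- c("ASP", "GLU", "LYS", "ARG")
aromatic_set <- c("PHE", "TRP", "TYR", "HIS")

#' Monte-Carlo volume of a union of spheres
#'
#' Samples points uniformly in the axis-aligned bounding box of the spheres
#' and estimates the union volume as the hit fraction times the box volume.
#' The binomial standard error of the estimate is returned alongside.
#'
#' @param spheres Data frame with columns `cx`, `cy`, `cz`, `radius`.
#' @param n_samples Number of Monte-Carlo samples (at least 1e4; default
#'   2e4).
#' @param seed Integer seed making the estimate reproducible.
#' @return List with `volume` (cubic Angstrom) and `se`.
#' @examples
#' s <- data.frame(cx = 0, cy = 0, cz = 0, radius = 4)
#' pocket_volume(s, seed = 1)  # ~ 4/3 pi 4^3 = 268.08
#' @export
pocket_volume <- function(spheres, n_samples = 2e4, seed = 1) {
  stopifnot(nrow(spheres) >= 1, n_samples >= 1e4)
  lo <- c(min(spheres$cx - spheres$radius), min(spheres$cy - spheres$radius),
          min(spheres$cz - spheres$radius))
  hi <- c(max(spheres$cx + spheres$radius), max(spheres$cy + spheres$radius),
          max(spheres$cz + spheres$radius))
  vbox <- prod(hi - lo)
  with_seed(seed, {
    px <- runif(n_samples, lo[1], hi[1])
    py <- runif(n_samples, lo[2], hi[2])
    pz <- runif(n_samples, lo[3], hi[3])
    inside <- rep(FALSE, n_samples)
    for (i in seq_len(nrow(spheres))) {
      todo <- which(!inside)
      if (length(todo) == 0) break
      d2 <- (px[todo] - spheres$cx[i])^2 + (py[todo] - spheres$cy[i])^2 +
        (pz[todo] - spheres$cz[i])^2
      inside[todo[d2 <= spheres$radius[i]^2]] <- TRUE
    }
    p <- mean(inside)
    list(volume = p * vbox, se = vbox * sqrt(p * (1 - p) / n_samples))
  })
}

#' Compute the descriptor vector of a pocket
#'
#' Populates the [feature_schema()] fields from the pocket's alpha spheres,
#' its lining residues and their secondary-structure labels. Hydrophobicity
#' averages the Kyte-Doolittle index over lining residues with a defined
#' index; nonstandard residues contribute to counts and class fractions
#' only. Lining residues without an SS label (e.g., termini of broken
#' chains) count as coil. Compactness is the mean pairwise distance between
#' sphere centres (0 for a single sphere).
#'
#' @param pocket A `fab_pocket`.
#' @param structure The structure the pocket was detected on (kept in the
#'   signature for interface symmetry; lining residues already live in the
#'   pocket).
#' @param ss SS label data frame from [assign_ss()], or `NULL` to label all
#'   lining residues coil.
#' @param n_samples,seed Monte-Carlo settings for the volume term, see
#'   [pocket_volume()].
#' @return Named numeric vector following [feature_schema()], with the
#'   schema version attached as attribute `"version"`.
#' @export
compute_features <- function(pocket, structure, ss = NULL,
                             n_samples = 2e4, seed = 1) {
  lin <- pocket$lining
  if (is.null(lin) || nrow(lin) == 0) stop("malformed pocket: empty lining")
  sp <- pocket$spheres
  cen <- as.matrix(sp[, c("cx", "cy", "cz")])
  compact <- if (nrow(cen) > 1) mean(dist(cen)) else 0
  vol <- pocket_volume(sp, n_samples = n_samples, seed = seed)$volume
  kd <- kd_scale[lin$resname]
  hyd <- if (all(is.na(kd))) 0 else mean(kd, na.rm = TRUE)
  if (is.null(ss)) {
    lab <- rep("C", nrow(lin))
  } else {
    mk <- function(d) paste(d$chain, d$resno, d$icode, sep = "\r")
    lab <- ss$label[match(mk(lin), mk(ss))]
    lab[is.na(lab)] <- "C"
  }
  v <- c(n_spheres = nrow(sp),
         mean_radius = mean(sp$radius),
         max_radius = max(sp$radius),
         apolar_fraction = mean(sp$apolar),
         volume = vol,
         compactness = compact,
         hydrophobicity = hyd,
         polar_residue_fraction = mean(lin$resname %in% polar_set),
         charged_residue_fraction = mean(lin$resname %in% charged_set),
         aromatic_residue_fraction = mean(lin$resname %in% aromatic_set),
         helix_fraction = mean(lab == "H"),
         strand_fraction = mean(lab == "E"),
         coil_fraction = mean(lab == "C"),
         n_lining_residues = nrow(lin))
  stopifnot(identical(names(v), as.character(feature_schema())))
  attr(v, "version") <- attr(feature_schema(), "version")
  v
}

#' Column-wise z-score normalization with reusable statistics
#'
#' Fits per-column mean/sd on a training matrix, or applies previously
#' fitted statistics to new rows (held-out folds, prediction inputs).
#' Zero-variance columns pass through untouched with a
#' warning; the fitted statistics are meant to be stored inside a trained
#' model so exactly the training-fold statistics are reused downstream.
#'
#' @param X Numeric matrix, rows = pockets, columns in [feature_schema()]
#'   order.
#' @param stats `NULL` to fit on `X`, or a previously returned `stats` list.
#' @return List with `X` (normalized matrix) and `stats`
#'   (`mean`, `sd`, `constant` logical per column).
#' @export
normalize_features <- function(X, stats = NULL) {
  X <- as.matrix(X)
  if (is.null(stats)) {
    mu <- colMeans(X)
    sdv <- apply(X, 2, sd)
    constant <- !is.finite(sdv) | sdv == 0
    if (any(constant))
      warning("zero-variance column(s) left unscaled: ",
              paste(colnames(X)[constant], collapse = ", "))
    mu[constant] <- 0   # constant columns pass through untouched
    sdv[constant] <- 1
    stats <- list(mean = mu, sd = sdv, constant = constant)
  } else {
    if (ncol(X) != length(stats$mean))
      stop("column count mismatch: matrix has ", ncol(X),
           " columns, stats expect ", length(stats$mean))
  }
  Z <- sweep(sweep(X, 2, stats$mean), 2, stats$sd, "/")
  list(X = Z, stats = stats)
}
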