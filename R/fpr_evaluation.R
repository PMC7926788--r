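#' Build a negative evaluation pool
#'
#' A negative pool is a table of ligand-bound structures whose ligands are
#' not fatty acids (nor FA-like): the exclusion list removes every listed
#' ligand code from each entry, and entries left without any bound ligand
#' are dropped, since a pool entry must carry at least one ligand in a
#' cavity.
#'
#' @param entries Data frame with columns `id`, `path` and `ligand_codes`
#'   (semicolon-separated chemical component codes).
#' @param exclusion Character vector of codes to purge, e.g., from
#'   [load_ligand_exclusion()].
#' @return The filtered pool data frame, with attribute
#'   `"exclusion_applied" = TRUE`.
#' @export
build_negative_pool <- function(entries, exclusion = character()) {
  stopifnot(all(c("id", "path", "ligand_codes") %in% names(entries)))
  exclusion <- toupper(exclusion)
  codes <- strsplit(toupper(entries$ligand_codes), ";", fixed = TRUE)
  codes <- lapply(codes, function(x) setdiff(trimws(x), c(exclusion, "")))
  keep <- lengths(codes) > 0
  pool <- entries[keep, , drop = FALSE]
  pool$ligand_codes <- vapply(codes[keep], paste, character(1),
                              collapse = ";")
  rownames(pool) <- NULL
  attr(pool, "exclusion_applied") <- TRUE
  pool
}

#' Sample structures from a pool without replacement
#'
#' Uniform, seed-reproducible sampling; the drawn identifiers form the run
#' manifest stored in every FPR report.
#'
#' @param pool Pool data frame (one row per structure).
#' @param n Sample size, at most `nrow(pool)`.
#' @param seed Integer seed.
#' @return The sampled rows, with attribute `"seed"`.
#' @export
sample_pool <- function(pool, n, seed) {
  if (n > nrow(pool))
    stop("requested sample of ", n, " from a pool of ", nrow(pool))
  idx <- with_seed(seed, sample.int(nrow(pool), n))
  out <- pool[idx, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

#' False-positive rate as a percentage
#'
#' @param n_positive Count of pockets called positive.
#' @param n_total Total pockets evaluated (at least 1).
#' @return `100 * n_positive / n_total`, rounded to 1 decimal.
#' @examples
#' compute_fpr(1281, 27222)  # 4.7
#' @export
compute_fpr <- function(n_positive, n_total) {
  if (n_total < 1) stop("n_total must be at least 1")
  if (n_positive < 0 || n_positive > n_total)
    stop("n_positive must lie in [0, n_total]")
  round(100 * n_positive / n_total, 1)
}

#' Estimate false-positive rates of two models on a negative pool
#'
#' Samples `n_sample` structures from the (exclusion-filtered) pool, runs
#' cavity detection with ligand atoms removed (the training convention),
#' computes features, scores every pocket with both models at the strict
#' threshold, and reports per-model and consensus positive counts and FPR
#' percentages. Because the consensus set is the intersection of the two
#' positive sets, the consensus FPR never exceeds either per-model FPR.
#'
#' @param pool Pool data frame from [build_negative_pool()] (columns `id`,
#'   `path`).
#' @param model_a,model_b Trained `fab_model` objects.
#' @param params [detection_params()] reused from training for internal
#'   consistency.
#' @param n_sample Structures to sample; default the whole pool.
#' @param seed Sampling seed.
#' @param volume_seed Seed of the Monte-Carlo volume term.
#' @return A `fab_fpr_report`: counts, FPR percentages, manifest, seed.
#' @export
evaluate_fpr <- function(pool, model_a, model_b,
                         params = detection_params(),
                         n_sample = nrow(pool), seed = 1, volume_seed = 1) {
  sampled <- sample_pool(pool, n_sample, seed)
  feats <- list()
  for (i in seq_len(nrow(sampled))) {
    s <- read_pdb(sampled$path[i], id = sampled$id[i])
    pockets <- detect_pockets(s, params, include_ligands = FALSE)
    if (length(pockets) == 0) next
    ss <- assign_ss(s)
    for (p in pockets)
      feats[[length(feats) + 1]] <- compute_features(p, s, ss,
                                                     seed = volume_seed)
  }
  if (length(feats) == 0)
    stop("no pockets detected over the sampled pool; ",
         "check the detection parameters")
  X <- do.call(rbind, feats)
  pa <- predict(model_a, X)
  pb <- predict(model_b, X)
  cons <- consensus_call(pa, pb)
  n <- nrow(X)
  structure(list(n_structures_sampled = nrow(sampled),
                 n_pockets_total = n,
                 n_positive_a = sum(pa$positive),
                 n_positive_b = sum(pb$positive),
                 n_positive_consensus = sum(cons),
                 fpr_percent_a = compute_fpr(sum(pa$positive), n),
                 fpr_percent_b = compute_fpr(sum(pb$positive), n),
                 fpr_percent_consensus = compute_fpr(sum(cons), n),
                 sample_seed = seed,
                 manifest = sampled$id),
            class = "fab_fpr_report")
}

#' @export
print.fab_fpr_report <- function(x, ...) {
  cat("fab_fpr_report: ", x$n_pockets_total, " pockets over ",
      x$n_structures_sampled, " structures (seed ", x$sample_seed, ")\n",
      sep = "")
  cat(sprintf("  model A: %d positive, FPR %.1f%%\n", x$n_positive_a,
              x$fpr_percent_a))
  cat(sprintf("  model B: %d positive, FPR %.1f%%\n", x$n_positive_b,
              x$fpr_percent_b))
  cat(sprintf("  consensus: %d positive, FPR %.1f%%\n",
              x$n_positive_consensus, x$fpr_percent_consensus))
  invisible(x)
}
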