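#' Classifier hyperparameters
#'
#' Settings of the multilayer-perceptron pocket classifier: a single hidden
#' layer of logistic units trained by quasi-Newton optimization (BFGS, via
#' \pkg{nnet}) on cross-entropy with L2 weight decay. Decay plus an
#' iteration cap regularize the fit. The decision threshold is strict:
#' a pocket is called positive only when its score exceeds the cutoff
#' (`score > threshold`), never at equality.
#'
#' @param hidden Hidden-layer width (default 32).
#' @param l2 L2 weight-decay coefficient (default 1e-4).
#' @param max_epochs Maximum optimizer iterations (default 500).
#' @param seed Integer seed controlling weight initialization; recorded in
#'   every trained model.
#' @param threshold Score cutoff in (0, 1); default 0.5, applied strictly.
#' @return A `fab_classifier_params` list.
#' @export
classifier_params <- function(hidden = 32, l2 = 1e-4, max_epochs = 500,
                              seed = 1, threshold = 0.5) {
  stopifnot(hidden >= 1, l2 >= 0, max_epochs >= 1,
            threshold > 0, threshold < 1)
  structure(list(hidden = as.integer(hidden), l2 = l2,
                 max_epochs = as.integer(max_epochs),
                 seed = as.integer(seed), threshold = threshold),
            class = "fab_classifier_params")
}

#' Train the MLP pocket classifier
#'
#' Fits feature normalization on the training rows only, then trains the
#' MLP. The returned model carries the hyperparameters, the feature-schema
#' version, the normalization statistics and the seed, so scoring is fully
#' reproducible and schema-checked.
#'
#' @param X Numeric feature matrix with [feature_schema()] columns.
#' @param y 0/1 labels, both classes present, at least 10 rows.
#' @param params [classifier_params()].
#' @return A `fab_model` object.
#' @export
train_fa_model <- function(X, y, params = classifier_params()) {
  X <- as.matrix(X)
  y <- as.integer(y)
  if (nrow(X) < 10) stop("need at least 10 training rows")
  if (length(unique(y)) < 2)
    stop("both classes must be present in the training labels")
  if (anyNA(X) || any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1, ]
    stop("non-finite feature at row ", bad[1], ", column ",
         colnames(X)[bad[2]])
  }
  check_schema(X)
  norm <- suppressWarnings(normalize_features(X))
  fit <- with_seed(params$seed,
                   nnet::nnet(norm$X, y, size = params$hidden,
                              decay = params$l2, maxit = params$max_epochs,
                              entropy = TRUE, trace = FALSE,
                              MaxNWts = 10000))
  structure(list(params = params,
                 schema_version = attr(feature_schema(), "version"),
                 feature_names = colnames(X),
                 norm_stats = norm$stats,
                 fit = fit,
                 converged = fit$convergence == 0,
                 provenance = list(n = nrow(X),
                                   n_pos = sum(y == 1),
                                   n_neg = sum(y == 0),
                                   seed = params$seed)),
            class = "fab_model")
}

check_schema <- function(X, model = NULL) {
  want <- as.character(feature_schema())
  if (is.null(colnames(X)) || !identical(colnames(X), want))
    stop("feature schema mismatch: matrix columns do not follow ",
         attr(feature_schema(), "version"))
  if (!is.null(model) &&
      !identical(model$schema_version, attr(feature_schema(), "version")))
    stop("feature schema mismatch: model was trained under ",
         model$schema_version)
  invisible(TRUE)
}

#' @export
print.fab_model <- function(x, ...) {
  cat("fab_model (MLP, hidden = ", x$params$hidden, ", seed = ",
      x$params$seed, ")\n", sep = "")
  cat("  trained on ", x$provenance$n, " pockets (",
      x$provenance$n_pos, " positive / ", x$provenance$n_neg,
      " negative), schema ", x$schema_version, "\n", sep = "")
  invisible(x)
}

#' Score pockets with a trained model
#'
#' Applies the model's stored normalization and returns, per row, a score
#' in \[0, 1\] (1 = confident fatty-acid binder) and the strict positive
#' call `score > threshold`. A score exactly at the threshold is negative.
#'
#' @param object A `fab_model`.
#' @param X Feature matrix with [feature_schema()] columns.
#' @param ... Unused.
#' @return Data frame with columns `score` and `positive`.
#' @export
predict.fab_model <- function(object, X, ...) {
  X <- as.matrix(X)
  check_schema(X, object)
  Z <- normalize_features(X, object$norm_stats)$X
  score <- as.numeric(predict(object$fit, Z))
  score <- pmin(pmax(score, 0), 1)
  data.frame(score = score, positive = score > object$params$threshold)
}

# Stratified fold assignment: within each class, shuffle and deal members
# round-robin so fold sizes and class balance differ by at most 1.
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

#' Stratified k-fold cross-validation of the pocket classifier
#'
#' Assigns rows to `k` stratified folds with a recorded seed, refits the
#' model from scratch on each training split (normalization included), and
#' scores the held-out fold at the strict threshold. Reports per-fold
#' accuracy, their mean, and the pooled accuracy over all held-out
#' predictions.
#'
#' @param X,y,params As in [train_fa_model()].
#' @param k Fold count (default 5). Each class must have at least `k`
#'   members.
#' @param fold_seed Seed of the fold assignment (default `params$seed`).
#' @return A `fab_cv` object: `k`, `fold_accuracy`, `mean_accuracy`,
#'   `pooled_accuracy`, `fold_seed`, `fold` assignment vector.
#' @export
cross_validate <- function(X, y, params = classifier_params(), k = 5,
                           fold_seed = params$seed) {
  X <- as.matrix(X); y <- as.integer(y)
  tab <- table(y)
  if (length(tab) < 2) stop("both classes must be present")
  if (any(tab < k)) stop("each class needs at least k = ", k, " members")
  fold <- stratified_folds(y, k, fold_seed)
  acc <- numeric(k)
  pooled_hit <- 0L
  for (f in seq_len(k)) {
    tr <- fold != f; te <- !tr
    stopifnot(!any(tr & te))  # reported accuracy never touches training rows
    m <- train_fa_model(X[tr, , drop = FALSE], y[tr], params)
    pr <- predict(m, X[te, , drop = FALSE])
    hit <- sum((pr$positive & y[te] == 1) | (!pr$positive & y[te] == 0))
    acc[f] <- hit / sum(te)
    pooled_hit <- pooled_hit + hit
  }
  structure(list(k = k, fold_accuracy = acc, mean_accuracy = mean(acc),
                 pooled_accuracy = pooled_hit / length(y),
                 fold_seed = fold_seed, fold = fold),
            class = "fab_cv")
}

#' @export
print.fab_cv <- function(x, ...) {
  cat("fab_cv: ", x$k, "-fold stratified cross-validation\n", sep = "")
  cat("  fold accuracy: ", paste(round(x$fold_accuracy, 3), collapse = " "),
      "\n  mean ", round(x$mean_accuracy, 4), ", pooled ",
      round(x$pooled_accuracy, 4), "\n", sep = "")
  invisible(x)
}

#' Two-model consensus call
#'
#' A pocket is consensus-positive only when it is positive (strictly above
#' threshold) under both models — the consensus set is exactly the
#' intersection of the two positive sets, so its false-positive rate can
#' never exceed either model's.
#'
#' @param pred_a,pred_b Prediction data frames from [predict.fab_model()],
#'   aligned to the same pockets.
#' @return Logical vector of consensus calls.
#' @export
consensus_call <- function(pred_a, pred_b) {
  if (nrow(pred_a) != nrow(pred_b))
    stop("prediction length mismatch: ", nrow(pred_a), " vs ", nrow(pred_b))
  pred_a$positive & pred_b$positive
}
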