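#' F-score ranking of features for a binary classification problem
#'
#' For each feature i, with class means \eqn{\bar{x}^+_i}, \eqn{\bar{x}^-_i}
#' and overall mean \eqn{\bar{x}_i},
#' \deqn{F(i) = \frac{(\bar{x}^+_i - \bar{x}_i)^2 + (\bar{x}^-_i - \bar{x}_i)^2}
#'   {\frac{1}{n^+ - 1}\sum_k (x^+_{k,i} - \bar{x}^+_i)^2 +
#'    \frac{1}{n^- - 1}\sum_k (x^-_{k,i} - \bar{x}^-_i)^2}}
#' the ratio of between-class separation to pooled within-class variance, as
#' computed by LIBSVM's feature-selection script. A feature with nonzero
#' separation and zero within-class variance is a perfect separator and gets
#' an infinite score (ranked first); a feature with zero separation scores 0.
#' Ties are broken by ascending feature index.
#'
#' @param X Feature matrix (samples x features).
#' @param y Labels; positive class `"PSBP"`. Both classes need >= 2 samples.
#' @return A `feature_ranking`: list with `scores` (per input column) and
#'   `order` (column indices by descending score).
#' @export
fscore <- function(X, y) {
  pos <- is_positive(y)
  if (sum(pos) < 2L || sum(!pos) < 2L) {
    stop("F-score needs at least 2 samples in each class", call. = FALSE)
  }
  Xp <- X[pos, , drop = FALSE]
  Xn <- X[!pos, , drop = FALSE]
  mp <- colMeans(Xp); mn <- colMeans(Xn); m <- colMeans(X)
  vp <- apply(Xp, 2, stats::var)
  vn <- apply(Xn, 2, stats::var)
  num <- (mp - m)^2 + (mn - m)^2
  den <- vp + vn
  scores <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  names(scores) <- colnames(X)
  structure(list(scores = scores,
                 order = order(-scores, seq_along(scores))),
            class = "feature_ranking")
}

#' Forward feature selection along the F-score ranking
#'
#' Features are added to an initially empty set one by one in descending
#' F-score order; after each addition the stratified k-fold cross-validated
#' SVM accuracy of the current set is measured. The prefix achieving the
#' maximum accuracy is the optimal subset; ties go to the smallest prefix.
#'
#' By default one (cost, gamma) grid search is run on the full feature block
#' and that configuration is held fixed during the sweep; `retune = TRUE`
#' re-runs the grid search at every prefix size (much slower).
#'
#' @param X Feature matrix (one block: AAC, DPC, or combined).
#' @param y Labels; positive class `"PSBP"`.
#' @param ranking Optional [fscore()] result for `X` (computed if `NULL`).
#' @param k Folds for the selection CV.
#' @param seed Seed for the fold split (fixed across the whole sweep).
#' @param config Optional fixed [svm_config()]; overrides the initial grid
#'   search when `retune = FALSE`.
#' @param retune Re-run the grid search at every prefix size.
#' @param max_k Largest prefix size to consider (default: all features).
#' @return A `feature_subset`: list with `indices` (column indices of `X`, in
#'   ranking order), `features` (their names), `achieved_accuracy`, `config`,
#'   and `curve` (`data.frame` of prefix size vs accuracy).
#' @export
forward_select <- function(X, y, ranking = NULL, k = 5, seed = 1,
                           config = NULL, retune = FALSE,
                           max_k = ncol(X)) {
  if (is.null(ranking)) ranking <- fscore(X, y)
  stopifnot(inherits(ranking, "feature_ranking"),
            length(ranking$order) == ncol(X))
  max_k <- min(max_k, ncol(X))
  folds <- kfold_split(y, k = k, seed = seed)
  if (!retune && is.null(config)) {
    config <- grid_search(X, y, folds = folds)
  }
  acc <- numeric(max_k)
  for (kk in seq_len(max_k)) {
    cols <- ranking$order[seq_len(kk)]
    Xk <- X[, cols, drop = FALSE]
    cfg <- if (retune) grid_search(Xk, y, folds = folds) else config
    acc[kk] <- fold_accuracy(Xk, y, folds, cfg$cost, cfg$gamma)
  }
  best <- which.max(acc)  # ties -> smallest prefix
  idx <- ranking$order[seq_len(best)]
  cfg_best <- if (retune) grid_search(X[, idx, drop = FALSE], y, folds = folds) else config
  structure(list(indices = idx,
                 features = colnames(X)[idx],
                 achieved_accuracy = acc[best],
                 config = cfg_best,
                 seed = seed,
                 curve = data.frame(k = seq_len(max_k), accuracy = acc)),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("feature_subset: %d features, CV accuracy %.4f\n",
              length(x$indices), x$achieved_accuracy))
  invisible(x)
}

#' Persist a feature subset as plain text plus a JSON sidecar
#'
#' Writes one feature name per line to `path`, and `<path>.json` with the
#' achieved accuracy, CV seed and the full accuracy-vs-k curve.
#'
#' @param subset A `feature_subset`.
#' @param path Output path for the feature-name list.
#' @return `path`, invisibly.
#' @export
write_feature_subset <- function(subset, path) {
  writeLines(subset$features, path)
  jsonlite::write_json(
    list(achieved_accuracy = subset$achieved_accuracy,
         seed = subset$seed,
         cost = subset$config$cost, gamma = subset$config$gamma,
         curve = subset$curve),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
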