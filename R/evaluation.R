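#' Stratified k-fold split
#'
#' Randomly partitions sample indices into k folds, stratified by class:
#' within each class, fold sizes differ by at most 1, and the leftover
#' samples are rotated across folds between classes so overall fold sizes are
#' as equal as possible (e.g. 104+104 samples in 5 folds gives sizes
#' 42, 42, 42, 41, 41). Deterministic given `seed`.
#'
#' @param labels Class labels (length n), or an integer n for an
#'   unstratified split.
#' @param k Number of folds.
#' @param seed RNG seed.
#' @return List of k disjoint integer index vectors covering 1..n.
#' @export
kfold_split <- function(labels, k = 5, seed = 1) {
  if (length(labels) == 1L && is.numeric(labels)) {
    labels <- rep("all", labels)
  }
  n <- length(labels)
  if (n < k) stop("need at least as many samples as folds", call. = FALSE)
  set.seed(seed)
  folds <- replicate(k, integer(0), simplify = FALSE)
  offset <- 0L
  for (cl in unique(as.character(labels))) {
    idx <- which(as.character(labels) == cl)
    idx <- if (length(idx) > 1L) sample(idx) else idx
    nc <- length(idx)
    sizes <- rep(nc %/% k, k)
    rem <- nc %% k
    if (rem > 0L) {
      extra <- ((offset + seq_len(rem) - 1L) %% k) + 1L
      sizes[extra] <- sizes[extra] + 1L
      offset <- (offset + rem) %% k
    }
    stops <- cumsum(sizes)
    starts <- stops - sizes + 1L
    for (f in seq_len(k)) {
      if (sizes[f] > 0L) folds[[f]] <- c(folds[[f]], idx[starts[f]:stops[f]])
    }
  }
  folds
}

#' Classification metrics from a confusion matrix
#'
#' Sensitivity Sn = TP/(TP+FN), specificity Sp = TN/(TN+FP), accuracy
#' Acc = (TP+TN)/(TP+FN+FP+TN), and the Matthews correlation coefficient
#' MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)).
#' When any MCC denominator factor is zero the coefficient is undefined; it
#' is reported as 0 with `mcc_undefined = TRUE` (a documented convention).
#'
#' @param tp,fp,tn,fn Non-negative counts.
#' @return List with `Sn`, `Sp`, `Acc`, `MCC`, `mcc_undefined`, and the
#'   counts.
#' @export
#' @examples
#' metrics_from_confusion(tp = 92, fp = 15, tn = 89, fn = 12)
metrics_from_confusion <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  tp <- as.numeric(tp); fp <- as.numeric(fp)
  tn <- as.numeric(tn); fn <- as.numeric(fn)
  sn <- if (tp + fn > 0) tp / (tp + fn) else NaN
  sp <- if (tn + fp > 0) tn / (tn + fp) else NaN
  acc <- (tp + tn) / (tp + fn + fp + tn)
  den2 <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  undef <- den2 == 0
  mcc <- if (undef) 0 else (tp * tn - fp * fn) / sqrt(den2)
  list(Sn = sn, Sp = sp, Acc = acc, MCC = mcc, mcc_undefined = undef,
       TP = tp, FP = fp, TN = tn, FN = fn)
}

#' ROC curve and AUC
#'
#' Builds the ROC curve by sweeping the decision threshold over all distinct
#' scores (tied scores move as one block) and integrates by the trapezoidal
#' rule; also computes the equivalent Mann-Whitney statistic (concordant
#' pairs, ties counted 1/2). The two values agree by construction and both
#' are returned.
#'
#' @param scores Per-sample scores (e.g. PSBP probabilities); higher means
#'   more positive.
#' @param labels Labels; positive class `"PSBP"` (or TRUE / 1). Both classes
#'   must be present.
#' @return List with `auc` (trapezoidal), `mann_whitney`, and `roc`
#'   (`data.frame` of fpr, tpr, threshold).
#' @export
roc_auc <- function(scores, labels) {
  pos <- is_positive(labels)
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0L || nn == 0L) stop("ROC needs both classes", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  # collapse tied scores into single threshold steps
  grp <- cumsum(!duplicated(s))
  tp_step <- tapply(p, grp, sum)
  fp_step <- tapply(!p, grp, sum)
  tpr <- c(0, cumsum(tp_step) / np)
  fpr <- c(0, cumsum(fp_step) / nn)
  thr <- c(Inf, s[!duplicated(s)])
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  r <- rank(scores)  # average ranks handle ties as 1/2
  mw <- (sum(r[pos]) - np * (np + 1) / 2) / (np * nn)
  list(auc = auc, mann_whitney = mw,
       roc = data.frame(fpr = fpr, tpr = tpr, threshold = thr))
}

#' Cross-validated evaluation of an RBF-SVM on a feature matrix
#'
#' Splits the data into stratified k folds; for each fold trains a
#' probability SVM on the remaining folds and scores the held-out samples.
#' Headline Sn/Sp/Acc/MCC are fold averages; the AUC is computed on the
#' pooled held-out scores (a k-point averaged ROC is ill-defined at small n).
#' The pooled confusion matrix and per-fold metrics are also returned.
#'
#' @param X Feature matrix.
#' @param y Labels; positive class `"PSBP"`.
#' @param config An [svm_config()]; if `NULL`, a [grid_search()] is run first
#'   on the full data with the same folds.
#' @param k Number of folds.
#' @param seed Seed for the fold split and fold-model calibration.
#' @param threshold Decision threshold on the PSBP probability.
#' @return A `metrics_report`: list with `Sn`, `Sp`, `Acc`, `MCC`
#'   (fold-averaged), `AUC` (pooled), `acc_pooled`, `confusion` (pooled),
#'   `per_fold`, `config`, `scores` (pooled held-out probabilities in input
#'   order), `k`, `seed`.
#' @export
cross_validate <- function(X, y, config = NULL, k = 5, seed = 1,
                           threshold = 0.5) {
  y <- as_label_factor(y)
  folds <- kfold_split(y, k = k, seed = seed)
  if (is.null(config)) config <- grid_search(X, y, folds = folds)
  n <- nrow(X)
  prob <- rep(NA_real_, n)
  per_fold <- vector("list", length(folds))
  for (f in seq_along(folds)) {
    test_idx <- folds[[f]]
    tr <- setdiff(seq_len(n), test_idx)
    model <- train_model(X[tr, , drop = FALSE], y[tr], config,
                         features = colnames(X), seed = seed)
    prob[test_idx] <- model_probabilities(model, X[test_idx, , drop = FALSE])
    pred_pos <- prob[test_idx] >= threshold
    truth_pos <- y[test_idx] == "PSBP"
    m <- metrics_from_confusion(tp = sum(pred_pos & truth_pos),
                                fp = sum(pred_pos & !truth_pos),
                                tn = sum(!pred_pos & !truth_pos),
                                fn = sum(!pred_pos & truth_pos))
    per_fold[[f]] <- m
  }
  pooled_pred <- prob >= threshold
  truth <- y == "PSBP"
  pooled <- metrics_from_confusion(tp = sum(pooled_pred & truth),
                                   fp = sum(pooled_pred & !truth),
                                   tn = sum(!pooled_pred & !truth),
                                   fn = sum(!pooled_pred & truth))
  fold_mean <- function(field) mean(vapply(per_fold, `[[`, numeric(1), field))
  roc <- roc_auc(prob, truth)
  structure(list(Sn = fold_mean("Sn"), Sp = fold_mean("Sp"),
                 Acc = fold_mean("Acc"), MCC = fold_mean("MCC"),
                 AUC = roc$auc, acc_pooled = pooled$Acc,
                 confusion = pooled, per_fold = per_fold, roc = roc$roc,
                 scores = prob, config = config, k = k, seed = seed),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "%d-fold CV: Sn %.4f  Sp %.4f  Acc %.4f  MCC %.4f  AUC %.4f (pooled)\n",
    x$k, x$Sn, x$Sp, x$Acc, x$MCC, x$AUC))
  invisible(x)
}

#' Serialize a metrics report as JSON
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    list(Sn = report$Sn, Sp = report$Sp, Acc = report$Acc, MCC = report$MCC,
         AUC = report$AUC, acc_pooled = report$acc_pooled,
         confusion = report$confusion[c("TP", "FP", "TN", "FN")],
         per_fold = lapply(report$per_fold, function(m)
           m[c("Sn", "Sp", "Acc", "MCC", "TP", "FP", "TN", "FN")]),
         cost = report$config$cost, gamma = report$config$gamma,
         k = report$k, seed = report$seed),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write ROC points as a two-column TSV (fpr, tpr)
#' @param report A `metrics_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_roc_points <- function(report, path) {
  utils::write.table(report$roc[, c("fpr", "tpr")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
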