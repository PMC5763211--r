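#' @importFrom e1071 svm
NULL

# Normalize labels to a logical "is positive class" vector.
# Positive class is "PSBP" (or TRUE / 1); anything else is negative.
is_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  as.character(labels) %in% c("PSBP", "TRUE", "1")
}

as_label_factor <- function(labels) {
  factor(ifelse(is_positive(labels), "PSBP", "non-PSBP"),
         levels = c("non-PSBP", "PSBP"))
}

#' RBF-SVM configuration
#'
#' @param cost Error/cost parameter C (> 0).
#' @param gamma RBF kernel width parameter (> 0).
#' @param probability Fit Platt-style probability estimates (default TRUE,
#'   mirroring LIBSVM's `-b 1`).
#' @return An `svm_config` list.
#' @export
svm_config <- function(cost, gamma, probability = TRUE) {
  stopifnot(is.numeric(cost), cost > 0, is.numeric(gamma), gamma > 0)
  structure(list(cost = cost, gamma = gamma, probability = probability),
            class = "svm_config")
}

#' Canonical log2 grids for the (cost, gamma) search
#'
#' The canonical LIBSVM grid: cost over 2^-5, 2^-3, ..., 2^15 and gamma over
#' 2^-15, 2^-13, ..., 2^3.
#' @name svm_grids
#' @return Numeric vector of grid values.
#' @export
default_cost_grid <- function() 2^seq(-5, 15, by = 2)

#' @rdname svm_grids
#' @export
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

# Mean fold accuracy of an RBF-SVM at fixed (cost, gamma) over given folds.
# Class-prediction accuracy only (no probability model): used by the grid
# search and the forward-selection sweep where only accuracy matters.
fold_accuracy <- function(X, y, folds, cost, gamma) {
  y <- as_label_factor(y)
  accs <- vapply(folds, function(test_idx) {
    tr <- setdiff(seq_len(nrow(X)), test_idx)
    if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE)
    pred <- stats::predict(fit, X[test_idx, , drop = FALSE])
    mean(pred == y[test_idx])
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

# Mean fold accuracy through the probability pathway (Platt-calibrated
# PSBP probability thresholded at 0.5) — the prediction mode the final
# models use. Used to resolve grid-search ties, where the cheap
# class-prediction score cannot distinguish a well-calibrated model from a
# degenerate low-cost one whose probability model is unusable.
fold_accuracy_prob <- function(X, y, folds, cost, gamma, seed = 1) {
  y <- as_label_factor(y)
  accs <- vapply(folds, function(test_idx) {
    tr <- setdiff(seq_len(nrow(X)), test_idx)
    if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
    set.seed(seed)
    fit <- e1071::svm(X[tr, , drop = FALSE], y[tr], kernel = "radial",
                      cost = cost, gamma = gamma, scale = FALSE,
                      probability = TRUE)
    pred <- stats::predict(fit, X[test_idx, , drop = FALSE], probability = TRUE)
    prob <- attr(pred, "probabilities")[, "PSBP"]
    mean((prob >= 0.5) == (y[test_idx] == "PSBP"))
  }, numeric(1))
  mean(accs, na.rm = TRUE)
}

#' Grid search for the RBF-SVM (cost, gamma) pair
#'
#' Exhaustive search over the canonical log2 grids, scoring each pair by
#' stratified k-fold cross-validated accuracy on the given data. Pairs tied
#' at the maximum are re-scored through the probability pathway (Platt
#' probability thresholded at 0.5, the mode the final models are trained
#' in), which weeds out degenerate low-cost configurations whose class
#' predictions look fine but whose probability model is unusable; remaining
#' ties are broken by smaller cost, then smaller gamma (preferring smoother
#' models).
#'
#' @param X Feature matrix (samples x features).
#' @param y Labels; positive class `"PSBP"`.
#' @param k Number of folds (default 5).
#' @param seed Seed for the fold split.
#' @param cost_grid,gamma_grid Candidate values.
#' @param folds Optional pre-computed fold list (overrides `k`/`seed`).
#' @return An `svm_config` with an extra `cv_accuracy` element.
#' @export
grid_search <- function(X, y, k = 5, seed = 1,
                        cost_grid = default_cost_grid(),
                        gamma_grid = default_gamma_grid(),
                        folds = NULL) {
  pos <- is_positive(y)
  if (all(pos) || all(!pos)) stop("grid search needs both classes", call. = FALSE)
  if (is.null(folds)) folds <- kfold_split(y, k = k, seed = seed)
  grid <- expand.grid(gamma = gamma_grid, cost = cost_grid)  # cost-major order
  grid <- grid[order(grid$cost, grid$gamma), ]
  acc <- vapply(seq_len(nrow(grid)), function(i) {
    fold_accuracy(X, y, folds, grid$cost[i], grid$gamma[i])
  }, numeric(1))
  tied <- which(acc == max(acc))
  if (length(tied) > 1L) {
    pacc <- vapply(tied, function(i) {
      fold_accuracy_prob(X, y, folds, grid$cost[i], grid$gamma[i], seed = seed)
    }, numeric(1))
    best <- tied[which.max(pacc)]  # first max: smallest cost, then gamma
  } else {
    best <- tied
  }
  cfg <- svm_config(grid$cost[best], grid$gamma[best])
  cfg$cv_accuracy <- acc[best]
  cfg
}

#' Train an RBF-SVM on a feature matrix
#'
#' Fits a radial-kernel SVM with probability estimation (Platt calibration,
#' LIBSVM `-b 1`). Features are composition fractions already in \[0, 1\] and
#' are not rescaled. The calibration's internal randomness is pinned by
#' `seed`, recorded in the model metadata.
#'
#' @param X Feature matrix with feature-name column names.
#' @param y Labels; positive class `"PSBP"`; both classes required.
#' @param config An [svm_config()].
#' @param features Feature names (defaults to `colnames(X)`); must index into
#'   [feature_names()].
#' @param seed Calibration seed.
#' @return A `psbp_model`.
#' @export
train_model <- function(X, y, config, features = colnames(X), seed = 1) {
  stopifnot(inherits(config, "svm_config"))
  y <- as_label_factor(y)
  if (nlevels(droplevels(y)) < 2L) stop("training needs both classes", call. = FALSE)
  if (is.null(features) || length(features) != ncol(X)) {
    stop("feature names must match the matrix dimensionality", call. = FALSE)
  }
  if (any(!features %in% feature_names())) {
    stop("unknown feature names in model definition", call. = FALSE)
  }
  set.seed(seed)
  fit <- e1071::svm(X, y, kernel = "radial", cost = config$cost,
                    gamma = config$gamma, scale = FALSE,
                    probability = config$probability)
  structure(list(svm = fit, config = config, features = features,
                 n_pos = sum(y == "PSBP"), n_neg = sum(y == "non-PSBP"),
                 seed = seed,
                 toolkit = paste0("psbp ", as.character(utils::packageVersion("psbp")))),
            class = "psbp_model")
}

#' @export
print.psbp_model <- function(x, ...) {
  cat(sprintf("psbp RBF-SVM: %d features, cost=%g gamma=%g, trained on %d+/%d-\n",
              length(x$features), x$config$cost, x$config$gamma,
              x$n_pos, x$n_neg))
  invisible(x)
}

# PSBP-class probabilities for rows of X under a trained model.
model_probabilities <- function(model, X) {
  pred <- stats::predict(model$svm, X, probability = TRUE)
  attr(pred, "probabilities")[, "PSBP"]
}

#' Predict polystyrene binding for peptides
#'
#' Encodes each peptide with the model's feature subset and returns the PSBP
#' class probability; a peptide is labeled `"PSBP"` iff its probability is at
#' least `threshold` (default 0.5). Invalid or too-short peptides get a
#' per-row error note; the rest are still processed.
#'
#' @param model A `psbp_model`.
#' @param pep Peptide set (`data.frame` with id/sequence) or character vector
#'   of sequences.
#' @param threshold Decision threshold on the PSBP probability.
#' @return `data.frame` with columns id, sequence, label, probability, note.
#' @export
predict_peptides <- function(model, pep, threshold = 0.5) {
  stopifnot(inherits(model, "psbp_model"))
  if (is.character(pep)) {
    pep <- data.frame(id = paste0("seq", seq_along(pep)),
                      sequence = toupper(pep), stringsAsFactors = FALSE)
  }
  needs_dpc <- any(nchar(model$features) == 2L)
  n <- nrow(pep)
  note <- character(n); ok <- logical(n)
  for (i in seq_len(n)) {
    v <- validate_sequence(pep$sequence[i])
    if (!v$ok) {
      note[i] <- v$reason
    } else if (needs_dpc && nchar(pep$sequence[i]) < 2L) {
      note[i] <- "DPC undefined for length-1 peptide"
    } else {
      ok[i] <- TRUE
    }
  }
  prob <- rep(NA_real_, n)
  if (any(ok)) {
    X <- t(vapply(toupper(pep$sequence[ok]),
                  function(s) encode(s, model$features),
                  numeric(length(model$features))))
    colnames(X) <- model$features
    rownames(X) <- NULL
    prob[ok] <- model_probabilities(model, X)
  }
  label <- ifelse(is.na(prob), NA_character_,
                  ifelse(prob >= threshold, "PSBP", "non-PSBP"))
  data.frame(id = pep$id, sequence = toupper(pep$sequence), label = label,
             probability = prob, note = note, stringsAsFactors = FALSE)
}

#' Save / load a trained model
#'
#' The model file is a self-describing serialized archive carrying the SVM
#' state, the feature-name list, the (cost, gamma) configuration and training
#' metadata. Loading verifies the feature list against the stored SVM
#' dimensionality.
#'
#' @param model A `psbp_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "psbp_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop(sprintf("model file not found: %s", path), call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "psbp_model")) stop("not a psbp model file", call. = FALSE)
  if (length(model$features) != ncol(model$svm$SV)) {
    stop("corrupt model file: feature list does not match SVM dimensionality",
         call. = FALSE)
  }
  model
}
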