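#' Full training pipeline: encode, select, tune, cross-validate, fit
#'
#' Runs the complete modeling pipeline on a curated labeled dataset:
#' composition encoding of the chosen feature block, F-score ranking, forward
#' feature selection, a (cost, gamma) grid search on the selected subset,
#' stratified k-fold cross-validated evaluation, and a final probability SVM
#' trained on all data with the selected subset and tuned configuration.
#'
#' @param dataset A `labeled_dataset` (see [assemble_dataset()] /
#'   [generate_dataset()]).
#' @param block Feature block: `"dpc"` (400 dipeptide features, the headline
#'   model), `"aac"` (20 residue features) or `"both"` (420).
#' @param k Cross-validation folds.
#' @param seed Seed controlling fold splits and SVM probability calibration.
#' @param retune Re-run the grid search at every prefix size during forward
#'   selection (slow; default FALSE holds one full-block configuration fixed).
#' @param select Run forward selection (default TRUE); FALSE evaluates the
#'   full block.
#' @param threshold Decision threshold on the PSBP probability.
#' @return A `psbp_pipeline`: list with `block`, `ranking`, `subset`,
#'   `config`, `metrics` (a `metrics_report`), and `model` (a `psbp_model`
#'   trained on all data).
#' @export
#' @examples
#' \donttest{
#' ds <- generate_dataset(synthetic_spec(n_per_class = 30, seed = 7))
#' fit <- run_pipeline(ds, block = "aac", seed = 7)
#' fit$metrics
#' }
run_pipeline <- function(dataset, block = c("dpc", "aac", "both"),
                         k = 5, seed = 1, retune = FALSE, select = TRUE,
                         threshold = 0.5) {
  block <- match.arg(block)
  xy <- dataset_xy(dataset)
  X <- feature_matrix(xy$sequences, block = block)
  y <- xy$labels
  ranking <- fscore(X, y)
  if (select) {
    subset <- forward_select(X, y, ranking, k = k, seed = seed, retune = retune)
  } else {
    subset <- structure(list(indices = seq_len(ncol(X)),
                             features = colnames(X),
                             achieved_accuracy = NA_real_,
                             config = NULL, seed = seed,
                             curve = NULL),
                        class = "feature_subset")
  }
  Xsel <- X[, subset$indices, drop = FALSE]
  config <- grid_search(Xsel, y, k = k, seed = seed)
  metrics <- cross_validate(Xsel, y, config = config, k = k, seed = seed,
                            threshold = threshold)
  model <- train_model(Xsel, y, config, features = subset$features, seed = seed)
  structure(list(block = block, ranking = ranking, subset = subset,
                 config = config, metrics = metrics, model = model,
                 k = k, seed = seed),
            class = "psbp_pipeline")
}

#' @export
print.psbp_pipeline <- function(x, ...) {
  cat(sprintf("psbp pipeline (%s block): %d selected features\n",
              toupper(x$block), length(x$subset$indices)))
  print(x$metrics)
  invisible(x)
}
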