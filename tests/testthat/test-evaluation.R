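test_that("stratified k-fold splits cover all indices with near-equal sizes", {
  y10 <- rep(c("PSBP", "non-PSBP"), 5)
  f <- kfold_split(y10, k = 5, seed = 1)
  expect_equal(sort(unlist(f)), 1:10)
  expect_true(all(lengths(f) == 2L))
  for (g in f) expect_equal(sum(y10[g] == "PSBP"), 1L)

  y208 <- rep(c("PSBP", "non-PSBP"), each = 104)
  f208 <- kfold_split(y208, k = 5, seed = 2)
  expect_equal(sort(lengths(f208), decreasing = TRUE), c(42, 42, 42, 41, 41))
  expect_equal(sort(unlist(f208)), 1:208)
  # class balance within each fold differs by at most 1
  for (g in f208) {
    expect_lte(abs(sum(y208[g] == "PSBP") - sum(y208[g] == "non-PSBP")), 1L)
  }
  expect_identical(kfold_split(y208, 5, seed = 7), kfold_split(y208, 5, seed = 7))
  expect_error(kfold_split(rep("PSBP", 3), k = 5), "at least")
})

test_that("confusion-matrix metrics match the defining arithmetic and edge cases", {
  perfect <- metrics_from_confusion(10, 0, 10, 0)
  expect_equal(perfect[c("Sn", "Sp", "Acc", "MCC")],
               list(Sn = 1, Sp = 1, Acc = 1, MCC = 1))
  inverted <- metrics_from_confusion(0, 10, 0, 10)
  expect_equal(inverted$Acc, 0)
  expect_equal(inverted$MCC, -1)
  undef <- metrics_from_confusion(0, 0, 10, 10)  # nothing predicted positive... TP+FP=0
  expect_equal(undef$MCC, 0)
  expect_true(undef$mcc_undefined)
})

test_that("metrics agree with a brute-force per-sample tally on random predictions", {
  set.seed(14)
  for (rep in 1:10) {
    n <- 50
    truth <- sample(c(TRUE, FALSE), n, replace = TRUE)
    pred <- sample(c(TRUE, FALSE), n, replace = TRUE)
    m <- metrics_from_confusion(tp = sum(pred & truth), fp = sum(pred & !truth),
                                tn = sum(!pred & !truth), fn = sum(!pred & truth))
    expect_equal(m$Acc, mean(pred == truth))
    if (any(truth)) expect_equal(m$Sn, mean(pred[truth]))
    if (any(!truth)) expect_equal(m$Sp, mean(!pred[!truth]))
    expect_gte(m$MCC, -1); expect_lte(m$MCC, 1)
  }
})

test_that("MCC is invariant under a simultaneous label and prediction swap", {
  m1 <- metrics_from_confusion(tp = 30, fp = 9, tn = 22, fn = 4)
  m2 <- metrics_from_confusion(tp = 22, fp = 4, tn = 30, fn = 9)  # swapped roles
  expect_equal(m1$MCC, m2$MCC)
  expect_equal(m1$Acc, m2$Acc)
  expect_equal(m1$Sn, m2$Sp)
  expect_equal(m1$Sp, m2$Sn)
})

test_that("trapezoidal AUC equals Mann-Whitney pair counting, including ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.3, 0.2), c(TRUE, TRUE, FALSE, FALSE))$auc, 1.0)
  expect_equal(roc_auc(rep(0.5, 6), rep(c(TRUE, FALSE), 3))$auc, 0.5)
  # hand-enumerated: 1 concordant of 2 positive-negative pairs
  expect_equal(roc_auc(c(0.9, 0.7, 0.4), c(TRUE, FALSE, TRUE))$auc, 0.5)
  set.seed(15)
  for (rep in 1:20) {
    n <- sample(6:40, 1)
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- round(stats::runif(n), 1)  # coarse rounding forces ties
    r <- roc_auc(scores, labels)
    expect_equal(r$auc, r$mann_whitney)
    expect_equal(r$auc, auc_pairs(scores, labels))
    expect_equal(r$roc$fpr[1], 0); expect_equal(r$roc$tpr[nrow(r$roc)], 1)
  }
  expect_error(roc_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(16)
  for (rep in 1:5) {
    labels <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 30, replace = TRUE))
    scores <- round(stats::runif(32), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(roc_auc(scores, labels)$auc, ref)
  }
})

test_that("cross-validation on separable synthetic data is perfect and reproducible", {
  ds <- generate_dataset(synthetic_spec(n_per_class = 20, seed = 77,
                                        aromatic_enrichment = 8,
                                        motif_fraction = 1))
  xy <- dataset_xy(ds)
  X <- feature_matrix(xy$sequences, "aac")
  r <- cross_validate(X, xy$labels, k = 5, seed = 1)
  expect_gte(r$Acc, 0.95)
  expect_gte(r$AUC, 0.99)
  r2 <- cross_validate(X, xy$labels, config = r$config, k = 5, seed = 1)
  expect_equal(r$scores, r2$scores)
  expect_equal(r$Acc, r2$Acc)
  # fold-averaged and pooled accuracy agree closely
  expect_lt(abs(r$Acc - r$acc_pooled), 1 / min(lengths(kfold_split(xy$labels, 5, 1))))
  # report serialization round-trips headline numbers
  tf <- withr::local_tempfile(fileext = ".json")
  write_metrics_report(r, tf)
  j <- jsonlite::read_json(tf, simplifyVector = TRUE)
  expect_equal(j$Acc, r$Acc)
  expect_equal(j$AUC, r$AUC)
  tr <- withr::local_tempfile(fileext = ".tsv")
  write_roc_points(r, tr)
  roc <- utils::read.delim(tr)
  expect_equal(names(roc), c("fpr", "tpr"))
})
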