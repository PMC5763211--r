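# Independent brute-force F-score: explicit loops over the definition sums.
fscore_oracle <- function(x, pos) {
  xp <- x[pos]; xn <- x[!pos]
  mp <- sum(xp) / length(xp); mn <- sum(xn) / length(xn)
  m <- sum(x) / length(x)
  sp2 <- sum((xp - mp)^2) / (length(xp) - 1)
  sn2 <- sum((xn - mn)^2) / (length(xn) - 1)
  num <- (mp - m)^2 + (mn - m)^2
  den <- sp2 + sn2
  if (den == 0) { if (num == 0) 0 else Inf } else num / den
}

test_that("F-score matches a brute-force oracle and handles degenerate features", {
  X <- cbind(const = rep(0.3, 4),
             perfect = c(1, 1, -1, -1),
             noisy = c(0.6, 0.8, 0.1, 0.3))
  y <- c("PSBP", "PSBP", "non-PSBP", "non-PSBP")
  r <- fscore(X, y)
  expect_equal(unname(r$scores["const"]), 0)
  expect_equal(unname(r$scores["perfect"]), Inf)
  expect_equal(unname(r$scores["noisy"]),
               fscore_oracle(X[, "noisy"], c(TRUE, TRUE, FALSE, FALSE)))
  # perfect separator ranked first; constant last
  expect_equal(r$order[1], 2L)
  expect_equal(r$order[3], 1L)

  set.seed(7)
  Xr <- matrix(stats::rnorm(40 * 6), 40, 6)
  yr <- rep(c("PSBP", "non-PSBP"), each = 20)
  rr <- fscore(Xr, yr)
  for (j in 1:6) {
    expect_equal(unname(rr$scores[j]), fscore_oracle(Xr[, j], yr == "PSBP"))
  }
  expect_true(all(sort(rr$order) == 1:6))  # order is a permutation
  expect_true(all(rr$scores >= 0))
})

test_that("F-score requires two samples per class and breaks ties by index", {
  X <- matrix(1:6, ncol = 2)
  expect_error(fscore(X, c("PSBP", "non-PSBP", "non-PSBP")), "at least 2")
  # duplicated column: identical scores, original index ranked first
  Xd <- cbind(a = c(1, 2, 5, 6), b = c(1, 2, 5, 6))
  rd <- fscore(Xd, c("non-PSBP", "non-PSBP", "PSBP", "PSBP"))
  expect_equal(rd$order, c(1L, 2L))
})

test_that("forward selection finds a single perfect feature and stops there", {
  set.seed(42)
  n <- 40
  y <- rep(c("PSBP", "non-PSBP"), each = n / 2)
  X <- cbind(signal = ifelse(y == "PSBP", 1, 0),
             matrix(stats::rnorm(n * 5), n, 5))
  colnames(X) <- c("signal", paste0("noise", 1:5))
  sel <- forward_select(X, y, seed = 3)
  expect_equal(sel$features, "signal")
  expect_equal(sel$achieved_accuracy, 1.0)
  # the achieved accuracy is the maximum of the retained curve
  expect_equal(sel$achieved_accuracy, max(sel$curve$accuracy))
  expect_equal(nrow(sel$curve), ncol(X))
})

test_that("forward selection needs both of two complementary features", {
  set.seed(10)
  n <- 60
  y <- rep(c("PSBP", "non-PSBP"), each = n / 2)
  # two additive half-signals: either alone overlaps, both separate fully
  f1 <- ifelse(y == "PSBP", 0.6, 0) + stats::rnorm(n, 0, 0.25)
  f2 <- ifelse(y == "PSBP", 0.6, 0) + stats::rnorm(n, 0, 0.25)
  X <- cbind(f1 = f1, f2 = f2, noise = stats::rnorm(n, 0, 1))
  sel <- forward_select(X, y, seed = 4)
  acc1 <- sel$curve$accuracy[1]
  acc2 <- sel$curve$accuracy[2]
  expect_gt(acc2, acc1)            # the second informative feature helps
  expect_true(all(c("f1", "f2") %in% colnames(X)[sel$indices[1:2]]))
})

test_that("forward selection is reproducible for a fixed seed", {
  set.seed(5)
  n <- 30
  y <- rep(c("PSBP", "non-PSBP"), each = n / 2)
  X <- cbind(s = ifelse(y == "PSBP", 1, 0) + stats::rnorm(n, 0, 0.4),
             n1 = stats::rnorm(n), n2 = stats::rnorm(n))
  a <- forward_select(X, y, seed = 8)
  b <- forward_select(X, y, seed = 8)
  expect_identical(a$indices, b$indices)
  expect_identical(a$achieved_accuracy, b$achieved_accuracy)
  expect_identical(a$curve, b$curve)
})

test_that("feature subsets persist as plain text plus JSON sidecar", {
  set.seed(6)
  n <- 20
  y <- rep(c("PSBP", "non-PSBP"), each = n / 2)
  X <- cbind(WG = ifelse(y == "PSBP", 1, 0), WF = stats::rnorm(n))
  sel <- forward_select(X, y, seed = 2)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_feature_subset(sel, tf)
  expect_equal(readLines(tf), sel$features)
  side <- jsonlite::read_json(paste0(tf, ".json"), simplifyVector = TRUE)
  expect_equal(side$achieved_accuracy, sel$achieved_accuracy)
  expect_equal(side$curve$accuracy, sel$curve$accuracy)
})
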