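# Shared fixtures and an independent brute-force oracle or two.

random_peptides <- function(n, min_len = 2, max_len = 15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n), function(i) {
    L <- sample(min_len:max_len, 1)
    paste(sample(amino_acids(), L, replace = TRUE), collapse = "")
  }, character(1))
}

# Two well-separated Gaussian blobs in 2 features; returns list(X, y).
separable_blobs <- function(n_per_class = 20, gap = 6, seed = 1) {
  set.seed(seed)
  X <- rbind(matrix(stats::rnorm(n_per_class * 2), ncol = 2),
             matrix(stats::rnorm(n_per_class * 2) + gap, ncol = 2))
  colnames(X) <- c("A", "C")  # any valid feature names
  y <- rep(c("non-PSBP", "PSBP"), each = n_per_class)
  list(X = X, y = y)
}

# Brute-force AUC oracle: exhaustive concordant-pair enumeration, ties 1/2.
auc_pairs <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  tot <- 0
  for (i in pos) for (j in neg) {
    tot <- tot + if (scores[i] > scores[j]) 1 else if (scores[i] == scores[j]) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# The shipped synthetic stand-in training corpus (104+104), curated once.
.cache <- new.env(parent = emptyenv())

training_dataset <- function() {
  if (is.null(.cache$ds)) {
    pos <- read_peptides(system.file("extdata", "synthetic_training_pos.fasta",
                                     package = "psbp"))
    neg <- read_peptides(system.file("extdata", "synthetic_training_neg.fasta",
                                     package = "psbp"))
    .cache$ds <- assemble_dataset(pos, neg, trim_cysteines = FALSE)
  }
  .cache$ds
}

# Ten replicate DPC pipeline runs (seeds 1..10) on the training corpus;
# computed lazily once and shared across acceptance checks.
dpc_runs <- function() {
  if (is.null(.cache$dpc)) {
    ds <- training_dataset()
    .cache$dpc <- lapply(1:10, function(s) run_pipeline(ds, "dpc", seed = s))
  }
  .cache$dpc
}

aac_runs <- function() {
  if (is.null(.cache$aac)) {
    ds <- training_dataset()
    .cache$aac <- lapply(1:10, function(s) run_pipeline(ds, "aac", seed = s))
  }
  .cache$aac
}
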