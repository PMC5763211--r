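test_that("generalized Jaccard similarity matches hand-counted multisets", {
  expect_equal(generalized_jaccard("WWW", "WWW"), 1.0)
  expect_equal(generalized_jaccard("AAA", "CCC"), 0.0)
  # counts: min-sum = 2 (two shared A), max-sum = 4 (3 A + 1 W)
  expect_equal(generalized_jaccard("AAW", "AAA"), 0.5)
  # same residue multiset, different order
  expect_equal(generalized_jaccard("WHW", "HWW"), 1.0)
  expect_error(generalized_jaccard("", "AAA"), "empty")
  expect_error(generalized_jaccard("AXA", "AAA"), "invalid residue")
})

test_that("generalized Jaccard is symmetric and reflexive on random pairs", {
  seqs <- random_peptides(20, seed = 11)
  for (i in 1:10) {
    a <- seqs[2 * i - 1]; b <- seqs[2 * i]
    expect_equal(generalized_jaccard(a, b), generalized_jaccard(b, a))
    expect_equal(generalized_jaccard(a, a), 1.0)
    s <- generalized_jaccard(a, b)
    expect_gte(s, 0); expect_lte(s, 1)
  }
})

test_that("exact-duplicate removal drops cross-set matches and keeps first of self-dups", {
  neg <- peptides(c("WHW", "ACD"))
  pos <- peptides("WHW")
  expect_equal(remove_exact_duplicates(neg, pos)$sequence, "ACD")
  neg2 <- peptides(c("ACD", "ACD"))
  expect_equal(remove_exact_duplicates(neg2, peptides(character(0), character(0)))$sequence, "ACD")
  expect_equal(nrow(remove_exact_duplicates(neg[0, ], pos)), 0L)
})

test_that("similarity filter is strict and monotone in the threshold", {
  neg <- peptides("AAW"); pos <- peptides("AAA")
  expect_equal(filter_by_similarity(neg, pos, 0.90)$sequence, "AAW")
  neg2 <- peptides("WHW"); pos2 <- peptides("HWW")
  expect_equal(nrow(filter_by_similarity(neg2, pos2, 0.90)), 0L)
  expect_equal(filter_by_similarity(neg2, pos2, 1.01)$sequence, "WHW")
  # monotonicity: result at t1 < t2 is a subset of result at t2
  negs <- peptides(random_peptides(30, seed = 5))
  poss <- peptides(random_peptides(10, seed = 6))
  for (pair in list(c(0.3, 0.6), c(0.6, 0.9), c(0.5, 1.0))) {
    r1 <- filter_by_similarity(negs, poss, pair[1])$sequence
    r2 <- filter_by_similarity(negs, poss, pair[2])$sequence
    expect_true(all(r1 %in% r2))
  }
})

test_that("assemble_dataset applies trim, validation, dedup and similarity in order", {
  ds <- assemble_dataset(c("CWHWC", "FHAAW"),
                         c("WHW", "ACDACD", "ACDACD", "GGSGGS", "AXDF"))
  # positive cysteine trimming happened
  expect_true("WHW" %in% ds$positives$sequence)
  # negative identical to (trimmed) positive dropped, self-dup dropped, invalid dropped
  expect_equal(sort(ds$negatives$sequence), c("ACDACD", "GGSGGS"))
  expect_true(any(ds$log$reason == "duplicate-of-positive"))
  expect_true(any(ds$log$reason == "duplicate-within-negatives"))
  expect_true(any(grepl("invalid residue", ds$log$reason)))
  expect_true(any(ds$log$reason == "flanking-cysteines"))
  # dataset invariants hold by construction
  expect_false(any(ds$negatives$sequence %in% ds$positives$sequence))
  for (n in ds$negatives$sequence) {
    for (p in ds$positives$sequence) {
      expect_lt(generalized_jaccard(n, p), 0.90)
    }
  }
})

test_that("assemble_dataset preserves all-valid disjoint input and errors on empty classes", {
  pos <- random_peptides(8, min_len = 6, max_len = 8, seed = 21)
  neg <- vapply(random_peptides(8, min_len = 6, max_len = 8, seed = 22),
                function(s) chartr("WYF", "GGG", s), character(1))
  ds <- assemble_dataset(pos, neg, threshold = 1.01, trim_cysteines = FALSE)
  expect_equal(ds$positives$sequence, toupper(pos))
  expect_equal(ds$negatives$sequence, unname(toupper(neg)))
  expect_error(assemble_dataset(c("WHW"), c("WHW")), "no negatives")
})

test_that("curation log exports as tab-separated text", {
  ds <- assemble_dataset(c("CWHWC"), c("WHW", "ACDE"))
  tf <- withr::local_tempfile(fileext = ".tsv")
  write_curation_log(ds, tf)
  log <- utils::read.delim(tf)
  expect_true(all(c("sequence", "stage", "action", "reason") %in% names(log)))
  expect_gt(nrow(log), 0L)
})
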