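#' Generalized Jaccard similarity between two peptide sequences
#'
#' Multiset extension of the Jaccard index. With count vectors x, y over the
#' chosen representation, returns sum_i min(x_i, y_i) / sum_i max(x_i, y_i).
#' Symmetric; equals 1 iff the two sequences have identical count multisets.
#' The default representation is residue counts; an overlapping-dipeptide
#' count representation is available because the multiset generalization is
#' defined for any token set.
#'
#' @param a,b Valid, non-empty peptide sequences.
#' @param representation `"residue"` (default) or `"dipeptide"`.
#' @return Similarity in \[0, 1\].
#' @export
#' @examples
#' generalized_jaccard("AAW", "AAA")  # 0.5
generalized_jaccard <- function(a, b, representation = c("residue", "dipeptide")) {
  representation <- match.arg(representation)
  for (s in c(a, b)) {
    v <- validate_sequence(s)
    if (!v$ok) stop(v$reason, call. = FALSE)
  }
  count <- function(s) {
    if (representation == "residue") {
      toks <- strsplit(toupper(s), "", fixed = TRUE)[[1]]
      lv <- amino_acids()
    } else {
      if (nchar(s) < 2L) stop("dipeptide representation needs length >= 2", call. = FALSE)
      toks <- dipeptide_tokens(toupper(s))
      lv <- dipeptide_names()
    }
    tabulate(factor(toks, levels = lv), nbins = length(lv))
  }
  x <- count(a); y <- count(b)
  sum(pmin(x, y)) / sum(pmax(x, y))
}

#' Remove exact duplicates from a negative peptide set
#'
#' Drops any negative whose sequence exactly matches a positive sequence,
#' and within-negative exact duplicates (first occurrence kept).
#'
#' @param negatives,positives Peptide sets.
#' @return Filtered negative peptide set.
#' @export
remove_exact_duplicates <- function(negatives, positives) {
  keep <- !duplicated(negatives$sequence) &
    !(negatives$sequence %in% positives$sequence)
  negatives[keep, , drop = FALSE]
}

#' Filter negatives by Generalized Jaccard similarity to the positives
#'
#' Keeps only negatives whose similarity to EVERY positive is strictly below
#' `threshold` ("below 90%" read as strict inequality).
#'
#' @param negatives,positives Peptide sets.
#' @param threshold Similarity threshold in (0, 1\]; values > 1 disable the
#'   filter. Default 0.90.
#' @param representation Passed to [generalized_jaccard()].
#' @return Filtered negative peptide set.
#' @export
filter_by_similarity <- function(negatives, positives, threshold = 0.90,
                                 representation = c("residue", "dipeptide")) {
  representation <- match.arg(representation)
  if (nrow(negatives) == 0L || nrow(positives) == 0L) return(negatives)
  keep <- vapply(negatives$sequence, function(n) {
    all(vapply(positives$sequence, function(p) {
      generalized_jaccard(n, p, representation)
    }, numeric(1)) < threshold)
  }, logical(1))
  negatives[keep, , drop = FALSE]
}

#' Assemble a curated, labeled training dataset
#'
#' Applies the curation pipeline, in order: flanking-cysteine trimming
#' (circular-peptide rule) -> validation (invalid peptides dropped with a
#' logged reason) -> exact-duplicate removal (within each class, and
#' negatives matching a positive) -> Generalized Jaccard similarity filter
#' on the negatives. Positives are never filtered against negatives.
#'
#' @param raw_positives,raw_negatives Peptide sets (or character vectors of
#'   sequences).
#' @param threshold Similarity threshold for [filter_by_similarity()].
#' @param trim_cysteines Apply [trim_flanking_cysteines()] first (default
#'   TRUE; a prediction-time caller would not).
#' @param representation Passed to [generalized_jaccard()].
#' @return A `labeled_dataset`: list with `positives`, `negatives` (peptide
#'   sets) and `log` (`data.frame` of id, sequence, stage, action, reason).
#' @export
assemble_dataset <- function(raw_positives, raw_negatives, threshold = 0.90,
                             trim_cysteines = TRUE,
                             representation = c("residue", "dipeptide")) {
  representation <- match.arg(representation)
  as_pepset <- function(x, prefix) {
    if (is.character(x)) {
      data.frame(id = paste0(prefix, seq_along(x)),
                 sequence = toupper(x), stringsAsFactors = FALSE)
    } else {
      data.frame(id = as.character(x$id), sequence = toupper(x$sequence),
                 stringsAsFactors = FALSE)
    }
  }
  pos <- as_pepset(raw_positives, "pos")
  neg <- as_pepset(raw_negatives, "neg")
  log <- data.frame(id = character(0), sequence = character(0),
                    stage = character(0), action = character(0),
                    reason = character(0), stringsAsFactors = FALSE)
  note <- function(df, stage, action, reason) {
    if (nrow(df) == 0L) return(invisible())
    log <<- rbind(log, data.frame(id = df$id, sequence = df$sequence,
                                  stage = stage, action = action,
                                  reason = reason, stringsAsFactors = FALSE))
  }

  if (trim_cysteines) {
    for (nm in c("pos", "neg")) {
      df <- get(nm)
      trimmed <- trim_flanking_cysteines(df$sequence)
      changed <- trimmed != df$sequence
      note(df[changed, , drop = FALSE], "trim", "trimmed", "flanking-cysteines")
      df$sequence <- trimmed
      assign(nm, df)
    }
  }

  drop_invalid <- function(df) {
    ok <- logical(nrow(df)); why <- character(nrow(df))
    for (i in seq_len(nrow(df))) {
      v <- validate_sequence(df$sequence[i])
      ok[i] <- v$ok && nchar(df$sequence[i]) >= 2L
      why[i] <- if (!v$ok) v$reason else if (!ok[i]) "length < 2" else ""
    }
    bad <- df[!ok, , drop = FALSE]
    if (nrow(bad) > 0L) {
      note(cbind(bad), "validate", "dropped", why[!ok])
    }
    df[ok, , drop = FALSE]
  }
  pos <- drop_invalid(pos)
  neg <- drop_invalid(neg)

  dup_pos <- pos[duplicated(pos$sequence), , drop = FALSE]
  note(dup_pos, "dedup", "dropped", "duplicate-within-positives")
  pos <- pos[!duplicated(pos$sequence), , drop = FALSE]

  dup_self <- neg[duplicated(neg$sequence), , drop = FALSE]
  note(dup_self, "dedup", "dropped", "duplicate-within-negatives")
  dup_cross <- neg[!duplicated(neg$sequence) &
                     neg$sequence %in% pos$sequence, , drop = FALSE]
  note(dup_cross, "dedup", "dropped", "duplicate-of-positive")
  neg <- remove_exact_duplicates(neg, pos)

  kept <- filter_by_similarity(neg, pos, threshold, representation)
  filtered <- neg[!neg$sequence %in% kept$sequence, , drop = FALSE]
  note(filtered, "similarity", "dropped",
       sprintf("generalized-jaccard >= %.2f to a positive", threshold))
  neg <- kept

  if (nrow(pos) == 0L) stop("no positives survived curation", call. = FALSE)
  if (nrow(neg) == 0L) stop("no negatives survived curation", call. = FALSE)
  structure(list(positives = pos, negatives = neg, log = log,
                 threshold = threshold, representation = representation),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat(sprintf("labeled_dataset: %d positives, %d negatives (similarity < %.2f)\n",
              nrow(x$positives), nrow(x$negatives), x$threshold))
  if (nrow(x$log) > 0L) {
    cat(sprintf("  curation log: %d entries\n", nrow(x$log)))
  }
  invisible(x)
}

#' Write the curation log as a tab-separated file
#' @param dataset A `labeled_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curation_log <- function(dataset, path) {
  utils::write.table(dataset$log, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Labels and sequences of a labeled dataset, in modeling order
#'
#' Positives first, then negatives; labels are a factor with levels
#' `c("non-PSBP", "PSBP")` so that "PSBP" is the positive class.
#'
#' @param dataset A `labeled_dataset`.
#' @return List with `sequences` (character) and `labels` (factor).
#' @export
dataset_xy <- function(dataset) {
  seqs <- c(dataset$positives$sequence, dataset$negatives$sequence)
  labels <- factor(rep(c("PSBP", "non-PSBP"),
                       c(nrow(dataset$positives), nrow(dataset$negatives))),
                   levels = c("non-PSBP", "PSBP"))
  list(sequences = seqs, labels = labels)
}
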