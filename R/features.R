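#' Names of the 400 dipeptide features, row-major alphabetical order
#' @return Character vector ("AA", "AC", ..., "YY").
#' @export
dipeptide_names <- function() {
  aa <- amino_acids()
  as.vector(t(outer(aa, aa, paste0)))
}

#' Names of all 420 composition features
#'
#' Indices 1-20 are the amino-acid composition (AAC) block in alphabetical
#' residue order; indices 21-420 are the dipeptide composition (DPC) block in
#' row-major order (first residue x second residue, both alphabetical). This
#' layout is fixed: feature subsets and persisted models depend on it.
#'
#' @return Character vector of length 420.
#' @export
feature_names <- function() c(amino_acids(), dipeptide_names())

dipeptide_tokens <- function(sequence) {
  L <- nchar(sequence)
  substring(sequence, 1:(L - 1L), 2:L)
}

#' Amino-acid composition (AAC) of one peptide
#'
#' Component for residue r is count(r) / L; the 20 components sum to 1.
#'
#' @param sequence A valid peptide sequence (length >= 1).
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' aac("WHWSWG")["W"]  # 0.5
aac <- function(sequence) {
  v <- validate_sequence(sequence)
  if (!v$ok) stop(v$reason, call. = FALSE)
  s <- toupper(sequence)
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  counts <- tabulate(factor(chars, levels = amino_acids()), nbins = 20L)
  stats::setNames(counts / length(chars), amino_acids())
}

#' Dipeptide composition (DPC) of one peptide
#'
#' Overlapping windows at positions (1,2) ... (L-1, L), so the counts sum to
#' L - 1; component j is count(j) / (L - 1) and the 400 components sum to 1.
#'
#' @param sequence A valid peptide sequence of length >= 2.
#' @return Named numeric vector of length 400.
#' @export
#' @examples
#' dpc("WAW")[c("WA", "AW")]  # 0.5, 0.5
dpc <- function(sequence) {
  v <- validate_sequence(sequence)
  if (!v$ok) stop(v$reason, call. = FALSE)
  s <- toupper(sequence)
  if (nchar(s) < 2L) stop("DPC undefined for length-1 peptide", call. = FALSE)
  toks <- dipeptide_tokens(s)
  counts <- tabulate(factor(toks, levels = dipeptide_names()), nbins = 400L)
  stats::setNames(counts / length(toks), dipeptide_names())
}

#' Encode a peptide as a (possibly projected) composition vector
#'
#' Concatenates AAC and DPC (420 components) and, if `subset` is given,
#' projects onto those feature indices preserving index order.
#'
#' @param sequence A valid peptide sequence.
#' @param subset `NULL` for all 420 features, or an integer vector of
#'   1-based feature indices into [feature_names()] (or a character vector of
#'   feature names).
#' @return Named numeric vector.
#' @export
#' @examples
#' sum(encode("WAW"))  # 2: each block sums to 1
encode <- function(sequence, subset = NULL) {
  if (is.character(subset)) subset <- match(subset, feature_names())
  full_needed <- is.null(subset) || any(subset > 20L)
  a <- aac(sequence)
  if (full_needed) {
    vec <- c(a, dpc(sequence))
  } else {
    vec <- c(a, stats::setNames(numeric(400), dipeptide_names()))
  }
  if (is.null(subset)) return(vec)
  if (any(is.na(subset)) || any(subset < 1L) || any(subset > 420L)) {
    stop("feature subset indices must be in 1..420", call. = FALSE)
  }
  vec[subset]
}

#' Composition feature matrix for a set of peptides
#'
#' @param sequences Character vector of valid peptide sequences (or a
#'   peptide set `data.frame`).
#' @param block `"both"` (420 columns), `"aac"` (20) or `"dpc"` (400).
#' @return Numeric matrix, one row per peptide, with feature-name columns.
#' @export
feature_matrix <- function(sequences, block = c("both", "aac", "dpc")) {
  block <- match.arg(block)
  if (is.data.frame(sequences)) sequences <- sequences$sequence
  enc <- switch(block,
                both = function(s) c(aac(s), dpc(s)),
                aac = aac,
                dpc = dpc)
  m <- t(vapply(sequences, enc,
                numeric(switch(block, both = 420L, aac = 20L, dpc = 400L))))
  rownames(m) <- NULL
  m
}

#' Write a labeled feature matrix as tab-separated values
#'
#' First column `label`, then one column per feature, named by
#' [feature_names()] convention.
#'
#' @param m Feature matrix with column names.
#' @param labels Factor or character labels, one per row.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(m, labels, path) {
  df <- data.frame(label = as.character(labels), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a labeled feature matrix in sparse SVM-light style format
#'
#' One line per sample: label (`+1` for the positive class, `-1` otherwise)
#' followed by `index:value` pairs with 1-based feature indices in ascending
#' order; zero entries omitted.
#'
#' @param m Feature matrix.
#' @param labels Labels; the positive class is `"PSBP"` (or `1`/`TRUE`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_svm_sparse <- function(m, labels, path) {
  ypm <- ifelse(as.character(labels) %in% c("PSBP", "1", "TRUE"), "+1", "-1")
  lines <- vapply(seq_len(nrow(m)), function(i) {
    nz <- which(m[i, ] != 0)
    paste(ypm[i], paste(sprintf("%d:%g", nz, m[i, nz]), collapse = " "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
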