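#' Background residue distributions
#'
#' `"uniform"` puts probability 1/20 on each residue (the simplest documented
#' null); `"natural"` uses approximate natural protein abundances.
#'
#' @param background `"uniform"` or `"natural"`.
#' @return Named numeric vector of 20 probabilities summing to 1, in
#'   [amino_acids()] order.
#' @export
background_distribution <- function(background = c("uniform", "natural")) {
  background <- match.arg(background)
  if (background == "uniform") {
    return(stats::setNames(rep(1 / 20, 20), amino_acids()))
  }
  # approximate UniProtKB/Swiss-Prot residue abundances (percent)
  p <- c(A = 8.25, C = 1.38, D = 5.45, E = 6.75, F = 3.86, G = 7.07,
         H = 2.27, I = 5.96, K = 5.84, L = 9.66, M = 2.42, N = 4.06,
         P = 4.70, Q = 3.93, R = 5.53, S = 6.56, T = 5.34, V = 6.87,
         W = 1.08, Y = 2.92)
  p <- p[amino_acids()]
  p / sum(p)
}

#' Specification for a synthetic PSBP-like dataset
#'
#' Defines a balanced binary peptide dataset whose positives mimic the
#' reported statistical structure of polystyrene surface-binding peptides:
#' enrichment of the aromatic residues W, Y and F, and recurrent PS-binding
#' motifs (`WXXW`, `FHXXW`, `WXXWXXXW`; `X` = any residue). Negatives are
#' random peptides of the same lengths drawn from the background
#' distribution.
#'
#' @param n_per_class Peptides per class (default 104, the shape of the
#'   published training corpus).
#' @param lengths Candidate peptide lengths (default 7 and 12, common
#'   phage-display library sizes).
#' @param length_weights Sampling weights for `lengths`.
#' @param motifs Motif patterns over the residue alphabet plus wildcard `X`.
#' @param motif_fraction Fraction of positives carrying an explicitly planted
#'   motif (default 0.7).
#' @param aromatic_enrichment Multiplier on the W/Y/F background frequency in
#'   positives (default 3), renormalized.
#' @param background Background residue distribution (see
#'   [background_distribution()]).
#' @param similarity_threshold Generalized Jaccard curation threshold.
#' @param seed RNG seed; the generated dataset is a pure function of the
#'   spec.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_per_class = 104,
                           lengths = c(7, 12),
                           length_weights = c(0.5, 0.5),
                           motifs = c("WXXW", "FHXXW", "WXXWXXXW"),
                           motif_fraction = 0.7,
                           aromatic_enrichment = 3,
                           background = c("uniform", "natural"),
                           similarity_threshold = 0.90,
                           seed = 1) {
  background <- match.arg(background)
  stopifnot(n_per_class >= 1, length(lengths) == length(length_weights),
            all(lengths >= 2), motif_fraction >= 0, motif_fraction <= 1,
            aromatic_enrichment > 0)
  if (motif_fraction > 0 && max(lengths) < max(nchar(motifs))) {
    stop("all lengths are shorter than the longest motif", call. = FALSE)
  }
  for (m in motifs) {
    chars <- strsplit(toupper(m), "")[[1]]
    if (!all(chars %in% c(amino_acids(), "X"))) {
      stop(sprintf("motif '%s' contains characters outside the alphabet + X", m),
           call. = FALSE)
    }
  }
  structure(list(n_per_class = n_per_class, lengths = lengths,
                 length_weights = length_weights / sum(length_weights),
                 motifs = toupper(motifs), motif_fraction = motif_fraction,
                 aromatic_enrichment = aromatic_enrichment,
                 background = background,
                 similarity_threshold = similarity_threshold, seed = seed),
            class = "synthetic_spec")
}

enriched_distribution <- function(spec) {
  p <- background_distribution(spec$background)
  p[c("W", "Y", "F")] <- p[c("W", "Y", "F")] * spec$aromatic_enrichment
  p / sum(p)
}

draw_residues <- function(n, p) {
  sample(amino_acids(), n, replace = TRUE, prob = p)
}

# sample() treats a length-1 numeric as 1:x; index explicitly instead
draw_length <- function(spec) {
  spec$lengths[sample.int(length(spec$lengths), 1, prob = spec$length_weights)]
}

#' Generate synthetic positive (PSBP-like) peptides
#'
#' With probability `motif_fraction` a uniformly chosen motif (among those
#' fitting the drawn length; longer motifs are excluded from the draw) is
#' planted at a uniform random offset, its `X` wildcards drawn from the
#' background distribution; all residual positions are drawn from the
#' aromatics-enriched distribution. Otherwise the whole sequence is drawn
#' from the enriched distribution. Uses the current RNG state.
#'
#' @param spec A [synthetic_spec()].
#' @param n Number of peptides.
#' @return Character vector of sequences.
#' @export
generate_positive <- function(spec, n = 1) {
  bg <- background_distribution(spec$background)
  en <- enriched_distribution(spec)
  vapply(seq_len(n), function(i) {
    L <- draw_length(spec)
    chars <- draw_residues(L, en)
    if (stats::runif(1) < spec$motif_fraction) {
      fits <- spec$motifs[nchar(spec$motifs) <= L]
      if (length(fits) > 0L) {
        motif <- strsplit(fits[sample.int(length(fits), 1)], "")[[1]]
        off <- sample.int(L - length(motif) + 1L, 1) - 1L
        for (j in seq_along(motif)) {
          chars[off + j] <- if (motif[j] == "X") draw_residues(1, bg) else motif[j]
        }
      }
    }
    paste(chars, collapse = "")
  }, character(1))
}

#' Generate synthetic negative (background) peptides
#'
#' Sequences drawn i.i.d. from the background residue distribution at lengths
#' drawn from the length distribution. Uses the current RNG state.
#'
#' @inheritParams generate_positive
#' @return Character vector of sequences.
#' @export
generate_negative <- function(spec, n = 1) {
  bg <- background_distribution(spec$background)
  vapply(seq_len(n), function(i) {
    L <- draw_length(spec)
    paste(draw_residues(L, bg), collapse = "")
  }, character(1))
}

#' Generate a curated synthetic labeled dataset
#'
#' Generates positives and negatives per the spec, passes them through the
#' curation pipeline ([assemble_dataset()], without cysteine trimming since
#' generated peptides are linear), and tops up with freshly sampled peptides
#' until exactly `n_per_class` survive per class (bounded resampling).
#'
#' @param spec A [synthetic_spec()].
#' @param max_rounds Resampling rounds before giving up.
#' @return A `labeled_dataset` with exactly `n_per_class` peptides per class.
#' @export
generate_dataset <- function(spec, max_rounds = 100) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  n <- spec$n_per_class
  pos_pool <- generate_positive(spec, n)
  neg_pool <- generate_negative(spec, n)
  for (round in seq_len(max_rounds)) {
    ds <- assemble_dataset(pos_pool, neg_pool,
                           threshold = spec$similarity_threshold,
                           trim_cysteines = FALSE)
    short_pos <- n - nrow(ds$positives)
    short_neg <- n - nrow(ds$negatives)
    if (short_pos <= 0L && short_neg <= 0L) {
      ds$positives <- ds$positives[seq_len(n), , drop = FALSE]
      ds$negatives <- ds$negatives[seq_len(n), , drop = FALSE]
      ds$positives$id <- paste0("pos", seq_len(n))
      ds$negatives$id <- paste0("neg", seq_len(n))
      ds$spec <- spec
      return(ds)
    }
    if (short_pos > 0L) pos_pool <- c(pos_pool, generate_positive(spec, short_pos + 5L))
    if (short_neg > 0L) neg_pool <- c(neg_pool, generate_negative(spec, short_neg + 5L))
  }
  stop("could not satisfy per-class counts after bounded resampling", call. = FALSE)
}

#' Serialize a synthetic spec as JSON
#' @param spec A `synthetic_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_synthetic_spec <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
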