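#' The 20 canonical amino acids, alphabetical one-letter codes
#'
#' Fixed residue order used throughout the package: AAC feature indices and
#' the row/column order of dipeptide features both follow this vector.
#'
#' @return Character vector of length 20 (`"A"`, `"C"`, ..., `"Y"`).
#' @export
#' @examples
#' amino_acids()
amino_acids <- function() {
  c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
    "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
}

#' Construct a peptide set
#'
#' A peptide set is a plain `data.frame` with columns `id` and `sequence`,
#' the unit of all I/O in this package. Sequences are uppercased; every
#' sequence must pass [validate_sequence()].
#'
#' @param sequence Character vector of peptide sequences.
#' @param id Optional character vector of identifiers; defaults to
#'   `"seq1"`, `"seq2"`, ...
#' @return A `data.frame` with columns `id`, `sequence`.
#' @export
#' @examples
#' peptides(c("WHWSWG", "ACDEFG"))
peptides <- function(sequence, id = NULL) {
  sequence <- toupper(as.character(sequence))
  if (is.null(id)) id <- paste0("seq", seq_along(sequence))
  stopifnot(length(id) == length(sequence))
  for (i in seq_along(sequence)) {
    v <- validate_sequence(sequence[i])
    if (!v$ok) {
      stop(sprintf("invalid sequence for '%s': %s", id[i], v$reason),
           call. = FALSE)
    }
  }
  data.frame(id = as.character(id), sequence = sequence,
             stringsAsFactors = FALSE)
}

#' Validate a peptide sequence
#'
#' Accepts a sequence iff, after uppercasing, every character is one of the
#' 20 canonical one-letter amino-acid codes. Ambiguous residues
#' (B, J, O, U, X, Z) and non-alphabetic characters are rejected; the
#' rejection names the first offending character and its position.
#' Rejection is a return value, not an error, so curation can log it.
#'
#' @param sequence A single character string.
#' @return A list with elements `ok` (logical) and `reason` (`NA` when ok).
#' @export
#' @examples
#' validate_sequence("ACDEFGHIKLMNPQRSTVWY")$ok
#' validate_sequence("ACDX")$reason
validate_sequence <- function(sequence) {
  if (length(sequence) != 1L || !is.character(sequence) || is.na(sequence)) {
    return(list(ok = FALSE, reason = "sequence must be a single string"))
  }
  s <- toupper(sequence)
  if (nchar(s) == 0L) return(list(ok = FALSE, reason = "empty sequence"))
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% amino_acids())
  if (length(bad) > 0L) {
    p <- bad[1]
    return(list(ok = FALSE,
                reason = sprintf("invalid residue \"%s\" at position %d",
                                 chars[p], p)))
  }
  list(ok = TRUE, reason = NA_character_)
}

#' Parse peptides from FASTA text
#'
#' Standard FASTA: records begin with `">"`; the first whitespace-delimited
#' token of the header becomes the id; wrapped sequence lines are
#' concatenated and uppercased before validation. `";"`-comment lines and
#' `"*"` stop characters are not supported and raise an error.
#'
#' @param text Multi-line FASTA string (or character vector of lines).
#' @return Peptide set (`data.frame` with `id`, `sequence`).
#' @export
#' @examples
#' parse_fasta(">p1\nWHWSWG")
parse_fasta <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty FASTA input", call. = FALSE)
  }
  if (any(startsWith(trimws(lines), ";"))) {
    stop("';' comment lines are not supported in FASTA input", call. = FALSE)
  }
  if (!startsWith(trimws(lines[nzchar(trimws(lines))][1]), ">")) {
    stop("not FASTA: first non-blank line must start with '>'", call. = FALSE)
  }
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_seq <- character(0)
  flush <- function() {
    s <- paste(cur_seq, collapse = "")
    if (nchar(s) == 0L) {
      stop(sprintf("empty sequence in record %s", cur_id), call. = FALSE)
    }
    ids <<- c(ids, cur_id); seqs <<- c(seqs, s)
  }
  for (ln in lines) {
    ln <- trimws(ln)
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      if (!is.null(cur_id)) flush()
      hdr <- sub("^>", "", ln)
      tok <- strsplit(trimws(hdr), "\\s+")[[1]]
      cur_id <- if (length(tok) >= 1L && nzchar(tok[1])) tok[1] else "unnamed"
      cur_seq <- character(0)
    } else {
      if (is.null(cur_id)) stop("sequence data before first '>' header", call. = FALSE)
      cur_seq <- c(cur_seq, ln)
    }
  }
  flush()
  peptides(seqs, ids)
}

#' Parse peptides from plain text, one sequence per line
#'
#' Blank lines are skipped; leading/trailing whitespace is stripped; ids are
#' auto-generated (`"seq1"`, `"seq2"`, ...) in input order. Invalid residues
#' raise an error naming the line.
#'
#' @param text Multi-line string (or character vector of lines).
#' @return Peptide set (`data.frame` with `id`, `sequence`).
#' @export
#' @examples
#' parse_plain("WHWSWG\nACDEFG")
parse_plain <- function(text) {
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  lines <- trimws(sub("\r$", "", lines))
  keep <- which(nzchar(lines))
  seqs <- toupper(lines[keep])
  for (j in seq_along(seqs)) {
    v <- validate_sequence(seqs[j])
    if (!v$ok) {
      stop(sprintf("line %d: %s", keep[j], v$reason), call. = FALSE)
    }
  }
  peptides(seqs)
}

#' Read peptides from a file (FASTA or plain text)
#'
#' @param path File path.
#' @param format `"auto"` (FASTA iff the first non-blank character is `>`),
#'   `"fasta"`, or `"plain"`.
#' @return Peptide set.
#' @export
read_peptides <- function(path, format = c("auto", "fasta", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    nb <- trimws(lines[nzchar(trimws(lines))])
    format <- if (length(nb) > 0 && startsWith(nb[1], ">")) "fasta" else "plain"
  }
  if (format == "fasta") parse_fasta(lines) else parse_plain(lines)
}

#' Render a peptide set as FASTA text
#' @param pep Peptide set.
#' @return Single FASTA string.
#' @export
render_fasta <- function(pep) {
  paste(sprintf(">%s\n%s", pep$id, pep$sequence), collapse = "\n")
}

#' Render a peptide set as plain text (one sequence per line)
#' @param pep Peptide set.
#' @return Single string.
#' @export
render_plain <- function(pep) paste(pep$sequence, collapse = "\n")

#' Write a peptide set to a FASTA file
#' @param pep Peptide set.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(pep, path) {
  writeLines(render_fasta(pep), path)
  invisible(path)
}

#' Trim flanking cysteines of circular peptides
#'
#' Phage-display circular peptides are displayed between a fixed pair of
#' cysteines; the curation step removes them. If a sequence starts AND ends
#' with `"C"` and has length >= 3, the first and last residues are removed
#' (once, not recursively); otherwise it is returned unchanged.
#'
#' @param sequence Character vector of valid sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' trim_flanking_cysteines("CWHWC")  # "WHW"
#' trim_flanking_cysteines("CWHW")   # unchanged
trim_flanking_cysteines <- function(sequence) {
  s <- toupper(sequence)
  n <- nchar(s)
  doit <- n >= 3L & startsWith(s, "C") & endsWith(s, "C")
  s[doit] <- substr(s[doit], 2L, n[doit] - 1L)
  s
}
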