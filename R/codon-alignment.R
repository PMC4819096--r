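# Codon alignment container and FASTA I/O.

#' Construct a codon alignment
#'
#' Builds a codon-aware alignment from equal-length nucleotide sequences.
#' Sequences must consist of `A,C,G,T,-`, have length divisible by 3, and
#' every codon must be either fully gapped (`---`) or fully ungapped;
#' frame-breaking gaps are rejected.
#'
#' @param sequences Named character vector of aligned nucleotide sequences.
#' @return An object of class `codon_alignment`: a list with `taxa`
#'   (sequence labels), `codons` (taxa x codon-column character matrix) and
#'   `length_nt`.
#' @export
#' @examples
#' aln <- codon_alignment(c(human = "ATGTTT", mouse = "ATGTTC"))
#' ncol(aln$codons)
codon_alignment <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences)))) {
    stop("all sequences must be named")
  }
  if (anyDuplicated(names(sequences))) stop("duplicate sequence names")
  sequences <- toupper(sequences)
  widths <- nchar(sequences)
  if (length(unique(widths)) != 1L) {
    stop("all sequences must have equal length; got widths ",
         paste(unique(widths), collapse = ", "))
  }
  len <- widths[[1]]
  if (len == 0L) stop("empty alignment")
  if (len %% 3L != 0L) stop("alignment length ", len, " is not divisible by 3")
  bad_chars <- grepl("[^ACGT-]", sequences)
  if (any(bad_chars)) {
    stop("sequence(s) contain characters outside {A,C,G,T,-}: ",
         paste(names(sequences)[bad_chars], collapse = ", "))
  }
  n_codons <- len %/% 3L
  starts <- 3L * (seq_len(n_codons) - 1L) + 1L
  codons <- t(vapply(sequences, function(s) {
    substring(s, starts, starts + 2L)
  }, character(n_codons)))
  if (n_codons == 1L) {
    codons <- matrix(vapply(sequences, function(s) substring(s, 1L, 3L), ""),
                     ncol = 1L, dimnames = list(names(sequences), NULL))
  }
  has_gap <- grepl("-", codons)
  full_gap <- codons == GAP_CODON
  if (any(has_gap & !full_gap)) {
    idx <- which(has_gap & !full_gap, arr.ind = TRUE)[1L, ]
    stop("frame-breaking gap in sequence '", rownames(codons)[idx[1L]],
         "' at codon ", idx[2L],
         ": codons must be fully gapped or fully ungapped")
  }
  structure(list(taxa = names(sequences), codons = codons, length_nt = len),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("codon_alignment:", length(x$taxa), "taxa x",
      ncol(x$codons), "codons (", x$length_nt, "nt )\n")
  invisible(x)
}

#' Extract aligned nucleotide sequences
#'
#' @param x A `codon_alignment`.
#' @param ... Unused.
#' @return Named character vector of nucleotide sequences.
#' @export
as.character.codon_alignment <- function(x, ...) {
  stats::setNames(apply(x$codons, 1L, paste0, collapse = ""), x$taxa)
}

#' Read a codon alignment from FASTA
#'
#' All records must share the same length (an alignment), which must be
#' divisible by 3 with whole-codon gaps only.
#'
#' @param path FASTA file of aligned nucleotide sequences.
#' @return A [codon_alignment()].
#' @export
read_codon_alignment <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) stop("no sequences in ", path)
  codon_alignment(stats::setNames(as.character(seqs), names(seqs)))
}

#' Write a codon alignment to FASTA
#'
#' Sequences are wrapped at 60 columns.
#'
#' @param aln A `codon_alignment`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  seqs <- Biostrings::DNAStringSet(as.character(aln))
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

#' Drop low-coverage codon columns
#'
#' Retains alignment columns whose fraction of ungapped codons is at least
#' `min_coverage`, preserving order. Mirrors the common practice of
#' eliminating positions with sparse site coverage before phylogenetic
#' analysis.
#'
#' @param aln A `codon_alignment`.
#' @param min_coverage Minimum ungapped fraction in (0, 1]; default 0.35.
#' @return A filtered `codon_alignment`; the removed column indices are kept
#'   in attribute `"removed_columns"`.
#' @export
filter_columns_by_coverage <- function(aln, min_coverage = 0.35) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!(min_coverage > 0 && min_coverage <= 1)) {
    stop("min_coverage must be in (0, 1]")
  }
  coverage <- colMeans(aln$codons != GAP_CODON)
  keep <- coverage >= min_coverage
  if (!any(keep)) stop("coverage filter removed every column")
  out <- codon_alignment(stats::setNames(
    apply(aln$codons[, keep, drop = FALSE], 1L, paste0, collapse = ""),
    aln$taxa))
  attr(out, "removed_columns") <- which(!keep)
  out
}
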