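# Shared sequence and interval helpers. The internal alphabet is DNA
# ({A,C,G,T,N}); U is accepted on input and normalized to T, and RNA letters
# only reappear in human-readable reports. All coordinates are 1-based
# inclusive, the R/Bioconductor convention; BED input is converted at parse
# time and GFF3 is native.

#' Normalize a nucleotide string to the internal DNA alphabet
#'
#' Uppercases and converts U to T. Ambiguity codes other than N are rejected.
#'
#' @param x character vector of sequences.
#' @param allow_n keep `N` (default) or treat it as invalid.
#' @return character vector of normalized sequences.
#' @export
normalize_seq <- function(x, allow_n = TRUE) {
  y <- unname(chartr("u", "T", chartr("U", "T", toupper(x))))
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  bad <- stringr::str_detect(y, pat)
  if (any(bad, na.rm = TRUE)) {
    stop("non-nucleotide characters in sequence(s): ",
         paste(utils::head(which(bad), 3), collapse = ", "), call. = FALSE)
  }
  y
}

#' Reverse complement of DNA sequences
#' @param x character vector over {A,C,G,T,N}.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' Display a DNA string as RNA
#' @param x character vector over the DNA alphabet.
#' @return character vector with T replaced by U.
#' @export
as_rna <- function(x) chartr("T", "U", x)

# genome: tibble with columns id, sequence (from read_genome_fasta)
genome_seq <- function(genome, seq_id) {
  i <- match(seq_id, genome$id)
  if (is.na(i)) stop("unknown sequence id: ", seq_id, call. = FALSE)
  genome$sequence[[i]]
}

genome_len <- function(genome, seq_id) nchar(genome_seq(genome, seq_id))

#' Extract the transcript-strand sequence of a genomic interval
#'
#' Returns the 5'->3' sequence on the transcribed strand: for minus-strand
#' loci the genomic substring is reverse-complemented, so downstream logic
#' always reasons in transcript space.
#'
#' @param genome assembly tibble from [read_genome_fasta()].
#' @param seq_id chromosome/scaffold id.
#' @param start,end 1-based inclusive genomic coordinates.
#' @param strand `"+"` or `"-"`.
#' @return a single character string.
#' @export
extract_locus_sequence <- function(genome, seq_id, start, end, strand = "+") {
  n <- genome_len(genome, seq_id)
  if (start < 1 || end > n || start > end) {
    stop("interval [", start, ",", end, "] outside ", seq_id,
         " (length ", n, ")", call. = FALSE)
  }
  s <- substr(genome_seq(genome, seq_id), start, end)
  if (identical(strand, "-")) revcomp(s) else s
}

# Map a transcript-space position on a locus back to genomic coordinates.
transcript_to_genomic <- function(pos, locus_start, locus_end, strand) {
  if (identical(strand, "-")) locus_end - pos + 1L else locus_start + pos - 1L
}

# Fraction of `read` interval [s1,e1] covered by [s2,e2].
overlap_frac <- function(s1, e1, s2, e2) {
  ov <- pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
  ov / (e1 - s1 + 1L)
}
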