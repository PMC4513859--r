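# Read filtering, RPM normalization, and exact alignment of reads onto
# candidate precursors (sense strand, no mismatches) or onto toy genomes.

#' Read filter configuration
#'
#' Defaults mirror the standard sRNA-seq preprocessing for miRNA discovery:
#' reads shorter than 18 nt or longer than 26 nt, or containing any unknown
#' nucleotide, are discarded.
#'
#' @param min_len,max_len inclusive length bounds in nt.
#' @param reject_ambiguous discard reads containing N.
#' @return a list of class `read_filter_config`.
#' @export
read_filter_config <- function(min_len = 18L, max_len = 26L,
                               reject_ambiguous = TRUE) {
  stopifnot(min_len > 0, min_len <= max_len)
  structure(list(min_len = as.integer(min_len), max_len = as.integer(max_len),
                 reject_ambiguous = reject_ambiguous),
            class = "read_filter_config")
}

#' Filter collapsed reads by length and ambiguity
#'
#' @param reads tibble with `sequence`, `count`, `sample`.
#' @param config a [read_filter_config()].
#' @return list with `reads` (the retained tibble) and `accounting`, a tibble
#'   of read counts per outcome (`retained`, `too_short`, `too_long`,
#'   `ambiguous`). Counts are conserved: the accounting column sums to the
#'   input total.
#' @export
filter_reads <- function(reads, config = read_filter_config()) {
  len <- nchar(reads$sequence)
  has_n <- stringr::str_detect(reads$sequence, "N")
  cause <- dplyr::case_when(
    config$reject_ambiguous & has_n ~ "ambiguous",
    len < config$min_len ~ "too_short",
    len > config$max_len ~ "too_long",
    TRUE ~ "retained"
  )
  accounting <- tibble(cause = c("retained", "too_short", "too_long",
                                 "ambiguous")) |>
    left_join(
      tibble(cause = cause, count = reads$count) |>
        group_by(.data$cause) |>
        summarise(reads = sum(.data$count), n_distinct = n(),
                  .groups = "drop"),
      by = "cause") |>
    mutate(reads = dplyr::coalesce(.data$reads, 0L),
           n_distinct = dplyr::coalesce(.data$n_distinct, 0L))
  list(reads = reads[cause == "retained", , drop = FALSE],
       accounting = accounting)
}

#' Reads-per-million normalization
#'
#' @param count read count(s).
#' @param library_size total mapped reads in the library (must be > 0).
#' @return `count * 1e6 / library_size`, exact; tables report two decimals.
#' @export
rpm_normalize <- function(count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  count * 1e6 / library_size
}

# All exact occurrences (possibly overlapping) of `pattern` in `subject`.
exact_occurrences <- function(subject, pattern) {
  hits <- .mismatch_scan(subject, pattern, 0L)
  if (length(hits) == 0) integer(0) else hits[seq(1, length(hits), by = 2)]
}

#' Map collapsed reads exactly onto a precursor (sense strand)
#'
#' Every exact, full-length occurrence of each read on the precursor's sense
#' strand is recorded; a read occurring at k positions contributes k stack
#' entries, each carrying its full count and flagged `multi_hit`. Precursors
#' are transcripts, so antisense hits are deliberately not searched; the
#' number of reads whose reverse complement (but not the read itself) occurs
#' is reported in the `antisense_skipped` attribute.
#'
#' @param reads tibble with `sequence`, `count` and optionally `sample`.
#' @param precursor precursor sequence (5'->3', transcript strand).
#' @param locus_id identifier attached to the stack.
#' @return a read-stack tibble: `locus_id`, `start`, `end`, `length`,
#'   `count`, `sample`, `sequence`, `multi_hit`.
#' @export
map_to_precursor <- function(reads, precursor, locus_id = "locus") {
  stopifnot(nchar(precursor) > 0)
  precursor <- normalize_seq(precursor)
  if (!"sample" %in% names(reads)) reads$sample <- "sample1"
  anti <- 0L
  rows <- purrr::pmap_dfr(
    reads[, c("sequence", "count", "sample")],
    function(sequence, count, sample) {
      pos <- exact_occurrences(precursor, sequence)
      if (length(pos) == 0) {
        if (length(exact_occurrences(precursor, revcomp(sequence))) > 0) {
          anti <<- anti + 1L
        }
        return(tibble())
      }
      tibble(start = pos, length = nchar(sequence), count = count,
             sample = sample, sequence = sequence,
             multi_hit = length(pos) > 1L)
    })
  if (nrow(rows) == 0) {
    rows <- tibble(start = integer(), length = integer(), count = integer(),
                   sample = character(), sequence = character(),
                   multi_hit = logical())
  }
  out <- mutate(rows, locus_id = locus_id, end = .data$start + .data$length - 1L) |>
    select("locus_id", "start", "end", "length", "count", "sample",
           "sequence", "multi_hit") |>
    arrange(.data$start, .data$length, .data$sequence)
  attr(out, "antisense_skipped") <- anti
  out
}

#' Exact alignment of reads to a toy genome on both strands
#'
#' A stand-in for an external aligner, intended for small synthetic genomes
#' only: every exact full-length occurrence of each read is reported on both
#' strands. Minus-strand hits carry the read 5'->3' with strand `-`.
#'
#' @param reads tibble with `sequence`, `count`.
#' @param genome assembly tibble from [read_genome_fasta()].
#' @param max_genome total assembly size bound (default 10 Mb); larger
#'   genomes are refused with guidance to supply SAM alignments instead.
#' @return alignment tibble: `sequence`, `seq_id`, `start`, `end`, `strand`,
#'   `count`, `multi_hit`.
#' @export
naive_genome_align <- function(reads, genome, max_genome = 1e7) {
  if (sum(genome$length) > max_genome) {
    stop("assembly exceeds the toy bound (", max_genome, " bp); align with ",
         "an external tool and supply SAM via read_sam_alignments()",
         call. = FALSE)
  }
  hits <- purrr::map_dfr(seq_len(nrow(reads)), function(i) {
    rd <- reads$sequence[i]
    purrr::map_dfr(seq_len(nrow(genome)), function(g) {
      chr <- genome$sequence[g]
      fw <- exact_occurrences(chr, rd)
      rv <- exact_occurrences(chr, revcomp(rd))
      tibble(start = c(fw, rv),
             strand = rep(c("+", "-"), c(length(fw), length(rv)))) |>
        mutate(seq_id = genome$id[g])
    }) |>
      mutate(sequence = rd, count = reads$count[i],
             end = .data$start + nchar(rd) - 1L)
  })
  if (nrow(hits) == 0) {
    return(tibble(sequence = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  count = integer(), multi_hit = logical()))
  }
  hits |>
    group_by(.data$sequence) |>
    mutate(multi_hit = n() > 1L) |>
    ungroup() |>
    select("sequence", "seq_id", "start", "end", "strand", "count",
           "multi_hit") |>
    arrange(.data$seq_id, .data$start, .data$strand, .data$sequence)
}
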