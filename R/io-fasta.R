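# FASTA / FASTQ ingestion. Parsing is delegated to Biostrings; this layer
# enforces the package's invariants (unique ids, U->T normalization, the
# "_x<count>" collapsed-read header dialect) and returns tibbles.

#' Read a genome assembly from FASTA
#'
#' @param path FASTA file (plain or gzip).
#' @return tibble with columns `id` (first word of the header), `sequence`
#'   (uppercase DNA, U normalized to T) and `length`.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("empty FASTA: ", path, call. = FALSE)
  ids <- stringr::str_extract(names(set), "^\\S+")
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- normalize_seq(as.character(set))
  if (any(nchar(seqs) == 0)) stop("empty FASTA record in ", path, call. = FALSE)
  tibble(id = ids, sequence = unname(seqs), length = nchar(seqs))
}

#' Write sequences to FASTA
#'
#' @param x tibble with columns `id` and `sequence`.
#' @param path output file.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 70L) {
  set <- Biostrings::BStringSet(setNames(x$sequence, x$id))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Read small RNA reads, collapsing to distinct sequences with counts
#'
#' Two dialects are supported: `collapsed_fasta` expects miRDeep-style headers
#' ending in `_x<count>`; `fastq` reads raw records and collapses identical
#' sequences on ingest.
#'
#' @param path input file.
#' @param dialect `"collapsed_fasta"` or `"fastq"`.
#' @param sample sample identifier attached to every read.
#' @return tibble with columns `sequence`, `count`, `sample`, sorted by
#'   decreasing count then sequence.
#' @export
read_collapsed_reads <- function(path, dialect = c("collapsed_fasta", "fastq"),
                                 sample = "sample1") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "collapsed_fasta") {
    set <- Biostrings::readBStringSet(path)
    counts <- suppressWarnings(
      as.integer(stringr::str_match(names(set), "_x(\\d+)\\s*$")[, 2])
    )
    if (anyNA(counts)) {
      stop("collapsed_fasta headers must end in _x<count>; offending record: ",
           names(set)[which(is.na(counts))[1]], call. = FALSE)
    }
    reads <- tibble(sequence = normalize_seq(as.character(set)),
                    count = counts)
  } else {
    set <- Biostrings::readBStringSet(path, format = "fastq")
    reads <- tibble(sequence = normalize_seq(as.character(set)), count = 1L)
  }
  reads |>
    group_by(.data$sequence) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    mutate(sample = sample) |>
    arrange(dplyr::desc(.data$count), .data$sequence)
}

#' Write collapsed reads in the `_x<count>` FASTA dialect
#' @param reads tibble with `sequence` and `count`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_collapsed_reads <- function(reads, path) {
  ids <- sprintf("r%d_x%d", seq_len(nrow(reads)), reads$count)
  write_fasta(tibble(id = ids, sequence = reads$sequence), path)
}
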