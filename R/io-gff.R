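# GFF3 / BED / SAM boundaries. rtracklayer parses GFF3 and BED; Rsamtools
# parses SAM (mandatory-field subset). Introns are not explicit in GFF3 and
# are derived as inter-exon gaps within each transcript; intergenic regions
# are derivable on demand as the complement of gene spans.

#' Read a GFF3 annotation, deriving introns
#'
#' @param path GFF3 file.
#' @param derive_introns emit one `intron` feature per adjacent exon pair per
#'   transcript (default TRUE).
#' @return tibble with columns `seq_id`, `source`, `type`, `start`, `end`,
#'   `strand`, `id`, `parent`.
#' @export
read_gff3 <- function(path, derive_introns = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% names(md)) {
    vapply(as.list(md$Parent), function(p) {
      if (length(p) == 0) NA_character_ else as.character(p[[1]])
    }, character(1))
  } else {
    rep(NA_character_, length(gr))
  }
  feats <- tibble(
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    source = if ("source" %in% names(md)) as.character(md$source) else ".",
    type   = as.character(md$type),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    id     = if ("ID" %in% names(md)) as.character(md$ID) else NA_character_,
    parent = parent
  )
  if (derive_introns) feats <- bind_rows(feats, derive_introns(feats))
  feats
}

#' Derive intron features from the exons of each transcript
#'
#' One intron is emitted per adjacent exon pair per transcript, independently
#' for transcripts that share exon boundaries.
#'
#' @param features feature tibble (as from [read_gff3()]).
#' @return tibble of intron features (possibly empty).
#' @export
derive_introns <- function(features) {
  exons <- filter(features, .data$type == "exon", !is.na(.data$parent))
  if (nrow(exons) == 0) return(features[0, ])
  parents <- filter(features, .data$id %in% unique(exons$parent))
  purrr::map_dfr(split(exons, exons$parent), function(ex) {
    par <- filter(parents, .data$id == ex$parent[1])
    if (nrow(par) == 1 &&
        (min(ex$start) < par$start || max(ex$end) > par$end)) {
      stop("exon outside the span of its parent ", ex$parent[1], call. = FALSE)
    }
    ex <- arrange(ex, .data$start)
    if (nrow(ex) < 2) return(ex[0, ])
    tibble(
      seq_id = ex$seq_id[-1], source = "derived", type = "intron",
      start = ex$end[-nrow(ex)] + 1L, end = ex$start[-1] - 1L,
      strand = ex$strand[-1],
      id = sprintf("%s.intron%d", ex$parent[-1], seq_len(nrow(ex) - 1)),
      parent = ex$parent[-1]
    )
  })
}

#' Derive intergenic regions as the complement of gene spans
#'
#' @param features feature tibble containing `gene` rows.
#' @param genome assembly tibble from [read_genome_fasta()].
#' @return tibble of `intergenic` features covering every base not within a
#'   gene span.
#' @export
derive_intergenic <- function(features, genome) {
  genes <- filter(features, .data$type == "gene")
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chr <- genome$id[i]
    len <- genome$length[i]
    g <- filter(genes, .data$seq_id == chr)
    occupied <- IRanges::reduce(IRanges::IRanges(g$start, g$end))
    gaps <- IRanges::setdiff(IRanges::IRanges(1L, len), occupied)
    if (length(gaps) == 0) return(tibble())
    tibble(
      seq_id = chr, source = "derived", type = "intergenic",
      start = IRanges::start(gaps), end = IRanges::end(gaps),
      strand = "*",
      id = sprintf("%s.intergenic%d", chr, seq_along(gaps)),
      parent = NA_character_
    )
  })
}

#' Read candidate precursor loci from BED6
#'
#' BED half-open 0-based coordinates are converted to 1-based inclusive.
#'
#' @param path BED file.
#' @return tibble with `locus_id`, `seq_id`, `start`, `end`, `strand`.
#' @export
read_candidate_bed <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "bed")
  nm <- S4Vectors::mcols(gr)$name
  if (is.null(nm)) nm <- sprintf("locus%04d", seq_along(gr))
  tibble(
    locus_id = as.character(nm),
    seq_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = ifelse(as.character(GenomicRanges::strand(gr)) == "*", "+",
                    as.character(GenomicRanges::strand(gr)))
  )
}

#' Write candidate or certified loci as BED6
#' @param loci tibble with `locus_id`, `seq_id`, `start`, `end`, `strand`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_candidate_bed <- function(loci, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   loci$seq_id, loci$start - 1L, loci$end,
                   loci$locus_id, loci$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read genome alignments from a SAM file (mandatory fields only)
#'
#' @param path SAM file. Unmapped records are dropped; only fully mapped,
#'   ungapped reads are expected (the upstream contract).
#' @return tibble with `read_id`, `sequence`, `seq_id`, `start`, `end`,
#'   `strand`, `count` (parsed from a `_x<count>` read-name suffix when
#'   present, else 1).
#' @export
read_sam_alignments <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (!requireNamespace("Rsamtools", quietly = TRUE)) {
    stop("Rsamtools is required to read SAM input", call. = FALSE)
  }
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  rec <- Rsamtools::scanBam(bam)[[1]]
  keep <- !is.na(rec$pos)
  sq <- as.character(rec$seq)[keep]
  cnt <- suppressWarnings(
    as.integer(stringr::str_match(rec$qname[keep], "_x(\\d+)$")[, 2])
  )
  tibble(
    read_id = rec$qname[keep],
    sequence = normalize_seq(sq),
    seq_id = as.character(rec$rname)[keep],
    start = rec$pos[keep],
    end = rec$pos[keep] + nchar(sq) - 1L,
    strand = as.character(rec$strand)[keep],
    count = ifelse(is.na(cnt), 1L, cnt)
  )
}

#' Write certified miRNA loci as GFF3
#'
#' Emits, per certified locus, one `miRNA_primary_transcript` line plus two
#' `miRNA` lines (mature and star products) with 1-based inclusive
#' coordinates. Rows are ordered by locus id so output is byte-deterministic.
#'
#' @param certified tibble with columns `locus_id`, `seq_id`, `start`, `end`,
#'   `strand`, `mature_start`, `mature_end`, `star_start`, `star_end`
#'   (product coordinates in transcript space on the precursor).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mirna_gff3 <- function(certified, path) {
  certified <- arrange(certified, .data$locus_id)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(certified))) {
    x <- certified[i, ]
    g <- function(p) transcript_to_genomic(p, x$start, x$end, x$strand)
    prod_line <- function(suffix, s, e) {
      sprintf("%s\tmircert\tmiRNA\t%d\t%d\t.\t%s\t.\tID=%s.%s;Parent=%s",
              x$seq_id, min(g(s), g(e)), max(g(s), g(e)), x$strand,
              x$locus_id, suffix, x$locus_id)
    }
    lines <- c(
      lines,
      sprintf("%s\tmircert\tmiRNA_primary_transcript\t%d\t%d\t.\t%s\t.\tID=%s",
              x$seq_id, x$start, x$end, x$strand, x$locus_id),
      prod_line("mature", x$mature_start, x$mature_end),
      prod_line("star", x$star_start, x$star_end)
    )
  }
  writeLines(lines, path)
  invisible(path)
}
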