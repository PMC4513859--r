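# Genome-fraction coverage accounting, genomic context of certified loci,
# cluster detection and the convergent-gene-pair sRNA comparison. Interval
# machinery is delegated to GenomicRanges/IRanges.

coverage_classes <- c("rRNA", "tRNA", "snoRNA", "transposon", "exon",
                      "intron", "intergenic")

features_to_granges <- function(features) {
  GenomicRanges::GRanges(
    seqnames = features$seq_id,
    ranges = IRanges::IRanges(features$start, features$end))
}

#' Genome-fraction coverage table from read alignments
#'
#' Each aligned read is assigned to exactly one feature class: the class of
#' highest precedence it overlaps by at least `min_overlap` of the read
#' length. Class sizes are made disjoint under the same precedence, so reads
#' are conserved and no base is counted in two classes.
#'
#' @param alignments tibble from [naive_genome_align()] or
#'   [read_sam_alignments()] (`sequence`, `seq_id`, `start`, `end`, `count`).
#' @param features feature tibble including derived introns (and intergenic
#'   rows, e.g. from [derive_intergenic()]).
#' @param precedence class precedence, highest first.
#' @param min_overlap read->class assignment rule (default 0.5).
#' @param count_mode `"once"` counts a multi-mapping read at its first
#'   reported alignment only; `"per-hit"` counts every alignment.
#' @return tibble of class rows: `feature_class`, `read_count`,
#'   `cumulative_size_bp`, `coverage` (reads per bp, two decimals; 0 with
#'   `size_zero = TRUE` for empty classes).
#' @export
feature_coverage_table <- function(alignments, features,
                                   precedence = coverage_classes,
                                   min_overlap = 0.5,
                                   count_mode = c("once", "per-hit")) {
  count_mode <- match.arg(count_mode)
  if (count_mode == "once" && nrow(alignments) > 0) {
    alignments <- distinct(alignments, .data$sequence, .keep_all = TRUE)
  }
  class_gr <- lapply(setNames(precedence, precedence), function(cl) {
    GenomicRanges::reduce(features_to_granges(
      filter(features, .data$type == cl)))
  })
  # disjoint sizes under precedence
  sizes <- numeric(length(precedence))
  occupied <- GenomicRanges::GRanges()
  for (k in seq_along(precedence)) {
    own <- GenomicRanges::setdiff(class_gr[[k]], occupied)
    sizes[k] <- sum(GenomicRanges::width(own))
    occupied <- GenomicRanges::reduce(c(occupied, class_gr[[k]]))
  }

  counts <- setNames(numeric(length(precedence)), precedence)
  if (nrow(alignments) > 0) {
    reads_gr <- GenomicRanges::GRanges(
      alignments$seq_id, IRanges::IRanges(alignments$start, alignments$end))
    assigned <- rep(FALSE, nrow(alignments))
    rlen <- alignments$end - alignments$start + 1L
    for (k in seq_along(precedence)) {
      if (all(assigned)) break
      hits <- GenomicRanges::findOverlaps(reads_gr, class_gr[[k]])
      if (length(hits) == 0) next
      q <- S4Vectors::queryHits(hits)
      ov <- GenomicRanges::width(IRanges::pintersect(
        reads_gr[q], class_gr[[k]][S4Vectors::subjectHits(hits)]))
      ok <- unique(q[ov / rlen[q] >= min_overlap])
      take <- ok[!assigned[ok]]
      counts[k] <- sum(alignments$count[take])
      assigned[take] <- TRUE
    }
  }
  tibble(
    feature_class = precedence,
    read_count = unname(counts),
    cumulative_size_bp = sizes,
    coverage = ifelse(sizes > 0, round(unname(counts) / sizes, 2), 0),
    size_zero = sizes == 0
  )
}

#' Coverage arithmetic from printed per-class counts and sizes
#'
#' @param counts tibble with `feature_class`, `read_count`,
#'   `cumulative_size_bp`.
#' @return the input with `coverage` = reads per bp (two decimals).
#' @export
coverage_from_counts <- function(counts) {
  mutate(counts, coverage = ifelse(.data$cumulative_size_bp > 0,
                                   round(.data$read_count /
                                           .data$cumulative_size_bp, 2), 0))
}

#' Percentage of mapped reads falling in gene-annotated regions
#' @param counts tibble with `feature_class` and `read_count`.
#' @param genic classes counted as genes (default exon + intron).
#' @return percentage of the total mapped reads.
#' @export
genic_read_percent <- function(counts, genic = c("exon", "intron")) {
  100 * sum(counts$read_count[counts$feature_class %in% genic]) /
    sum(counts$read_count)
}

#' Genomic context of a certified locus
#'
#' The host gene is the gene with the largest overlap; within the host, the
#' context is the maximal-overlap feature with priority UTR > exon > intron
#' on ties. A locus spanning two genes is flagged.
#'
#' @param locus one-row tibble (`locus_id`, `seq_id`, `start`, `end`,
#'   `strand`).
#' @param features feature tibble including derived introns.
#' @return one-row tibble: `locus_id`, `context` (intronic / exonic / UTR /
#'   intergenic), `host_gene`, `same_strand`, `multi_gene`.
#' @export
genomic_context <- function(locus, features) {
  genes <- filter(features, .data$type == "gene",
                  .data$seq_id == locus$seq_id)
  ov <- pmax(0L, pmin(genes$end, locus$end) -
               pmax(genes$start, locus$start) + 1L)
  hit <- which(ov > 0)
  if (length(hit) == 0) {
    return(tibble(locus_id = locus$locus_id, context = "intergenic",
                  host_gene = NA_character_, same_strand = NA,
                  multi_gene = FALSE))
  }
  host <- genes[hit[order(-ov[hit], genes$start[hit])][1], ]
  # transcripts of the host
  mrna_ids <- filter(features, .data$type == "mRNA",
                     .data$parent == host$id)$id
  sub <- filter(features,
                .data$parent %in% mrna_ids | .data$parent %in% host$id,
                .data$type %in% c("five_prime_UTR", "three_prime_UTR",
                                  "exon", "CDS", "intron"))
  cls <- dplyr::case_when(
    sub$type %in% c("five_prime_UTR", "three_prime_UTR") ~ "UTR",
    sub$type %in% c("exon", "CDS") ~ "exonic",
    TRUE ~ "intronic")
  sov <- pmax(0L, pmin(sub$end, locus$end) -
                pmax(sub$start, locus$start) + 1L)
  context <- if (nrow(sub) == 0 || all(sov == 0)) {
    "intronic"  # inside a gene with no finer annotation
  } else {
    prio <- c(UTR = 1L, exonic = 2L, intronic = 3L)
    agg <- tibble(cls = cls, ov = sov) |>
      group_by(.data$cls) |>
      summarise(ov = max(.data$ov), .groups = "drop") |>
      mutate(prio = prio[.data$cls]) |>
      arrange(dplyr::desc(.data$ov), .data$prio)
    agg$cls[1]
  }
  tibble(locus_id = locus$locus_id, context = context,
         host_gene = host$id,
         same_strand = identical(locus$strand, host$strand),
         multi_gene = length(hit) > 1)
}

#' Cluster miRNA loci lying within a maximum genomic gap
#'
#' Single-linkage chaining on the same chromosome: two loci join a cluster
#' when the gap between them (end-to-start, i.e. intervening bases) is
#' strictly less than `max_gap`.
#'
#' @param loci tibble with `locus_id`, `seq_id`, `start`, `end`.
#' @param max_gap gap bound in bp (default 5000; "within 5 kb" is strict).
#' @return the input with `cluster_id` and `cluster_size` columns; output
#'   order is by locus id, independent of input order.
#' @export
find_clusters <- function(loci, max_gap = 5000L) {
  loci <- arrange(loci, .data$seq_id, .data$start, .data$locus_id)
  out <- loci |>
    group_by(.data$seq_id) |>
    mutate(gap = .data$start - dplyr::lag(cummax(.data$end)) - 1L,
           new_cluster = is.na(.data$gap) | .data$gap >= max_gap,
           cluster_index = cumsum(.data$new_cluster)) |>
    ungroup() |>
    mutate(cluster_id = paste0(.data$seq_id, ".c", .data$cluster_index)) |>
    group_by(.data$cluster_id) |>
    mutate(cluster_size = n()) |>
    ungroup() |>
    select(-"gap", -"new_cluster", -"cluster_index") |>
    arrange(.data$locus_id)
  out
}

#' Convergently transcribed adjacent gene pairs
#'
#' Scans genes in chromosomal order and pairs an upstream `+` gene with the
#' next adjacent `-` gene (head-to-head 3' ends); each gene belongs to at
#' most one pair (greedy left-to-right).
#'
#' @param features feature tibble with `gene` rows carrying strands.
#' @return tibble of pairs: `gene_plus`, `gene_minus`, `seq_id`, `gap`.
#' @export
convergent_pairs <- function(features) {
  genes <- filter(features, .data$type == "gene") |>
    arrange(.data$seq_id, .data$start)
  purrr::map_dfr(split(genes, genes$seq_id), function(g) {
    pairs <- tibble()
    i <- 1L
    while (i < nrow(g)) {
      if (g$strand[i] == "+" && g$strand[i + 1] == "-") {
        pairs <- bind_rows(pairs, tibble(
          gene_plus = g$id[i], gene_minus = g$id[i + 1],
          seq_id = g$seq_id[i], gap = g$start[i + 1] - g$end[i] - 1L))
        i <- i + 2L
      } else {
        i <- i + 1L
      }
    }
    pairs
  })
}

#' Compare sRNA production between convergent and non-convergent genes
#'
#' Rank-based comparison (Kruskal-Wallis) of per-gene sRNA abundance between
#' genes in convergent pairs and all other genes, both raw and normalized by
#' mRNA abundance (sRNA / mRNA), since convergent genes may simply be more
#' highly transcribed.
#'
#' @param gene_srna tibble with `gene_id`, `srna` (FPKM-like abundance).
#' @param gene_mrna tibble with `gene_id`, `mrna` (FPKM).
#' @param pairs tibble from [convergent_pairs()].
#' @return object of class `convergent_comparison`: list with `raw` and
#'   `normalized` test results, group medians and exclusion accounting; has
#'   [tidy()] and [glance()] methods.
#' @export
convergent_srna_comparison <- function(gene_srna, gene_mrna, pairs) {
  conv_ids <- unique(c(pairs$gene_plus, pairs$gene_minus))
  dat <- left_join(gene_srna, gene_mrna, by = "gene_id")
  excluded <- sum(is.na(dat$mrna) | dat$mrna <= 0)
  dat <- filter(dat, !is.na(.data$mrna), .data$mrna > 0) |>
    mutate(group = ifelse(.data$gene_id %in% conv_ids, "convergent",
                          "other"),
           ratio = .data$srna / .data$mrna)
  insufficient <- length(unique(dat$group)) < 2 || nrow(pairs) == 0
  run_test <- function(x) {
    if (insufficient) return(list(statistic = NA_real_, p.value = NA_real_))
    kruskal.test(x, factor(dat$group))
  }
  raw <- run_test(dat$srna)
  norm <- run_test(dat$ratio)
  med <- dat |>
    group_by(.data$group) |>
    summarise(median_srna = median(.data$srna),
              median_mrna = median(.data$mrna),
              median_ratio = median(.data$ratio),
              n = n(), .groups = "drop")
  structure(list(raw = raw, normalized = norm, medians = med,
                 n_pairs = nrow(pairs), excluded_no_mrna = excluded,
                 insufficient = insufficient),
            class = "convergent_comparison")
}

#' @export
tidy.convergent_comparison <- function(x, ...) {
  tibble(
    comparison = c("raw_srna", "normalized_srna"),
    statistic = c(unname(x$raw$statistic), unname(x$normalized$statistic)),
    p.value = c(x$raw$p.value, x$normalized$p.value),
    method = "Kruskal-Wallis rank sum test"
  )
}

#' @export
glance.convergent_comparison <- function(x, ...) {
  tibble(n_pairs = x$n_pairs, excluded_no_mrna = x$excluded_no_mrna,
         insufficient_data = x$insufficient,
         p_raw = x$raw$p.value, p_normalized = x$normalized$p.value)
}

#' @export
print.convergent_comparison <- function(x, ...) {
  cat("<convergent_comparison> ", x$n_pairs, " gene pairs; ",
      x$excluded_no_mrna, " genes excluded (no mRNA abundance)\n", sep = "")
  if (x$insufficient) {
    cat("insufficient data for the rank test\n")
  } else {
    cat(sprintf("raw sRNA:        KW chi-sq = %.3f, p = %.3g\n",
                x$raw$statistic, x$raw$p.value))
    cat(sprintf("mRNA-normalized: KW chi-sq = %.3f, p = %.3g\n",
                x$normalized$statistic, x$normalized$p.value))
  }
  invisible(x)
}

#' Windowed sRNA read counts along chromosomes
#'
#' @param alignments alignment tibble.
#' @param genome assembly tibble.
#' @param window non-overlapping window size in bp (default 25 kb).
#' @return tibble with `seq_id`, `window_start`, `window_end`, `reads`.
#' @export
windowed_read_counts <- function(alignments, genome, window = 25000L) {
  purrr::map_dfr(seq_len(nrow(genome)), function(i) {
    chr <- genome$id[i]
    starts <- seq.int(1L, genome$length[i], by = window)
    a <- filter(alignments, .data$seq_id == chr)
    idx <- findInterval(a$start, starts)
    cnt <- tapply(a$count, factor(idx, levels = seq_along(starts)), sum)
    tibble(seq_id = chr, window_start = starts,
           window_end = pmin(starts + window - 1L, genome$length[i]),
           reads = as.integer(dplyr::coalesce(as.vector(cnt), 0)))
  })
}
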