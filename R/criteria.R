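# Product calling and the four validation criteria:
#   (i)   >= 15 nt of the miRNA pair with the opposite arm of the hairpin,
#   (ii)  expression evidence for both the miRNA and the miRNA*,
#   (iii) the 3p product extends 2 nt beyond the 5p product at its 3' end
#         (and symmetrically), the signature of Dicer processing,
#   (iv)  precise 5' cleavage: >= 66% of reads start at the same nucleotide.
# Rejections are diagnosed (no reads / dominant read outside the miRNA /
# invalid duplex / no star / low homogeneity), and loci embedded in extended
# palindromic regions are down-graded to WEAK.

#' Validation criteria configuration
#'
#' @param min_arm_pairs criterion (i) threshold, nt (default 15).
#' @param min_homogeneity criterion (iv) threshold, fraction (default 0.66).
#' @param required_offset criterion (iii) Dicer overhang, nt (default 2).
#' @param min_star_reads criterion (ii) threshold, reads (default 1).
#' @param star_start_tolerance accepted distance between an observed star
#'   read 5' end and the predicted star 5' end, nt (default 1).
#' @param weak_extension extension used by the genomic-context check, nt per
#'   side (default 150).
#' @param cluster_window reads are assigned to a product when their 5' end
#'   lies within this distance of the modal 5' position, nt (default 3).
#' @param min_read_overlap fraction of a read that must overlap a product to
#'   enter the homogeneity denominator (default 0.5).
#' @return a list of class `criteria_config`.
#' @export
criteria_config <- function(min_arm_pairs = 15L, min_homogeneity = 0.66,
                            required_offset = 2L, min_star_reads = 1L,
                            star_start_tolerance = 1L, weak_extension = 150L,
                            cluster_window = 3L, min_read_overlap = 0.5) {
  stopifnot(min_homogeneity > 0, min_homogeneity <= 1, required_offset >= 0)
  structure(list(
    min_arm_pairs = as.integer(min_arm_pairs),
    min_homogeneity = min_homogeneity,
    required_offset = as.integer(required_offset),
    min_star_reads = as.integer(min_star_reads),
    star_start_tolerance = as.integer(star_start_tolerance),
    weak_extension = as.integer(weak_extension),
    cluster_window = as.integer(cluster_window),
    min_read_overlap = min_read_overlap
  ), class = "criteria_config")
}

# Most abundant read cluster among stack rows: reads whose 5' end lies
# within +/- window of the modal (highest-count, ties leftmost) 5' position.
# Returns NULL or a list(start, end, length, count, rows).
top_cluster <- function(stack, window = 3L) {
  if (nrow(stack) == 0) return(NULL)
  by_start <- stack |>
    group_by(.data$start) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count), .data$start)
  modal <- by_start$start[1]
  rows <- filter(stack, abs(.data$start - modal) <= window)
  len <- rows |>
    group_by(.data$length) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count), .data$length)
  list(start = modal, length = len$length[1],
       end = modal + len$length[1] - 1L,
       count = sum(rows$count), rows = rows)
}

# Arm of an interval relative to the main hairpin loop: "5p", "3p" or "loop"
# (midpoint inside the terminal loop).
arm_of_interval <- function(start, end, loop) {
  mid <- (start + end) / 2
  if (mid < loop$loop_start) "5p" else if (mid > loop$loop_end) "3p" else "loop"
}

#' Call miRNA and miRNA* products from a read stack
#'
#' The most abundant read cluster on each hairpin arm is considered and the
#' more strongly expressed of the two is called the miRNA (ties break to the
#' 5p arm). If only one arm carries reads the star interval is predicted
#' from the pairing table via [predict_star()] with zero supporting reads.
#'
#' @param stack read-stack tibble from [map_to_precursor()].
#' @param fold the precursor `hairpin_fold`.
#' @param config a [criteria_config()].
#' @return one-row duplex tibble: mature and star intervals, arms, counts,
#'   modal 5' position, and whether the star was observed or predicted.
#'   Returns `NULL` (the NO_READS signal) for an empty stack.
#' @export
call_products <- function(stack, fold, config = criteria_config()) {
  if (is.null(stack) || nrow(stack) == 0) return(NULL)
  loop <- main_hairpin_loop(fold)
  if (is.null(loop)) return(NULL)
  arm <- vapply(seq_len(nrow(stack)), function(i) {
    arm_of_interval(stack$start[i], stack$end[i], loop)
  }, character(1))
  clusters <- purrr::compact(list(
    `5p` = top_cluster(stack[arm == "5p", ], config$cluster_window),
    `3p` = top_cluster(stack[arm == "3p", ], config$cluster_window)
  ))
  if (length(clusters) == 0) return(NULL)
  counts <- vapply(clusters, `[[`, numeric(1), "count")
  # ties break to 5p: stable order of the list is 5p first
  mi_arm <- names(clusters)[which.max(counts)]
  mi <- clusters[[mi_arm]]
  st_arm <- setdiff(c("5p", "3p"), mi_arm)
  if (st_arm %in% names(clusters)) {
    st <- clusters[[st_arm]]
    star_observed <- TRUE
    star_start <- st$start; star_end <- st$end; star_count <- st$count
  } else {
    star_observed <- FALSE
    star_count <- 0L
    st <- tryCatch(
      predict_star(fold, mi$start, mi$end, config$required_offset,
                   config$min_arm_pairs),
      error = function(e) NULL)
    star_start <- if (is.null(st)) NA_integer_ else unname(st["start"])
    star_end <- if (is.null(st)) NA_integer_ else unname(st["end"])
  }
  tibble(
    mirna_start = mi$start, mirna_end = mi$end, mirna_arm = mi_arm,
    mirna_count = mi$count, mirna_modal5 = mi$start,
    star_start = star_start, star_end = star_end, star_arm = st_arm,
    star_count = star_count, star_observed = star_observed
  )
}

#' 5' processing homogeneity of a product
#'
#' The denominator is the set of reads overlapping the product interval by
#' at least `min_read_overlap` of the read length; the fraction is the count
#' share of reads starting at the modal 5' position.
#'
#' @param stack read-stack tibble.
#' @param start,end product interval.
#' @param min_read_overlap denominator rule (default 0.5).
#' @return one-row tibble: `fraction`, `modal_start`, `total_reads`,
#'   `defined` (FALSE when the denominator is empty, in which case the
#'   fraction is reported as 0).
#' @export
homogeneity <- function(stack, start, end, min_read_overlap = 0.5) {
  den <- filter(stack, overlap_frac(.data$start, .data$end, !!start, !!end)
                >= min_read_overlap)
  if (nrow(den) == 0) {
    return(tibble(fraction = 0, modal_start = NA_integer_, total_reads = 0L,
                  defined = FALSE))
  }
  by_start <- den |>
    group_by(.data$start) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    arrange(dplyr::desc(.data$count), .data$start)
  tibble(fraction = by_start$count[1] / sum(by_start$count),
         modal_start = by_start$start[1],
         total_reads = sum(by_start$count), defined = TRUE)
}

#' Evaluate the four validation criteria for a called duplex
#'
#' Criterion (iii) is evaluated from the pairing table rather than from
#' observed star reads, so it is decidable even when star coverage is
#' minimal: the 3p product's 3' end must equal partner(5p start) + offset,
#' and symmetrically at the other duplex end.
#'
#' @param duplex one-row tibble from [call_products()].
#' @param stack read-stack tibble.
#' @param fold the precursor `hairpin_fold`.
#' @param config a [criteria_config()].
#' @return one-row tibble with the measured values and pass flags
#'   `pass_i` .. `pass_iv`.
#' @export
evaluate_criteria <- function(duplex, stack, fold,
                              config = criteria_config()) {
  arm_pairs <- paired_in_region(fold, duplex$mirna_start, duplex$mirna_end)
  pass_i <- arm_pairs >= config$min_arm_pairs

  # (ii) star expression: reads whose 5' end is near the star 5' end
  if (is.na(duplex$star_start)) {
    star_reads <- 0L
  } else {
    star_reads <- stack |>
      filter(abs(.data$start - duplex$star_start) <=
               config$star_start_tolerance) |>
      dplyr::pull(.data$count) |>
      sum()
  }
  pass_ii <- star_reads >= config$min_star_reads

  # (iii) 2-nt 3' overhangs at both duplex ends, from the pairing table
  if (is.na(duplex$star_start)) {
    off_a <- off_b <- FALSE
  } else {
    if (duplex$mirna_arm == "5p") {
      d5 <- c(duplex$mirna_start, duplex$mirna_end)
      d3 <- c(duplex$star_start, duplex$star_end)
    } else {
      d5 <- c(duplex$star_start, duplex$star_end)
      d3 <- c(duplex$mirna_start, duplex$mirna_end)
    }
    p5 <- partner_at(fold, d5[1], d5[1], d5[2])
    p3 <- partner_at(fold, d3[1], d3[1], d3[2])
    off_a <- !is.na(p5) && d3[2] == p5 + config$required_offset
    off_b <- !is.na(p3) && d5[2] == p3 + config$required_offset
  }
  pass_iii <- off_a && off_b

  hom <- homogeneity(stack, duplex$mirna_start, duplex$mirna_end,
                     config$min_read_overlap)
  pass_iv <- hom$defined & hom$fraction >= config$min_homogeneity

  tibble(
    arm_pairs = arm_pairs, pass_i = pass_i,
    star_reads = star_reads, pass_ii = pass_ii,
    offset_ok_3p_end = off_a, offset_ok_5p_end = off_b, pass_iii = pass_iii,
    homogeneity = hom$fraction, homogeneity_defined = hom$defined,
    pass_iv = pass_iv
  )
}

# Largest read cluster (sliding +/- window sum of 5' start counts) among
# stack rows; 0 when empty.
max_cluster_count <- function(stack, window = 3L) {
  if (nrow(stack) == 0) return(0)
  by_start <- stack |>
    group_by(.data$start) |>
    summarise(count = sum(.data$count), .groups = "drop")
  max(vapply(by_start$start, function(p) {
    sum(by_start$count[abs(by_start$start - p) <= window])
  }, numeric(1)))
}

#' Genomic-context (extended palindrome) check for a certified locus
#'
#' The locus is extended by `weak_extension` nt on both sides (truncated at
#' chromosome ends), reads are re-mapped and the extension re-folded. The
#' locus is flagged WEAK if (a) any read cluster outside the duplex carries
#' more reads than the miRNA*, or (b) the extended structure no longer
#' pairs the miRNA to the star arm (duplex not preserved), the pattern of
#' complex palindromic regions that generate many sRNA species.
#'
#' @param genome assembly tibble.
#' @param locus one-row tibble with `seq_id`, `start`, `end`, `strand`.
#' @param stack precursor read stack (used for duplex coordinates).
#' @param duplex one-row tibble from [call_products()].
#' @param config a [criteria_config()].
#' @param reads optionally, the full filtered read set (tibble with
#'   `sequence`, `count`, `sample`); defaults to the reads in `stack`. The
#'   full set matters because flank-derived sRNAs do not map to the
#'   unextended precursor.
#' @return one-row tibble: `weak`, `external_cluster_max`, `star_count`,
#'   `duplex_pairs_extended`, `structure_preserved`, truncation notes.
#' @export
extended_context_check <- function(genome, locus, stack, duplex,
                                   config = criteria_config(),
                                   reads = NULL) {
  if (is.null(reads)) {
    reads <- distinct(stack, .data$sequence, .data$count, .data$sample)
  }
  len <- genome_len(genome, locus$seq_id)
  gs <- max(1L, locus$start - config$weak_extension)
  ge <- min(len, locus$end + config$weak_extension)
  ext <- extract_locus_sequence(genome, locus$seq_id, gs, ge, locus$strand)
  lead <- if (identical(locus$strand, "-")) ge - locus$end else locus$start - gs

  ext_stack <- map_to_precursor(reads, ext, locus_id = locus$locus_id %||%
                                  "locus")
  mi <- c(duplex$mirna_start, duplex$mirna_end) + lead
  st <- c(duplex$star_start, duplex$star_end) + lead

  in_duplex <- overlap_frac(ext_stack$start, ext_stack$end, mi[1], mi[2]) >=
    config$min_read_overlap
  if (!anyNA(st)) {
    in_duplex <- in_duplex |
      overlap_frac(ext_stack$start, ext_stack$end, st[1], st[2]) >=
        config$min_read_overlap
  }
  external_max <- max_cluster_count(ext_stack[!in_duplex, ],
                                    config$cluster_window)

  ext_fold <- fold(ext)
  dpx_pairs <- if (anyNA(st)) 0L else {
    p <- ext_fold$pairs[mi[1]:mi[2]]
    sum(!is.na(p) & p >= st[1] - 2L & p <= st[2] + 2L)
  }
  preserved <- dpx_pairs >= config$min_arm_pairs

  tibble(
    weak = external_max > duplex$star_count || !preserved,
    external_cluster_max = external_max,
    star_count = duplex$star_count,
    duplex_pairs_extended = dpx_pairs,
    structure_preserved = preserved,
    truncated_5p = (locus$start - gs) < config$weak_extension,
    truncated_3p = (ge - locus$end) < config$weak_extension
  )
}

#' Classify a candidate miRNA locus
#'
#' Applies the rejection taxonomy in gate order: NO_READS for an empty
#' stack; DOMINANT_OUTSIDE_MIRNA when the most abundant read does not
#' overlap the called miRNA; DUPLEX_INVALID when criterion (i) or (iii)
#' fails structurally; NO_STAR / LOW_HOMOGENEITY for criterion (ii)/(iv)
#' failures; EXTENDED_PALINDROME (verdict WEAK) when the genomic-context
#' check trips; otherwise VALID.
#'
#' @param locus one-row tibble with at least `locus_id`; `seq_id`, `start`,
#'   `end`, `strand` are required when `genome` is supplied.
#' @param stack read-stack tibble (may be empty).
#' @param fold the precursor `hairpin_fold`.
#' @param config a [criteria_config()].
#' @param genome optional assembly tibble; when supplied, loci passing
#'   criteria (i)-(iv) additionally undergo [extended_context_check()].
#' @param reads optional full filtered read set for the context check.
#' @return one-row tibble: `locus_id`, `verdict` (VALID/WEAK/REJECT),
#'   `reason_codes` (comma-joined), the called duplex columns and criterion
#'   measurements (NA where not reached).
#' @export
classify <- function(locus, stack, fold, config = criteria_config(),
                     genome = NULL, reads = NULL) {
  locus_id <- locus$locus_id %||% "locus"
  empty_dup <- tibble(
    mirna_start = NA_integer_, mirna_end = NA_integer_,
    mirna_arm = NA_character_, mirna_count = NA_real_,
    mirna_modal5 = NA_integer_, star_start = NA_integer_,
    star_end = NA_integer_, star_arm = NA_character_,
    star_count = NA_real_, star_observed = NA)
  res <- function(verdict, codes, duplex = empty_dup, crit = NULL) {
    base <- tibble(locus_id = locus_id, verdict = verdict,
                   reason_codes = paste(codes, collapse = ","))
    out <- dplyr::bind_cols(base, duplex)
    if (!is.null(crit)) out <- dplyr::bind_cols(out, crit)
    out
  }

  if (is.null(stack) || nrow(stack) == 0) {
    return(res("REJECT", "NO_READS"))
  }
  duplex <- call_products(stack, fold, config)
  dominant <- stack |>
    arrange(dplyr::desc(.data$count), .data$start) |>
    slice(1)
  if (is.null(duplex)) {
    # reads exist but no product could be called on either arm
    return(res("REJECT", "DOMINANT_OUTSIDE_MIRNA"))
  }
  dom_overlap <- pmax(0L, pmin(dominant$end, duplex$mirna_end) -
                        pmax(dominant$start, duplex$mirna_start) + 1L)
  if (dom_overlap == 0L) {
    return(res("REJECT", "DOMINANT_OUTSIDE_MIRNA", duplex))
  }
  crit <- evaluate_criteria(duplex, stack, fold, config)
  codes <- character(0)
  if (!crit$pass_i || !crit$pass_iii) codes <- c(codes, "DUPLEX_INVALID")
  if (!crit$pass_ii) codes <- c(codes, "NO_STAR")
  if (!crit$pass_iv) codes <- c(codes, "LOW_HOMOGENEITY")
  if (length(codes) > 0) {
    return(res("REJECT", codes, duplex, crit))
  }
  if (!is.null(genome)) {
    ctx <- extended_context_check(genome, locus, stack, duplex, config, reads)
    if (ctx$weak) {
      out <- res("WEAK", "EXTENDED_PALINDROME", duplex, crit)
      return(dplyr::bind_cols(out, ctx[, c("external_cluster_max",
                                           "structure_preserved")]))
    }
  }
  res("VALID", character(0), duplex, crit)
}

#' Detect miRNA-offset RNAs (moRNAs) at a certified locus
#'
#' Reports read clusters lying within the foldback but outside the
#' miRNA/miRNA* duplex that show 5' processing homogeneity >= the criterion
#' (iv) threshold. A cluster is flagged `phased` when its 5' (or 3') end
#' lies within 0-2 nt of the adjacent duplex product's end, the in-phase
#' signature of sequential Dicer cuts.
#'
#' @param stack read-stack tibble.
#' @param duplex one-row tibble from [call_products()].
#' @param fold the precursor `hairpin_fold`.
#' @param config a [criteria_config()].
#' @param max_phase_gap maximum gap (nt) to the duplex for the phased flag.
#' @return tibble of moRNA calls: interval, sequence, count, homogeneity,
#'   `first_nt` (RNA letter), `phased`.
#' @export
detect_mornas <- function(stack, duplex, fold, config = criteria_config(),
                          max_phase_gap = 2L) {
  empty <- tibble(start = integer(), end = integer(), sequence = character(),
                  count = numeric(), homogeneity = numeric(),
                  first_nt = character(), phased = logical())
  loop <- main_hairpin_loop(fold)
  if (is.null(loop) || nrow(stack) == 0) return(empty)
  fb <- foldback_walk(fold, loop$i, loop$j)
  in_fb <- overlap_frac(stack$start, stack$end, fb["a"], fb["b"]) >=
    config$min_read_overlap
  in_dup <- overlap_frac(stack$start, stack$end,
                         duplex$mirna_start, duplex$mirna_end) >=
    config$min_read_overlap
  if (!is.na(duplex$star_start)) {
    in_dup <- in_dup | overlap_frac(stack$start, stack$end,
                                    duplex$star_start, duplex$star_end) >=
      config$min_read_overlap
  }
  cand <- stack[in_fb & !in_dup, ]
  out <- empty
  while (nrow(cand) > 0) {
    cl <- top_cluster(cand, config$cluster_window)
    hom <- homogeneity(cl$rows, cl$start, cl$end, config$min_read_overlap)
    if (hom$fraction >= config$min_homogeneity) {
      dup_ends <- c(duplex$mirna_start, duplex$mirna_end,
                    duplex$star_start, duplex$star_end)
      dup_ends <- dup_ends[!is.na(dup_ends)]
      gap <- min(abs(c(outer(c(cl$start, cl$end), dup_ends, "-"))) - 1L)
      out <- bind_rows(out, tibble(
        start = cl$start, end = cl$end,
        sequence = substr(fold$sequence, cl$start, cl$end),
        count = cl$count, homogeneity = hom$fraction,
        first_nt = as_rna(substr(fold$sequence, cl$start, cl$start)),
        phased = gap >= -1L & gap <= max_phase_gap
      ))
    }
    cand <- filter(cand, abs(.data$start - cl$start) > config$cluster_window)
  }
  arrange(out, .data$start)
}
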