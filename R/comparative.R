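# Family assignment, structural summaries across miRNA sets, the
# first-nucleotide bias test, and cross-genome homology search.

#' Best ungapped pairwise identity between two sequences
#'
#' The two sequences are slid against each other over every ungapped offset;
#' identity is the maximal number of matching positions divided by the
#' length of the longer sequence, in percent (a conservative denominator).
#'
#' @param a,b nucleotide strings.
#' @return percent identity in `[0, 100]`; 100 iff the sequences are
#'   identical.
#' @export
pairwise_identity <- function(a, b) {
  a <- normalize_seq(a); b <- normalize_seq(b)
  stopifnot(nchar(a) > 0, nchar(b) > 0)
  va <- strsplit(a, "")[[1]]; vb <- strsplit(b, "")[[1]]
  na <- length(va); nb <- length(vb)
  best <- 0L
  for (off in seq.int(-(nb - 1L), na - 1L)) {
    ia <- seq.int(max(1L, 1L + off), min(na, nb + off))
    ib <- ia - off
    m <- sum(va[ia] == vb[ib])
    if (m > best) best <- m
  }
  100 * best / max(na, nb)
}

#' Seed region (nucleotides 2-8) of a mature miRNA
#' @param x mature sequence(s), >= 8 nt.
#' @return the 7-mer seed(s).
#' @export
seed_region <- function(x) {
  if (any(nchar(x) < 8)) stop("sequence shorter than 8 nt", call. = FALSE)
  substr(normalize_seq(x), 2, 8)
}

#' Assign mature miRNAs to families
#'
#' Seed mode groups sequences sharing an identical seed (nt 2-8); identity
#' mode links pairs whose best ungapped identity is at least `threshold`
#' percent. Families are the single-linkage closure of qualifying pairs and
#' partition the input; family ids are the lexicographically smallest member
#' locus id, so output is independent of input order.
#'
#' @param matures tibble with `locus_id` and `mature_seq`.
#' @param mode `"seed"` or `"identity"`.
#' @param threshold percent identity threshold for identity mode
#'   (default 85).
#' @return the input with `family_id` and `family_size` columns, ordered by
#'   locus id.
#' @export
assign_families <- function(matures, mode = c("seed", "identity"),
                            threshold = 85) {
  mode <- match.arg(mode)
  matures <- arrange(matures, .data$locus_id)
  n <- nrow(matures)
  seeds <- if (mode == "seed") seed_region(matures$mature_seq)
  edges <- integer(0)
  if (n > 1) {
    if (mode == "seed") {
      for (grp in split(seq_len(n), seeds)) {
        if (length(grp) > 1) {
          edges <- c(edges, rbind(grp[-length(grp)], grp[-1]))
        }
      }
    } else {
      for (i in seq_len(n - 1)) {
        for (j in seq.int(i + 1, n)) {
          if (pairwise_identity(matures$mature_seq[i],
                                matures$mature_seq[j]) >= threshold) {
            edges <- c(edges, i, j)
          }
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(edges) > 0) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  fam <- vapply(seq_len(n), function(i) {
    min(matures$locus_id[comp == comp[i]])
  }, character(1))
  matures |>
    mutate(family_id = fam, mode = mode, threshold = threshold) |>
    group_by(.data$family_id) |>
    mutate(family_size = n()) |>
    ungroup()
}

#' Structural summary of a mature miRNA annotation set
#'
#' @param matures tibble with `locus_id`, `mature_seq`, `star_seq`, `arm`
#'   (5p/3p), `mature_rpm`, `star_rpm`, optionally `foldback_length` and
#'   `set_label`.
#' @return object of class `mirna_structural_summary`: mature/star length
#'   histograms, first-nucleotide compositions (U/A/C/G fractions, summing
#'   to 1), 3p arm preference, foldback-length mean, and the mean over loci
#'   of the mature/star abundance ratio (star-zero loci excluded and
#'   counted). Has [tidy()], [glance()] and [autoplot()] methods.
#' @export
structural_summary <- function(matures) {
  if (nrow(matures) == 0) stop("empty annotation set", call. = FALSE)
  first_comp <- function(seqs) {
    f <- as_rna(substr(normalize_seq(seqs), 1, 1))
    counts <- table(factor(f, levels = c("U", "A", "C", "G")))
    as.vector(counts) / length(seqs)
  }
  len_hist <- function(seqs) {
    tibble(length = nchar(seqs)) |>
      group_by(.data$length) |>
      summarise(n = n(), .groups = "drop")
  }
  has_star_rpm <- "star_rpm" %in% names(matures) &&
    any(!is.na(matures$star_rpm))
  if (has_star_rpm) {
    ok <- !is.na(matures$star_rpm) & matures$star_rpm > 0 &
      !is.na(matures$mature_rpm)
    ratios <- matures$mature_rpm[ok] / matures$star_rpm[ok]
    ratio_mean <- if (length(ratios)) mean(ratios) else NA_real_
    ratio_excluded <- sum(!ok)
  } else {
    ratio_mean <- NA_real_; ratio_excluded <- nrow(matures)
  }
  fb <- if ("foldback_length" %in% names(matures)) {
    mean(matures$foldback_length, na.rm = TRUE)
  } else {
    NA_real_
  }
  structure(list(
    set_label = matures$set_label[1] %||% "set",
    n = nrow(matures),
    mature_lengths = len_hist(matures$mature_seq),
    star_lengths = len_hist(matures$star_seq[!is.na(matures$star_seq)]),
    mature_first_nt = setNames(first_comp(matures$mature_seq),
                               c("U", "A", "C", "G")),
    star_first_nt = setNames(
      first_comp(matures$star_seq[!is.na(matures$star_seq)]),
      c("U", "A", "C", "G")),
    arm_3p_fraction = mean(matures$arm == "3p"),
    foldback_mean = fb,
    ratio_mean = ratio_mean,
    ratio_excluded = ratio_excluded
  ), class = "mirna_structural_summary")
}

#' @export
glance.mirna_structural_summary <- function(x, ...) {
  mode_len <- x$mature_lengths$length[which.max(x$mature_lengths$n)]
  tibble(
    set_label = x$set_label, n = x$n,
    pct_mature_modal_len =
      100 * max(x$mature_lengths$n) / sum(x$mature_lengths$n),
    modal_mature_length = mode_len,
    mature_first_u = unname(x$mature_first_nt["U"]),
    star_first_u = unname(x$star_first_nt["U"]),
    arm_3p_fraction = x$arm_3p_fraction,
    foldback_mean = x$foldback_mean,
    ratio_mean = x$ratio_mean, ratio_excluded = x$ratio_excluded
  )
}

#' @export
tidy.mirna_structural_summary <- function(x, ...) {
  bind_rows(
    mutate(x$mature_lengths, metric = "mature_length", value = NA_real_),
    mutate(x$star_lengths, metric = "star_length", value = NA_real_),
    tibble(length = NA_integer_, n = NA_integer_,
           metric = paste0("mature_first_", names(x$mature_first_nt)),
           value = unname(x$mature_first_nt)),
    tibble(length = NA_integer_, n = NA_integer_,
           metric = paste0("star_first_", names(x$star_first_nt)),
           value = unname(x$star_first_nt)),
    tibble(length = NA_integer_, n = NA_integer_,
           metric = c("arm_3p_fraction", "foldback_mean", "ratio_mean"),
           value = c(x$arm_3p_fraction, x$foldback_mean, x$ratio_mean))
  ) |>
    mutate(set_label = x$set_label)
}

#' @export
print.mirna_structural_summary <- function(x, ...) {
  g <- glance(x)
  cat("<mirna_structural_summary> ", x$set_label, ": ", x$n, " loci\n",
      sep = "")
  cat(sprintf("modal mature length %d nt (%.1f%%); first-nt U %.0f%% ",
              g$modal_mature_length, g$pct_mature_modal_len,
              100 * g$mature_first_u))
  cat(sprintf("(mature) / %.0f%% (star)\n", 100 * g$star_first_u))
  cat(sprintf("3p arm %.0f%%; mean foldback %.1f nt; mean miRNA/miRNA* %.1f",
              100 * g$arm_3p_fraction, g$foldback_mean, g$ratio_mean))
  cat(" (", x$ratio_excluded, " star-zero loci excluded)\n", sep = "")
  invisible(x)
}

#' Fisher exact test for first-nucleotide U bias between two sets
#'
#' @param u_a,n_a U-count and total for set A.
#' @param u_b,n_b U-count and total for set B.
#' @return tidy one-row tibble with `odds_ratio` and `p.value` from
#'   [stats::fisher.test()] on the 2x2 U-vs-other table.
#' @export
first_nt_bias_test <- function(u_a, n_a, u_b, n_b) {
  if (n_a == 0 || n_b == 0) stop("zero totals", call. = FALSE)
  m <- matrix(c(u_a, n_a - u_a, u_b, n_b - u_b), nrow = 2)
  ft <- fisher.test(m)
  tibble(odds_ratio = unname(ft$estimate), p.value = ft$p.value,
         u_a = u_a, n_a = n_a, u_b = u_b, n_b = n_b)
}

#' Search a genome for homologues of a miRNA/miRNA* pair
#'
#' Both the mature and star sequences are queried against both strands of
#' the target genome, retaining ungapped matches with at most
#' `max_mismatches` mismatches. The region around each match (+/- `flank`
#' nt) is recovered and folded; only hits where the matched region attains
#' at least `min_arm_pairs` opposite-arm pairs in the folded context (i.e.
#' can sit on a hairpin stem) are retained.
#'
#' @param mature,star query sequences (star may be `NA`).
#' @param target_genome assembly tibble of the subject genome.
#' @param max_mismatches maximum mismatches (default 3, i.e. "fewer than
#'   four").
#' @param flank recovered context per side (default 100 nt).
#' @param min_arm_pairs hairpin filter threshold (default 15).
#' @return tibble of retained hits: `query`, `seq_id`, `start`, `end`,
#'   `strand`, `mismatches`, `arm_pairs`.
#' @export
homology_search <- function(mature, star, target_genome, max_mismatches = 3L,
                            flank = 100L, min_arm_pairs = 15L) {
  queries <- purrr::compact(list(
    mature = if (!is.na(mature)) normalize_seq(mature) else NULL,
    star = if (!is.na(star) && length(star)) normalize_seq(star) else NULL))
  hits <- purrr::imap_dfr(queries, function(q, nm) {
    purrr::map_dfr(seq_len(nrow(target_genome)), function(g) {
      chr <- target_genome$sequence[g]
      scan1 <- function(pat, strand) {
        v <- .mismatch_scan(chr, pat, as.integer(max_mismatches))
        if (length(v) == 0) {
          return(tibble(start = integer(), mismatches = integer(),
                        strand = character()))
        }
        tibble(start = v[seq(1, length(v), 2)],
               mismatches = v[seq(2, length(v), 2)],
               strand = strand)
      }
      bind_rows(scan1(q, "+"), scan1(revcomp(q), "-")) |>
        mutate(seq_id = target_genome$id[g], query = nm,
               end = .data$start + nchar(q) - 1L)
    })
  })
  if (nrow(hits) == 0) {
    return(tibble(query = character(), seq_id = character(),
                  start = integer(), end = integer(), strand = character(),
                  mismatches = integer(), arm_pairs = integer()))
  }
  hits$arm_pairs <- vapply(seq_len(nrow(hits)), function(i) {
    chr_len <- target_genome$length[match(hits$seq_id[i], target_genome$id)]
    cs <- max(1L, hits$start[i] - flank)
    ce <- min(chr_len, hits$end[i] + flank)
    ctx <- extract_locus_sequence(target_genome, hits$seq_id[i], cs, ce,
                                  hits$strand[i])
    if (identical(hits$strand[i], "-")) {
      lo <- ce - hits$end[i] + 1L
    } else {
      lo <- hits$start[i] - cs + 1L
    }
    hi <- lo + (hits$end[i] - hits$start[i])
    paired_in_region(fold(ctx), lo, hi)
  }, integer(1))
  hits |>
    filter(.data$arm_pairs >= min_arm_pairs) |>
    select("query", "seq_id", "start", "end", "strand", "mismatches",
           "arm_pairs") |>
    arrange(.data$seq_id, .data$start, .data$query)
}
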