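# Hairpin secondary structure. The default engine is deterministic base-pair
# maximization (AU/GC/GU, minimum hairpin loop of 3 unpaired nt) with a
# leftmost-first tie-break, implemented in C++; a thermodynamic engine could
# be substituted without changing any contract because downstream code only
# consumes the pairing table.

#' Fold a precursor sequence
#'
#' @param sequence nucleotide string (DNA or RNA letters), length >= 10.
#' @param min_loop minimum number of unpaired nucleotides in a hairpin loop.
#' @return an object of class `hairpin_fold`: list with `sequence`
#'   (normalized DNA), `structure` (dot-bracket), `pairs` (integer partner
#'   table, `NA` = unpaired), `n_pairs`, and `energy` (`NA` for the
#'   combinatorial engine).
#' @export
fold <- function(sequence, min_loop = 3L) {
  seq <- normalize_seq(sequence, allow_n = TRUE)
  if (nchar(seq) < 10) stop("sequence shorter than 10 nt", call. = FALSE)
  pt <- .nussinov_pairs(seq, as.integer(min_loop))
  pairs <- ifelse(pt == 0L, NA_integer_, pt)
  structure(
    list(sequence = seq,
         structure = db_from_pairs(pairs),
         pairs = pairs,
         n_pairs = sum(!is.na(pairs)) %/% 2L,
         energy = NA_real_),
    class = "hairpin_fold")
}

db_from_pairs <- function(pairs) {
  db <- rep(".", length(pairs))
  i <- which(!is.na(pairs))
  db[i] <- ifelse(pairs[i] > i, "(", ")")
  paste(db, collapse = "")
}

#' @export
print.hairpin_fold <- function(x, ...) {
  cat("<hairpin_fold> ", nchar(x$sequence), " nt, ", x$n_pairs, " pairs\n",
      sep = "")
  cat(as_rna(x$sequence), "\n", x$structure, "\n", sep = "")
  invisible(x)
}

#' Tidy a hairpin fold into a per-position tibble
#' @param x a `hairpin_fold`.
#' @param ... unused.
#' @return tibble with `position`, `base`, `partner`, `paired`.
#' @export
tidy.hairpin_fold <- function(x, ...) {
  tibble(position = seq_len(nchar(x$sequence)),
         base = strsplit(x$sequence, "")[[1]],
         partner = x$pairs,
         paired = !is.na(x$pairs))
}

#' One-row summary of a hairpin fold
#' @param x a `hairpin_fold`.
#' @param ... unused.
#' @return tibble with `length`, `n_pairs`, `frac_paired`, `n_hairpin_loops`.
#' @export
glance.hairpin_fold <- function(x, ...) {
  tibble(length = nchar(x$sequence), n_pairs = x$n_pairs,
         frac_paired = 2 * x$n_pairs / nchar(x$sequence),
         n_hairpin_loops = nrow(hairpin_loops(x)))
}

#' Count positions in an interval paired to the opposite arm
#'
#' Counts only pairs whose partner lies outside the interval (i.e. across the
#' terminal loop on the opposite arm), never local self-pairs within the
#' interval.
#'
#' @param fold a `hairpin_fold`.
#' @param start,end 1-based inclusive interval on the folded sequence.
#' @return integer count.
#' @export
paired_in_region <- function(fold, start, end) {
  n <- nchar(fold$sequence)
  if (start < 1 || end > n || start > end) {
    stop("interval [", start, ",", end, "] outside the fold (length ", n,
         ")", call. = FALSE)
  }
  p <- fold$pairs[start:end]
  sum(!is.na(p) & (p < start | p > end))
}

# Estimated partner of `pos`, extrapolating through unpaired terminal
# positions from the nearest paired neighbor inside [lo, hi]: along a stem
# partners step by -1 as positions step by +1, so the estimate is
# partner(j) + (j - pos).
partner_at <- function(fold, pos, lo = 1L, hi = nchar(fold$sequence)) {
  if (!is.na(fold$pairs[pos])) return(fold$pairs[pos])
  cand <- seq.int(lo, hi)
  cand <- cand[!is.na(fold$pairs[cand])]
  if (length(cand) == 0) return(NA_integer_)
  j <- cand[order(abs(cand - pos), cand)][1]
  est <- fold$pairs[j] + (j - pos)
  as.integer(min(max(est, 1L), nchar(fold$sequence)))
}

#' Predict the star product of a mature miRNA from the pairing table
#'
#' The star interval is constructed so that each end of the miRNA/miRNA*
#' duplex carries the 2-nt 3' overhang left by RNase-III (Dicer) processing:
#' star start = partner(mature_end - offset) and star end =
#' partner(mature_start) + offset, clamped to the precursor. Unpaired
#' terminal mature positions are resolved by extrapolation from the nearest
#' paired neighbor.
#'
#' @param fold a `hairpin_fold`.
#' @param mirna_start,mirna_end mature product interval (1-based inclusive).
#' @param offset Dicer overhang in nt (default 2).
#' @param min_arm_pairs minimum opposite-arm pairs required of the mature
#'   interval before a star is predicted.
#' @return named integer vector `c(start = , end = )`.
#' @export
predict_star <- function(fold, mirna_start, mirna_end, offset = 2L,
                         min_arm_pairs = 15L) {
  if (paired_in_region(fold, mirna_start, mirna_end) < min_arm_pairs) {
    stop("mature interval has fewer than ", min_arm_pairs,
         " opposite-arm pairs; no star can be predicted", call. = FALSE)
  }
  n <- nchar(fold$sequence)
  s <- partner_at(fold, mirna_end - offset, mirna_start, mirna_end)
  e <- partner_at(fold, mirna_start, mirna_start, mirna_end) + offset
  c(start = max(1L, min(s, n)), end = max(1L, min(as.integer(e), n)))
}

#' Hairpin (terminal) loops of a fold
#'
#' @param fold a `hairpin_fold`.
#' @return tibble with one row per innermost pair `(i, j)` enclosing no other
#'   paired position: columns `i`, `j`, `loop_start`, `loop_end`, `depth`
#'   (number of pairs enclosing the loop, a proxy for stem importance).
#' @export
hairpin_loops <- function(fold) {
  p <- fold$pairs
  idx <- which(!is.na(p) & p > seq_along(p))
  if (length(idx) == 0) {
    return(tibble(i = integer(), j = integer(), loop_start = integer(),
                  loop_end = integer(), depth = integer()))
  }
  paired <- !is.na(p)
  rows <- purrr::map_dfr(idx, function(i) {
    j <- p[i]
    inner <- if (j - i >= 2) paired[(i + 1):(j - 1)] else logical(0)
    if (any(inner)) return(tibble())
    depth <- sum(idx < i & p[idx] > j)
    tibble(i = i, j = j, loop_start = i + 1L, loop_end = j - 1L,
           depth = depth)
  })
  arrange(rows, dplyr::desc(.data$depth), .data$i)
}

# The terminal loop whose enclosing stem is deepest (ties -> leftmost),
# optionally restricted to loops lying within [lo, hi].
main_hairpin_loop <- function(fold, lo = 1L, hi = nchar(fold$sequence)) {
  loops <- hairpin_loops(fold)
  loops <- filter(loops, .data$i >= lo, .data$j <= hi)
  if (nrow(loops) == 0) return(NULL)
  loops[1, ]
}

# Walk outward from a terminal loop pair (i0, j0) along both arms in
# lockstep. The walk stops at the base pair immediately before (a) the first
# run of >= 3 consecutive unpaired nucleotides on either arm, or (b) the
# first position whose partner lies outside the growing stem (another
# secondary structure), or at the sequence ends.
foldback_walk <- function(fold, i0, j0, max_unpaired_run = 3L) {
  p <- fold$pairs
  n <- length(p)
  a <- i0; b <- j0
  repeat {
    # next paired position leftward of a
    a2 <- a - 1L
    while (a2 >= 1L && is.na(p[a2])) a2 <- a2 - 1L
    b2 <- b + 1L
    while (b2 <= n && is.na(p[b2])) b2 <- b2 + 1L
    if (a2 < 1L || b2 > n) break                       # sequence end
    if ((a - a2 - 1L) >= max_unpaired_run) break       # 5'-arm unpaired run
    if ((b2 - b - 1L) >= max_unpaired_run) break       # 3'-arm unpaired run
    if (p[a2] != b2) break                             # branching structure
    a <- a2; b <- b2
  }
  c(a = a, b = b)
}

#' Foldback length of a hairpin locus
#'
#' The locus plus `flank` nt of genomic context on each side (truncated at
#' chromosome ends) is recovered on the transcript strand and folded. The
#' terminal loop enclosing the locus is located and the stem is walked
#' outward on both arms in lockstep; the foldback ends at the first run of
#' three consecutive unpaired nucleotides on either arm, or at the first
#' position whose partner lies outside the growing stem (another secondary
#' structure). The reported length spans both arms plus the terminal loop.
#'
#' @param genome assembly tibble from [read_genome_fasta()].
#' @param locus one-row tibble (or list) with `seq_id`, `start`, `end`,
#'   `strand`.
#' @param flank flanking context in nt (default 100).
#' @param max_unpaired_run arm-wise unpaired-run length that terminates the
#'   foldback (default 3).
#' @return one-row tibble with `foldback_length`, arm and loop spans (in
#'   extended-transcript coordinates), and the flank actually available.
#' @export
foldback_length <- function(genome, locus, flank = 100L,
                            max_unpaired_run = 3L) {
  len <- genome_len(genome, locus$seq_id)
  gs <- max(1L, locus$start - flank)
  ge <- min(len, locus$end + flank)
  ext <- extract_locus_sequence(genome, locus$seq_id, gs, ge, locus$strand)
  # transcript-space span of the original locus within the extension
  lead <- if (identical(locus$strand, "-")) ge - locus$end else locus$start - gs
  lo <- lead + 1L
  hi <- lead + (locus$end - locus$start + 1L)
  f <- fold(ext)
  loop <- main_hairpin_loop(f, lo, hi)
  if (is.null(loop)) {
    stop("extended fold contains no hairpin enclosing the locus", call. = FALSE)
  }
  w <- foldback_walk(f, loop$i, loop$j, max_unpaired_run)
  tibble(
    foldback_length = unname(w["b"] - w["a"] + 1L),
    arm5_start = unname(w["a"]), arm5_end = loop$i,
    loop_start = loop$loop_start, loop_end = loop$loop_end,
    arm3_start = loop$j, arm3_end = unname(w["b"]),
    flank_5p = lo - 1L, flank_3p = nchar(ext) - hi
  )
}
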