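# Independent oracles and small fixture builders used across the suite.

# Max base-pair count by memoized top-down recursion, independent of the
# package's bottom-up DP engine. AU/GC/GU pairs, hairpin loop >= min_loop.
oracle_max_pairs <- function(seq, min_loop = 3L) {
  v <- strsplit(toupper(chartr("U", "T", seq)), "")[[1]]
  can <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    best <- rec(i + 1L, j)
    for (k in seq.int(i + min_loop + 1L, j)) {
      if (can(v[i], v[k])) {
        cand <- 1L + rec(i + 1L, k - 1L) +
          (if (k < j) rec(k + 1L, j) else 0L)
        if (cand > best) best <- cand
      }
    }
    memo[[key]] <- best
    best
  }
  if (length(v) < min_loop + 2L) return(0L)
  rec(1L, length(v))
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A designed hairpin with inert poly-A flanks: flank + arm + loop +
# complement-arm + flank. Arms are {A,G}/{T,C} with G-C outermost pairs so
# the flanks cannot recruit stem bases.
designed_hairpin_seq <- function(stem, loop = 4L, flank = 0L) {
  arm1 <- sample(c("A", "G"), stem, replace = TRUE)
  arm1[c(1, 2, stem - 1, stem)] <- "G"
  arm1s <- paste(arm1, collapse = "")
  paste0(strrep("A", flank), arm1s,
         paste0("G", strrep("A", loop - 1L)), mircert::revcomp(arm1s),
         strrep("A", flank))
}

# a small in-memory genome tibble
toy_genome <- function(...) {
  seqs <- c(...)
  tibble::tibble(id = names(seqs), sequence = unname(seqs),
                 length = nchar(seqs))
}

# stack tibble from (start, length, count) triples on a precursor
toy_stack <- function(precursor, starts, lengths, counts,
                      locus_id = "toy") {
  tibble::tibble(
    locus_id = locus_id, start = as.integer(starts),
    end = as.integer(starts + lengths - 1L), length = as.integer(lengths),
    count = as.integer(counts), sample = "s1",
    sequence = substr(precursor, starts, starts + lengths - 1L),
    multi_hit = FALSE)
}
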