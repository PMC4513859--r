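# Synthetic hairpin loci with known truth. Designed precursors are built so
# that the pair-maximizing fold is provably the designed duplex: the 5' arm
# is drawn over {A,G} and the 3' arm is its exact complement over {T,C}, so
# no within-arm, loop or lead/tail pairing is legal and the only maximal
# structure is the full stem. Controlled exceptions (a U at the mature 5'
# end on the 5p arm; engineered mismatch positions set to A on the 3' arm)
# are re-verified against the designed fold at build time, with redraw on
# ambiguity.

#' Specification of one synthetic locus
#'
#' Defaults are the structural conditions reported for the brown-algal
#' miRNA repertoire: 21-nt matures on the 3p arm with a 5' U, long stems
#' (83 bp + 4-nt loop = 170-nt designed foldback), a 2-nt Dicer offset,
#' 0.9 5' processing homogeneity and a 446-fold miRNA/miRNA* abundance
#' ratio.
#'
#' @param class locus class: `true_mirna`, `weak_palindrome`,
#'   `decoy_no_reads`, `decoy_dominant_outside`, `decoy_bad_duplex`,
#'   `sirna_like`.
#' @param mature_len mature product length, nt.
#' @param stem_len designed stem length, bp (>= mature_len).
#' @param loop_len terminal loop length, nt (>= 3; the loop is the
#'   non-self-pairing tetraloop GAAA when 4).
#' @param mismatches engineered non-pairing positions inside the mature
#'   interval.
#' @param dicer_offset designed 3' overhang, nt.
#' @param homogeneity fraction of mature reads starting at the designed 5'
#'   position (remainder spread over +/- 2 nt).
#' @param ratio mature:star read-count ratio.
#' @param arm arm carrying the mature product (`5p` or `3p`).
#' @param first_nt first nucleotide of the mature product (RNA letter).
#' @param total_reads total mature-product reads.
#' @param context requested genomic context (`intronic`, `UTR`,
#'   `intergenic`).
#' @return a list of class `locus_spec`.
#' @export
locus_spec <- function(class = "true_mirna", mature_len = 21L,
                       stem_len = 83L, loop_len = 4L, mismatches = 2L,
                       dicer_offset = 2L, homogeneity = 0.9, ratio = 446,
                       arm = "3p", first_nt = "U", total_reads = 500L,
                       context = "intronic") {
  stopifnot(stem_len >= mature_len, loop_len >= 3,
            homogeneity > 0, homogeneity <= 1,
            arm %in% c("5p", "3p"),
            class %in% c("true_mirna", "weak_palindrome", "decoy_no_reads",
                         "decoy_dominant_outside", "decoy_bad_duplex",
                         "sirna_like"))
  structure(list(class = class, mature_len = as.integer(mature_len),
                 stem_len = as.integer(stem_len),
                 loop_len = as.integer(loop_len),
                 mismatches = as.integer(mismatches),
                 dicer_offset = as.integer(dicer_offset),
                 homogeneity = homogeneity, ratio = ratio, arm = arm,
                 first_nt = first_nt,
                 total_reads = as.integer(total_reads), context = context),
            class = "locus_spec")
}

comp_base <- c(A = "T", C = "G", G = "C", T = "A")

# Designed product intervals on a lead(2) + arm1 + loop + arm2 + tail(2)
# precursor, in transcript coordinates.
designed_layout <- function(spec) {
  ns <- spec$stem_len; ll <- spec$loop_len; L <- spec$mature_len
  d <- spec$dicer_offset
  a1 <- function(r) 2L + r                    # arm1 index r = 1..ns
  a2 <- function(k) 2L + ns + ll + k          # arm2 index k = 1..ns
  partner_a1 <- function(r) a2(ns + 1L - r)
  p5 <- c(start = a1(1L), end = a1(L))
  p3 <- c(start = partner_a1(L - d), end = partner_a1(1L) + d)
  list(a1 = a1, a2 = a2, partner_a1 = partner_a1, p5 = p5, p3 = p3,
       total = 2L * ns + ll + 4L)
}

#' Build a designed hairpin precursor from a locus specification
#'
#' The returned fold is verified to be the unique pair-maximizing structure
#' of the sequence (the generator redraws the stem on ambiguity, up to a
#' retry bound).
#'
#' @param spec a [locus_spec()]. Uses the current RNG state; seed upstream.
#' @param max_retries redraw bound.
#' @return list: `sequence`, `fold` (a verified `hairpin_fold`),
#'   `mature` / `star` intervals (named vectors, transcript coords),
#'   `arm`, `expected_arm_pairs`, `spec`.
#' @export
build_hairpin <- function(spec, max_retries = 25L) {
  lay <- designed_layout(spec)
  ns <- spec$stem_len; ll <- spec$loop_len; L <- spec$mature_len
  d <- spec$dicer_offset
  first_dna <- chartr("U", "T", spec$first_nt)
  blunt <- identical(spec$class, "decoy_bad_duplex")
  # mismatch positions: arm1 interior, away from the duplex-end anchors;
  # beyond a third of the mature the substitution runs destabilize the
  # designed fold, so the builder refuses rather than loop on redraws
  mm_ok <- setdiff(seq.int(3L, L - d - 2L), c(1L, 2L, L - d, L))
  if (spec$mismatches > 0 &&
      (length(mm_ok) < spec$mismatches || spec$mismatches > L %/% 3)) {
    stop("too many mismatches for this mature length", call. = FALSE)
  }
  mm_pos <- if (spec$mismatches > 0) {
    mm_ok[round(seq(1, length(mm_ok), length.out = spec$mismatches))]
  } else {
    integer(0)
  }
  for (try in seq_len(max_retries)) {
    arm1 <- sample(c("A", "G"), ns, replace = TRUE)
    if (spec$arm == "3p") {
      # the product 5' nt sits at the partner of arm1[L - d]
      arm1[L - d] <- comp_base[[first_dna]]
      arm1[1:2] <- "G"   # G-C outermost pairs: inert to A-rich flanks
    } else {
      arm1[2L] <- "G"
      arm1[1L] <- first_dna                 # mature starts the 5p arm
    }
    arm2 <- rev(unname(comp_base[arm1]))     # exact antiparallel complement
    if (length(mm_pos)) {
      # symmetric substitutions that can pair nothing across the arms
      # (C on the purine arm, A on the pyrimidine arm), so engineered
      # mismatches cannot be rescued by register-shifted refolding
      arm1[mm_pos] <- "C"
      arm2[ns + 1L - mm_pos] <- "A"
    }
    seq <- paste0("AA", paste(arm1, collapse = ""),
                  paste0("G", strrep("A", ll - 1L)),
                  paste(arm2, collapse = ""), "AA")
    f <- fold(seq)
    designed <- rep(NA_integer_, lay$total)
    for (r in setdiff(seq_len(ns), mm_pos)) {
      designed[lay$a1(r)] <- lay$partner_a1(r)
      designed[lay$partner_a1(r)] <- lay$a1(r)
    }
    ok <- identical(f$pairs, designed)
    if (ok) {
      mature <- if (spec$arm == "3p") lay$p3 else lay$p5
      star <- if (spec$arm == "3p") lay$p5 else lay$p3
      if (blunt) {
        # reads will be placed blunt (no overhang); intervals reflect that
        p3b <- c(start = lay$partner_a1(L), end = lay$partner_a1(1L))
        if (spec$arm == "3p") mature <- p3b else star <- p3b
      }
      exp_pairs <- if (spec$arm == "3p" && !blunt) {
        L - d - spec$mismatches
      } else {
        L - spec$mismatches
      }
      return(list(sequence = seq, fold = f, mature = mature, star = star,
                  arm = spec$arm, mismatch_positions = mm_pos,
                  expected_arm_pairs = exp_pairs, spec = spec))
    }
  }
  stop("could not realize an unambiguous designed fold in ", max_retries,
       " draws", call. = FALSE)
}

# Deterministic allocation of `total` reads over 5' offsets:
# `homogeneity` at the modal position, remainder split over +/-1, +/-2.
spread_counts <- function(total, homogeneity) {
  modal <- round(total * homogeneity)
  rest <- total - modal
  side <- c(rep(rest %/% 4, 4))
  extra <- rest - sum(side)
  if (extra > 0) side[seq_len(extra)] <- side[seq_len(extra)] + 1L
  counts <- c(side[1], side[2], modal, side[3], side[4])
  names(counts) <- c("-2", "-1", "0", "1", "2")
  counts[counts > 0]
}

#' Simulate the read stack of a synthetic locus
#'
#' @param spec a [locus_spec()].
#' @param hairpin result of [build_hairpin()].
#' @param sample sample id.
#' @return tibble of reads (`sequence`, `count`, `sample`) drawn from the
#'   precursor in transcript space; empty for `decoy_no_reads`.
#' @export
simulate_reads <- function(spec, hairpin, sample = "sim") {
  seq <- hairpin$sequence
  L <- spec$mature_len
  read_at <- function(start, count) {
    tibble(sequence = substr(seq, start, start + L - 1L), count = count,
           sample = sample)
  }
  m <- hairpin$mature; s <- hairpin$star
  star_n <- max(1L, as.integer(round(spec$total_reads / spec$ratio)))
  out <- switch(
    spec$class,
    decoy_no_reads = tibble(sequence = character(), count = integer(),
                            sample = character()),
    sirna_like = {
      tri <- function(start, total) {
        w <- c(0.15, 0.2, 0.3, 0.2, 0.15)
        cnt <- pmax(1L, as.integer(round(total * w)))
        purrr::map2_dfr(start + (-2:2), cnt, read_at)
      }
      bind_rows(tri(m["start"], round(spec$total_reads * 0.8)),
                tri(s["start"], round(spec$total_reads * 0.2)))
    },
    decoy_dominant_outside = {
      lay <- designed_layout(spec)
      loop_mid <- 2L + spec$stem_len + (spec$loop_len + 1L) %/% 2L
      bind_rows(
        purrr::map2_dfr(m["start"] + (-2:2),
                        spread_counts(50L, spec$homogeneity), read_at),
        read_at(s["start"], 5L),
        read_at(loop_mid - (L %/% 2), 500L)  # dominant cluster in the loop
      )
    },
    { # true_mirna, weak_palindrome, decoy_bad_duplex
      bind_rows(
        purrr::map2_dfr(m["start"] + (-2:2),
                        spread_counts(spec$total_reads, spec$homogeneity),
                        read_at),
        read_at(s["start"], star_n)
      )
    })
  out |>
    group_by(.data$sequence, .data$sample) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    select("sequence", "count", "sample")
}

# expected classification of a spec under the default criteria, derived
# analytically from the generator parameters
expected_truth <- function(spec, config = criteria_config()) {
  switch(spec$class,
    decoy_no_reads = list(verdict = "REJECT", codes = "NO_READS"),
    decoy_dominant_outside = list(verdict = "REJECT",
                                  codes = "DOMINANT_OUTSIDE_MIRNA"),
    decoy_bad_duplex = list(verdict = "REJECT", codes = "DUPLEX_INVALID"),
    sirna_like = list(verdict = "REJECT", codes = "LOW_HOMOGENEITY"),
    weak_palindrome = list(verdict = "WEAK", codes = "EXTENDED_PALINDROME"),
    {
      d <- spec$dicer_offset
      pairs_ok <- (spec$mature_len - d * (spec$arm == "3p") -
                     spec$mismatches) >= config$min_arm_pairs
      hom_ok <- spec$homogeneity >= config$min_homogeneity
      if (pairs_ok && hom_ok && d == config$required_offset) {
        list(verdict = "VALID", codes = "")
      } else if (!pairs_ok || d != config$required_offset) {
        list(verdict = "REJECT", codes = "DUPLEX_INVALID")
      } else {
        list(verdict = "REJECT", codes = "LOW_HOMOGENEITY")
      }
    })
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Background between planted loci is pairing-inert (poly-A): under a
# base-pair maximization engine, complex background would let flank bases
# "peel" designed stem pairs into flank pairings (each re-routing nets one
# extra pair), shredding planted hairpins in extended folds. Inert flanks
# keep every designed structure the provable optimum of its neighborhood;
# the cost in realism is documented in the methods vignette.
background_dna <- function(n) strrep("A", n)

#' Configuration for a synthetic dataset
#'
#' @param n_true,n_no_reads,n_dominant_outside,n_bad_duplex,n_sirna,n_weak
#'   locus counts per class.
#' @param n_chromosomes chromosomes to distribute loci over.
#' @param spec_overrides named list of [locus_spec()] arguments applied to
#'   every locus (class-specific behaviour is still driven by `class`).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_true = 20L, n_no_reads = 5L,
                              n_dominant_outside = 5L, n_bad_duplex = 5L,
                              n_sirna = 5L, n_weak = 2L,
                              n_chromosomes = 2L, spec_overrides = list()) {
  structure(list(n_true = n_true, n_no_reads = n_no_reads,
                 n_dominant_outside = n_dominant_outside,
                 n_bad_duplex = n_bad_duplex, n_sirna = n_sirna,
                 n_weak = n_weak, n_chromosomes = n_chromosomes,
                 spec_overrides = spec_overrides),
            class = "simulation_config")
}

#' Generate a synthetic genome, annotation, read library and truth table
#'
#' Plants non-overlapping designed hairpin loci (and decoys of every class)
#' in uniform-random background DNA, synthesizes host genes realizing the
#' requested genomic contexts, simulates the read library, and records a
#' machine-readable truth table with the expected verdict and reason codes
#' of every locus under the default criteria. Identical `(config, seed)`
#' yield identical output.
#'
#' @param config a [simulation_config()].
#' @param seed integer seed controlling every random draw.
#' @return list of class `mircert_dataset`: `genome`, `features`, `reads`,
#'   `candidates`, `truth`, `hairpins` (per-locus design details), `seed`.
#' @export
generate_dataset <- function(config = simulation_config(), seed = 1L) {
  withr::with_seed(as.integer(seed), generate_dataset_impl(config))
}

generate_dataset_impl <- function(config) {
  classes <- c(rep("true_mirna", config$n_true),
               rep("decoy_no_reads", config$n_no_reads),
               rep("decoy_dominant_outside", config$n_dominant_outside),
               rep("decoy_bad_duplex", config$n_bad_duplex),
               rep("sirna_like", config$n_sirna),
               rep("weak_palindrome", config$n_weak))
  n_loci <- length(classes)
  if (n_loci == 0) stop("no loci requested", call. = FALSE)
  # shuffle class order so classes mix across chromosomes/contexts
  classes <- classes[sample.int(n_loci)]
  contexts <- rep(c("intronic", "intronic", "intergenic", "intronic", "UTR"),
                  length.out = n_loci)
  strands <- rep(c("+", "-", "+"), length.out = n_loci)
  strands[classes == "weak_palindrome"] <- "+"

  specs <- lapply(classes, function(cl) {
    do.call(locus_spec, c(list(class = cl), config$spec_overrides))
  })
  # draw hairpins whose simulated reads occur in no other precursor (in
  # either direction), so reads map back uniquely to their own locus
  hairpins <- vector("list", n_loci)
  locus_reads <- vector("list", n_loci)
  occurs_in <- function(reads, precursor) {
    any(vapply(reads, function(r) {
      length(exact_occurrences(precursor, r)) > 0
    }, logical(1)))
  }
  for (i in seq_len(n_loci)) {
    for (redraw in 1:25) {
      hp <- build_hairpin(specs[[i]])
      rs <- unique(simulate_reads(specs[[i]], hp)$sequence)
      clash <- FALSE
      for (j in seq_len(i - 1)) {
        if (occurs_in(rs, hairpins[[j]]$sequence) ||
            occurs_in(locus_reads[[j]], hp$sequence)) {
          clash <- TRUE
          break
        }
      }
      if (!clash) {
        hairpins[[i]] <- hp
        locus_reads[[i]] <- rs
        break
      }
    }
    if (is.null(hairpins[[i]])) {
      stop("could not draw a collision-free locus", call. = FALSE)
    }
  }

  per_chrom <- split(seq_len(n_loci),
                     rep(seq_len(config$n_chromosomes), length.out = n_loci))
  genome_rows <- list()
  locus_rows <- list()
  feat_rows <- list()
  read_rows <- list()
  for (ci in seq_along(per_chrom)) {
    chr <- sprintf("chr%d", ci)
    pieces <- character(0)
    pos <- 0L
    for (i in per_chrom[[ci]]) {
      hp <- hairpins[[i]]
      spec <- specs[[i]]
      gap <- 400L + sample.int(400L, 1L)
      plen <- nchar(hp$sequence)
      gseq <- if (strands[i] == "-") revcomp(hp$sequence) else hp$sequence
      # minus-strand loci read their flanks reverse-complemented, so the
      # inert pad must be poly-T on the genomic strand
      pad <- if (strands[i] == "-") 200L else 0L
      if (pad > 0) gseq <- paste0(strrep("T", pad), gseq, strrep("T", pad))
      if (spec$class == "weak_palindrome") {
        # 5'-side extension: a degenerate palindromic copy of the 3' arm
        # that seeds extra sRNA clusters (weak loci are planted on +).
        # The two windows the flank clusters are read from are overwritten
        # with sequences alien to every precursor, so those reads map only
        # in the extended region.
        pal <- mutate_seq(revcomp(substr(hp$sequence, plen - 150L, plen)),
                          rate = 0.2)
        L <- spec$mature_len
        for (off in c(32L, 92L)) {
          substr(pal, off, off + L - 1L) <- paste(
            sample(c("C", "G", "T"), L, replace = TRUE), collapse = "")
        }
        lead_bg <- background_dna(max(0L, gap - nchar(pal)))
        pieces <- c(pieces, lead_bg, pal)
        pos <- pos + nchar(lead_bg) + nchar(pal)
      } else {
        bg <- background_dna(gap)
        pieces <- c(pieces, bg)
        pos <- pos + gap
      }
      start <- pos + pad + 1L
      end <- start + plen - 1L
      pieces <- c(pieces, gseq)
      pos <- pos + nchar(gseq)
      locus_rows[[i]] <- tibble(
        locus_id = sprintf("syn%03d", i), seq_id = chr,
        start = start, end = end, strand = strands[i],
        class = spec$class, context = contexts[i])
      reads_i <- simulate_reads(spec, hp)
      if (spec$class == "weak_palindrome") {
        # two upstream (transcript 5') clusters stronger than the star
        star_n <- max(1L, as.integer(round(spec$total_reads / spec$ratio)))
        up <- function(offset, count) {
          tibble(sequence = substr(paste(pieces, collapse = ""),
                                   start - offset,
                                   start - offset + spec$mature_len - 1L),
                 count = count, sample = "sim")
        }
        reads_i <- bind_rows(reads_i, up(120L, star_n * 5L + 10L),
                             up(60L, star_n * 2L + 5L))
      }
      read_rows[[i]] <- reads_i
    }
    pieces <- c(pieces, background_dna(600L))
    genome_rows[[ci]] <- tibble(id = chr,
                                sequence = paste(pieces, collapse = ""))
  }
  genome <- bind_rows(genome_rows) |> mutate(length = nchar(.data$sequence))
  candidates <- bind_rows(locus_rows) |> arrange(.data$locus_id)

  # synthesize host genes realizing the requested contexts
  gi <- 0L
  for (i in seq_len(nrow(candidates))) {
    x <- candidates[i, ]
    if (x$context == "intergenic") next
    gi <- gi + 1L
    gene_id <- sprintf("gene%03d", gi)
    g_start <- max(1L, x$start - 300L)
    g_end <- min(genome$length[genome$id == x$seq_id], x$end + 300L)
    g_strand <- if (gi %% 10 == 0) setdiff(c("+", "-"), x$strand) else x$strand
    base <- tibble(seq_id = x$seq_id, source = "sim", strand = g_strand,
                   parent = NA_character_)
    mrna_id <- paste0(gene_id, ".t1")
    feat_rows[[length(feat_rows) + 1L]] <- bind_rows(
      mutate(base, type = "gene", start = g_start, end = g_end, id = gene_id),
      mutate(base, type = "mRNA", start = g_start, end = g_end, id = mrna_id,
             parent = gene_id),
      if (x$context == "intronic") {
        bind_rows(
          mutate(base, type = "exon", start = g_start, end = x$start - 60L,
                 id = paste0(mrna_id, ".e1"), parent = mrna_id),
          mutate(base, type = "exon", start = x$end + 60L, end = g_end,
                 id = paste0(mrna_id, ".e2"), parent = mrna_id))
      } else { # UTR
        bind_rows(
          mutate(base, type = "exon", start = g_start, end = g_end,
                 id = paste0(mrna_id, ".e1"), parent = mrna_id),
          mutate(base, type = "three_prime_UTR", start = x$start - 20L,
                 end = g_end, id = paste0(mrna_id, ".utr"),
                 parent = mrna_id))
      })
  }
  features <- bind_rows(feat_rows)
  features <- bind_rows(features, derive_introns(features))

  reads <- bind_rows(read_rows) |>
    group_by(.data$sequence, .data$sample) |>
    summarise(count = sum(.data$count), .groups = "drop") |>
    select("sequence", "count", "sample") |>
    arrange(dplyr::desc(.data$count), .data$sequence)

  truth <- purrr::map_dfr(seq_len(n_loci), function(i) {
    x <- filter(candidates, .data$locus_id == sprintf("syn%03d", i))
    exp <- expected_truth(specs[[i]])
    mutate(x, expected_verdict = exp$verdict, expected_codes = exp$codes,
           mature_len = specs[[i]]$mature_len,
           homogeneity = specs[[i]]$homogeneity,
           mismatches = specs[[i]]$mismatches,
           arm = specs[[i]]$arm)
  }) |> arrange(.data$locus_id)

  structure(list(genome = genome, features = features, reads = reads,
                 candidates = select(candidates, "locus_id", "seq_id",
                                     "start", "end", "strand"),
                 truth = truth,
                 hairpins = setNames(hairpins, sprintf("syn%03d",
                                                       seq_len(n_loci)))),
            class = "mircert_dataset")
}

# point mutations at a fixed rate (used to degrade planted palindromes)
mutate_seq <- function(seq, rate = 0.2) {
  v <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(v)) < rate)
  v[hit] <- vapply(v[hit], function(b) {
    sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  }, character(1))
  paste(v, collapse = "")
}

#' Write a synthetic dataset to disk
#'
#' Emits genome FASTA, GFF3 annotation, collapsed reads FASTA, candidate
#' BED and a truth TSV.
#'
#' @param dataset a `mircert_dataset`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(dataset$genome, file.path(dir, "genome.fa"))
  write_gff3_features(dataset$features, file.path(dir, "annotation.gff3"))
  write_collapsed_reads(dataset$reads, file.path(dir, "reads.fa"))
  write_candidate_bed(dataset$candidates, file.path(dir, "candidates.bed"))
  readr::write_tsv(dataset$truth, file.path(dir, "truth.tsv"))
  invisible(dir)
}

# plain GFF3 emitter for feature tibbles (deterministic row order)
write_gff3_features <- function(features, path) {
  features <- arrange(features, .data$seq_id, .data$start, .data$type,
                      .data$id)
  attrs <- ifelse(is.na(features$parent),
                  sprintf("ID=%s", features$id),
                  sprintf("ID=%s;Parent=%s", features$id, features$parent))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$seq_id, features$source, features$type,
                   features$start, features$end, features$strand, attrs)
  writeLines(c("##gff-version 3", lines), path)
  invisible(path)
}
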