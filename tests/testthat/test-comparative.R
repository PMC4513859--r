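test_that("pairwise identity slides ungapped and normalizes by the longer", {
  a <- "TGACTAGATGATCGATGGACA"
  expect_equal(pairwise_identity(a, a), 100)
  b <- a
  substr(b, 3, 3) <- "C"; substr(b, 10, 10) <- "C"; substr(b, 16, 16) <- "A"
  expect_equal(pairwise_identity(a, b), 100 * 18 / 21)
  # a 20-nt prefix aligns at offset 0 with 20 matches over 21
  expect_equal(pairwise_identity(a, substr(a, 1, 20)), 100 * 20 / 21)
  # symmetry
  expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
  # 100 iff identical
  expect_lt(pairwise_identity(a, b), 100)
})

test_that("family assignment is single-linkage and order-invariant", {
  base <- "TGACTAGATGATCGATGGACA"
  mut <- function(s, pos, to) { substr(s, pos, pos) <- to; s }
  seqs <- tibble::tibble(
    locus_id = c("l1", "l2", "l3", "l4"),
    mature_seq = c(base,
                   mut(base, 12, "C"),          # seed differs at nt 12? no: nt2-8 intact
                   mut(base, 3, "C"),           # seed broken
                   "AAAAAAAAGGGGGGGGAAAAA"))
  fam_seed <- assign_families(seqs, mode = "seed")
  expect_equal(fam_seed$family_id[fam_seed$locus_id %in% c("l1", "l2")],
               c("l1", "l1"))
  expect_equal(fam_seed$family_id[fam_seed$locus_id == "l3"], "l3")

  # identity mode at the 85% boundary: 18/21 = 85.7 joins
  id_fam <- assign_families(seqs[1:2, ], mode = "identity", threshold = 85)
  three_mut <- Reduce(function(s, p) mut(s, p, "C"), c(3, 12, 15), base)
  pairboundary <- assign_families(
    tibble::tibble(locus_id = c("x", "y"),
                   mature_seq = c(base, three_mut)),
    mode = "identity", threshold = 85)
  expect_equal(unique(pairboundary$family_id), "x")

  # transitive closure: A~B, B~C but A!~C
  a <- base
  b <- Reduce(function(s, p) mut(s, p, "C"), c(3, 5), base)      # 2 diffs to a
  c2 <- Reduce(function(s, p) mut(s, p, "C"), c(3, 5, 8, 10), base) # 2 to b, 4 to a
  expect_gte(pairwise_identity(a, b), 90)
  expect_gte(pairwise_identity(b, c2), 90)
  expect_lt(pairwise_identity(a, c2), 85)
  tri <- assign_families(
    tibble::tibble(locus_id = c("A", "B", "C"), mature_seq = c(a, b, c2)),
    mode = "identity", threshold = 90)
  expect_equal(length(unique(tri$family_id)), 1L)

  # permutation invariance and nestedness under threshold relaxation
  shuf <- assign_families(
    tibble::tibble(locus_id = c("C", "A", "B"), mature_seq = c(c2, a, b)),
    mode = "identity", threshold = 90)
  expect_equal(dplyr::arrange(shuf, locus_id)$family_id,
               dplyr::arrange(tri, locus_id)$family_id)
  tight <- assign_families(
    tibble::tibble(locus_id = c("A", "B", "C"), mature_seq = c(a, b, c2)),
    mode = "identity", threshold = 95)
  # lowering the threshold never splits a family
  expect_gte(length(unique(tight$family_id)),
             length(unique(tri$family_id)))

  expect_error(assign_families(
    tibble::tibble(locus_id = "s", mature_seq = "ACGTACG"), mode = "seed"),
    "shorter")
})

test_that("structural summaries compute compositions, arms and ratios", {
  mat <- tibble::tibble(
    locus_id = c("l1", "l2"),
    mature_seq = c("TGACTAGATGATCGATGGACA", "AGACTAGATGATCGATGGACAA"),
    star_seq = c("TGTCCATCGATCATCTAGTCA", "TTGTCCATCGATCATCTAGTC"),
    arm = c("3p", "3p"),
    mature_rpm = c(1000, 100), star_rpm = c(10, 10),
    foldback_length = c(170, 150), set_label = "toy")
  s <- structural_summary(mat)
  g <- glance(s)
  expect_equal(unname(s$mature_first_nt["U"]), 0.5)
  expect_equal(sum(s$mature_first_nt), 1)
  expect_equal(sum(s$star_first_nt), 1)
  expect_equal(g$arm_3p_fraction, 1)
  expect_equal(g$foldback_mean, 160)
  # mean of per-locus ratios: (100 + 10) / 2
  expect_equal(g$ratio_mean, 55)
  expect_equal(s$mature_lengths$n, c(1L, 1L))
  expect_error(structural_summary(mat[0, ]), "empty")

  # star-zero loci are excluded from the ratio and counted
  mat$star_rpm[2] <- 0
  s2 <- structural_summary(mat)
  expect_equal(s2$ratio_mean, 100)
  expect_equal(s2$ratio_excluded, 1L)
})

test_that("first-nucleotide bias test matches exact hypergeometric", {
  same <- first_nt_bias_test(30, 60, 30, 60)
  expect_equal(same$p.value, 1)
  strong <- first_nt_bias_test(59, 64, 16, 64)
  expect_lt(strong$p.value, 0.001)
  expect_equal(strong$p.value,
               fisher.test(matrix(c(59, 5, 16, 48), 2))$p.value)
  extreme <- first_nt_bias_test(10, 10, 0, 10)
  expect_lt(extreme$p.value, 0.001)
  expect_true(is.infinite(extreme$odds_ratio) || extreme$odds_ratio > 100)
  expect_error(first_nt_bias_test(0, 0, 5, 10), "zero")
})

test_that("homology search is mismatch-bounded and hairpin-filtered", {
  set.seed(47)
  # stem short enough that the partner arm falls inside the recovered
  # +/- 100 nt context
  hp <- build_hairpin(locus_spec(mismatches = 0, stem_len = 40))
  mature <- substr(hp$sequence, hp$mature["start"], hp$mature["end"])
  star <- substr(hp$sequence, hp$star["start"], hp$star["end"])

  # planted full precursor: both queries hit, zero mismatches
  g <- toy_genome(chr1 = paste0(strrep("A", 150), hp$sequence,
                                strrep("A", 150)))
  hits <- homology_search(mature, star, g)
  exact <- hits[hits$mismatches == 0, ]
  expect_true(all(c("mature", "star") %in% exact$query))
  expect_true(all(hits$arm_pairs >= 15))

  # diverged copy: 3 mismatches retained, 4 excluded
  mut_at <- function(s, k) {
    v <- strsplit(s, "")[[1]]
    v[k] <- ifelse(v[k] == "T", "C", "T")
    paste(v, collapse = "")
  }
  m3 <- Reduce(mut_at, c(5, 9, 13), mature)
  m4 <- Reduce(mut_at, c(5, 9, 13, 17), mature)
  expect_equal(unique(homology_search(m3, NA, g)$mismatches), 3L)
  expect_equal(nrow(homology_search(m4, NA, g, max_mismatches = 3)), 0L)

  # a match in a pairing-free context is filtered by the hairpin test
  gflat <- toy_genome(chr1 = paste0(strrep("A", 150), mature,
                                    strrep("A", 150)))
  expect_equal(nrow(homology_search(mature, NA, gflat)), 0L)

  # minus-strand copies are found
  grc <- toy_genome(chr1 = paste0(strrep("T", 150), revcomp(hp$sequence),
                                  strrep("T", 150)))
  hits_rc <- homology_search(mature, NA, grc)
  expect_gte(sum(hits_rc$strand == "-" & hits_rc$mismatches == 0), 1L)

  # with zero mismatches allowed, hits coincide with the exact matcher
  exact <- naive_genome_align(tibble::tibble(sequence = mature, count = 1L),
                              g)
  h0 <- homology_search(mature, NA, g, max_mismatches = 0)
  expect_equal(h0$start, exact$start[exact$strand == "+"])
})
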