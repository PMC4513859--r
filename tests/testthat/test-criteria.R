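# Product calling and the four validation criteria on designed loci.

make_true_locus <- function(seed = 101, ...) {
  set.seed(seed)
  spec <- locus_spec(...)
  hp <- build_hairpin(spec)
  reads <- simulate_reads(spec, hp)
  stack <- map_to_precursor(reads, hp$sequence, "toy")
  list(spec = spec, hp = hp, reads = reads, stack = stack)
}

test_that("the most abundant arm product is called the miRNA", {
  x <- make_true_locus()
  dup <- call_products(x$stack, x$hp$fold)
  expect_equal(dup$mirna_arm, "3p")
  expect_equal(dup$mirna_start, unname(x$hp$mature["start"]))
  expect_equal(dup$mirna_end, unname(x$hp$mature["end"]))
  expect_true(dup$star_observed)
  expect_equal(dup$star_start, unname(x$hp$star["start"]))
  expect_gte(dup$mirna_count, dup$star_count)
})

test_that("equal arm counts break the tie to 5p", {
  x <- make_true_locus(mismatches = 0)
  pre <- x$hp$sequence
  stack <- toy_stack(pre,
                     starts = c(x$hp$star["start"], x$hp$mature["start"]),
                     lengths = c(21, 21), counts = c(100, 100))
  dup <- call_products(stack, x$hp$fold)
  expect_equal(dup$mirna_arm, "5p")
})

test_that("a one-armed stack gets a predicted star with zero reads", {
  x <- make_true_locus(mismatches = 0)
  stack <- toy_stack(x$hp$sequence, x$hp$mature["start"], 21, 200)
  dup <- call_products(stack, x$hp$fold)
  expect_false(dup$star_observed)
  expect_equal(dup$star_count, 0L)
  expect_equal(dup$star_start, unname(x$hp$star["start"]))
  expect_equal(dup$star_end, unname(x$hp$star["end"]))
})

test_that("homogeneity sits exactly on the 66% boundary arithmetic", {
  x <- make_true_locus(mismatches = 0)
  pre <- x$hp$sequence
  m <- x$hp$mature
  cfg <- criteria_config()
  st1 <- toy_stack(pre, c(m["start"], m["start"] + 1), c(21, 21), c(8, 4))
  h1 <- homogeneity(st1, m["start"], m["end"])
  expect_equal(h1$fraction, 8 / 12)
  expect_true(h1$fraction >= cfg$min_homogeneity)

  st2 <- toy_stack(pre, c(m["start"], m["start"] + 2), c(21, 21), c(65, 35))
  h2 <- homogeneity(st2, m["start"], m["end"])
  expect_equal(h2$fraction, 0.65)
  expect_false(h2$fraction >= cfg$min_homogeneity)

  st3 <- toy_stack(pre, m["start"], 21, 1)
  expect_equal(homogeneity(st3, m["start"], m["end"])$fraction, 1)

  h0 <- homogeneity(st3, unname(x$hp$star["start"]),
                    unname(x$hp$star["end"]))
  expect_equal(h0$fraction, 0)
  expect_false(h0$defined)
})

test_that("a designed perfect locus passes all four criteria", {
  x <- make_true_locus()
  dup <- call_products(x$stack, x$hp$fold)
  rep <- evaluate_criteria(dup, x$stack, x$hp$fold)
  expect_true(rep$pass_i && rep$pass_ii && rep$pass_iii && rep$pass_iv)
  expect_equal(rep$arm_pairs, x$hp$expected_arm_pairs)
  expect_equal(rep$homogeneity, 0.9)
})

test_that("blunt duplex ends fail the Dicer-offset criterion only", {
  x <- make_true_locus(class = "decoy_bad_duplex", mismatches = 0)
  dup <- call_products(x$stack, x$hp$fold)
  rep <- evaluate_criteria(dup, x$stack, x$hp$fold)
  expect_true(rep$pass_i)
  expect_true(rep$pass_ii)
  expect_false(rep$pass_iii)
  expect_true(rep$pass_iv)
})

test_that("a star without supporting reads fails criterion ii", {
  x <- make_true_locus(mismatches = 0)
  stack <- toy_stack(x$hp$sequence, x$hp$mature["start"], 21, 200)
  dup <- call_products(stack, x$hp$fold)
  rep <- evaluate_criteria(dup, stack, x$hp$fold)
  expect_false(rep$pass_ii)
  expect_equal(rep$star_reads, 0L)
  expect_true(rep$pass_iii)  # structure-decided, despite no star coverage
})

test_that("classification reproduces the rejection taxonomy", {
  x <- make_true_locus()
  locus <- tibble::tibble(locus_id = "toy")
  empty <- x$stack[0, ]
  expect_equal(classify(locus, empty, x$hp$fold)$reason_codes, "NO_READS")

  # dominant read in the loop
  loop_read <- toy_stack(x$hp$sequence, 2L + x$hp$spec$stem_len - 8L, 21,
                         5000)
  st <- dplyr::bind_rows(x$stack, loop_read)
  cls <- classify(locus, st, x$hp$fold)
  expect_equal(cls$verdict, "REJECT")
  expect_equal(cls$reason_codes, "DOMINANT_OUTSIDE_MIRNA")

  # clean locus
  ok <- classify(locus, x$stack, x$hp$fold)
  expect_equal(ok$verdict, "VALID")
  expect_equal(ok$reason_codes, "")

  # insufficient pairing
  y <- make_true_locus(mismatches = 7, arm = "5p")
  dup <- classify(locus, y$stack, y$hp$fold)
  expect_equal(dup$verdict, "REJECT")
  expect_match(dup$reason_codes, "DUPLEX_INVALID")
})

test_that("raising the homogeneity threshold never rescues a rejection", {
  for (h in c(0.5, 0.7, 0.95)) {
    x <- make_true_locus(homogeneity = h)
    locus <- tibble::tibble(locus_id = "toy")
    thresholds <- c(0.4, 0.66, 0.9, 0.99)
    verdicts <- vapply(thresholds, function(th) {
      classify(locus, x$stack, x$hp$fold,
               criteria_config(min_homogeneity = th))$verdict
    }, character(1))
    # once rejected, stays rejected as the threshold rises
    expect_true(all(diff(verdicts == "VALID") <= 0), info = h)
  }
})

test_that("classification is invariant under uniform count scaling", {
  x <- make_true_locus(homogeneity = 0.7)
  locus <- tibble::tibble(locus_id = "toy")
  base <- classify(locus, x$stack, x$hp$fold)
  scaled <- x$stack
  scaled$count <- scaled$count * 13L
  again <- classify(locus, scaled, x$hp$fold)
  expect_equal(again$verdict, base$verdict)
  expect_equal(again$reason_codes, base$reason_codes)
  expect_equal(again$homogeneity, base$homogeneity)
})

test_that("the extended-context check flags palindromic neighborhoods", {
  set.seed(31)
  spec <- locus_spec(mismatches = 0)
  hp <- build_hairpin(spec)
  n <- nchar(hp$sequence)
  # clean context: inert flanks, reads confined to the duplex
  g <- toy_genome(chr1 = paste0(strrep("A", 200), hp$sequence,
                                strrep("A", 200)))
  locus <- tibble::tibble(locus_id = "L", seq_id = "chr1", start = 201L,
                          end = 200L + n, strand = "+")
  reads <- simulate_reads(spec, hp)
  stack <- map_to_precursor(reads, hp$sequence, "L")
  dup <- call_products(stack, fold(hp$sequence))
  ctx <- extended_context_check(g, locus, stack, dup, reads = reads)
  expect_false(ctx$weak)
  expect_true(ctx$structure_preserved)

  # an external cluster stronger than the star: weak
  flank_read <- tibble::tibble(
    sequence = substr(as.character(g$sequence), 110, 130),
    count = 50L, sample = "sim")
  g2 <- g
  substr(g2$sequence, 110, 130) <- paste(
    sample(c("G", "C", "T"), 21, replace = TRUE), collapse = "")
  flank_read$sequence <- substr(g2$sequence, 110, 130)
  ctx2 <- extended_context_check(g2, locus, stack, dup,
                                 reads = dplyr::bind_rows(reads, flank_read))
  expect_true(ctx2$weak)
  expect_gt(ctx2$external_cluster_max, dup$star_count)

  # an upstream complement of the miRNA that captures it when the
  # precursor is extended: the duplex is no longer preserved, weak
  mature_seq <- substr(hp$sequence, dup$mirna_start, dup$mirna_end)
  decoy_arm <- revcomp(mature_seq)
  g3 <- toy_genome(chr1 = paste0(strrep("A", 100), decoy_arm,
                                 strrep("A", 30), hp$sequence,
                                 strrep("A", 200)))
  off <- 100L + nchar(decoy_arm) + 30L
  locus3 <- tibble::tibble(locus_id = "L", seq_id = "chr1",
                           start = off + 1L, end = off + n, strand = "+")
  ctx3 <- extended_context_check(g3, locus3, stack, dup, reads = reads)
  expect_true(ctx3$weak)
  expect_false(ctx3$structure_preserved)
})

test_that("moRNA detection reports phased, homogeneous side clusters", {
  set.seed(37)
  spec <- locus_spec(mismatches = 0, arm = "5p", first_nt = "U",
                     stem_len = 70)
  hp <- build_hairpin(spec)
  reads <- simulate_reads(spec, hp)
  stack <- map_to_precursor(reads, hp$sequence, "L")
  dup <- call_products(stack, hp$fold)
  # a crisp cluster abutting the mature 3' end, inside the foldback
  mor_start <- unname(hp$mature["end"]) + 1L
  mor <- toy_stack(hp$sequence, mor_start, 21, 40)
  mor$sample <- "sim"
  out <- detect_mornas(dplyr::bind_rows(stack, mor), dup, hp$fold)
  expect_equal(nrow(out), 1L)
  expect_true(out$phased)
  expect_equal(out$start, mor_start)
  expect_equal(out$homogeneity, 1)

  # diffuse low-homogeneity reads are not reported
  diffuse <- toy_stack(hp$sequence, mor_start + 20 + c(0, 2, 4, 6),
                       rep(18, 4), rep(10, 4))
  out2 <- detect_mornas(dplyr::bind_rows(stack, diffuse), dup, hp$fold)
  expect_equal(nrow(out2), 0L)

  # a crisp cluster 10 nt away is reported but not phased
  far <- toy_stack(hp$sequence, unname(hp$mature["end"]) + 11L, 21, 40)
  out3 <- detect_mornas(dplyr::bind_rows(stack, far), dup, hp$fold)
  expect_false(out3$phased[out3$start == unname(hp$mature["end"]) + 11L])
})
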