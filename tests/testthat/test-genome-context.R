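published_counts <- function() {
  readr::read_tsv(system.file("extdata", "ectocarpus_srna_feature_counts.tsv",
                              package = "mircert"),
                  show_col_types = FALSE)
}

test_that("coverage arithmetic reproduces the published per-class values", {
  tab <- coverage_from_counts(published_counts())
  expect_equal(tab$coverage[tab$feature_class == "rRNA"], 897.39)
  expect_equal(tab$coverage[tab$feature_class == "transposon"], 0.84)
  expect_equal(tab$coverage[tab$feature_class == "tRNA"], 34.61)
  expect_equal(tab$coverage[tab$feature_class == "exon"], 0.14)
  expect_equal(round(genic_read_percent(tab)), 37)
})

test_that("reads are assigned to one class by precedence and conserved", {
  g <- toy_genome(chr1 = strrep("A", 2000))
  feats <- tibble::tibble(
    seq_id = "chr1", source = "s",
    type   = c("gene", "exon", "intron", "rRNA"),
    start  = c(101L, 101L, 301L, 450L),
    end    = c(500L, 300L, 500L, 520L),
    strand = "+", id = paste0("f", 1:4), parent = NA)
  feats <- dplyr::bind_rows(feats, derive_intergenic(feats, g))
  aln <- tibble::tibble(
    sequence = paste0("r", 1:4),
    seq_id = "chr1",
    start = c(150L, 460L, 310L, 1000L),   # exon, rRNA>intron, intron, intergenic
    end   = c(170L, 480L, 330L, 1020L),
    strand = "+", count = c(5L, 7L, 2L, 11L))
  tab <- feature_coverage_table(aln, feats)
  expect_equal(tab$read_count[tab$feature_class == "exon"], 5)
  expect_equal(tab$read_count[tab$feature_class == "rRNA"], 7)
  expect_equal(tab$read_count[tab$feature_class == "intron"], 2)
  expect_equal(tab$read_count[tab$feature_class == "intergenic"], 11)
  # conservation: every read in exactly one class
  expect_equal(sum(tab$read_count), sum(aln$count))
  # disjoint sizes: intron size excludes the rRNA overlap
  expect_equal(tab$cumulative_size_bp[tab$feature_class == "intron"],
               200 - 51)
})

test_that("multi-mapping reads are counted once in 'once' mode", {
  g <- toy_genome(chr1 = strrep("A", 1000))
  feats <- derive_intergenic(
    tibble::tibble(seq_id = character(), source = character(),
                   type = character(), start = integer(), end = integer(),
                   strand = character(), id = character(),
                   parent = character()), g)
  aln <- tibble::tibble(sequence = c("r1", "r1"), seq_id = "chr1",
                        start = c(10L, 500L), end = c(30L, 520L),
                        strand = "+", count = c(9L, 9L))
  once <- feature_coverage_table(aln, feats)
  expect_equal(sum(once$read_count), 9)
  per <- feature_coverage_table(aln, feats, count_mode = "per-hit")
  expect_equal(sum(per$read_count), 18)
})

test_that("genomic context resolves host gene, feature class and strand", {
  feats <- tibble::tibble(
    seq_id = "chr1", source = "s",
    type   = c("gene", "mRNA", "exon", "exon", "intron", "three_prime_UTR"),
    start  = c(100L, 100L, 100L, 600L, 300L, 850L),
    end    = c(1000L, 1000L, 299L, 1000L, 599L, 1000L),
    strand = "+",
    id     = c("g1", "m1", "e1", "e2", "i1", "u1"),
    parent = c(NA, "g1", "m1", "m1", "m1", "m1"))
  intronic <- genomic_context(
    tibble::tibble(locus_id = "a", seq_id = "chr1", start = 350L,
                   end = 520L, strand = "+"), feats)
  expect_equal(intronic$context, "intronic")
  expect_equal(intronic$host_gene, "g1")
  expect_true(intronic$same_strand)

  utr <- genomic_context(
    tibble::tibble(locus_id = "b", seq_id = "chr1", start = 860L,
                   end = 980L, strand = "-"), feats)
  expect_equal(utr$context, "UTR")
  expect_false(utr$same_strand)

  ig <- genomic_context(
    tibble::tibble(locus_id = "c", seq_id = "chr1", start = 1500L,
                   end = 1600L, strand = "+"), feats)
  expect_equal(ig$context, "intergenic")
  expect_true(is.na(ig$host_gene))
})

test_that("cluster chaining respects the strict 5-kb rule", {
  mk <- function(starts, ends, ids, chr = "chr1") {
    tibble::tibble(locus_id = ids, seq_id = chr, start = starts, end = ends)
  }
  # gap of 4999 intervening bases: one cluster
  near <- find_clusters(mk(c(1000L, 7000L), c(2000L, 7170L), c("a", "b")))
  expect_equal(near$cluster_size, c(2L, 2L))
  expect_equal(near$cluster_id[1], near$cluster_id[2])
  # gap of exactly 5000: two singletons
  far <- find_clusters(mk(c(1000L, 7001L), c(2000L, 7170L), c("a", "b")))
  expect_equal(far$cluster_size, c(1L, 1L))
  # transitive chaining of three loci
  three <- find_clusters(mk(c(1000L, 5000L, 9000L),
                            c(1170L, 5170L, 9170L), c("a", "b", "c")))
  expect_equal(three$cluster_size, rep(3L, 3))
  # permutation invariance
  shuf <- find_clusters(mk(c(9000L, 1000L, 5000L),
                           c(9170L, 1170L, 5170L), c("c", "a", "b")))
  expect_equal(shuf, three)
  # different chromosomes never chain
  split <- find_clusters(dplyr::bind_rows(
    mk(1000L, 1170L, "a"), mk(1500L, 1670L, "b", chr = "chr2")))
  expect_equal(split$cluster_size, c(1L, 1L))
})

test_that("convergent pairs are head-to-head and greedy left-to-right", {
  mk_genes <- function(strands) {
    n <- length(strands)
    tibble::tibble(seq_id = "chr1", source = "s", type = "gene",
                   start = seq(1L, by = 1000L, length.out = n),
                   end = seq(800L, by = 1000L, length.out = n),
                   strand = strands, id = paste0("g", seq_len(n)),
                   parent = NA)
  }
  expect_equal(nrow(convergent_pairs(mk_genes(c("+", "-")))), 1L)
  expect_equal(nrow(convergent_pairs(mk_genes(c("+", "+")))), 0L)
  p4 <- convergent_pairs(mk_genes(c("+", "-", "+", "-")))
  expect_equal(nrow(p4), 2L)
  expect_equal(p4$gene_plus, c("g1", "g3"))
  # each gene in at most one pair: (-,+,-) middle gene pairs right only
  p3 <- convergent_pairs(mk_genes(c("-", "+", "-")))
  expect_equal(nrow(p3), 1L)
  expect_equal(p3$gene_plus, "g2")
})

test_that("normalized convergent comparison nulls out shared expression", {
  set.seed(41)
  n <- 500
  conv <- tibble::tibble(gene_id = paste0("c", 1:n),
                         srna = 2 * rlnorm(n), mrna = 2 * rlnorm(n))
  other <- tibble::tibble(gene_id = paste0("o", 1:n),
                          srna = rlnorm(n), mrna = rlnorm(n))
  pairs <- tibble::tibble(gene_plus = conv$gene_id[seq(1, n, 2)],
                          gene_minus = conv$gene_id[seq(2, n, 2)],
                          seq_id = "chr1", gap = 100L)
  cmp <- convergent_srna_comparison(
    dplyr::bind_rows(conv[, c("gene_id", "srna")],
                     other[, c("gene_id", "srna")]),
    dplyr::bind_rows(conv[, c("gene_id", "mrna")],
                     other[, c("gene_id", "mrna")]), pairs)
  td <- tidy(cmp)
  expect_lt(td$p.value[td$comparison == "raw_srna"], 0.01)
  expect_gt(td$p.value[td$comparison == "normalized_srna"], 0.05)

  # identical distributions: both tests null
  cmp2 <- convergent_srna_comparison(
    dplyr::bind_rows(conv[, c("gene_id", "srna")],
                     dplyr::mutate(other, srna = conv$srna)[,
                       c("gene_id", "srna")]),
    dplyr::bind_rows(conv[, c("gene_id", "mrna")],
                     dplyr::mutate(other, mrna = conv$mrna)[,
                       c("gene_id", "mrna")]), pairs)
  expect_gt(glance(cmp2)$p_raw, 0.05)

  # empty convergent set flags insufficient data
  cmp3 <- convergent_srna_comparison(
    other[, c("gene_id", "srna")], other[, c("gene_id", "mrna")],
    pairs[0, ])
  expect_true(glance(cmp3)$insufficient_data)

  # genes without mRNA abundance are excluded and counted
  cmp4 <- convergent_srna_comparison(
    dplyr::bind_rows(conv[, c("gene_id", "srna")],
                     other[, c("gene_id", "srna")]),
    dplyr::bind_rows(conv[, c("gene_id", "mrna")],
                     other[1:400, c("gene_id", "mrna")]), pairs)
  expect_equal(glance(cmp4)$excluded_no_mrna, 100L)
})

test_that("windowed counts partition reads along the chromosome", {
  g <- toy_genome(chr1 = strrep("A", 60000))
  aln <- tibble::tibble(sequence = paste0("r", 1:3), seq_id = "chr1",
                        start = c(100L, 26000L, 26100L),
                        end = c(120L, 26020L, 26120L), strand = "+",
                        count = c(2L, 3L, 4L))
  w <- windowed_read_counts(aln, g, window = 25000L)
  expect_equal(nrow(w), 3L)
  expect_equal(w$reads, c(2L, 7L, 0L))
})
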