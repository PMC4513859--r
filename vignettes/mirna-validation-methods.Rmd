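---
title: "Validating miRNA loci from read stacks: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating miRNA loci from read stacks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mircert)
library(dplyr)
```

## The problem

MicroRNAs have evolved independently in several eukaryotic lineages —
animals, land plants, chlorophyte algae, demosponges, slime molds and brown
algae — and in lineages outside the two classical model groups the only
reliable way to certify a candidate miRNA locus is structural: the small-RNA
read stack over a candidate hairpin must look like the product of RNase-III
(Dicer) processing. Prediction tools emit thousands of candidate hairpins;
most are siRNA sources, degradation products or palindromic repeats. This
package implements the validation step as a reusable, testable pipeline:
from a genome, an annotation, a collapsed sRNA read library and a set of
candidate precursor loci, it produces certified miRNA annotations, a
diagnosis for every rejected candidate, and downstream annotation
(genomic context, clusters, families, expression, foldback structure).

## The four validation criteria

A candidate locus is folded and its read stack inspected. The miRNA is
defined as the more strongly expressed of the two duplex products. The
locus is certified only if:

1. **Opposite-arm pairing** — at least `min_arm_pairs` (default 15)
   nucleotides of the miRNA pair with the opposite arm of the hairpin,
   counted from the pairing table; pairs internal to the miRNA interval do
   not count.
2. **Star expression** — at least `min_star_reads` (default 1) reads
   support the miRNA*, with their 5' end within
   `star_start_tolerance` (default 1 nt) of the predicted star 5' end.
3. **Dicer offset** — each duplex end shows the 2-nt 3' overhang left by
   RNase-III processing. This is evaluated from the pairing table
   (3p-product 3' end = partner(5p start) + 2, and symmetrically), so the
   criterion is decidable even when star coverage is a single read.
4. **5' homogeneity** — at least `min_homogeneity` (default 0.66) of the
   reads covering the miRNA start at the same nucleotide. The denominator
   is the set of reads overlapping the product by at least half their
   length; the numerator is the modal 5' position's count. The default
   0.66 is applied as an inclusive boundary: 8/12 ≈ 0.667 passes, 0.65
   fails.

Failures map onto a diagnosis, in gate order: `NO_READS` (empty stack),
`DOMINANT_OUTSIDE_MIRNA` (the most abundant read does not overlap the
called miRNA — the signature of mis-annotated siRNA loci),
`DUPLEX_INVALID` (criterion 1 or 3 fails structurally), then `NO_STAR` /
`LOW_HOMOGENEITY` for criterion 2/4 failures. These three structural
categories are exactly the failure modes observed when candidate sets
validated only by qPCR are re-examined against read data.

### Weak candidates

A locus can pass all four duplex-level criteria and still be untrustworthy
when it sits inside an extended palindromic region that produces many sRNA
species. `extended_context_check()` therefore extends the locus by
`weak_extension` (default 150 nt) per side, re-maps the read library and
re-folds. The locus is down-graded to `WEAK` when (a) any read cluster
outside the duplex carries more reads than the miRNA*, or (b) the extended
structure no longer pairs at least `min_arm_pairs` miRNA positions to the
star arm. The two-part rule is an operationalization — "complex, extensive
palindromic sequence" has no standard quantitative definition — and
reports label it as such: condition (a) is read-based and robust,
condition (b) is structure-based and engine-dependent.

## The folding engine

The default engine is deterministic base-pair maximization (Nussinov-style
dynamic programming, implemented in C++): Watson–Crick plus G·U wobble
pairs, minimum hairpin loop of 3 unpaired nucleotides, and a traceback that
pairs the leftmost base whenever some optimal structure does, to its
leftmost optimal partner. Ties therefore always resolve to the structure
whose sorted pair list is lexicographically earliest, making every fold
reproducible without a thermodynamics dependency. The engine is behind a
single function (`fold()`) that exposes only the pairing table, so a
thermodynamic engine (e.g. an RNAfold wrapper) can be substituted without
touching any downstream contract. The test suite pins the engine to an
independent exhaustive pair-maximization oracle over a thousand random
short sequences.

**Assumptions and costs of this choice.** Pair maximization has no notion
of stacking energy, so on long low-complexity or complementary flanks it
will happily trade designed stem pairs for flank pairings. Two design
decisions follow. First, criterion 1's count and criterion 3's offsets are
computed on the *unextended* precursor, where designed hairpins are exact
optima. Second, the synthetic-data generator plants loci in pairing-inert
(poly-A) background: in uniform-random background, extended folds would
"peel" outer stem pairs into chance flank pairings (each re-routing nets
one extra pair), shredding planted hairpins and making condition (b) above
meaningless. Inert background keeps every designed structure the provable
optimum of its neighborhood. The cost is realism: passing the recovery
suite shows the criteria and diagnoses are computed correctly, not that
the pipeline is robust to the structural noise of a real genome — for real
data a thermodynamic engine should be plugged in.

### Foldback length

The foldback is measured on the locus plus 100 nt of flanking sequence per
side: fold, find the terminal loop enclosing the locus, then walk outward
along both arms in lockstep. The walk ends at the first run of **three
consecutive unpaired nucleotides** — evaluated per arm, on either arm — or
at the first position whose partner lies outside the growing stem (another
secondary structure). Whether the three-unpaired rule should be assessed
on one arm or either arm is genuinely ambiguous; either-arm is the
stricter reading and is the default (`max_unpaired_run` is exposed for the
other). The reported length covers both arms plus the terminal loop, which
puts designed 83-bp-stem/4-nt-loop hairpins at exactly 170 nt — the scale
reported for brown-algal foldbacks, against ~82 nt for eumetazoan ones.

## Coordinates and alphabets

All internal coordinates are 1-based inclusive, the native convention of
R, IRanges and GFF3; BED input is converted at the parser boundary. (The
alternative, 0-based half-open throughout, buys nothing in R and fights
every dependency.) The internal alphabet is DNA ({A,C,G,T,N}); U is
normalized to T on input and RNA letters reappear only in human-readable
renderings. Minus-strand loci are reverse-complemented at extraction so
every downstream step reasons in transcript space.

## Expression and accounting

RPM = count × 10⁶ / library size. The library size is the total count of
retained reads that map anywhere in the run's mapping set, each distinct
read counted once — the denominator is genome-mapped rather than
all-reads, since the alternative is inflated by unmappable contaminants
(both are computable; the choice is a documented flag of the run, not a
hidden constant). Read filtering (default: keep 18–26 nt, drop any read
containing N) conserves counts: retained plus per-cause discarded counts
always sum to the input, and the accounting table is a first-class output.

For genome-fraction coverage accounting, each aligned read is assigned to
exactly one feature class — the highest-precedence class (rRNA > tRNA >
snoRNA > transposon > exon > intron > intergenic) it overlaps by at least
half the read length — and class sizes are made disjoint under the same
precedence, so reads are conserved and no base is double-counted.
Multi-mapping reads are counted once, at their first reported alignment,
by default (`count_mode = "per-hit"` is available); the published
accounting does not state its convention, and "once" keeps totals equal to
the distinct-read total.

## Families, clusters, comparisons

* **Families** — seed mode requires exact identity of nucleotides 2–8
  (1-based on the mature); identity mode links pairs whose best ungapped
  sliding alignment reaches the threshold (default 85%), with identity
  normalized by the *longer* sequence — the conservative denominator,
  flagged in output because alignment-software conventions differ.
  Families are the single-linkage closure, so lowering the threshold can
  only merge, never split.
* **Clusters** — single-linkage chaining of loci on the same chromosome
  with end-to-start gap strictly less than 5 kb ("within 5 kb" read as
  strict, edge-to-edge).
* **miRNA/miRNA\* abundance ratio** — mean over loci of the per-locus
  ratio, star-zero loci excluded and counted. Mean-of-ratios rather than
  ratio-of-means: the per-locus ratio is the biologically meaningful
  quantity, and the aggregation method is reported alongside the value.
* **Convergent gene pairs** — adjacent `+`/`-` genes (head-to-head 3'
  ends), each gene in at most one pair, greedy left-to-right. The sRNA
  comparison between convergent and other genes is run twice — raw, and
  normalized by mRNA abundance — with Kruskal–Wallis rank tests, because
  convergent genes may simply be more highly transcribed.
* **First-nucleotide bias** — Fisher's exact test on the 2×2 U-vs-other
  table between two annotation sets.
* **Homology search** — ungapped scan of mature and star against both
  strands of a target genome keeping matches with at most 3 mismatches
  ("fewer than four"); each hit's ±100 nt context is folded and the hit is
  kept only if the matched region attains `min_arm_pairs` opposite-arm
  pairs — a hairpin-context filter that removes matches in structureless
  sequence.

## The synthetic-data generator

`generate_dataset()` is the package's ground-truth instrument: it plants
designed hairpin loci of six classes (true miRNA, weak palindromic,
no-reads decoy, dominant-read-outside decoy, blunt-duplex decoy,
siRNA-like) into synthetic chromosomes with host genes realizing requested
genomic contexts, simulates the collapsed read library, and emits a truth
table whose expected verdict and reason codes are derived *analytically*
from the locus parameters. The core test property is parameter recovery:
under default settings the classifier must reproduce the truth table
exactly.

Defaults are the structural conditions reported for the brown-algal
repertoire, chosen once: 21-nt matures (84.3% of real loci are 21 nt) on
the 3p arm (66%) with a 5' U (92%), stems of 83 bp with a GAAA tetraloop
(designed foldback 170 nt, the reported mean), 2 engineered duplex
mismatches, a 2-nt Dicer offset, 0.9 processing homogeneity ("clear
majority" comfortably above the 0.66 threshold), 500 mature reads per
locus (mid-range of the reported 0.24–8387 RPM span) and a 446-fold
mature:star ratio (the reported mean; at 500 mature reads this realizes a
single star read, which is exactly the minimal-evidence regime criterion 2
must handle).

Designed precursors are built so the pair-maximizing fold is provably the
designed duplex: the 5' arm is drawn over {A,G}, the 3' arm is its exact
complement over {T,C} (so no within-arm, loop or flank pairing is legal,
and the only maximal non-crossing matching of the two arms is the
antiparallel identity), the outermost stem pairs are pinned to G–C, and
engineered mismatches substitute C on the purine arm against A on the
pyrimidine arm — bases that can pair nothing across the arms, so
mismatches cannot be rescued by register-shifted refolding. Controlled
exceptions (a U mature start on the 5p arm) are re-verified against the
designed pairing table at build time, with redraw on ambiguity. Read
counts are allocated deterministically (the modal 5' position receives the
homogeneity fraction, the remainder spreads over ±2 nt), so realized
homogeneity equals the specified value up to rounding.

What the generator does **not** emulate: sequencing error, adapter
contamination, quality scores, multi-mapping read families,
composition-realistic background (see the folding-engine section), RNA
editing, and overlapping gene models. Green recovery tests therefore
certify the decision logic and the bookkeeping, not performance on noisy
real libraries.

## Problem sizes in the test and acceptance runs

The recovery property runs on 20 true loci plus 5 decoys of each of the
four decoy classes (one seed per run); the folding oracle comparison uses
1000 random sequences of 10–25 nt; the foldback grid covers stems 20–80 bp
by loops 3–8 nt; unit fixtures use 40–83 bp stems. These sizes make the
default suite complete in a few minutes on one CPU while still exercising
every code path; all of them scale linearly if larger runs are wanted.

## Known limitations

* Base-pair maximization is a structural caricature; all structural
  conclusions on real genomes should be re-derived with a thermodynamic
  engine behind `fold()`.
* The weak-candidate rule is an operationalization of a qualitative
  published pattern; its structure-based half inherits the engine's
  limitations.
* `naive_genome_align()` is exact-match only and bounded to toy genomes
  (10 Mb); real alignments enter via SAM.
* Mirtron logic is out of scope; intronic loci only carry a
  boundary-adjacency annotation via their genomic context.
* The pipeline assumes adapter-trimmed input reads.
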