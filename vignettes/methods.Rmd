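---
title: "Methods: long-read structural variant calling in svlr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: long-read structural variant calling in svlr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the calling model
and its assumptions, the tunable parameters and why their defaults are what
they are, what the bundled simulator does and does not emulate, the
numerical choices inside the consensus and breakpoint machinery, and the
places where the design was genuinely open and a choice had to be made.

## The calling model

Long reads carry SV evidence in two forms. A variant small enough to be
spanned by one alignment appears *inside* a read's CIGAR string: a deletion
as a `D` operation, an insertion as an `I` operation. A variant that breaks
colinearity — an inversion, a duplication junction, a translocation, or an
insertion longer than the aligner will bridge — splits the read into a
primary alignment plus supplementary alignments, and the breakpoints sit at
the segment junctions. `extract_signatures()` reduces every read to a list
of such signatures: indels at or above 100 bp, clips at or above 500 bp,
and split-pair classifications (opposite strands on one chromosome →
inversion; same strand but the second segment mapping *upstream* of where
colinearity predicts → tandem-duplication-like junction, reported as `DUP`;
different chromosomes → `TRA`). The 100 bp indel floor reflects the error
regime of the data this pipeline targets: Nanopore-scale reads carry
frequent 1–10 bp indel errors, and a conservative length floor is what
keeps the candidate space clean.

Calling is then clustering plus filtering, with every threshold exposed in
`svlr_config()`:

1. **Cluster** same-type signatures along the genome (single linkage;
   window 50 bp for indels, 100 bp for inversions/translocations). A
   cluster is a candidate when ≥ 2 distinct reads with MAPQ ≥ 20 support
   it.
2. **Merge** candidates of one type whose breakpoints are within 300 bp
   (insertions) / 1000 bp (other types) / 500 bp (inter-chromosomal
   breakends) *and* whose intervals overlap reciprocally by ≥ 80%.
   Insertions have zero-length reference intervals, so the reciprocal
   overlap is replaced by a length ratio ≥ 0.8 — the natural analogue.
3. **Support filters.** Reads whose signature falls in the terminal 10% of
   the read are unreliable (alignment ends fray) and are discarded first.
   Deletion-supporting reads that also carry an insertion near the
   breakpoint (≥ 10% of the deletion length for deletions under 1 kb, 30%
   above, within 30 bp) are discarded: such read-local indel pairs are a
   known alignment artifact that manufactures false deletions. The
   surviving support is tested against per-size thresholds (deletions
   100–500 bp: 4 reads; 501–1000 bp: 3; above 1 kb: 2; insertions up to
   1 kb: 3; larger: 2, or ≥ 2 long-clipped reads on each side — the
   signature a too-long-to-span insertion leaves).
4. **Region filters.** VAF = support / spanning-read depth must be ≥ 0.03;
   depth counts a read if *any* of its segments spans the breakpoint,
   because for a homozygous inversion the inverted segment is usually the
   supplementary one. A call is dropped when ≥ 30% of reads within 500 bp
   of a breakpoint have MAPQ < 30 (ambiguous mapping territory), when an
   inversion/duplication/translocation span is ≥ 80% short repeats
   (Simple/Tandem + Low_complexity — tandem-repeat length polymorphism
   mimics these classes), or when both breakpoints fall in different
   segments of one segmental duplication.
5. **Population merge.** Pass calls are grouped across samples under the
   same identity rule; each carrier contributes 2 alleles at VAF ≥ 0.7
   (homozygous) else 1, and variants with cohort allele frequency ≥ 0.1
   are retained.

Somatic calling reuses the full germline detection on the tumor, then
subtracts: any tumor candidate with ≥ 1 supporting read in the matched
normal (raw clusters — filtering the normal first would leak borderline
germline variants into the somatic set), any candidate present in the
pooled normal panel, and any candidate where the matched normal has depth
below 9 at either breakpoint (too shallow to certify absence). The
short-repeat filter extends to deletions and the segmental-duplication
filter to all types at this stage, trading recall for the higher
specificity somatic calling demands.

## Consensus sequences and breakpoint anatomy

Individual long reads are too noisy to read a junction directly, so for
each indel the package gathers, from every support read, the read
subsequence covering the breakpoint ± 500 bp (pooled across samples for
shared variants) and builds a majority-vote consensus with an internal star
multiple alignment:

- the backbone is the median-length segment (robust against chimeric or
  truncated outliers at both ends of the length distribution);
- every other segment is aligned to it with a banded ends-free affine
  alignment — match 1, mismatch −2, gap-open −2, gap-extend −1, band
  half-width 0.2 × the longer length, widened by the length difference so
  truncated segments stay inside the band;
- per backbone column the plurality symbol among covering segments is
  emitted (gap-majority columns emit nothing; ties resolve toward the
  backbone symbol, then lexicographically — determinism over elegance);
- insertions relative to the backbone are left-normalized (rotated through
  equal backbone bases) so homopolymer placements coalesce on one
  junction, and emitted when a majority of crossing segments insert there
  — or at least a third of them (minimum 3). The relaxed floor is
  deliberate: under the affine scores, a segment whose own deletion error
  lies within a few bases of a backbone-deleted site absorbs the expected
  insertion operation into mismatches, so genuinely missing bases collect
  well under 100% of the votes, while junctions created by isolated read
  insertion errors collect only one or two. The two populations are far
  apart; the floor sits between them.
- one refinement pass re-votes all segments against the first-pass
  consensus. The first backbone is a real read with its own ~7% deletion
  errors; the second pass recovers most of what those cost.

A consensus is accepted only if it remaps consistently: an insertion's
implied insertion point must fall within 100 bp of the original call, a
deletion's remapped junction must overlap the call interval. Remapping
uses supplied BLAT PSL records when available, otherwise the internal
aligner against a local reference window (minimum identity 0.7, mirroring
a permissive BLAT setting).

Breakpoint anatomy is measured from the accepted consensus and the two
reference flanks (breakpoint ± 500 bp). The pre-breakpoint half of the
upstream flank and the post-breakpoint half of the downstream flank are
*fit*-aligned to anchor the junction; homology is then the summed
exact-match extension across the junction in both directions, and the
junction insertion is the consensus stretch between the anchors covered by
neither flank. An earlier design used two unconstrained local alignments
and measured their overlap, but local alignment overshoots by chance
matches (a quarter of random bases match), blurring a blunt junction into
1–3 bp of apparent homology — fatal when the NAHR boundary must separate
homology 100 from 101 exactly. Anchored exact extension measures genuine
sequence identity only. Note one consequence: 1–2 bp of *chance* homology
at a junction is genuine sequence identity and is reported as such; the
simulator therefore guards the boundary bases of planted junctions so
truth labels are exact.

Mechanism bands: homology > 100 bp → NAHR (the only bound stated by the
breakpoint-analysis tradition this follows with a precise value);
2–100 bp → alternative end joining; otherwise NHEJ when the junction
insertion is under 10 bp and FoSTeS/MMBIR at 10 bp or more. The 2 bp
microhomology floor and the 10 bp templated-insertion cut follow the
conventions of prior breakpoint studies and are single configuration
constants (`alt_ej_min_homology`, `fostes_min_insertion`), not derived
quantities.

Ancestral inference compares each indel's breakpoint-flank distance in the
reference against the distance between the same (lifted) anchors in an
outgroup genome: ratio = (d_outgroup − 200) / (d_ref − 200), with ± 100 bp
anchors contributing the 200. A ratio in [−0.3, 0.3] means the outgroup
lacks the extra sequence; [0.7, 1.3] means it matches the reference; the
gaps are unclassified (single-mutation parsimony cannot interpret them).
Band edges are inclusive. For insertions the reference-side anchor
distance is taken on the allele-length scale (insertion length + 200), so
the denominator never degenerates to zero — the formula is stated for
deletions, and this is the unique reading that makes it symmetric.

## The simulator: what it emulates and what it does not

The simulator exists so that every stage can be tested end to end with
known truth. It emulates the features the caller actually consumes:

- a reference with planted Alu-like (~300 bp) and L1-like (~6 kb) element
  copies (internally fixed consensus sequences, ~3% divergence per copy,
  random strand, some 5′-truncated) plus tandem-repeat runs, with exact
  RepeatMasker `.out` / TRF `.dat` annotations written by construction;
- donor haplotypes with spiked deletions, insertions (random, Alu-like,
  L1-like, tandem-duplicated, viral, pseudogene-like content), inversions
  and tandem duplications; deletions can carry planted breakpoint homology
  (an NAHR-style recombination substrate stamped into the reference) or
  untemplated junction insertions;
- reads with log-normal lengths (mean 5457.9 bp, the scale of real
  Nanopore genome runs) and per-base errors at 3.8% substitution, 4.4%
  insertion, 6.6% deletion — the error profile of the data this pipeline
  targets; truth alignments are emitted directly from the donor-to-
  reference block map, including split records with SA tags at inversion
  and duplication junctions, and segments under 100 bp are soft-clipped
  away as a real aligner would.

It does **not** emulate base-quality structure, strand-specific or
context-specific (homopolymer) error enrichment, chimeric library
artifacts, the full human repeat landscape, or mapping ambiguity — every
simulated record has MAPQ 60, and reads are sampled from the forward donor
strand only (signature geometry is strand-symmetric, so the caller sees
the same evidence patterns either way). Consequently, passing tests
demonstrate that the *rules* are implemented exactly and that recovery
works under the stated error model; they do not certify performance on
real data, where mapping ambiguity in long repeats is the dominant
difficulty and the low-MAPQ and repeat filters carry real weight.

Study conditions fixed in the test suite and acceptance script: spike-in
recovery uses a 1 Mb genome (two 500 kb chromosomes), 60 SVs (20 DEL /
20 INS / 10 INV / 10 DUP), indel lengths log-uniform on 100–2000 bp,
half the variants homozygous and half heterozygous, 20× coverage; the
somatic study uses a 300 kb genome, 20 shared germline and 10
tumor-private SVs at 30× with error-free reads (the somatic criterion is
exactness of the subtraction, not error tolerance); consensus recovery
uses 50 insertions of 100–5000 bp with 8–15 segments each.

## Numerical choices and degenerate inputs

- The pairwise aligner (Rcpp) uses rolling full-width score rows with
  banded traceback storage; modes cover global, ends-free, fit (all of the
  query inside the subject) and local alignment. Band placement follows
  the length-proportional diagonal; `fit` and `local` modes disable
  banding since the diagonal is unknown.
- Cluster and merge representatives are member medians, rounded to
  integers; ties in the median-length backbone choice resolve to the
  first.
- Zero-length inputs: an empty SAM yields an empty alignment table; a
  cluster of one read is a singleton (never a candidate); a single-segment
  consensus is returned verbatim and flagged low-confidence; an empty
  callset against a non-empty truth set reports precision = recall = 0
  with a degenerate flag rather than NaN.
- Greedy benchmark matching (ascending distance, one-to-one) is checked in
  the tests against maximum bipartite matching and against exhaustive
  string oracles for breakpoint anatomy and interval coverage.
- Mapped SAM records with missing or malformed CIGARs are counted and
  skipped with a warning before BAM conversion (htslib silently demotes
  them to unmapped, so the scan happens on the SAM text).

## Open design decisions

Several points were genuinely open and are recorded here as the package's
choices:

- **Genotype for population allele counting**: VAF ≥ 0.7 → homozygous (2
  alleles), else 1. Isolated in `genotype_allele_count()`.
- **Deletions above 1 kb** fall back to the base 2-read support rule; the
  per-size ladder is only specified up to 1 kb.
- **Chimera screening** is a heuristic: split pairs overlapping by more
  than half of the shorter read interval are discarded (ligation
  artifacts), and clusters whose members share an identical within-read
  breakpoint fraction are flagged `chimeric`.
- **Intra-chromosomal translocations present as tandem duplications**
  (order-inverted colinear splits) and are typed `DUP` throughout; a
  colinear same-strand split is only promoted to this class when the
  reference order contradicts the read order by more than 20 bp (micro-
  homology slack) or the gap exceeds 100 kb.
- **Clip breakends** are not free-standing calls; they only corroborate
  large insertions (the ≥ 2-clipped-reads-per-side rule). Resolving them
  by local remapping of the clipped sequence is deliberately left to the
  upstream aligner's supplementary records.
- **A single LTR/DNA transposon covering ≥ 80%** of a consensus has no
  slot in the repeat-category enumeration (built around SINE/LINE
  biology); it is binned as `multi_repeat` and will misdescribe a genome
  where single LTR insertions are common.
- The **manual review** step that a human would perform on somatic
  candidates is replaced by a machine-readable per-call read-evidence
  table (`somatic_review.tsv`); nothing is silently dropped.

## Known limitations

- No genotype likelihoods, phasing, or sub-100 bp indels.
- The internal star MSA is not a partial-order alignment; pathological
  segment sets (many chimeras) can drag the backbone off target before
  the refinement pass.
- The viral mini-mapper is a desk-scale k-mer seed-and-extend tool for
  genomes of a few kb; production virus integration calling should feed
  externally produced alignments.
- Copy-number segmentation, clustered-SV narrative reconstruction and
  driver-gene annotation are out of scope.
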