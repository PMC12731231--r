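---
title: "Ensemble two-field HLA genotyping: methods and design notes"
author: "HLAensemble"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble two-field HLA genotyping: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(HLAensemble)
```

## The problem

The HLA loci on chromosome 6p21.3 are the most polymorphic region of the
human genome, and computational HLA typing from short-read sequencing is
correspondingly fragile: the four widely used tools wrapped by this package
(OptiType, Polysolver, ATHLATES, seq2HLA) disagree with each other often
enough that no single tool on a single library should be taken at face
value. Two complementary ideas make typing both faster and more
trustworthy, and this package implements both at desk scale:

1. **HLA-targeted read filtering.** Only a small fraction of an exome or
   RNA-seq library derives from the HLA region. Extracting the read pairs
   that could align to known HLA alleles — and only those — shrinks the
   typing tools' input by one to two orders of magnitude while, ideally,
   leaving their genotype calls unchanged. The package quantifies that
   "ideally" with an explicit concordance statistic instead of assuming it.
2. **Ensemble consensus calling.** Each patient contributes three
   libraries (normal exome *N*, tumor exome *T*, tumor RNA-seq *R*), and
   each library can be typed by several tools. Integrating all available
   two-field calls per allele slot turns tool idiosyncrasies into votes:
   full agreement is a high-confidence *unanimous* call, a unique modal
   allele is the *consensus*, and a tie is reported as *ambiguous* rather
   than silently broken.

Two-field resolution (e.g. `A*02:01`) identifies a distinct protein
sequence and is the resolution that matters for peptide-binding
applications such as neoantigen prediction; all calls are normalized to it
at the ingestion boundary.

## The applicability matrix

Not every tool can type every locus from every library. OptiType and
Polysolver type only the class I loci (A, B, C); ATHLATES and seq2HLA also
type the class II loci (DPA1, DPB1, DQA1, DQB1, DRA, DRB1); and ATHLATES
produces no result from RNA-seq libraries at all. Under the full design
this yields, per patient:

```{r applicability}
toolApplicability()
expectedSlotCount("I")    # class I: 4 tools x 3 sources - ATHLATES x R
expectedSlotCount("II")   # class II: ATHLATES x {N,T} + seq2HLA x {N,T,R}
```

These counts (11 and 5) are the denominators against which unanimity is
judged: a class I slot is unanimous only when all 11 applicable cells
voted for the same allele. Failed runs (including every ATHLATES-by-RNA
cell) reduce the vote total but are never counted as disagreement.

## Consensus rules

Votes are counted per (tool, source) cell with equal weight; no tool is
privileged, because there is no principled basis for a weighting. Within
each genotype the two allele slots are assigned by lexicographic order of
the canonical two-field rendering. The tools report unordered allele
pairs, so some convention is required to compare "first" alleles across
tools; lexicographic slotting is deterministic and symmetric across tools.
The alternative — bipartite matching of each genotype against the emerging
consensus — was considered and rejected as a default because it makes the
consensus depend on iteration order; it can be emulated by post-processing
if needed.

Outcomes per slot:

* `unanimous` — a single distinct allele with support = total = expected;
* `consensus` — a unique modal allele, with support at least
  `minSupportFraction x total` (default 0, i.e. pure plurality);
* `ambiguous` — two or more alleles tie for maximal support;
* `no_call` — no votes at all.

`minSupportFraction` is exposed because a minimum-support threshold is a
natural hardening of plurality voting, but no specific value is canonical;
the default of 0 reproduces plain most-frequent-call behaviour with ties
reported as ambiguous.

Allele equality compares the numeric value of each field (tools differ in
zero-padding) and retains expression suffixes: a null allele (`C*04:09N`)
is functionally distinct from its expressed counterpart, and since
two-field comparisons are protein-level, discarding the suffix would
conflate a protein that is made with one that is not. Suffix handling
during two-field reduction is not standardized across tools, so retention
is this package's documented choice.

## The read filter

The filter classifies a read pair as HLA-region-specific when at least one
mate shares at least `minShared` k-mers (default 1) of length `k` (default
21) with the combined genomic+cDNA reference set, on either strand. When
only one mate matches, the partner is *rescued* so the output remains
strictly paired — typing tools require intact pairs, and the partner of a
true HLA read is evidence even when it straddles a boundary the reference
does not cover.

k-mer containment was chosen over full alignment deliberately. The
filtering contract is *retention*: every read that an aligner could map to
an HLA allele (including multimappers) must survive. A shared-21-mer test
is a strict superset of "alignable with default aligner settings" for
reads of typical length and error rate, runs with no external
dependencies, and is trivially auditable. The cost is asymmetric in the
right direction: false *retention* only makes the filtered file slightly
larger, while false *removal* could change a genotype. With 100 bp reads,
a single substitution leaves a clean flank of at least 21 bases whenever
the error is not dead-center over every shared window, so `minShared = 1`
tolerates the error rates of modern instruments. Reads shorter than `k`
cannot match and are dropped (with their mate, unless the mate matches).

Defaults: `k = 21` is long enough that a random 100-mer shares a k-mer
with a megabase-scale reference with probability well under 1e-6, and
short enough to tolerate one substitution per ~21 bases; `minShared = 1`
is the permissive extreme, consistent with the retention contract.

Both the retained percentage and its complement are always reported
(`summarizeReduction()`), because "percent reduction" in the literature is
ambiguous between the two readings and the numbers differ by an order of
magnitude.

## Evaluation statistics

**Concordance** compares genotypes derived from filtered reads against
those derived from the original reads, per (patient, gene, tool, source)
cell, counting agreeing alleles as the maximum multiset intersection of
the two diploid genotypes (0, 1 or 2). The denominator per cell is the
larger of the two genotypes' allele counts, so a dropped allele is a
disagreement but a partial call cannot inflate the percentage. Cells where
either side failed contribute to neither numerator nor denominator: a
comparison requires two genotypes. Aggregation is available overall, per
patient, per gene and per tool; groups with an empty denominator are
reported as undefined rather than dropped.

**The diversity ratio** asks how internally stable one tool is across
sequencing sources: per (patient, gene, allele-slot) cell, count the
distinct alleles the tool called across its applicable sources, and divide
the total by the number of cells with at least one call. A ratio of
exactly 1 means perfect internal agreement; the statistic is bounded below
by 1 whenever every counted cell has a call. The per-slot denominator is
used because it is the only choice under which the ideal value of 1 is
attainable for heterozygous patients — a per-gene denominator would count
an ordinary heterozygote as "diverse".

**Quality retention** is defined for the two tools that report a quality
metric — ATHLATES (typing score, 0 = confidently resolved pair) and
seq2HLA (prediction p-value, confident below 0.05). Retention is the
percentage of cells, among those where both the original and the filtered
run produced a quality-bearing genotype, whose *binary* confidence
classification agrees. The underlying value may drift; what matters to a
downstream user is whether a call stays on the confident side of the
tool's own rule. No standard retention arithmetic exists, so this
operationalization is stated prominently wherever the number is reported.

## The synthetic-data generator

Real patient sequencing data cannot be redistributed, so the package
ships a generator that emulates the structure every module consumes,
with truth labels throughout:

* **Reference**: one uniform-random ancestor per locus; each allele is the
  ancestor with a fixed number of substitutions at distinct positions,
  named `A*01:01`, `A*01:02`, ... Defaults: 6 alleles per locus of
  1200 bp with 15 substitutions (roughly 1% divergence, the order of
  spread within an HLA allele group).
* **Cohort**: diploid genotypes drawn uniformly with replacement per
  locus, so homozygotes occur at the rate the allele count implies.
* **Reads**: 100 bp pairs from ~300 ± 30 bp fragments at uniform positions
  on each truth haplotype (5 pairs per haplotype per locus by default),
  with per-base substitution errors at 0.1%, plus background pairs of
  random sequence screened to share no 21-mer with the reference — the
  one property background must have, guaranteed by construction. Read
  names carry the origin label.
* **Call tables**: per applicable (tool, source) cell, each truth allele
  is reported intact with probability `1 - callErrorRate` (default 2%) or
  replaced by a uniformly different allele of the locus; ATHLATES-by-RNA
  cells are emitted as failed records; quality values are drawn on the
  correct side of each tool's confidence rule, with 10% of records not
  confident.

What the generator does *not* emulate — and what passing tests therefore
do not demonstrate about real data: the paralog structure of the HLA
region (pseudogenes and cross-locus similarity that make real filtering
harder than random-background filtering), exon/intron architecture and
RNA splicing, realistic allele-frequency skew, linkage between loci, and
tool-specific correlated error modes (the simulator's call errors are
independent across cells). The generator validates the *machinery* —
bookkeeping, rescue, voting, metrics — not the biological difficulty of
the typing problem.

All randomness flows from one integer seed; the reference, truth,
read and call-table streams use fixed offsets from it, so any stage can
be regenerated independently and identical seeds give byte-identical
outputs.

## Numerical and degenerate-input choices

* Ties in consensus voting are never broken — they are the definition of
  `ambiguous`.
* Empty FASTQ input filters to empty output with a zeroed summary; an
  all-background input yields 0% remaining. A reduction percentage over
  zero input reads is an error, not `NaN`.
* A reference in which every sequence is shorter than `k` is rejected as
  unusable rather than silently matching nothing.
* Unparseable allele text is an error naming the offending token, but
  recognized no-call tokens (`"no"`, `"-"`, empty) are a distinct no-call
  signal, and a tool's unparseable *field* degrades that slot to no-call
  rather than aborting ingestion of the file.
* Duplicate call cells resolve last-write-wins with a warning, matching
  append-style workflows where a rerun supersedes an earlier record.

## Problem sizes

The shipped tests run the generator at small, fixed sizes chosen to make
every property checkable in seconds while still exercising all code
paths: cohorts of 2-8 patients and 2-3 loci for exact identities; 200
read pairs plus 200 background pairs for filter retention; and a
200-patient, nine-locus cohort at a 20% per-slot call error rate for the
stochastic consensus-accuracy check, for which a binomial argument
predicts per-slot failure well under 5% at 5-11 votes per slot. Seeds are
fixed in code; the accuracy assertion is a property of the configured
conditions, not of a particular lucky draw.

## Known limitations

* The k-mer filter's permissiveness is calibrated for retention, not
  precision; with the real, highly self-similar HLA reference it will
  also retain reads from HLA pseudogenes and paralogs. That is the
  intended behaviour for a pre-filter, but the retained fraction on real
  data will exceed what random-background simulations suggest.
* Reads containing alleles absent from the reference are removed by
  construction; the approach is unsuitable for novel-allele discovery.
* Per-tool output dialects vary across tool versions; the adapters target
  the common layouts and degrade unparseable fields to no-calls, but new
  versions may need adapter updates. The canonical call TSV is the stable
  interchange surface.
* G-group/P-group resolution and IMGT ambiguity-list expansion are out of
  scope; only the first listed allele of an ambiguity string is used.
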