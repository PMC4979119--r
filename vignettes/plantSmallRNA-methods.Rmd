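---
title: "Methods: small RNA and degradome analysis in plantSmallRNA"
author: "plantSmallRNA authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: small RNA and degradome analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plantSmallRNA)
```

# Scope

plantSmallRNA re-implements, as a tested and reusable pipeline, the
computational analysis used in plant small-RNA studies that compare a
fertile line with a cytoplasmic male-sterile (CMS) line: cleaning and
collapsing replicated small-RNA libraries, partitioning unique tags into
annotation categories, identifying known mature miRNAs, discovering novel
miRNA hairpins from genome windows, testing differential expression on
TPM-normalized counts, and calling miRNA cleavage targets from a pooled
degradome (PARE) library. A seeded synthetic-data module generates genomes
with planted hairpins, replicated negative-binomial count libraries and
degradome tags, so that every stage of the pipeline has a ground-truth
recovery test that runs at desk scale.

# Read cleaning and tag collapsing

Raw reads are filtered on mean Phred quality (default threshold 20,
inclusive) and ambiguous bases (default none allowed), the 3' adapter is
trimmed at the leftmost position where an adapter prefix of at least 6 nt
matches with at most 1 mismatch, and inserts of 18-30 nt (inclusive
bounds) are kept. Adapter-adapter ligation products trim to an empty
insert and are discarded. The adapter defaults to the standard Illumina
small-RNA 3' adapter (`TGGAATTCTCGGGTGCCAAGG`) and every threshold is an
argument. The published tables report both "high quality" and "clean"
read counts without defining the split; here the quality filter produces
the high-quality count and adapter/length selection produces the clean
count, which reproduces the `clean <= high_quality <= total` ordering.
Clean reads are collapsed to unique tags carrying per-library counts
(`UniqueTagSet`), ordered by descending total count with lexicographic
tie-breaking so all downstream output is deterministic. Percentages in
summary tables are rounded half-up at the printed precision (one decimal
for cleaning rates, two for annotation fractions), matching how such
tables are conventionally typeset.

# Annotation categories

Each unique tag is assigned to exactly one category in the fixed priority
order rRNA > tRNA > snRNA > snoRNA > exon_sense > exon_antisense >
intron_sense > intron_antisense > unannotated. The order is a design
choice: ncRNA identity is more specific than positional overlap, and
sense-strand gene overlap is more informative than antisense. An ncRNA
match is an exact substring hit against the reference set in either
orientation; exact matching is conservative and deterministic where a
covariance-model search would be fuzzier. Genomic categories come from
exact mapping of the tag to both strands of the genome (grouped
constant-width dictionaries, so large tag sets classify in bulk) and
overlap with exon/intron models; sense means the mapping strand equals
the feature strand. A tag hitting several features takes the
highest-priority category, so permuting reference input order never
changes an assignment.

# Known miRNAs, families and isomiRs

A tag identifies a known mature miRNA when an ungapped comparison over
all relative offsets, with overhanging bases counted as mismatches,
yields at most 2 mismatches; only matures within 2 nt of the tag's
length are considered. This reading of "nearly perfect match (mismatch
<= 2)" — substitutions only, no indels, symmetric in the two roles — keeps
the count well-defined and matches common small-RNA annotation practice.
A tag matching several matures is reported against all of them;
family-level summaries count each family once. Families derive from the
name by stripping the species prefix and variant suffixes
(`cga-miR167a.1` is family `miR167`). Precursors are located by mapping
each mature perfectly to the genome, evaluating the flanked window (below),
and merging overlapping passing windows regardless of arm strand, so the
two arms of one stem yield one precursor and one mature may own several
precursors. IsomiRs are tags mapping exactly into a precursor whose start
and end both sit within 2 nt of a mature's span.

# Novel hairpin discovery

Unannotated tags that were not claimed by the known-miRNA step, with at
least 5 supporting reads in total (an abundance floor the source
procedure leaves unstated), are mapped perfectly to the genome. Every
locus is extended by 200 nt on both sides (clamped at chromosome ends;
for a typical 21-24-nt tag this yields the ~420-450-nt windows of the
original procedure), minus-strand windows are reverse-complemented, and
the window is folded.

## Folding engine

The default folding backend is an in-package dynamic program over a
nearest-neighbor energy model: Turner-style Watson-Crick stacking free
energies, weak (and for tandem wobbles destabilizing) G:U stacks,
hairpin-, bulge- and interior-loop penalties with logarithmic size
extrapolation, a flat multibranch closing penalty, a minimum hairpin loop
of 3 nt and interior loops limited to 20 unpaired bases. The recursion is
the standard `V`/`W` scheme (`V(i,j)` = best energy with `i,j` paired,
`W(i,j)` = best energy on the interval) with traceback to a dot-bracket
string. The model guarantees: balanced, pseudoknot-free structures; only
AU/UA/CG/GC/GU/UG pairs; and MFE at most 0 for every sequence, because
the open structure is always available. Loop penalties matter: without
them, chance chains of short helices in random flanking sequence are
"free" and both litter the structure and mimic duplexes. Any other
folder can be plugged in through `foldRNA(backend=)` — a ready-made
adapter for ViennaRNA's `RNAfold` is provided and is used as an
independent cross-check in the test suite — and must satisfy the same
structure contract.

## Duplex criteria

A window passes when all four flags hold:

* `mfe_ok` — window MFE at or below -20 kcal/mol ("below -20" is read as
  an inclusive bound at the threshold);
* `arm_ok` — the mature sits on one arm: no self-pairing inside the
  mature span (which would mean it contains the loop), and at most 2
  duplex pairs on the minority side (a planted stem's terminal base is
  occasionally co-opted by a flanking helix, which should not disqualify
  the locus);
* `pairing_ok` — at least 14 mature bases pair within the duplex, with
  no internal bulge larger than 4 nt;
* `overhang_ok` — the derived miRNA/miRNA* duplex leaves exactly 2
  unpaired nt at the 3' end of each strand.

The duplex itself is delimited the way the classical MIREAP-style tools
do: only pairs whose partner lies within 35 nt (plus the mature length)
of the mature's edges are duplex pairs — more distant partners belong to
flanking helices — and the paired positions are segmented into blocks,
broken where the mature- or partner-side jump exceeds the bulge
tolerance, with the largest block taken as the duplex. The star span runs
from the partner of the 3'-most duplex-paired mature base (excluding the
mature's 2-nt 3' overhang) to 2 nt past the partner of the mature's
5'-most paired base; on a perfect stem this is the complementary block
offset by 2, and with bulges the star length may differ from the
mature's by the bulge size. The 14-base/4-nt/35-nt defaults mirror the
cited tool's and are all arguments. Novel matures are named
`can-miRn-<k>` in order of descending abundance. Star-sequence read
support is not required for a call (the structural criteria alone
decide); observed stars simply appear among the isomiR/tag mappings.

# Expression and differential expression

Counts are normalized to transcripts per million of the library's clean
reads (`tpm = count / clean_total * 1e6`), held in a
`SummarizedExperiment` with the design (line, stage, replicate) as column
data. Replicate agreement is the Pearson correlation of
natural-log-transformed TPM with a pseudocount of 1.

Differential expression between the sterile and fertile line uses a
two-sided pooled-variance Student's t-test on TPM, Benjamini-Hochberg
FDR across the test family, and a strict fold-change gate: a miRNA is
differential when its pseudocounted mean-TPM fold change exceeds 1.5 (or
falls below 1/1.5, since down-regulated miRNAs qualify too) and q < 0.05.
The source phrasing — expression "at three stages was compared" — admits
two designs, and the package implements both:

* **pooled (default)**: one test per miRNA, each line contributing its
  stages x replicates libraries (n = 6 vs 6 for the standard design, 10
  degrees of freedom), BH across miRNAs. This is the default because a
  per-stage test with two replicates per group has 2 degrees of freedom,
  and the smallest two-sided p-value such a t-test can realistically
  produce is far above the BH cutoffs that a family of hundreds of tests
  implies — under that reading essentially nothing can ever reach
  q < 0.05, which is incompatible with the procedure having reported
  dozens of differential miRNAs.
* **per-stage** (`mode = "per-stage"`): the literal per-stage reading
  (n = replicates vs replicates per stage), BH pooled over all miRNA x
  stage tests, a miRNA differential when any stage is significant.

Per-stage log2 ratios of pseudocounted mean TPM (negative =
down-regulated in the sterile line) feed the heat-map stage:
average-linkage (UPGMA) hierarchical clustering on a 1 - Pearson
distance between rows, computed with `hclust`, with the brute-force
agglomeration as a test oracle. The pseudocount of 1 TPM before logs and
ratios handles zeros, which the source procedure does not discuss.
Degenerate cases are explicit: zero pooled variance with equal means
gives t = 0, p = 1; with unequal means the result is flagged; constant
series make correlations degenerate rather than NaN.

# Degradome target calling

Degradome tags mark uncapped 5' ends of mRNA fragments. Tags are mapped
to the transcriptome by exact sense-strand match, multi-mapping tags
counted at every locus, and each transcript accumulates a profile of tag
5'-end positions. Candidate sites come from scanning every ungapped
antiparallel alignment of a miRNA along a transcript with the
position-weighted plant scoring scheme (mismatch 1, G:U wobble 0.5,
penalties doubled at miRNA positions 2-13, cutoff 4.5) — the scheme the
classical plant degradome tools use, adopted here as a design decision
since the source names only its tooling; all parameters are arguments.
Cleavage is expected between the transcript positions pairing miRNA
positions 10 and 11, so the diagnostic tag 5' end sits at the position
opposite miRNA position 10. A site is supported when at least 2 tags
fall within 1 nt of that coordinate. Supported sites are categorized by
abundance: class 1 when the cleavage signal matches the transcript's
maximum, class 2 when it is at least the median of the non-zero
positions but below the maximum, class 3 otherwise. The source defines
only classes 1 and 3 qualitatively; the median boundary for class 2 is
this package's reconstruction, scale-invariant by construction and
exposed as an argument. Because the site count sums a +/-1-nt window it
can exceed the single-position maximum, so class 1 tests
"at least the maximum". One pooled degradome library serves all samples,
as in the emulated design, so target calls are made on pooled tags.

# The synthetic-data generator

`makeGenome` builds uniform-random chromosomes and plants, at
well-separated loci: hairpins (mature + random loop + reverse complement
of the mature) for known and novel miRNAs; lone decoy tags with no
complementary arm; multi-exon plus-strand gene models whose spliced
exons form the transcriptome; and perfect reverse-complement target
sites written into exons for the first few known matures, which defines
degradome truth. ncRNA reference sets are generated independently.
Every planted locus is self-verified with the same fold-and-evaluate
path the discovery stage uses — hairpins must pass, decoys must fail —
and ambiguous draws (about 1% of random draws) are redrawn, so
"recall 1 / zero decoy calls" is a property of the truth object, not a
seed lottery.

`simulateSmallRNA` emits raw reads (insert plus adapter) for the
2-line x 3-stage x 2-replicate design: miRNA counts are
negative-binomial with dispersion 0.05 — chosen so simulated replicate
ln-TPM correlations land in the 0.85-0.99 band reported for the emulated
experiment — around lognormal baselines (median 200, log-sd 1.5, a
realistic several-orders-of-magnitude abundance spread). The
differentially expressed matures default to one miR167-like pattern
(3-fold down in the sterile line at stages 2-3 only) and one
miR399-like pattern (3-fold down throughout), both planted at high
baseline abundance as the dominant guide strands they emulate.
Background reads follow the annotation-category proportions and a
24-nt-dominant length distribution with a secondary 21-nt mode, as in
plant small-RNA libraries where 24-nt heterochromatic siRNAs dominate. A
small fraction of low-quality reads and adapter dimers gives the
cleaning stages real work. `simulateDegradome` plants Poisson-distributed
signal tags exactly at the expected cleavage coordinates and uniform
background starts at a configurable per-nucleotide rate.

What the generator does not emulate: sequencing errors, isomiR ladders
around planted matures, RNA modifications, multi-locus gene families
with near-identical members, length-dependent ligation bias, and genome
repeats. Passing recovery tests therefore show the pipeline's logic is
correct on clean signal at desk scale; they do not certify performance
on real libraries, where those factors matter.

# Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale:
two chromosomes of 15 kb, 10-20 planted miRNAs, libraries of a few
thousand reads, 200-miRNA count simulations over 20 seeds, and 10,000
null draws for t-test calibration — sizes chosen so the full suite
completes in a few minutes on one core while every recovery statistic
still has enough trials to be meaningful. Fold-change recovery,
sensitivity and false-discovery measurements use fixed seeds recorded in
the tests. Ties in unique-tag ordering break lexicographically; UPGMA
ties resolve by `hclust`'s deterministic merge order; all coordinates are
held 1-based closed in `GRanges` (the platform convention) with 0-based
half-open spans only where window-local arithmetic is clearer, and
file I/O follows each format's own convention.

# Known limitations

The folding engine is a deliberately compact nearest-neighbor model, not
a replacement for a full thermodynamic folder: its energies are
approximate (dangles, terminal mismatches, special hairpin loops and
coaxial stacking are omitted), so absolute MFE values differ from
ViennaRNA's even though hairpin calls agree on clear-cut cases. Exact
substring matching stands in for covariance-model ncRNA search, so
diverged ncRNA copies fall through to the genomic categories.
Multi-mapping tags are counted fully at every locus rather than
fractionally. The t-test/BH procedure is implemented as specified by the
emulated study; a count-model framework (negative-binomial GLMs) would
be preferable for new designs but is intentionally out of scope.
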