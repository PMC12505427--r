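---
title: "Analysing reduced endosymbiont consortia: split genes, stop-codon usage, pathway complementarity and genome pairs"
author: "endosym authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing reduced endosymbiont consortia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endosym)
```

## The biological setting

Planthoppers and other sap-feeding insects house obligate bacterial
endosymbionts in a dedicated organ, the bacteriome.  Over tens of
millions of years of strict vertical transmission these bacteria undergo
genome erosion: their chromosomes shrink to 130--500 kb, GC content
collapses to 18--27%, and the surviving gene set narrows to what the
host cannot do itself — chiefly biosynthesis of the ten essential amino
acids (EAAs) and some B vitamins.  A single host species typically
carries a *consortium* of two or three co-primary symbionts whose gene
repertoires are complementary: one partner retains the branched-chain
amino acid pathways, another the remaining EAAs, a third cysteine and
vitamins.

`endosym` packages the recurring analyses of such systems:

1. **Split-gene detection** — in one extremely AT-rich symbiont genome,
   annotation reports many genes "split in two halves": two adjacent CDS
   that merge into a single reading frame interrupted by exactly one
   internal stop codon.  The package detects these pairs, emits a merged
   annotation, and tabulates stop-codon usage in three groups (intact
   terminal stops, internal stops, second-half terminal stops) to probe
   whether some stops might be read through or repurposed.
2. **Pathway completeness and consortium complementarity** — per-genome
   presence of biosynthesis genes against a curated catalog, pathway
   completeness, and step-wise union across consortium members.
3. **Pairwise genome comparisons** — rotation-aware SNP counting on
   circular genome pairs, 16S rRNA percent identity, OrthoANI-style
   average nucleotide identity, reciprocal-best-hit orthologue sharing,
   and summary genome statistics (length, GC%, feature counts).
4. **A synthetic-genome generator** with tracked ground truth, so that
   every analysis stage can be validated end-to-end with exact recall
   and precision, offline.

## Split genes: model and detection criterion

A split gene arises when a point mutation converts one sense codon into
a stop.  The annotation pipeline then reports two CDS: the first half
ends at the new stop, the second half begins at the following codon, so
the two halves are adjacent, on the same strand, and in the same frame.
In practice such halves are confirmed by manual BlastX domain
inspection against a protein database; `endosym` replaces that external
evidence with the *geometric* criterion that is its testable core.  A neighbouring
same-strand CDS pair (A, B) is a `SplitCandidate` iff:

* B is the next CDS downstream of A in coding orientation;
* the merged span from A's coding start to B's coding end has length
  divisible by 3 (no frameshift);
* translating the merged span in A's frame yields **exactly one**
  internal stop, located at or after A's annotated stop and before B's
  first codon;
* both halves are at least `min_half_length` codons (default 10) and
  the inter-half gap is at most `max_gap` nt (default 30).

Each CDS joins at most one candidate; pairing is greedy left-to-right
with a smaller-gap tie-break, so fragment chains degrade deterministically
into successive pairs.  Users with external homology evidence can pass a
table of locus-tag pairs that bypasses the gap cutoff.  The defaults are
permissive enough for the common stop-codon-only split (gap 0--3 nt)
while excluding unrelated neighbours, whose intergenic spacers in these
genomes are typically tens to hundreds of nt.

The criterion is deliberately conservative about what it claims: it
detects *mergeable* pairs, and on real annotations an unrelated gene
pair separated by a short, stop-free, in-frame spacer is
indistinguishable from a true split gene without homology evidence.
The synthetic generator therefore keeps intergenic spacers above
`max_gap` (31 nt floor), which makes planted splits the only qualifying
pairs and recall and precision exactly 1.0 — a property the test suite
asserts.  On real data the two evidence sources should be combined, and
detected candidates are reported alongside, not merged with, the
annotation's own pseudogene calls.

### Stop-codon usage in three groups

With candidates in hand, stop codons are tabulated for (1) terminal
stops of intact CDS, (2) the internal stop of each candidate, and (3)
the terminal stop of each candidate's second half.  Frequencies are
reported as integer percentages, rounded half away from zero to match
the convention of published tables; CDS that do not end in a stop codon
are excluded from group 1 and counted.  The package reports the table
and makes no claim about differences between groups: an elevated TGA
share among internal stops is an empirical observation to be reported,
not an invariant.

## Translation and coordinates

Translation uses the bacterial genetic code (table 11) with stop set
{TAA, TAG, TGA}; no codon reassignment is applied even though stop
repurposing is one hypothesis for the split genes — the package records
internal stops and leaves reassignment inference to future work.
Codons containing IUPAC ambiguity codes translate to `X`, and ambiguous
bases are excluded from both numerator and denominator of GC%, keeping
all statistics deterministic.

Internally all coordinates are 0-based half-open; GFF3, GenBank and the
TSV feature dialect are 1-based inclusive and converted only at the file
boundary, which keeps the merging arithmetic free of off-by-one cases.
Features crossing the origin of a circular genome are normalised to a
two-segment representation, and extraction follows the
`complement(join(...))` semantics: segments are concatenated in join
order and reverse-complemented as a whole for minus-strand features.

## The pathway catalog and complementarity model

The shipped catalog covers 13 pathways: the ten EAAs, cysteine,
riboflavin and biotin.  Each pathway is an ordered list of enzymatic
steps; each step is a set of alternative gene symbols (isozymes such as
`aroF`/`aroG`, or alternative enzymes such as `dapC`/`argD`).  Two
routes are catalogued in their host-complemented form, reflecting how
these consortia actually operate: methionine as the terminal
`metC`/`metE` reactions from host-derived cystathionine, and arginine as
the `carAB`--`argFGH` route from host-supplied glutamine/ornithine.
Gene symbols explicitly reported for these symbionts in the primary
literature are marked `source=reported` in the shipped presence fixture;
the remainder of the published repertoire is marked `source=curated`.  The catalog is data,
not code: curation disputes are resolved by editing a TSV.

Presence is called by annotated gene symbol after synonym normalisation
(case-insensitive), not by homology search — exactly testable, and
replaceable by an externally produced symbol table for real genomes.  A
symbol carried only by a merged split gene scores `present_split`,
which *counts toward coverage* (`bioA` and `ribD` are conventionally
scored as retained although split) while remaining visible in reports.

Consortium union marks a step covered when any member covers it.
`jointly_complete` additionally tolerates steps whose every alternative
is on a whitelist of host-complemented or lineage-wide-absent genes;
the default whitelist is `ilvA`, `hisN`, `yigB`, the three genes that
are missing from every relevant genome sequenced to date without
abolishing the phenotype.  Whitelisting is monotone: enlarging the list
can never revoke joint completeness.  Whether a pathway like methionine
"counts" as jointly produced is thus an explicit configuration decision,
not a hidden threshold: the union completeness fraction is always
reported alongside the boolean.

## Pairwise comparisons

**Rotation.** Closed circular genomes are deposited at arbitrary start
coordinates.  `rotate_align` finds the rotation supported by the most
k-mers (default k = 17) that occur exactly once in each genome — under
pure rotation plus scattered substitutions the true offset is the mode
of anchor position differences; ties break to the smallest offset.

**SNPs.** After rotation normalisation, equal-length pairs are compared
column-wise: substitutions are columns where both bases are unambiguous
and differ; ambiguity-containing columns are tallied separately and
never counted as substitutions.  Unequal-length pairs (up to 10%
difference) are segmented along a collinear chain of shared unique
anchors (longest increasing subsequence, thinned to one anchor per
~200 nt) and each inter-anchor segment is globally aligned; gap runs
count as indel events.  This avoids an intractable full
quadratic alignment of ~480 kb molecules while remaining exact for the
substitution-only regime, where the count is provably rotation-invariant
(the test suite checks recovery of planted counts under arbitrary
rotations, and symmetry in the argument order).

**16S identity.** Overlap (ends-free) global alignment, identity =
matches / aligned columns with internal gaps in the denominator and
terminal overhangs excluded — the standard convention for near-complete
rRNA comparisons; printed values are rounded half away from zero to
whole percent.  The reverse complement of the second sequence is tried
automatically.

**ANI.** An OrthoANI-style reciprocal-best-fragment mean: each genome is
cut into non-overlapping 1020-nt fragments; each fragment is placed in
the other genome by unique-k-mer seeding and aligned against a ±60 nt
window (global on the fragment, local in the window).  Reciprocal best
pairs with ≥ 70% fragment coverage contribute the mean of their two
directional identities.  Small numeric deviation from BLAST-based web
calculators is expected and documented; when no fragment pair qualifies
the result is flagged undefined rather than reported as 0.

**Orthologue sharing** is simplified to reciprocal best hits by local
protein alignment (BLOSUM62, gap open 11 / extend 1) with lexicographic
tie-breaks; full orthogroup graph clustering is out of scope.

## The synthetic generator: what it emulates, and what not

`simulate_genome` produces a circular genome of exactly the requested
length: ATG-initiated, stop-terminated, internally stop-free CDS with
codons sampled position-independently under the target nucleotide
weights (stop codons rejected and resampled), separated by intergenic
spacers with a 31-nt floor.  Defaults mirror the genomes this package
targets: 150 kb, GC 0.20, 150 genes of ~300 codons, spacers of ~90 nt
mean.  Terminal stops are drawn from (TAA 0.80, TAG 0.07, TGA 0.13) and
planted internal stops from (TAA 0.55, TAG 0.09, TGA 0.36), the usage
observed in the split-gene-rich genome, so fixtures resemble the real
object of study.  `plant_split_genes` rewrites exactly one mid-gene
codon (both halves kept ≥ 15 codons) and replaces the annotation by the
two halves; `mutate_pair` plants an exact number of substitutions, by
default re-drawing any that would create or destroy a stop codon inside
an annotated CDS, so SNP planting and split planting never interact;
`simulate_16s_pair` diverges a 1500-nt backbone at exactly
`round(length × (1 − identity))` positions.

All randomness flows from explicit seeds through a single stream per
operation (the caller's RNG state is saved and restored), making every
output byte-deterministic across platforms.

What the generator does **not** emulate — and hence what passing tests
do not show about real data: indels and rearrangements within a pair
(except via `count_snps`' segmented mode, which is tested on constructed
deletions), mutation-selection codon bias beyond the nucleotide-weight
model, overlapping or nested genes, RNA genes, short real intergenic
spacers below the detection gap threshold, and annotation errors other
than the split-gene pattern itself.  Claims about real genomes should
rest on the accession suite (`scripts/accession_suite.R`), which runs
the same functions on the deposited assemblies.

## Numerical and design choices

* Rounding of printed percentages and GC: half away from zero (matching
  published tables), at integer precision for identities and stop-codon
  frequencies and one decimal for GC.
* "87 genes split in two halves" is read as 87 merged genes, i.e. 87
  candidate pairs over 174 CDS; merged locus tags are
  `<first>_merged`.
* Same-strand overlapping CDS are rejected with an error listing the
  offending features rather than silently skipped: the merging
  arithmetic assumes a partial order.
* Whether published group-1 frequencies include pseudogene CDS is not
  stated; the default excludes features flagged pseudo
  (`include_pseudo = TRUE` to include them).
* Achieved GC is asserted within ±2 percentage points of target at
  generation time; the fixed ATG/stop codons perturb composition by well
  under that at default gene counts.
* Degenerate inputs: empty candidate sets yield header-only tables;
  an ANI with no qualifying pairs is `NA` with a warning; sequences
  under 1200 nt warn but still produce a 16S identity.

## Problem sizes used in the checks

The automated checks run entirely on synthetic data sized to exercise
the statistics without waste: a 150-kb / 150-gene genome with 20 planted
splits and a 68-substitution pair for exact-recovery checks; a 500-kb /
1000-gene genome with 1000 planted splits for the stop-usage
distribution (3-percentage-point tolerance at n = 1000); 30--60 kb
genomes for ANI and orthologue checks; and the shipped consortium
fixture for the complementarity pattern.  The exhaustive union oracle
enumerates all 2^15 presence patterns of a 3-genome × 5-step instance.

## Known limitations

* Presence calling trusts annotation gene symbols; unannotated or
  mis-labelled genes require the external symbol-table hook.
* The split-gene criterion cannot distinguish a true split gene from an
  unrelated in-frame neighbour pair at gaps below `max_gap` without
  homology evidence.
* The catalog transcribes one published figure's gene boxes; other
  systems need their own catalog file (the loader accepts any).
* ANI here is not numerically identical to BLAST-based OrthoANIu;
  differences of a few hundredths of a percent are typical.
* No indel simulation, recombination, or phylogenetic sequence
  evolution; no stop-codon reassignment inference.
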