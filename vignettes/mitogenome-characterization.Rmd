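---
title: "Characterizing tick mitogenomes: composition, architecture, codon usage and distance-based phylogenetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing tick mitogenomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitocomp)
```

## The analysis this package implements

When a new tick (Ixodida) mitochondrial genome is sequenced, its
announcement rests on a small, standard set of computations over the
annotated ~14-15 kb circular molecule: the 37-gene inventory (13
protein-coding genes, 22 tRNAs, 2 rRNAs, plus zero or more control
regions), per-region nucleotide composition with strand-asymmetry skews,
the junction-by-junction bookkeeping of gene overlaps and intergenic
spacers, start/stop codon usage including the incomplete stops restored
by polyadenylation, relative synonymous codon usage (RSCU), and a
distance-based phylogeny over the concatenated protein-coding genes.
`mitocomp` implements that pipeline end to end over an explicit data
model (`mitogenome_record`, a sequence plus an ordered feature table),
and pairs it with a seeded synthetic-genome generator so every stage is
testable without downloading any accession.

## Coordinates, strands and reading orientation

Coordinates are 1-based and inclusive on both ends, the convention of
published organization tables (so a gene at 1,211-2,734 is
2,734 − 1,211 + 1 = 1,524 bp, which is how the packaged tables verify).
Strands use the tick-mitogenomics J/N (majority/minority) labels. The
deposited sequence orientation is taken to be the N reading
orientation, and J-labelled features are read as the reverse
complement. Published tables do not state this mapping explicitly, but
it is the only convention consistent with the sign structure of
published per-gene GC skews: genes annotated on N (e.g. *nad2*, *cox1*)
show negative GC skew while J-encoded genes (*nad1*, *nad4*, *rrnL*,
*rrnS*) show positive GC skew, which happens exactly when each gene is
measured on its own reading strand. `extract_region()` applies the
mapping; in GenBank input, `complement(...)` locations receive the J
label.

## Composition and skew

`base_composition()` counts `A,C,G,T` and reports percentages of total
length; anything outside the alphabet (`N` etc.) is tallied separately
and excluded from skew numerators and denominators. Skews are the usual
asymmetry statistics AT-skew = (A − T)/(A + T) and
GC-skew = (G − C)/(G + C), computed identically from counts or
percentages; a zero denominator returns `NA` rather than a crash or an
infinity. `per_region_composition()` produces the conventional table
layout: whole genome on the deposited strand, each PCG/rRNA on its
reading orientation, all 22 tRNAs pooled into one row, and the control
region. Reporting precision mirrors the field's tables (2 decimals for
percentages, 3 for skews, via `format_composition()`); internal math is
full precision.

## Architecture bookkeeping

`junction_analysis()` scores each consecutive feature pair as
`downstream$start - upstream$end - 1`: positive values are intergenic
spacers, negative values overlaps, 0 abutting; one shared base is an
overlap of 1. On circular records a closure junction from the last
feature back to the first is added with spacing
`L + first$start - last$end - 1`.

Published tables print this quantity in an "intergenic nucleotide"
column, and for the packaged *Haemaphysalis* tables every internal
junction recomputed from coordinates equals the printed value. The one
exception is the circular closure of the *H. nepalensis* table, where
the coordinates give 8 and the printed column 7. Because a published
total (the 464 bp spacer sum) is only reproducible from the printed
column, `junctions_from_printed()` exposes the printed path separately
from the coordinate path, and the tests pin each to its own value
rather than papering over the off-by-one.

## Codon usage

CDS extraction (`extract_cds()`) completes incomplete stops by the
polyadenylation convention: a CDS whose annotated length is ≡ 1 (mod 3)
must end in `T` and is completed to `TAA`; ≡ 2 (mod 3) must end in
`TA`. Anything else dangling is an error, not a silent fix. Translation
uses NCBI table 5 (invertebrate mitochondrial) by default - standard
for Ixodida, with `ATA`=Met, `TGA`=Trp, `AGA/AGG`=Ser - and the code is
configurable per call. RSCU follows the textbook definition
(observed count × family size / family total, 0 for unused amino
acids), so the mean RSCU across a used family is exactly 1. Two
auditable choices, both switchable: stop codons (complete or completed)
are excluded from RSCU and amino-acid totals, and ATN start codons are
counted as the amino acid they encode rather than forced to Met.
Counting is frame 0 of the completed CDS only; there is no fuzzy frame
search.

## Distance phylogenetics

The phylogeny stage is the classic distance workflow: concatenate
per-gene alignments (taxon sets must match exactly; rows are matched by
label), remove every column containing a gap or ambiguity in any taxon
("complete deletion"), compute p, Jukes-Cantor or Kimura two-parameter
distances, build a neighbor-joining start tree, and refine under the
Minimum Evolution criterion: branch lengths are re-fit by ordinary
least squares on the path-length equations for every candidate
topology, negative estimates are clamped to zero, and a
nearest-neighbor-interchange hill-climb accepts whichever neighbour
minimizes the clamped total tree length until no interchange improves
it. Saturated distances (non-positive logarithm arguments) are errors
naming the offending pair; a bootstrap replicate that saturates is
skipped with a warning and removed from the support denominator.

Deliberate numerical choices:

* NJ ties in the Q matrix are broken lexicographically on the joined
  clusters' smallest original taxon labels, making the tree independent
  of input row order.
* The ME search is NNI-only from an NJ start - the desk-scale default
  of the common distance-ME implementations; no SPR.
* Bootstrap column draws come from a single seeded generator, drawn up
  front in replicate-sized blocks, so replicate *r* is reproducible in
  isolation and results cannot depend on evaluation order.
* Support is computed by bipartition matching (each internal edge keyed
  by the tip set on the side away from the alphabetically first taxon),
  which is well-defined for unrooted trees.

On exactly additive matrices this machinery is exact: NJ recovers the
generating topology, the OLS residual is zero, and refinement is a
fixed point - properties the tests check by brute force against an
enumeration of *all* unrooted 4- and 5-taxon topologies.

The distance models are deliberately simple (p/JC69/K2P). Published
analyses of this kind sometimes name composite-likelihood or GTR-class
distances; those model families are not reproducible from a printed
tree figure in any case, so exact published support values are out of
scope here, and the pipeline's correctness is instead established by
simulation (below).

## What the generator emulates - and what it does not

`simulate_mitogenome()` produces an annotated circular genome under the
`"haemaphysalis37"` template: the published 37-gene order, strands,
classes, gene lengths, codon assignments and junction spacings of a
*Haemaphysalis* mitogenome, with ~78% A+T (the observed tick value) as
the default composition target. Specific choices:

* **Overlap ownership.** At an overlap junction the shared bases can
  satisfy only one codon-constrained party. The codon-constrained side
  (a PCG) owns them: a downstream PCG overwrites its upstream
  neighbour's tail, a downstream RNA gene simply reads the bases
  already deposited. Three published junctions are overlaps between two
  PCGs (*atp8*/*atp6*, *nad4*/*nad4l*, *nad6*/*cytb*); since two PCGs
  cannot share bases while both keeping their drawn start/stop codons,
  the template resolves exactly those three to abutting and keeps every
  other printed spacing verbatim. Anticodons are planted at the centre
  of each tRNA, so the ≤ 10 bp tRNA-edge overlaps of the template never
  touch them.
* **Incomplete stops** fall out of the template gene lengths: a PCG
  whose length is not a codon multiple ends in `T` or `TA` (truncated
  at its junction), reproducing the published single-T set
  (*cox2*, *cox3*, *nad4*, *nad6*).
* **Composition correction.** ORFs are built by codon rejection
  sampling (no internal `TAA`/`TAG`). Rejecting those AT-rich codons
  would depress A+T by about a percentage point at a 78% target, so
  the generator solves for the pre-rejection base bias whose
  post-rejection expectation equals the target; empirically the
  realized whole-genome A+T lands within a few tenths of a point of
  78%.
* **Determinism.** Everything derives from `spec$seed`; identical seeds
  give byte-identical FASTA/GenBank/.tbl output.

`evolve_alignment()` simulates per-site independent substitution along
a tree (JC, or K2P with a transition/transversion rate ratio), with no
indels - so its output is an alignment by construction.

What the synthetic data does **not** emulate: real codon usage (codons
are drawn iid given the composition target, so amino-acid ranks follow
codon-family arithmetic rather than real mitochondrial preference),
tRNA secondary structure, among-site rate variation, base-frequency
drift between lineages, and indels. Passing tests therefore demonstrate
algorithmic correctness under the stated models, not that any
biological conclusion about a particular species is reproduced; the
published per-species values that require the deposited sequences
(genome sizes, amino-acid totals, figure-level support values) are
treated as metadata, never recomputed.

## Degenerate inputs and edge policy

Table-only records (annotation without sequence) are first-class:
architecture bookkeeping works, and every sequence-dependent operation
refuses with a "sequence required" error rather than guessing. Empty
feature tables, end < start without an origin-spanning flag, duplicate
names, unknown region names, non-tRNA anticodon queries, internal stop
codons, all-gap alignments and sub-3-taxon distance matrices are all
explicit errors. Printed-number artifacts (digit-grouping commas,
stray internal spaces) are stripped during table parsing because the
tables this package consumes genuinely contain them.

## Problem sizes used by the test-suite and acceptance script

The suite runs the full stack at deliberately desk-sized scales: 4-8
taxa for tree inference (where brute-force enumeration of topologies is
feasible as an oracle), 10 kb alignments for the 20-replicate topology
recovery study, 50 kb for the two-taxon distance-estimator consistency
check, 100 bootstrap replicates for support. These sizes give the
statistical headroom the assertions need (e.g. a binomial ±1.5
percentage-point band on a 14.7 kb A+T fraction) while keeping a full
run in tens of seconds.

## Known limitations

* The GenBank reader targets annotated mitogenome flat files (single
  record, simple or `complement()` locations); it is not a general
  GenBank parser and does not handle joins, multi-record files or
  qualifier continuation lines beyond locations.
* ME search is local (NNI): for large, noisy matrices it inherits the
  usual local-optimum caveats; at the tested scales the brute-force
  checks show it is exact.
* The architecture identity Σ lengths − Σ overlaps + Σ gaps = L assumes
  features that do not span the origin; origin-spanning features are
  supported in extraction but the packaged templates do not use them.
* RSCU on very short CDS sets is dominated by sampling noise; the
  family-mean-equals-1 identity still holds exactly, but per-codon
  values should not be over-read.
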