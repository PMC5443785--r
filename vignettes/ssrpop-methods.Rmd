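---
title: "ssrpop: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ssrpop: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssrpop)
```

`ssrpop` analyses simple sequence repeat (SSR/microsatellite) variation
at population scale: genome-wide cataloguing, genomic-region and SINE
vicinity distribution, per-locus polymorphism statistics with
high-quality filtering, cross-species flank conservation,
loss-of-function screening, and distance-based phylogenetics. This
vignette explains the models behind each stage, the parameters that
matter, and the choices made where the design was genuinely open.

## Canonical motifs

A repeat tract can be read from any phase and from either strand, so a
repeat unit is only defined up to cyclic rotation and reverse
complementation. `canonical_motif()` maps a unit to the
lexicographically smallest string in that orbit, which makes the class
labels come out in the familiar form (`AC/GT` is written `AC`,
`AAAT/ATTT` is written `AAAT`). Units that are whole-number repetitions
of a shorter unit (`ACAC`, homopolymers) are rejected: they do not
define a period unambiguously, and the scanner only ever emits the
smallest (primitive) period of a tract. Exhaustive orbit counting gives
4, 10, 33, 102 and 350 classes for periods 2–6; `enumerate_motif_classes()`
reproduces these by brute force, and the test suite checks them against
an independent enumeration.

## The perfect-repeat scanner

`scan_sequence()` detects **maximal perfect runs**: for each period
*p*, positions where the base equals the base *p* positions ahead are
computed in one vectorised pass, and maximal stretches of such matches
define periodic regions. A region qualifies when its repeat count
reaches `max(ceiling(min_len / p), min_repeat)` — with the default
10 bp floor and minimum repeat 3 this yields minimum repeat counts 5,
4, 3, 3, 3 for periods 2–6. Three conventions:

* **Trimming**: a region's length is floored to a whole number of
  units, anchored at the leftmost full unit. A consequence is that a
  run with a partial trailing unit anchors differently on the two
  strands (by less than one period); the tests document this.
* **Primitive period**: when a physical run is describable by several
  periods (`ACACAC…` as period 2 or 4) only the primitive period is
  emitted, which also removes ambiguous-length repeats.
* **N handling**: `N` never participates in a repeat; runs do not span
  `N`s.

Alignment-based detectors tolerate impure repeats; this scanner is
deliberately exact, which makes it verifiable against a brute-force
oracle (the suite compares the two on hundreds of random sequences) and
makes planted-truth recovery on synthetic genomes an exact test rather
than a statistical one. Genome-scale counts from impure-repeat
detectors will therefore differ; this package's claims are about its
own documented definition.

After scanning, `resolve_overlaps()` removes **every** locus that
shares a base with another locus — both members of a pair, all members
of a cluster, nested loci included. Keeping the longer locus would have
been the other defensible reading; removing all is the stricter
interpretation and leaves a catalogue in which every retained locus is
unambiguous.

## Genomic regions

`region_model()` decomposes each transcript of a GFF3 annotation into
CDS, UTRs (exonic minus CDS, split by strand-aware position relative to
the CDS), introns (gaps between exons) and a promoter defined as
2,000 bp upstream of the transcription start site, clipped at the
chromosome boundary. Classification priority, per transcript and for
the summary label, is

CDS > 5′UTR > 3′UTR > non-coding exon > promoter > intron > intergenic.

The priority resolves loci straddling boundaries (a locus across an
exon/intron junction counts as the exonic class) and makes the region
tallies mutually exclusive. A promoter call requires that the locus
touches no exonic or intronic feature of that transcript; a promoter
call on one gene outranks "intergenic" from every other gene. Loci
hitting several transcripts with conflicting labels are flagged
`multi_transcript` rather than silently resolved. Densities divide SSR
bp overlapping a region-class union by the class's total bp; classes
with zero total length are reported as undefined (`NA`), not zero.

## SINE-boundary enrichment

Both edges of every SINE interval contribute a 200 bp flank, cut into
non-overlapping 20 bp bins indexed by distance from the edge; bins
truncated by a chromosome end lose the clipped bases from the
denominator. An SSR contributes by overlapping base pairs, not by
whole-locus assignment, because the quantity of interest is length
density. The element interior is excluded — whether windows should
extend into the SINE body was an open choice; flanks-only matches the
question being asked (enrichment *near* elements). The genome-wide SSR
fraction is the control level, and `top_enriched_motifs()` ranks motifs
by peak window density relative to that motif's own genome-wide
density.

## Genotype statistics and the high-quality filter

Alleles are identified by the total repeat-tract length in bp (tables
in the offset convention are converted on input using the catalogue's
reference lengths); this makes frameshift arithmetic a direct length
difference. Per locus: allele frequencies are counted over
2 × n_called chromosomes, MAF is the frequency of the
second-most-frequent allele (the natural multi-allelic extension, 0
for monomorphic loci), observed heterozygosity is the fraction of
called individuals with two distinct alleles, and
PIC = 1 − Σpᵢ² — the expected-heterozygosity form, not the classical
Botstein formula with its extra cross term. Mean coverage is total
mapped reads over called samples only.

The high-quality filter applies, jointly with polymorphism (≥ 2
alleles): mean coverage **strictly greater than** 3×, mean
−log₁₀(1−Q) **strictly greater than** 0.6, call rate **at least**
0.6, reference length **at most** 80 bp, MAF **strictly greater
than** 0.1. The boundary semantics follow the wording of each
criterion, and each boundary has a dedicated fixture test (coverage of
exactly 3.0 is rejected; a call rate of exactly 0.6 is retained; a
reference length of exactly 80 bp is retained).

## Flank conservation

The conservation of a locus is the number of species (0–14) in which
both 200 bp flanks align "co-ordinately": a left and a right hit on
the same target chromosome, in the same orientation, in the correct
relative order for that orientation, with a target-side gap of
**strictly less than 300 bp**. Orientation consistency is required —
the minimal reading of co-ordinate alignment; a gap of exactly 300 bp
does not count (fixture-tested). A species counts once however many
hit pairs qualify. The per-base conservation score is averaged over
both flanks, skipping unscored bases; a locus with no scored flank
base is missing, not zero. Score tracks are taken as input in
catalogue coordinates — cross-genome coordinate mapping is outside the
package.

## Loss-of-function classification

For each non-reference allele and each transcript the locus touches,
exactly one consequence is assigned with priority
frameshift > splice > in-frame: a length change that is not a multiple
of 3 within CDS is a frameshift; otherwise overlap with the first or
last 2 bp of an intron (donor/acceptor core, strand-aware) is a splice
call; a multiple-of-3 change in CDS is in-frame. The 2 bp core site is
used rather than a wider splice region — the conservative reading of
donor/acceptor interference. Pure whole-unit alleles of triplet motifs
can never frameshift, which the property tests assert. Biological
post-hoc reasoning (e.g. a GT insertion inside a GT-tandem donor being
tolerated) is left to the analyst; the classifier reports mechanical
overlap.

## Distances and neighbour joining

The between-individual distance is
1 − identical/(identical + distinct) over loci called in **both**
samples; genotypes are compared as unordered allele pairs, and loci
missing in either sample are excluded from both counts (the
denominator is identical + distinct only, so complete-pair exclusion
is the faithful reading). `nj_tree()` is an in-repo Saitou–Nei
implementation: Q-criterion, ties broken by the smallest (i, j) index
pair, standard branch-length formulas, final three-cluster star
closure. On additive matrices it recovers the generating topology and
branch lengths exactly (the suite verifies 100 random trees to 1e-9,
and cross-checks topologies against an independent implementation).
Negative branch lengths are clamped to zero at output with the count
recorded in the `clamped` attribute. Breed summaries report means for
homozygous/heterozygous counts and both mean and median for windowed
ratios; the window default is 10 Mb for real chromosomes, with
`run_pipeline()` using 200 kb on the small synthetic genome.

## The synthetic study design

`sim_config()` fixes the default study: 2 chromosomes × 1 Mb at GC
0.42; 500 planted SSRs (150/100/120/70/60 for periods 2–6, motif
classes weighted towards A/T-rich units, repeat counts
minimum + geometric(0.5), tracts capped at 72 bp) plus 40 A/T-rich
tetranucleotide repeats within 40 bp of SINE boundaries; 12 gene
models (4 exons × 300 bp, 800 bp introns, 180/150 bp UTRs) with 20 %
of trinucleotide loci planted inside 5′UTRs; 40 SINE copies of 300 bp;
8 breeds × 2 samples split into a high-diversity group ("CH", forced
heterozygosity 0.25) and a low-diversity group ("EU", 0.10), breed
allele frequencies drawn from a Dirichlet around a common base
spectrum with concentration 0.3 (strong breed structure, so that breed
mates pair in the tree as the planted truth), allele count per locus
growing with reference repeat count (Poisson rate 0.2 per repeat),
10 % missing calls, read support 1 + Poisson(5), call quality
Beta(8, 2); conservation categories drawn with geometrically decaying
probabilities 0.6^k and score levels −0.5 + 0.2 × category.

Two properties make the generator a ground-truth instrument rather
than a data imitation:

* **Background rejection.** After planting, any scanner detection that
  is not a planted locus has its non-planted bases re-sampled, and
  buffer bases around each tract are fixed so tracts cannot extend;
  the loop repeats until the scanner finds exactly the truth table.
  Planted-truth recovery is therefore an exact test.
* **Unambiguous score tracks.** Flank score intervals covered by the
  flanks of more than one locus are dropped, so every locus's mean
  flank score equals its planted level exactly.

What the generator does **not** emulate: impure/interrupted repeats,
sequencing error and allelic dropout correlated with GC content,
linkage between loci, coalescent ancestry within breeds, and real SINE
sequence content (intervals are coordinates only). Passing tests
therefore demonstrate correctness of the analysis chain under its
stated definitions, not robustness to those real-data phenomena.

Problem sizes in the tests and acceptance script (10 kb oracle
sequences, 1 Mb chromosomes, 200 samples for frequency calibration, 50
to 100 random trees) were chosen so each stage's check is decisive
while the whole suite stays in the minutes range on one CPU.

## Numerical and degenerate-input conventions

Coordinates are 0-based half-open internally, converted at I/O
boundaries (BED/bedGraph stay 0-based, GFF3 is 1-based inclusive).
Empty sequences, all-`N` chromosomes, empty catalogues, empty
annotations and empty hit tables all return well-formed empty results
rather than errors; malformed inputs (non-ACGT units, unsorted loci,
CDS outside exons, `end ≤ start` intervals, q ≥ 1, duplicate
sample × locus records) raise errors naming the problem. Allele
frequency draws clamp Dirichlet underflow at 1e-9; lexicographic
operations use C-locale (radix) ordering so results do not depend on
the session locale.
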