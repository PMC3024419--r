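---
title: "Repeat discovery and recombination analysis in circular organelle genomes"
author: "mitorecomb"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Repeat discovery and recombination analysis in circular organelle genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitorecomb)
```

## The problem

Plant mitochondrial genomes are usually assembled and drawn as a single
circle, but in vivo they are a dynamic population of molecules. Dispersed
repeats act as substrates for intramolecular homologous recombination: a
crossover between the two copies of a **direct** repeat resolves the circle
into two subgenomic circles whose sizes sum to the genome length, while a
crossover between the copies of an **inverted** repeat inverts the segment
between them without changing the genome size. Large repeats (over ~1 kb)
recombine freely; whether the short repeats (tens to a few hundred nt) that
dominate some genomes recombine at all is harder to establish, because the
standard PCR assay for recombinant junctions can itself create chimeric
molecules in vitro (template switching by the polymerase, or re-priming by
incompletely extended strands across any shared sequence).

`mitorecomb` implements the computational side of such a study as a reusable
pipeline: repeat discovery by self-alignment, non-redundant repeat-content
statistics, prediction of recombinant configurations and of the PCR assays
that would detect them, detection of chimeric sequencing reads that span
recombinant junctions, an in-silico control for PCR-mediated recombination,
and mutually exclusive genome-content accounting. A synthetic-data module
generates all inputs with known ground truth, so every stage is testable
without downloads.

## Coordinates and circularity

All user-facing coordinates are 1-based inclusive, the convention of printed
repeat tables, so a published table row can be pasted directly into a test.
An interval with `start > end` wraps through the origin; negative
coordinates are never used. Conversion to 0-based half-open coordinates
happens in exactly one place, the BED writer. Sequences are uppercase
`A/C/G/T/N`; `N` never matches anything in alignment and is excluded from
both terms of the GC computation. Circularity is not expressible in FASTA,
so it is declared out-of-band (a flag per record on `read_genome_fasta()`).

## Repeat discovery

`find_repeats()` is a seed-and-extend local aligner specialised for genome
self-comparison:

1. **Seeding.** All exact words of length `word_size` (default **W = 7 nt**)
   shared between the genome and itself, forward–forward (direct) and
   forward–reverse-complement (inverted). The trivial identity diagonal is
   excluded and mirror duplicates (A–B vs B–A) are reported once. Runs of
   seeds on one alignment diagonal are collapsed to a single representative
   before extension.
2. **Extension.** Gapped extension in both directions (Rcpp), maximising the
   score under match `M = +1`, mismatch `N = -3`, and affine gaps costing
   `Q + g*R` for a gap of length `g` (defaults `Q = R = 3`), with **X-drop**
   termination (default 20 score units): a row of the banded dynamic
   program is abandoned once every cell falls more than X below the best
   score seen. The band half-width is derived from `(X - Q)/R`, since a
   larger diagonal offset cannot survive the X-drop. Identity is
   matches / alignment columns.
3. **Filtering.** Karlin–Altschul E-values, `E = K * m * n * exp(-lambda*S)`
   with `m = n = L`; hits with `E <= 1` (default cutoff) are repeats. For
   the +1/−3 scoring scheme the ungapped `lambda ~ 1.374` and `K ~ 0.711`
   are used by default; both are parameters of `alignment_params()`, since
   scoring schemes are sometimes published without their statistical
   parameters.
4. **Canonicalisation.** Copies are ordered `start1 <= start2`; a hit is
   dropped when both of its copies are contained in (or overlap, on
   essentially the same diagonal as) the copies of a higher-scoring hit of
   the same orientation. The greedy-by-score rule guarantees the
   maximal-scoring alignment of a region always survives; tandem-array
   hits, which live on well-separated diagonals, are untouched.

**Circularity.** The search runs on the genome concatenated with itself,
excluding the offset-`L` self-diagonal, and coordinates are mapped back
modulo `L`. Every repeat — in particular one spanning the origin — then
appears intact in at least one image. (An earlier design rotated the genome
by `L/2` and merged the two searches; it fails for the corner case of a
repeat with one copy crossing the origin and the other crossing the rotation
point, which is truncated in both framings, so the doubled-genome search was
adopted instead.) E-values always use the original length.

## Repeat statistics

`coverage_profile()` computes the **non-redundant** repeat content: every
genomic position covered by at least one repeat copy is counted once,
however many repeats cover it, and positions are classified as covered by
short repeats only (below a 1-kb threshold by default), by large repeats
only, or by both ("short within large"). The four classes partition the
genome exactly — an invariant that is property-tested against a per-position
bitmap oracle. Which class a *hit* feeds is decided by its own alignment
length; which class a *position* lands in is decided by the positions.

`count_unique_coordinates()` reports the number of distinct begin–end
coordinates over all hit copies, the repeat-number estimate used in
genome-scale surveys. For a `k`-copy family this lies between `k` (a perfect
family, every pairwise alignment on a copy has identical coordinates) and
`k*(k-1)` (imperfect, variably sized copies); `family_coordinate_bounds()`
derives both bounds by enumerating all copy pairs, so a six-copy family
ranges from 6 to 30. A subtlety worth recording: a *perfect* family with
five or more copies cannot, on a four-letter alphabet, have all pairwise
maximal alignments share exact coordinates — some pair of copies must share
a first flanking base (pigeonhole), and a maximal-scoring local alignment
necessarily absorbs it. The pipeline tests therefore demand exact
coordinates for families of up to four copies and the theoretical bounds
above for larger ones.

## Recombinant configurations and assays

For a repeat with canonical copies `R1` (start `s1`) and `R2` (start `s2`)
on a circle of length `L`:

* **Direct**: two subgenomic circles of sizes `s2 - s1` and `L - (s2 - s1)`.
  Junction labels follow the flank lettering `A | R1 | B ... C | R2 | D`:
  the `A->D` product joins the upstream flank of copy 1 through the repeat
  to the downstream flank of copy 2, `C->B` the reverse. Both reciprocal
  products are emitted.
* **Inverted**: one circle of unchanged size with the inter-copy segment
  reverse-complemented in place; junctions `E->G` and `F->H`. Applying the
  prediction twice restores the original sequence (a tested invariant), and
  the double-stranded base composition (A+T and G+C totals) is conserved —
  note that single-strand composition is *not*, since the inverted segment
  moves to the complementary strand.

Junction sequences contain one full repeat copy plus `flank` nt of unique
sequence on each side, and are extracted from the *constructed* product, so
they always reflect the copy physically retained in that product (surfaced
as `repeat_copy` metadata). For imperfect repeats the true recombinant may
carry the partner copy's variant sites — the crossover position within the
repeat is unobservable — which is why the metadata reports which copy was
used rather than guessing. Every junction of a repeat with unique flanks is
absent from the reference genome as a contiguous string; that is precisely
why junction-spanning evidence (PCR products, chimeric reads) is
informative.

`design_assay()` places primers in the unique flanks immediately adjacent to
the repeat, oriented to amplify only from the recombinant configuration
(expected product `2 * primer_len + repeat_len`); windows whose sequence
occurs more than once in the genome, and layouts that would also amplify a
short product from the reference, are rejected and reported. For inverted
repeats the two primers of a pair lie on the *same* strand of the reference
and become convergent only after the inversion.

`detect_chimeric_reads()` first discards any read consistent with the main
assembly (contiguous match to the circular reference, either strand, up to
`max_mismatch` mismatches); surviving reads are matched against the
predicted junctions and accepted when they anchor with at least `min_anchor`
nt (default 20) in the unique flank on *both* sides of the repeat — anchors
inside the repeat cannot tell the copies apart, so only flank sequence
counts. `quantify_configurations()` then reports, per repeat, the ratio of
reference-junction-spanning reads to recombinant-junction-spanning reads,
flagging the ratio undefined when no recombinant read was seen; this is the
read-based analogue of the qPCR-style under-abundance estimate.

## The PCR-recombination control

The bi-species control replaces a true repeat with a **surrogate repeat**: a
near-identical region shared between two different genomes, each occurrence
flanked by sequence unique within and between the genomes
(`find_surrogate_repeats()`, same alignment engine, plus a flank-uniqueness
test with a mismatch allowance derived from the identity floor). Any PCR
product joining the two species' flanks can only have been formed in vitro.

`simulate_pcr()` models chimera formation with the simplest mechanism that
exhibits the observed behaviour: per extension crossing a shared region, the
growing strand switches, with probability
`p_switch * n_other / (n_other + k_half)`, to a template of the *other*
species and completes there (exchange onto another template of the same
species yields an identical molecule and is therefore folded into
non-switching). `k_half = 0` (the default) gives a pure Bernoulli switch,
used for the limit checks: no chimeras at `p_switch = 0`, and at
`p_switch = 1` every *informative* product — one synthesised on a
pure-species template while the other species was present — is chimeric. A
positive `k_half` makes exchange a bimolecular encounter, which is what
produces the experimentally observed template-concentration dependence;
molecule counts are tracked in scaled-down units with a capacity plateau
(`max_molecules`, default 5000) standing in for reagent exhaustion. With
several shared regions the per-extension switch probability is
`1 - (1 - p_eff)^n_shared_regions` (at most one switch per extension: the
re-annealed strand is assumed to complete on its new template). Cycle count
defaults to 35, a standard protocol. The simulator is sequence-aware but
error-free: the evidence it models concerns junction identity, not point
errors.

`concentration_response()` runs seeded replicates across a template dilution
series. With defaults (`p_switch = 0.02`, `k_half = 1000`) and realistic
template numbers, dilute total-DNA-like reactions yield chimeras in a
minority of assays while 70-fold more concentrated amplicon-like reactions
yield them in essentially all — the qualitative contrast the control is
designed to demonstrate. The simulator predicts only this trend, not which
individual assays succeed.

## Genome-content partition

`partition_genome()` assigns every position to exactly one top-level
category by precedence — conserved syntenic, then chloroplast-like, then
nuclear-like, then mitochondrial-like, with the remainder uncharacterized —
so the counts sum to the genome length exactly, however heavily the input
intervals overlap. The order between chloroplast- and nuclear-like is not
dictated by the accounting itself and is configurable; the default places
chloroplast first, matching the treatment of mitochondrial-like as the
residual similarity class. Sub-features (protein exons, cis-spliced introns,
rRNA, tRNA) are tallied informationally and take no part in the exactness
invariant, since they live inside the conserved-syntenic class. Percents are
rounded half-up to one decimal (printed-table style); banker's rounding is
available. Similarity classification itself (database searches) is upstream
of this module, which consumes labelled intervals or pre-classified totals.

## The synthetic-data generator

`generate_genome()` emulates the system under analysis: a circular genome of
configurable length with i.i.d. background at 45.1% GC (a typical plant
mitochondrial composition; configurable), planted repeat pairs of specified length,
identity and orientation, and labelled promiscuous-DNA segments. Copy 2 is
derived from copy 1 by exactly the number of substitutions realising the
requested identity (nearest achievable; requesting 93% identity on an 80-nt
repeat gives 6 substitutions and a realised 92.5%), reverse-complemented for
inverted repeats. Two generator conventions keep the planted coordinates
well-defined rather than merely nominal:

* substitutions are rejected unless every prefix and suffix of the planted
  alignment keeps a strictly positive score (the k-th substitution from
  either end at offset at least `4k + 1` under +1/−3 scoring) — otherwise
  the maximal-scoring local alignment would *correctly* trim the plant;
* the `boundary_guard` bases (default 3) flanking each copy are forced to
  differ between the two copy contexts — otherwise a chance flank match
  makes the true repeat longer than its nominal plant.

`generate_recombinant_molecules()` emits the reference plus the predicted
product(s) of one repeat at a chosen reference:recombinant weight ratio
(e.g. 100:1, emulating substoichiometric recombinant configurations), and
`generate_reads()` draws error-free reads with Poisson counts proportional
to weight × molecule length (so `depth` is the reference coverage) and
uniform circular start positions, labelling each read with its source
molecule and, where applicable, the junction it spans. An optional uniform
substitution rate exists for robustness experiments; chromatogram-style
quality modelling, clone-library insert simulation and uncloneable-region
effects are deliberately out of scope. What passing tests on these fixtures
show is that the *pipeline logic* is correct under the stated read model;
they do not establish robustness to real Sanger base-calling error or
cloning bias.

`generate_bispecies_fixture()` builds two unrelated backgrounds sharing only
planted surrogate regions with the same boundary conventions.

## Problem sizes and numerical choices

The test battery uses 10-kb genomes with six planted repeats spanning the
short-repeat range of interest (38–175 nt, 93–100% identity, both orientations;
20 seeded fixtures for the recovery check), 100 random instances for the
coverage oracle, read pools up to ~65,000 reads for abundance-ratio
recovery (chosen so the expected recombinant junction-read count exceeds 20,
keeping the 3-standard-deviation Poisson check meaningful at ratios of 40
and 100), and 100 seeded PCR replicates per concentration level. These sizes
were chosen to make every stochastic check well-powered while the whole
suite stays comfortably fast on a laptop. Tie-breaking in the aligner
prefers the shortest maximal extension (earliest best cell) and diagonal
moves over gaps at equal score; degenerate inputs (empty hit lists, zero
depth, single-molecule pools, all-`N` sequences) are tested explicitly.

## Known limitations

* The aligner is a self-comparison tool, not a general BLAST replacement: no
  translated searches, no masking, no multi-genome databases; exact
  reproduction of a particular aligner's hit lists (hit-culling and
  span-suppression heuristics differ between implementations) is not a
  goal.
* Gapped alignments report a single maximal-scoring path; alternative
  co-optimal paths (and hence identities differing in the last decimal) are
  not enumerated.
* Recombination prediction covers single crossovers between two copies;
  compound events across several repeats are out of scope.
* The PCR switching model is deliberately minimal — one Bernoulli exchange
  per crossing with an encounter saturation — and its parameters are
  phenomenological, not fitted to any measured chimera yields.
* Inversion prediction requires non-wrapping repeat copies; an inverted
  repeat with a copy spanning the origin is detected but its product is not
  constructed.
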