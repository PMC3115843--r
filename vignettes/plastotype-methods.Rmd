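---
title: "Methods: plastid genome typing, diversity and networks in plastotype"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plastid genome typing, diversity and networks in plastotype}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plastotype)
```

`plastotype` implements the analysis chain used to characterise chloroplast
DNA (cpDNA) variation in the olive tree: scan a handful of complete,
aligned plastomes for every usable polymorphism; model the resulting
fragment-analysis marker panel; call multilocus haplotypes on population
samples; and summarise the variation with diversity statistics, a
reduced-median network and exact parsimony trees. This vignette documents
the models, the tunable parameters, the numerical conventions, and the
choices made where the underlying procedures are conventionally left
unspecified.

## 1. Scanning aligned plastomes

The central container is a `PlastomeAlignment`: equal-length gapped rows
over `A,C,G,T,N,-` with a designated reference taxon. All variant positions
are reported in 1-based coordinates on the reference's ungapped sequence;
an insertion relative to the reference anchors to the preceding reference
base. This matches the convention in which positions are quoted on a named
reference genome.

**Substitutions.** A column is called a substitution when it carries at
least two distinct bases among non-gap, non-`N` rows, and is *excluded*
whenever any row is gapped. Substitutions and indels are therefore counted
separately and every alignment column belongs to exactly one of
{invariant, substitution, gap-involved} — a conservation property the test
suite checks against a brute-force column classifier. Multi-allelic columns
count once in genome-wide totals; pairwise counts (`pairwiseSubstitutions`)
count each differing pair over the pair's mutually ungapped, unambiguous
columns. Columns falling in the inverted repeat are counted as they appear;
no IR deduplication is attempted.

**Indels.** Maximal runs of adjacent gap columns with an identical
presence/absence pattern across taxa merge into one event. Classification:

* `ssr_motif` — the event lies in an annotated microsatellite tract and its
  length is a whole number of motifs (a repeat-count step);
* `repeated_motif_7_12` — a 7–12 bp event whose block equals the
  immediately adjacent upstream or downstream sequence (presence/absence of
  a duplicated motif);
* `long` — longer than 12 bp (the class of the 225-bp and 342-bp
  lineage-diagnostic deletions);
* `other_short` — everything else up to 12 bp.

**SSR detection.** `detectSSR()` finds maximal non-overlapping tracts of a
primitive motif (1–6 bp; a `(TT)6` run is reported as `(T)12`). Because
detection thresholds are conventionally unstated, the defaults are the
field's common screening settings — mononucleotide ≥ 8, dinucleotide ≥ 5,
tri- to hexanucleotide ≥ 4 repeats — and are configurable. On an alignment,
per-taxon repeat counts are read through the tract's columns (plus adjacent
insertion columns), so a taxon's count is exactly what its own sequence
carries.

**Rates.** `substitutionRate(s, L, T)` = (s/L)/T in substitutions per site
per year, reported to two significant figures. The convention divides the
*total pairwise* divergence by the divergence time T (not 2T); with
417–432 substitutions over ~155.5–155.9 kb and a 14–22 My divergence this
yields the 1.2–2.0 × 10⁻¹⁰ range. `percentDivergence()` reports
100·s/L at two decimals.

**Coding effects.** `codingEffect()` translates the codon containing a
substitution under each observed state (standard genetic code, either
strand, explicit frame offset) and labels the site synonymous,
non-synonymous or non-coding.

## 2. The marker panel

The packaged `olivePanel()` models the 64-locus olive typing system:
62 length-polymorphism loci (51 with variable microsatellite motifs) plus
two CAPS loci scored as restriction-site presence/absence. The 35 loci of
the published six multiplex PCRs carry their dye (NED / HEX / 6-FAM) and
allele size range; locus 10 is typed separately and completes the 36-locus
rapid characterisation set; loci 8 and 61 are the gel-scored 225-bp and
342-bp deletions, modelled as binary calls, with the 342-bp event (locus
61, in *ycf1*) diagnostic for lineage E3 and the 225-bp event for the South
Asian lineages. Loci outside the published multiplexes have no public size
range and are marked range-unknown. Primer sequences and PCR chemistry are
metadata with no computational role.

Numerical conventions that the sizing software normally hides had to be
fixed for reproducibility:

* **Binning**: raw fragment sizes round to the nearest integer bp, ties
  half-up (158.5 → 159); calls outside the locus range by more than 1 bp
  (configurable) are flagged off-ladder.
* **Repeat counts**: each SSR locus carries an anchor (a known size ↔
  repeat-count pair); `count = anchor_count + (size − anchor_size)/|motif|`,
  and a non-integer quotient is an error rather than silently rounded.
* **Multiplex validity**: within one dye, pooled across co-electrophoresed
  groups, allele size ranges must be pairwise disjoint, and groups hold at
  most six loci (amplifying five or six loci per reaction is the practical
  ceiling). `designMultiplex()` uses greedy interval colouring by ascending
  range start, first-fit onto dyes, then splits each dye track into groups —
  deterministic and always valid, with no optimality claim.

## 3. Haplotypes and diversity

Individuals with identical complete multilocus profiles share a haplotype.
An individual with missing calls is assigned only when *exactly one*
catalogued profile is consistent with its non-missing calls — the
conservative resolution of a question the field usually leaves implicit.
Names are lineage prefix + ordinal: the prefix comes from the first
matching lineage-diagnostic character (e.g. the locus-61 deletion ⇒ E3),
`U` when no rule matches; ordinals follow descending observed frequency at
catalog build time and are frozen once a catalog exists, so adding samples
never renames published haplotypes.

Discriminating power is the plug-in statistic

$$D = 1 - \sum_i p_i^2,$$

the probability that two individuals drawn at random carry different
haplotypes. No small-sample correction is applied, matching the printed
formula; pooled D is always computed from pooled counts, never by
averaging per-group values (the tests include a case where the two differ
drastically).

The packaged survey table stores the published haplotype percentages for
186 cultivars and five wild populations. Reconstructing integer counts from
one-decimal percentages needs each group's sample size;
`inferSampleSize()` returns the smallest n under which every printed
percentage is an integer count. For the five wild populations this yields
21, 23, 22, 37 and 26 individuals — totalling exactly the stated 129. One
column (Bin El Ouidane) sums to 104.9% in the source: every percentage is
individually exact at n = 21 but the implied counts total 22, so
`countsFromPercent()` reconciles by decrementing the largest count. The
pooled wild D rounds to 0.89 under either resolution, so nothing downstream
depends on this choice.

## 4. Reduced-median networks

Character coding follows the single-step mutation assumption for plastid
microsatellites: SSR loci become *ordered* characters equal to the repeat
count, other indels become binary presence/absence, and loci combining an
indel with a microsatellite emit one ordered plus one binary character
(the allele size is decomposed using the indel length's residue class
modulo the motif length; a mixed locus whose indel length is a multiple of
its motif is rejected as undecomposable). CAPS loci are excluded by default
— homoplastic restriction sites are informative at lineage level but
distort networks — so haplotype pairs distinguished only by CAPS merge into
one node; they can be included as binary characters on request.

Ordered characters are expanded to cumulative threshold indicators
("count ≥ t" for each unit step between the observed minimum and maximum),
which preserves pairwise distances exactly: weighted Hamming distance on
the expansion equals the weighted sum of absolute repeat-count differences.
Non-distance-preserving encodings were rejected because they change the
network metric.

The network itself is built by median closure: identical split patterns are
merged into a single character of summed weight, haplotypes with identical
vectors merge into one node, and the majority-state median of every node
triple is added until closure, after which nodes at Hamming distance one
are joined. A frequency-guided reduction then removes inferred median
nodes that are redundant — deletable without disconnecting the graph or
changing any observed-pair distance — whenever their support (summed
observed frequency of their neighbours) falls below 1/r of the
best-supported alternative. The reduction parameter r defaults to 2 and is
exposed; published analyses rarely state it, and equal character weights
are the default because reported results are robust to reweighting indels
versus microsatellites (the package tests weight-scaling invariance
directly). Ties in the reduction are broken by lower support first, then
lexicographic node id, making the output deterministic.

Two exact properties anchor this construction: on compatible
(homoplasy-free) characters the result equals the unique perfect phylogeny
— verified exhaustively against an independent laminar-family construction
for up to 8 haplotypes × 12 characters — and every observed haplotype
appears exactly once in a connected graph.

## 5. Exact parsimony

For the plastome-scale matrices this domain produces (a handful of taxa,
tens of informative sites), heuristic tree search is unnecessary:
`exhaustiveSearch()` enumerates all (2n−5)!! unrooted binary topologies by
stepwise addition (3 topologies for 4 taxa, 10,395 for 8) and refuses more
than 10 taxa. Scoring is Fitch parsimony with equal weights, gaps and `N`
treated as fully missing; the implementation roots each topology along a
pendant edge (where pairwise set-intersection Fitch is exact) and collapses
duplicate site patterns with weights. Correctness is checked against an
independent Sankoff dynamic programme with unit costs on random instances.

All equally most-parsimonious trees are retained; the strict consensus
keeps only splits present in every optimum. The bootstrap resamples sites
with replacement and counts a split in a replicate only when it appears in
that replicate's strict consensus, so ties propagate as unresolved rather
than inflating support. Rooting places the root on the outgroup's pendant
edge.

## 6. The synthetic-data generator

The simulator provides planted ground truth for every downstream stage. A
root genome is a seeded random sequence with microsatellite tracts planted
verbatim (the single flanking base on each side is forced off-motif so a
planted `(T)12` is exactly 12 repeats), plus designated long-deletion sites
and optional gene intervals. Evolution along a rooted genealogy draws, per
branch, Poisson numbers of substitutions (rate × genome length × branch
length), single-step SSR mutations per locus (±1 repeat, with a step that
would reach zero flipped to +1), and indels from a mixture over {7–12 bp
motif duplication, short deletion ≤ 6 bp, long deletion at a designated
site}.

Three generator-level rules keep the truth-to-alignment mapping exact:
overlapping events are rejected and redrawn (so every event owns its
columns), non-SSR events avoid planted tracts padded by one motif length
(so every event has a single unambiguous class), and designated
long-deletion intervals are reserved up front. A single integer seed drives
everything; the draw order (per branch: substitutions, then SSR steps per
locus, then indels) is fixed, and identical seeds give byte-identical
FASTA/TSV outputs.

Population genotyping draws each individual's source haplotype from a
per-population frequency simplex, then applies ±1 bp fragment mis-sizing
(before binning) and missing data at configurable rates.

What the generator deliberately does *not* emulate: recombination
(plastomes are effectively non-recombining), heteroplasmy, sequencing
reads or chromatogram artefacts such as stutter, and recurrent mutation at
a single site (events are non-overlapping, so simulated data are
homoplasy-free along the genome even though real microsatellites are not).
Passing truth-recovery tests therefore demonstrates correctness of the
detection logic, not robustness to homoplasy or sizing artefacts beyond the
modelled ±1 bp noise. No published within-lineage mutation parameters
exist for these genomes; the default rates are chosen to give desk-scale
alignments a few dozen events, which exercises every code path without
saturating the genome.

Default problem sizes follow the same desk-scale logic: test fixtures use
2–20 kb genomes (a full 155-kb simulation is just a parameter choice, not a
different code path), populations of tens to a few hundred individuals, and
10,000 individuals where convergence properties (law of large numbers for
haplotype frequencies, near-unbiasedness of D) are asserted.

## 7. Known limitations

* Alignment construction is out of scope: the scanner consumes an existing
  multiple alignment and inherits its errors.
* The full 64-locus panel carries public size ranges only for the 36
  rapid-characterisation loci; the rest are range-unknown and cannot be
  validated for multiplexing.
* The reduced-median construction is a deterministic formulation of the
  published approach; where the original application's unstated internal
  tie-breaks differ, reticulation details in highly homoplastic regions may
  differ too (the homoplasy-free case is exact).
* Exhaustive parsimony is intentionally capped at 10 taxa; heuristic
  search, likelihood and Bayesian methods are out of scope.
* `discriminatingPower()` is the uncorrected plug-in statistic; for very
  small groups the (n/(n−1)) correction would differ noticeably, and the
  package deliberately matches the uncorrected convention.
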