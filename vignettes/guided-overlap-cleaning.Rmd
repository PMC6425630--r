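---
title: "Guided overlap-graph cleaning with linkage maps"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided overlap-graph cleaning with linkage maps}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(maptig)
```

## The problem and the model

Overlap-layout assembly of noisy long reads builds a bidirected graph
with two vertices per read (one per orientation) and an edge for every
suffix–prefix overlap, then reads unitigs — maximal non-branching paths —
off the graph.  Overlaps between repeats or spuriously similar reads add
edges that connect distant parts of the genome; each one can break a
unitig or seed a misassembly.

A dense genetic linkage map provides an independent, genome-wide partial
order: markers localised on draft contigs, grouped into co-segregating
bins, bins ordered within chromosomes.  `maptig` treats a bin as a
*colour* — the pair (chromosome index, bin ordinal) — and annotates every
vertex of the overlap graph with the set of colours its read touches.
Two colours are *adjacent at distance d* when they lie on the same
chromosome and their ordinals differ by at most `d`; colours on different
chromosomes are never adjacent, because chromosomes are independent
linear orders.  An edge whose two coloured endpoints have no adjacent
colour pair cannot lie on any path that walks the genome in map order,
so it is removed.

The guarantee this aims at: if every read is correctly coloured and every
read that is not a chromosome endpoint retains at least one genomic
incoming and outgoing edge, then after removing all inconsistently
coloured edges every unitig is a *rainbow* unitig — no colour recurs
after being left, and colours never decrease along the path.  A spurious
edge between consistently coloured reads can survive, but its endpoint
then has a second (genomic) edge on the same side and branches, so no
unitig uses it.  The test suite asserts this property over twenty
simulated replicates.

Colour sets (not single colours) matter in practice: a 15 kb read at
typical dense-map densities spans about thirty bins.  The rainbow
conditions are therefore evaluated set-wise: an edge is consistent when
*some* pair of endpoint colours is adjacent, and monotonicity along a
path requires the per-chromosome minimum and maximum of the colour sets
to be non-decreasing, which reduces to the single-colour definition when
sets are singletons.

## Pipeline and parameters

1. **Colouring.**  Reads are mapped to any draft assembly (the package
   consumes PAF from any mapper).  Per read only the single longest
   mapping is kept — one read, one locus; deliberately no
   mapping-quality filter — with ties broken by (target, position) so
   selection is deterministic.  The mapping is stretched to cover the
   unmapped read prefix/suffix, each side capped at **250 bp**
   (insertions dominate long-read error profiles, so unmapped read bases
   overestimate the missing target span); on the minus strand the read
   prefix extends the target end.  Stretched intervals go into a block
   index (default block size **10 000 bp**, about one read length;
   answers are exact and independent of the block size, which the suite
   verifies against a linear scan) and every marker assigns its bin
   colour to all reads covering its position.
2. **Propagation** (depth limit **10**).  Unmapped reads inherit the
   union of the colour sets of the nearest mapping-coloured reads,
   found by BFS through uncoloured vertices in both edge directions.
   The pass is simultaneous: only mapping-derived colours seed it, so
   chains of uncoloured reads cannot amplify each other and the
   operation is idempotent.  A deeper limit would colour more reads but
   increasingly over-approximates.
3. **Conflict removal.**  A propagated set that skips bins has jumped
   across the genome and cannot clean anything usefully; the read is
   removed.  "Skips" is made precise as *two or more* consecutive
   missing ordinals (or any multi-chromosome set): a single missing bin
   is within the adjacency slack that noisy real maps need anyway.
   Mapping-derived colourings are left alone — they are evidence, not
   inference.
4. **Inconsistent-edge removal** (distance **d = 1** by default).  The
   degree definitions already allow one bin of slack, and removal
   counts change little over d ∈ {0..3} (the suite asserts removal is
   monotone in `d` and that unitig N50 moves < 5 % across that sweep).
   Edges with an *uncoloured* endpoint are never removed: the
   inconsistency definition quantifies over existing colours, and an
   empty set would make every such edge vacuously "inconsistent",
   disconnecting exactly the unmapped reads propagation exists to
   rescue.
5. **Simplification.**  Standard topology-only steps re-implemented as
   plumbing: transitive reduction (an edge is dropped when a two-hop
   path implies the same placement within a **1000 bp** fuzz, computed
   from overlap lengths and the middle read's length) followed by
   removal of dead-end side branches of at most **4** reads that merge
   into another path.  Isolated short paths are kept — they are
   legitimate unitigs, not artefacts.

Graph construction from all-vs-all PAF uses the standard record
classification: aligned spans under **2000 bp** are ignored, records
whose unaligned overhang exceeds min(1000 bp, 0.8 × span) are internal
matches, reads whose flanks fit inside the partner are contained and
removed *before* any edge is added, and the rest become dovetail edges
(plus mirrors).  Contained-read removal before colouring keeps the graph
small; their information is redundant with the containing read's.

## Unitig extraction details

Linear edges — edges (u, v) that are colour-consistent with
`deg_c^+(u) = deg_c^-(v) = 1` — form vertex-disjoint chains and cycles,
so extraction follows them; the colour-consistent degrees use distance
max(1, d).  With an entirely uncoloured graph every edge is consistent
and the procedure degenerates to plain unitig extraction, making the
guided problem a strict generalisation of the unguided one.  Three
conventions close gaps the formal definitions leave open:

* **Mirror reporting.**  Every path coexists with its
  reverse-complement mirror; the lexicographically smaller vertex
  sequence is reported.  Cycles are broken at their smallest vertex
  before the comparison so each cyclic component is reported once.
* **Orientation.**  Monotonicity is direction-dependent (the mirror of
  an increasing path decreases), so each path is reported in the
  orientation with fewer per-edge monotonicity violations and split at
  any edge that still decreases — a genuine colour "peak" splits the
  path, a merely reversed path is flipped, not fragmented.
* **First vertex.**  The non-decreasing condition referencing a
  predecessor is vacuous for the first vertex of a path.

Sequences are spelled by overlap arithmetic (first read, then each
successor minus its overlap-length prefix), so assembled length equals
Σ read lengths − Σ overlap lengths; the suite checks this conservation
and that error-free simulated chains reproduce the genome slice exactly.

## What the simulator emulates — and what it does not

`simulate_genome_and_map()` draws uniform random chromosome sequences
and places markers uniformly at 0.008 markers/bp; a marker within 200 bp
of its predecessor joins the predecessor's bin, which makes consecutive
bins ≥ 200 bp apart and yields ≈ 0.002 bins/bp — the density regime of
real dense maps.  With a mean marker gap of 125 bp the probability that
a 200 bp gap starts a new bin is about e^−1.6 ≈ 0.2, giving the observed
ratio of bins to markers.  The genome serves directly as its own draft
assembly: that choice isolates colouring and cleaning from draft
quality, which is a separate axis the package does not model.

`simulate_reads()` uses uniform start positions, truncated-normal
lengths, random strands, and i.i.d. per-base errors with an
insertion-biased mix (ins:del:sub = 6:2:2, so 10 % errors lengthen reads
by ≈ 4 %).  Deliberately **not** emulated: realistic long-read length
distributions and error burstiness, heterozygosity and pooled
individuals, engineered repeats, and chimeric reads.  Passing tests
therefore show the method's logic is right under its stated assumptions
— correct colouring, genomic connectivity — not that a particular real
genome will assemble well; on real data the colouring accuracy is
bounded by the mapper and the map, and repeats supply consistent-coloured
spurious edges that only the branching argument (not removal) defuses.

True overlaps are emitted in genomic-span coordinates, exact for
error-free reads and approximate otherwise — the same character as real
overlapper output.  Injected spurious overlaps are clean dovetails
between reads whose acceptable colour ranges are ≥ 5 bins apart (or on
different chromosomes), so at d ≤ 3 every injected edge that survives
containment is provably inconsistent; the suite asserts their complete
removal over twenty seeds.

## Numerical and representation choices

* Colours are packed as `chromosome_index × 10^6 + ordinal` for storage
  in vectors and GFA `cl:Z:` tags.  Packed subtraction then preserves
  the cross-chromosome separation for any realistic `d` (maps with
  ≥ 10^6 bins per chromosome are out of scope by two orders of
  magnitude).  The same packing makes the nearest-colour join used for
  edge consistency a single sorted rolling join.
* The evaluator's acceptable range for a read is [colour of last marker
  at/before its true start, colour of first marker at/after its true
  end], clamped to the chromosome's first/last bin at the ends; reads
  with empty colour sets are reported as `uncoloured`, and reads only
  partially inside their range as `partial`, rather than folding either
  into the inside/outside dichotomy.
* An edge is genomic for evaluation purposes when the truth intervals
  overlap by ≥ 1 bp — the weakest reading, which makes the reported
  spurious counts conservative (an edge is only called spurious when the
  reads share no genomic base at all).
* All generators take explicit seeds and every stage is deterministic
  given its inputs; the suite checks each CLI stage is byte-identical
  across reruns.

## Problem sizes

The shipped checks run a 2 × 500 kbp (test suite) or 2 × 1 Mbp
(acceptance script) genome at 40× coverage — about 5 300 reads and
19 000 graph links — which the whole pipeline processes in well under a
minute on one CPU; property tests use 30–200 kbp genomes across many
seeds.  These sizes were chosen as the smallest at which coverage,
containment and bin statistics behave like the full-scale regime; all
densities and parameters are identical to the defaults documented above.

## Known limitations

* Repeat-induced spurious overlaps between *nearby* regions (< `d` bins
  apart) are never removed; the method's value is against long-range
  confusion.
* Conflict removal only inspects propagated reads; a read mis-mapped by
  the aligner keeps its wrong colours and must be caught as an
  inconsistent edge instead.
* Cleaning acts per edge; it does not re-join unitigs across removed
  junctions or order unitigs along the map, although the reported
  per-unitig colour ranges make such ordering straightforward
  downstream.
* Consensus polishing is out of scope; spelled unitig sequences carry
  the raw read error rate.
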