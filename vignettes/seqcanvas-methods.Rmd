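---
title: "seqcanvas: layouts, alignment compositing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{seqcanvas: layouts, alignment compositing and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(seqcanvas)
```

## What the package computes

`seqcanvas` turns nucleotide sequence into rasters in which one pixel is
one base, under two families of invertible layouts, and composites
chained whole-genome alignments into gapped pseudosequence pairs with
per-base provenance.  Everything downstream — annotation overlays,
difference columns, the unique-sequence subtraction, alignment
statistics, DeepZoom pyramids — is built on those transforms, so this
vignette concentrates on how they are defined, which knobs matter, and
where design choices were genuinely open.

## The tile layout

A tile layout is a nested mixed-radix positional system.  Level k has a
radix $r_k$ (how many sub-units it holds) and a trailing padding $p_k$
in pixels; levels alternate axes, level 1 along x.  Index $i$ (0-based)
is decomposed into mixed-radix digits and each digit multiplied by its
level's pixel stride:

$$x = \sum_{k\ \mathrm{odd}} d_k s_k,\qquad
  y = \sum_{k\ \mathrm{even}} d_k s_k,\qquad
  d_k = \left\lfloor i \Big/ \textstyle\prod_{j<k} r_j \right\rfloor \bmod r_k$$

with $s_k = 1 + p_k$ for the first level on an axis and
$s_k = r_j s_j + p_k$ otherwise ($j$ the previous level on the same
axis).  Because a unit's stride includes its own trailing padding, one
uniform recurrence covers every level; the operational consequence is
that the visible gap between adjacent columns equals $p_3$ exactly,
while the gap between chromosome mega-columns is $p_5$ plus the last
column's trailing pad.

```{r}
tl <- tileLayout()     # [(100,1000,100,26,999), (0,0,3,9,700)]
strides(tl)
indexToPixel(tl, c(99, 100, 99999, 100000))
```

The inverse decomposes each axis greedily by descending strides; any
residue left after the finest level, or a digit exceeding its radix,
means the pixel lies in whitespace and `NA` is returned.  On drawable
pixels the inverse is exact — the test suite checks the round trip
exhaustively on a small layout and by sampling on the default — and it
is what snippet extraction (`extractSnippet`, default 300 bp) uses to
recover sequence from a probed pixel.

Contig placement starts every contig at a fresh column (its first base
at the top of the column, which keeps labels and visual separation
clean), moving to the next mega-column when the remainder of the
current one cannot hold it; several small contigs can share a
mega-column.  No index space is reserved for titles: labels are drawn
as overlays only, so the index ↔ pixel bijection stays uncluttered.

## The ideogram (Peano) layout

The ideogram layout threads sequence along a generalized Peano curve
over a $\prod_k a_k \times \prod_k b_k$ grid given x radices
$(a_1,\dots)$ and y radices $(b_1,\dots)$.  At each level an
$a \times b$ arrangement of sub-blocks is traversed in boustrophedon
order — columns alternately upward and downward — and sub-blocks are
mirrored (x-mirror on odd positions within a column, y-mirror in odd
columns) so that each block's exit cell is grid-adjacent to the next
block's entry cell.  By induction every sub-path runs corner to
opposite corner, which requires **odd radices**; an even radix breaks
continuity, and the constructor refuses it with that explanation.

The contract is the bijection-plus-continuity pair, not one canonical
cell order: the curve family is defined by "visits every cell exactly
once, every step is one grid unit", and the tests assert exactly that
(exhaustively, on several radix sets).  The precise mirror bookkeeping
is an implementation choice.

`scale` magnifies the drawing: bases land at $(s\,x, s\,y)$ and, for
$s>1$, the pixels between consecutive bases are traced in neutral gray
so the path remains visible through the whitespace; at the default
$s=1$ every pixel is sequence.  There is no sensible universal default
radix set for arbitrary sequence lengths, so radices are user-supplied;
the documented example (x = 3,3,3; y = 5,3,3, a 27×45 grid of 1,215
cells) is the one used throughout the tests.  Sequence longer than the
grid is an error advising larger radices; shorter sequence leaves the
tail background-colored.

## Alignment compositing

A chained liftOver file is linearized onto one reference chromosome at
a time:

1. The **master chain** is the highest-scoring chain targeting the
   chromosome.  LiftOver files are score-sorted, so "first" and
   "largest" coincide; using the maximum makes the rule threshold-free.
2. Master blocks copy both sides (`syntenic`); dt gaps leave
   reference-only sequence over `-`; dq gaps insert query-only sequence
   over `-` in the reference.
3. Remaining chains, sorted by reference start, fill still-unaligned
   reference positions (`intra` if their query contig matches the
   master's, `inter` otherwise); '-' strand chains contribute
   reverse-complemented query.  Overlaps with already-aligned positions
   are truncated and reported — rearrangements within rearrangements
   are deliberately not portrayed.
4. Query-unique sequence is pulled in **only** at master-chain dq gaps,
   minus any query interval already claimed by a secondary chain's
   aligned blocks.  The subtraction is this package's rule: without it
   an inversion (master dt = dq = L plus a '-' strand chain over the
   same segment) would paint the inverted query twice, once as an
   insertion and once as the secondary alignment.

Two invariants anchor the whole module and are enforced by validity
methods and tests: stripping `-` from the gapped reference reproduces
the input reference byte-exactly (the reference keeps its order and
copy number), and provenance intervals partition the gapped length.

### Statistics

`computeStats` reports lengths, coverage, identity, gap spectra and
N-exchange.  Conventions, chosen once and used consistently:

* Identity is case-insensitive (soft-masking is display information,
  not sequence difference).
* Aligned positions where either side is N are excluded from both the
  identical and non-identical tallies and reported separately
  (`refNToQueryBp`, `queryNToRefBp`), so
  `identical + nonIdentical == alignmentLength` holds exactly and
  coverage is quoted against the N-free reference length.
* `refGap*` counts maximal runs of unaligned *reference* sequence
  (query-side `-`, i.e. dt gaps); `queryGap*` counts maximal runs of
  `-` punched into the reference (query insertions, dq gaps).  Each
  maximal run counts once, with `>10`, `>100`, `>1000` bp thresholds.
  "Which side owns a gap" is genuinely ambiguous in prose descriptions
  of alignment tables; this package fixes the dt-side = reference-gap
  convention and the synthetic generator's ground truth uses the same
  definition.

`chainCoverageProfile` reports coverage of each reference contig by the
union of aligned blocks of its top-k chains (k = 1, 2, 3, all), with
and without N positions, plus a homolog/non-homolog split driven by a
configurable query→reference name map (so e.g. query chromosomes 2A and
2B can both count toward reference chromosome 2).

## The synthetic-data generator

The generator exists so that every module is testable without
downloads, with ground truth known *by construction* rather than by
re-running the code under test.  `genGenome` emulates the features a
nucleotide raster actually shows: regional G/C shifts (isochores read
as background color changes; base GC 0.41, a typical vertebrate
average) and planted tandem repeat arrays (texture).  It does **not**
model repeat evolution, sequencing error or realistic gene structure —
passing tests demonstrate the transforms and the compositing/statistics
machinery, not biological realism.

`mutationRecipe` places non-overlapping, non-touching events (minimum
5 bp separation, both chain ends aligned) along the reference: SNPs,
one-sided indels, inversions, translocations.  `mutateAndChain` applies
them and emits the exactly corresponding chain set — inversions as '-'
strand chains with coordinates on the reversed query, translocations as
separate chains against a second query contig — together with the
implied statistics.  The acceptance suite runs 100 seeded recipes
(2.5 kb reference; events spanning the 10/100/1000 bp gap thresholds)
and requires every statistic to equal ground truth exactly; sizes were
chosen so the full suite stays comfortably interactive while covering
every event type and threshold.

## Rendering choices

* Palette (Okabe-Ito, colorblind-safe): A (0,158,115), C (0,114,178),
  T (86,180,233), G (230,159,0), N (220,220,220), gap/background white.
  The design constraints were: greens/blues predominate, one warm hue
  (G) so GC-content shifts read as color temperature, N neutral.  The
  exact RGB values are this package's choice, declared in
  `defaultPalette()` and overridable.
* Annotation overlays blend per feature: introns toward white at
  α = 0.2, exons at 0.45, repeats toward black at 0.35.  The orderings
  (exon lighter than intron; repeats darken) are the contract; the
  constants are configurable arguments.  Overlapping annotations blend
  twice — visible as doubly highlighted areas, intentionally.
* Drop shadows for highlighted query genes are a 2 px ring around the
  feature bbox; where the ring intersects other annotated pixels it is
  shifted inward by the overlap and the adjustment logged.  The
  collision rule is under-determined by prose; inward shifting is the
  simplest behavior that never obscures someone else's annotation.
* Label fonts come from a built-in 5×7 bitmap font scaled integrally,
  with a monotone lookup by bbox area ({<10³ px²: skip, <10⁴: 8 px
  opaque, <10⁶: 14 px at 0.8, else 28 px at 0.5}) — larger features get
  larger, fainter labels.  A bitmap font keeps output byte-deterministic
  across platforms, which a system font renderer would not.
* DZI pyramids: Format png, Overlap 0, TileSize 256; level
  $L = \lceil \log_2 \max(w,h) \rceil$ down to 1×1, each lower level an
  area-average (2×2 mean) of the one above, so zoomed-out pixels are
  the merged color of their sequence.  Odd dimensions replicate the
  trailing row/column before averaging; the conservation test therefore
  uses even dimensions, where $4\sum I_{L-1} = \sum I_L$ exactly.
* The master PNG is written whenever both sides are under 2¹⁵ px;
  beyond that only the pyramid is emitted.

## Degenerate inputs and numerical notes

Indices are held as doubles (exact integers up to 2⁵³ — the default
layout's capacity is ~2.6×10¹¹, far past 32-bit range).  Empty
sequence sets render a minimal background canvas; an empty alignment
reports zero percentages with a warning; GFF seqids that match no
placed contig are an error listing the unmatched names (guessing a
reconciliation would silently misplace annotations).  All randomness in
the generator flows from a single integer seed, and renders contain no
clocks, so identical configurations reproduce byte-identical outputs.

## Known limitations

* Unaligned query interior to *secondary* chains is never pulled in;
  only master-chain dq gaps contribute query-unique sequence.  For
  highly fragmented alignments the query can therefore appear as a
  subset of the reference.
* VCF/BED annotations, BGZF input, netting of chains and reciprocal-best
  enforcement are out of scope; liftOver files come from external
  aligners.
* The HTML output is a static stub pointing at the DZI; the interactive
  viewer itself is not part of the package.
* Annotation direction and exon boundaries receive less visual emphasis
  than the sequence itself — by design, the bare nucleotides carry the
  signal.
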