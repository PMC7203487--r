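# seqcanvas

Nucleotide-resolution genome rasters: every base of a genome becomes one
pixel, placed by a deterministic, exactly invertible coordinate
transform, so a whole assembly can be inspected visually — from
chromosome structure down to single bases — and any pixel can be mapped
back to the sequence it came from.

`seqcanvas` is aimed at genome assembly QA, whole-genome comparison and
communication: spotting assembly artifacts, isochores, repeat arrays and
centromeres directly in the bare sequence; compositing a UCSC chained
liftOver alignment of two genomes into a four-column difference view
with per-base provenance; and quantifying alignment coverage, identity
and gap-size spectra.

## The core transforms

**Tile layout.** A nested mixed-radix map. With radices
r = (r₁, …, rₙ) (levels alternating x, y axes) and trailing paddings
p = (p₁, …, pₙ), a 0-based sequence index i has mixed-radix digits
dₖ = ⌊i / ∏_{j<k} rⱼ⌋ mod rₖ and is drawn at

    x = Σ_{k odd} dₖ·sₖ ,   y = Σ_{k even} dₖ·sₖ

where the strides sₖ follow s(first level on an axis) = 1 + p and
sₖ = rⱼ·sⱼ + pₖ (j the previous level on the same axis).  The default,
`[(100, 1000, 100, 26, 999), (0, 0, 3, 9, 700)]`, gives rows of 100 bp,
100 Kbp columns, 10 Mbp mega-rows and 260 Mbp chromosome mega-columns,
with 3/9/700 px of whitespace between columns/mega-rows/mega-columns.
The inverse (`pixelToIndex`) decomposes each axis greedily by descending
strides and returns `NA` exactly on whitespace — the basis for offline
"mouseover" sequence retrieval (`extractSnippet`, 300 bp snippets).

**Ideogram layout.** A generalized Peano space-filling curve defined by
per-level (x, y) radices (all odd): each level traverses an a×b grid of
sub-blocks in boustrophedon order with alternate sub-blocks mirrored, so
consecutive sequence positions are always unit grid neighbors and
locality is preserved at every scale.

**Alignment compositing.** All liftOver chains targeting a reference
chromosome are linearized onto the reference positive strand: the
highest-scoring (master) chain fixes the coordinate frame, secondary
chains fill still-unaligned reference intervals (reverse-complemented
for '-' strand chains), and master-chain query gaps pull in
query-unique sequence.  The gapped reference reproduces the input
reference exactly after removing '-', and per-base provenance
distinguishes syntenic (white), intrachromosomal (blue) and
interchromosomal (red) sources.

## Worked example

Generate a 3 kb synthetic reference, mutate it with a known recipe
(8 SNPs, a 40 bp reference-only segment, a 12 bp query insertion, a
200 bp inversion, a 150 bp translocation), composite the emitted chain
file and compute the alignment statistics:

```r
library(seqcanvas)
ref <- genGenome(nContigs = 1, lengths = 3000, seed = 1)
rec <- mutationRecipe(refLen = 3000, nSnp = 8,
                      indels = data.frame(side = c("ref", "query"),
                                          length = c(40, 12)),
                      inversions = 200, translocations = 150, seed = 1)
mc   <- mutateAndChain(ref, rec)
comp <- compositeAlignment(ref, mc$query, mc$chains)
comp
#> CompositeAlignment of 'chr1': gapped length 3012, 9 provenance intervals
#>   inter           150 bp
#>   intra           200 bp
#>   syntenic        2610 bp
#>   unaligned_query 12 bp
#>   unaligned_ref   40 bp
computeStats(comp)
#>   refLenWithN        3,000
#>   alignmentLength    2,960
#>   unalignedRef       40
#>   coveragePct        98.67%
#>   identical          2,952
#>   nonIdentical       8
#>   identityPct        99.73%
#>   refGapCount        1
#>   refGapsGt10        1
#>   queryGapCount      1
#>   ...
```

Reading: the 40 bp reference-only segment is the single unaligned run
(`refGapsGt10 = 1`, `coveragePct = 100·2960/3000 = 98.67`), the 8 SNPs
are the only non-identical aligned bases (`identityPct = 99.73`), and
the inversion/translocation re-enter the composite as 200 bp `intra`
and 150 bp `inter` provenance — every field equals the recipe's ground
truth (`mc$groundTruth`).

Rendering the same genome:

```r
tl  <- tileLayout()           # strides 1, 1, 103, 1009, 11000
map <- placeContigs(ref, tl)
img <- renderRaster(map, tl, ref)
writeMasterPng(img, "master.png")
buildPyramid(img, "dzi")      # DeepZoom pyramid for pan-and-zoom
```

Or from the shell via the installed script:

```sh
seqcanvas --fasta ref.fa --outname demo
seqcanvas --fasta ref.fa --query_fasta query.fa \
          --chainfile ref_to_query.chain --outname demo_aln
seqcanvas --outname demo --query chr1:1001     # 300 bp snippet log
```

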