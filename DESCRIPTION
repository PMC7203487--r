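Package: seqcanvas
Title: Nucleotide-Resolution Genome Rasters with Invertible Tile and
    Peano Layouts
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Renders every nucleotide of a genome as one pixel using
    deterministic, invertible coordinate transforms: a nested mixed-radix
    tile layout and a continuous Peano space-filling curve, both with
    exact forward (sequence index to pixel) and inverse (pixel to
    sequence index) maps.  Supports GFF/GTF annotation overlays and
    parallel annotation tracks, compositing of UCSC chained liftOver
    whole-genome alignments into gapped reference/query pseudosequences
    with per-base provenance, alignment summary statistics (coverage,
    identity, gap-size spectra, per-chain coverage profiles), a gallery
    view for directories of multiple sequence alignments, DeepZoom (DZI)
    image pyramids, and a seeded synthetic-data generator that produces
    FASTA/GFF/chain fixtures with exactly known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    png,
    xml2,
    jsonlite,
    optparse
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
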