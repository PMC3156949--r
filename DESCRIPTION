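Package: chromoband
Title: Quantitative Banding Analysis of Immunostained Metaphase Chromosomes
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying histone-modification banding on metaphase
    chromosomes from multi-channel fluorescence images. Traces the chromatid
    medial axis, averages perpendicular intensity segments, anchors genomic
    calibration at a marked centromere, normalizes each chromatid to percent of
    maximum staining, bins profiles into equal windows and averages chromatids
    with centromere background subtraction. Companion functions aggregate
    genomic annotations (genes, CpG islands, SINE repeats), ChIP-seq-like
    signal tracks and per-gene expression into fixed megabase windows, and
    correlate metaphase band profiles against these interphase features. A
    synthetic-data module renders chromatid images and annotation tables with
    known ground truth so every stage of the pipeline can be validated without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    EBImage,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    igraph,
    jsonlite,
    yaml,
    tiff,
    png,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Epigenetics, ImageAnalysis, Visualization, Coverage
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bands.R'
    'chromspec.R'
    'compare.R'
    'io.R'
    'pipeline.R'
    'render.R'
    'scan.R'
    'simulate.R'
    'trace.R'
    'utils.R'
    'warp.R'
    'windows.R'
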