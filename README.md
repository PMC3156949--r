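# chromoband

Quantitative analysis of histone-modification banding on metaphase
chromosomes.

Antibodies against histone modifications linked to active chromatin
(H3K4me3, H3K9ac, H3K27ac) stain metaphase chromosomes in sharply defined
bands corresponding to 10–50 Mb genomic segments. `chromoband` turns
multi-channel fluorescence images of single chromatids into calibrated,
windowed band profiles and correlates them with sequence-derived
chromosome properties — gene and CpG-island density, SINE repeat
frequency, interphase ChIP-seq signal and transcription — at fixed
megabase resolution.

## What it computes

For each chromatid image (green = immunostain, red = DAPI, blue = manual
centromere marker line) the scanning module:

1. traces the chromatid medial axis (automatic skeleton tracing, or a
   user-supplied polyline),
2. averages each channel over perpendicular segments along the axis,
3. locates the centromere as the blue-channel argmax,
4. maps arc length to megabases piecewise-linearly per arm, anchored so
   the centromere sits exactly at its genomic position (120 Mb on the
   chromosome-1 geometry of 247 Mb), undoing per-arm differential
   stretching,
5. rescales each channel to percent of its own maximum,
6. sums the normalized fluorescence within 25 equal windows
   (nominally 10 Mb each).

Window profiles from many chromatids are then averaged (mean ± SD per
window, n recorded) and the value of the centromere window is subtracted
as background, clipped at zero. The feature module bins BED annotations,
bedGraph coverage and per-gene expression tables into 10-Mb windows
(counts by midpoint, length-weighted means for signal, sums for
expression; totals conserved exactly). The comparison module reports the
Pearson correlation between any two window tracks,

r with p from t = r·√((n−2)/(1−r²)), df = n−2,

pairwise correlation matrices with Benjamini–Hochberg-adjusted columns,
and metaphase/interphase alignments in which a 10-Mb track is resampled
onto the 25-equal-window scheme by length-weighted averaging.

Because chromosome-scan images of this kind are generally not deposited,
the package includes a first-class simulator: a ground-truth band model
(baseline + Gaussian bands + centromere gap), per-arm stretch warps,
rendered three-channel chromatid images with photometric noise, and
coupled annotation/signal/expression tables whose windowed densities
track the band model with tunable strength. Every stage of the pipeline
is validated against this truth.

## Worked example

```r
library(chromoband)

spec <- chr1Spec()
spec
#> ChromSpec 'chr1': 247 Mb, centromere at 120 Mb
#>   25 scan windows (9.88 Mb each); 10-Mb feature windows

## render a synthetic chromatid: five-band truth, arms stretched 1.2x/0.9x
model <- fiveBandModel(spec)
img <- renderChromatid(spec, model, WarpModel(spec, 1.2, 0.9),
                       noiseSd = 0.02, seed = 1)
img
#> ChromImage: 45 x 534 px (y x x), pixel size 0.1 um, truth 'sim-chr1-seed1'

## scan it
raw <- scanProfile(img, traceMedialAxis(img), widthPx = 11)
cen <- locateCentromere(raw)      # blue-channel argmax: segment 281 of 502
profile <- subtractBackground(averageProfiles(list(
  binProfile(calibrateScan(raw, cen, spec)))))
profile
#> MeanProfile on chr1: 25 windows, 1 chromatid(s), background window 13 subtracted

## compare with a coupled synthetic gene annotation
genes <- simulateFeatures(spec, model, 3071, coupling = 0.9, seed = 2)
geneTrack <- countFeatures(genes, makeWindows(spec, widthMb = 10))
alignMetaphaseInterphase(profile, geneTrack)$correlation
#> CorrelationResult (pearson): r = 0.9606, p = 2.79e-14, n = 25
```

The recovered single-chromatid profile correlates at r = 0.96 with the
gene-density track generated from the same band model: the scan,
anchoring, normalization and binning chain preserves the banding
structure the image was rendered from.

The whole chain — simulate 24 chromatids, scan, aggregate, bin features,
correlate — runs as one call:

```r
rep <- runPipeline(demoConfig(nChromatids = 24, seed = 7), outdir = "out")
rep$recovery   # profile vs generating band model, r > 0.99
rep$correlations  # profile vs gene/CGI/SINE density, signal, expression
```

All intermediates (TIFF images with JSON truth sidecars, BED, bedGraph,
TSV tracks, the averaged profile, the correlation matrix and a
provenance manifest) are written under `outdir`; reruns with the same
config and seed are byte-identical.

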