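---
title: "Quantifying histone-modification banding on metaphase chromosomes"
author: "chromoband"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying histone-modification banding on metaphase chromosomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromoband)
```

## The analysis

Immunofluorescent staining of metaphase spreads with antibodies against
histone modifications such as H3K4me3, H3K9ac or H3K27ac reveals sharply
defined bands along each chromosome, each band spanning roughly 10-50 Mb
of genomic DNA. Turning those images into numbers that can be compared
with sequence-derived chromosome properties requires three steps, and this
package implements all of them:

1. **Scanning** (`traceMedialAxis()`, `scanProfile()`,
   `locateCentromere()`, `calibrateScan()`, `binProfile()`,
   `averageProfiles()`, `subtractBackground()`): trace the medial axis of
   a chromatid, average pixel intensities over segments perpendicular to
   that axis, anchor the genomic calibration at a manually marked
   centromere, normalize each chromatid to percent of its own maximum
   staining, bin the profile into equal windows, and average many
   chromatids with background subtraction at the centromere.
2. **Feature binning** (`makeWindows()`, `countFeatures()`,
   `binSignal()`, `sumExpression()`): aggregate gene/CGI/repeat
   annotations, ChIP-seq-like coverage and per-gene expression into fixed
   megabase windows over the same chromosome.
3. **Comparison** (`correlateTracks()`, `correlationMatrix()`,
   `alignMetaphaseInterphase()`): Pearson correlation of the windowed
   metaphase profile against the windowed interphase features, with the
   t-transform significance.

Because real scan images of this kind are rarely deposited, the package
carries a first-class synthetic-data module (`renderChromatid()`,
`simulateFeatures()`, `simulateSignal()`, `simulateExpression()`) that
generates images and annotation tables from a known ground truth, so
every stage can be validated quantitatively.

## The geometry and its constants

The reference geometry is human chromosome 1: 247 Mb long with the
centromere at 120 Mb (`chr1Spec()`). Scan profiles are binned into 25
equal windows of 247/25 = 9.88 Mb — "nominally 10 Mb" each — while
genomic features are binned into true 10-Mb windows (25 windows, the last
spanning 240-247 Mb). Both conventions are supported by `makeWindows()`
(`nWindows =` for equal windows, `widthMb =` for fixed-width windows with
a partial last window); equal-25 is the default for scan data because the
per-chromatid calibration distributes samples over the full length, and
`alignMetaphaseInterphase()` reconciles the two schemes by
length-weighted resampling when tracks built on different schemes are
compared.

## Centromere-anchored calibration

Chromosome arms stretch by different amounts during spread preparation,
so equating arc length with genomic distance across the whole chromatid
would misplace every band. The scanning procedure therefore anchors
calibration at the centromere, located as the argmax of the blue marker
channel (ties resolve to the lowest index, with a logged message).
Arc-length fractions on the p side of the anchor are mapped linearly onto
[0, 120] Mb and fractions on the q side onto [120, 247] Mb. For any
per-arm linear stretching this inversion is exact: the centromere segment
sits at exactly 120 Mb and simulated band peaks return to their
generative positions within one window at zero noise, which is one of the
package's standing acceptance properties. Real stretching need not be
linear within an arm; residual nonlinearity shows up as peak broadening
in the averaged profile (see below), not as a systematic shift.

After position calibration each channel is rescaled to percent of its own
maximum, so every calibrated scan attains exactly 100 in both green
(immunostain) and red (DAPI) — this makes chromatids from different
spreads commensurable before averaging.

## Window statistic, background, and other decisions

Several details of the procedure admit more than one reasonable reading;
the package fixes defaults and exposes switches:

* **Sum versus mean within windows.** With near-uniform sampling along
  the axis the per-window sum and mean differ only by a constant factor
  that cancels in any correlation. The default is to *sum* normalized
  fluorescence within each window per chromatid and then take the mean
  and sample SD across chromatids; `binProfile(stat = "mean")` selects
  the alternative.
* **Background window.** The background is the averaged profile's value
  in the window containing the centromere (window 13 of 25 on the chr1
  geometry, spanning 118.56-128.44 Mb), subtracted from every window and
  clipped at zero — fluorescence is nonnegative, and the centromeric
  heterochromatin block carries essentially no signal for the active
  modifications, so its residual staining estimates the preparation
  background. `subtractBackground(backgroundWindow =)` overrides the
  choice. SDs are left untouched by the subtraction.
* **Marker masking.** Pixels on the blue centromere marker line are
  excluded from the green/red perpendicular averages so the annotation
  stroke cannot distort the fluorescence profile at the centromere.
* **Feature assignment.** Features are assigned to the single window
  containing their midpoint (`assignBy = "start"` is available). At
  10-Mb windows the choice is immaterial for gene-sized intervals, but
  midpoint is symmetric and is the documented default. Signal tracks, by
  contrast, are length-weighted across window boundaries, because a
  coverage interval is a density, not a point event.
* **Correlation statistic.** The comparison module uses the Pearson
  product-moment correlation with the two-sided p-value from
  $t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ degrees of freedom; Spearman is
  available via `method = "spearman"`. All 25 windows enter by default;
  an `exclude =` argument allows dropping the centromere window, where
  both tracks sit near zero and inflate r. Raw p-values are reported;
  the pairwise matrix also carries a Benjamini-Hochberg column for
  transparency, but no correction is applied to the headline values.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
with defaults chosen as the study conditions the pipeline was built for:

* **Band model** (`BandModel`, `fiveBandModel()`): baseline plus
  Gaussian bumps in genomic coordinate, width given as FWHM. The
  reference truth has five bands of 15-25 Mb FWHM and amplitudes
  0.6-1.0 on the chr1 geometry, baseline 0.05, and a zero-amplitude gap
  at 115-125 Mb representing centric heterochromatin. A Gaussian is one
  smooth unimodal bump among many that would serve; it was chosen for
  closed-form evaluation.
* **Differential stretching** (`WarpModel`): one linear stretch factor
  per arm, renormalized so pter maps to 0 and qter to 1. The demo
  pipeline draws per-chromatid stretch factors lognormally
  (log-SD 0.15, i.e. arms typically ±15%).
* **Rendering** (`renderChromatid()`): a constant-width tube (radius
  9 px) around a gently bent axis (default 400-500 px long), green along
  the axis equal to the band model at the warped genomic position,
  additive Gaussian photometric noise (SD 0.02 on a 0-1 intensity scale)
  clipped to the channel range, a uniform DAPI-like red plateau at 0.75,
  and a 2-px blue marker line crossing the axis perpendicularly at the
  warped centromere. Channel values live in [0, 1]; where overlapping
  bands push the model above 1 the channel saturates, exactly as a
  camera would. Imaging bit depth and background level are generator
  parameters, not quantities inferred from data.
* **Annotations** (`simulateFeatures()`): feature midpoints drawn from a
  mixture — with probability `coupling` from a density proportional to
  the band model, otherwise uniform — so windowed counts correlate with
  the band model at a tunable strength, monotonically in `coupling`.
* **Signal and expression** (`simulateSignal()`,
  `simulateExpression()`): Poisson per-step coverage with expectation
  proportional to the band model, and gamma-distributed per-gene
  expression whose mean interpolates between flat and
  band-proportional. The demo uses 3,071 genes, matching the RefSeq
  gene count of chromosome 1 at the time of the analysis, plus 2,000
  CGI-like and 8,000 SINE-like features.
* **Seeding.** Every generator is a pure function of its parameters and
  a seed. A master seed expands into independent per-component
  substreams via `childSeed()`, so adding a generator to a pipeline
  never perturbs the streams of the others, and `runPipeline()` reruns
  are byte-identical.

What the generator does *not* emulate: optics (no point-spread function,
no chromatic shift), antibody chemistry, touching or overlapping
chromosomes in a spread, nonlinear within-arm stretching, and spatially
correlated noise. Tests passing on synthetic data therefore validate the
measurement chain — tracing, sampling, anchoring, normalization, binning,
averaging, correlation — under known truth; they do not certify
segmentation performance on real, cluttered spreads.

## Automated axis tracing

The original workflow tracked the medial axis manually. The automated
replacement thresholds the DAPI channel by Otsu's method, keeps the
largest connected component, thins it to a one-pixel skeleton
(Zhang-Suen), prunes the skeleton to its longest geodesic path on the
8-connected pixel graph, smooths by spline, and resamples at 1-px arc
steps. Because thinning retracts from the rounded chromatid tips, the
smoothed path is then extended along its end tangents while the distance
transform stays near the tube radius, which restores the endpoints to
within ~1 px of the true axis ends. `traceMedialAxis(mode = "provided")`
accepts a user polyline instead (validated against the chromatid mask),
reproducing the manual workflow; pter orientation is declared by the
caller or taken from truth metadata, never guessed.

Perpendicular sampling uses the local smoothed tangent and bilinear
interpolation at 1-px spacing across the declared width; segments
reaching outside the image are clamped with a logged warning, never an
error. The sampling width should be slightly less than the chromatid
width (the demo uses 11 px against an 18-px-wide tube).

## Numerical choices and degenerate inputs

* Arc fractions are normalized to exactly [0, 1]; the centromere segment
  is pinned to exactly 120 Mb after calibration (no floating-point
  drift at the anchor).
* Windows are half-open `[start, end)` with the last window closed;
  window arithmetic is done in base pairs (1 Mb = 1,000,000 bp exactly)
  to avoid float boundary ambiguity.
* Empty scan windows yield 0 with a warning; an all-zero blue channel is
  a hard error (no centromere, no calibration); a centromere at a scan
  endpoint is an error (one arm would vanish).
* Argmax ties (centromere, channel maximum) resolve to the lowest index
  with a logged message.
* Zero variance in a track makes a correlation undefined and raises an
  error; `correlationMatrix()` records such cells as NA with the reason
  instead of failing the whole table.
* TSV outputs serialize floats at 9 significant digits with `.` for
  missing values, which makes reruns bit-stable.

## Validation scale

The test-suite and acceptance runs use the following problem sizes,
chosen to exercise every code path at desk scale: 24 rendered chromatids
(matching the number averaged in the reference analysis) at 400-500 px
axis length; binning oracles on 1,000-10,000 random elements per format;
10,000 replicates for the null-calibration and estimator-recovery checks
of the correlation module at n = 25 windows; 50,000 simulated features
per coupling level for the monotonicity check. Under these conditions
the full pipeline recovers the five-band truth profile with Pearson
r > 0.99 and every truth band within one window of a local maximum, the
null rejection rate at p < 0.05 sits within 0.05 ± 0.01, and the mean
estimated r is within 0.01 of the generating correlation.

## Known limitations

* The tracer assumes one chromatid per image; whole-spread karyotyping,
  sister-chromatid pairing and chromosome identification are out of
  scope.
* Per-arm linear calibration cannot correct nonlinear stretching within
  an arm; such distortion broadens averaged peaks (the averaged profile's
  peaks are never narrower than the narrowest single-chromatid peak, a
  property the acceptance suite checks with an equivalent-width metric).
* Discrete band calling — turning the continuous profile into named
  cytogenetic-style bands — is deliberately not implemented; the
  analysis is correlational.
* The correlation p-values assume independent windows; adjacent 10-Mb
  windows of real chromatin are not independent, so p-values on real
  data should be read as descriptive.
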