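#' @import methods
#' @importFrom stats rnorm rpois rgamma runif sd approx smooth.spline predict
#'   cor pt setNames p.adjust
#' @importFrom utils read.delim write.table head tail
NULL

# ---------------------------------------------------------------------------
# ChromSpec
# ---------------------------------------------------------------------------

#' Chromosome geometry specification
#'
#' A \code{ChromSpec} records the genomic geometry a scan is calibrated
#' against: physical length in megabases, centromere position, the number of
#' equal windows used for scan binning and the window width used for feature
#' binning. Human chromosome 1 (247 Mb, centromere at 120 Mb, 25 scan
#' windows, 10-Mb feature windows) is available as [chr1Spec()].
#'
#' @slot name chromosome label, e.g. \code{"chr1"}.
#' @slot lengthMb chromosome length in megabases (> 0).
#' @slot centromereMb centromere position in megabases, strictly inside
#'   \code{(0, lengthMb)}.
#' @slot nScanWindows number of equal windows the scan profile is binned
#'   into (>= 2).
#' @slot featureWindowMb window width in megabases for feature binning (> 0).
#'
#' @seealso [ChromSpec()], [chr1Spec()]
#' @exportClass ChromSpec
setClass("ChromSpec",
  representation(
    name = "character",
    lengthMb = "numeric",
    centromereMb = "numeric",
    nScanWindows = "integer",
    featureWindowMb = "numeric"
  )
)

setValidity("ChromSpec", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "'name' must be a single non-empty string")
  if (length(object@lengthMb) != 1L || !is.finite(object@lengthMb) ||
      object@lengthMb <= 0)
    msg <- c(msg, "'lengthMb' must be a single positive number")
  if (length(object@centromereMb) != 1L || !is.finite(object@centromereMb) ||
      object@centromereMb <= 0 || object@centromereMb >= object@lengthMb)
    msg <- c(msg, "'centromereMb' must lie strictly inside (0, lengthMb)")
  if (length(object@nScanWindows) != 1L || object@nScanWindows < 2L)
    msg <- c(msg, "'nScanWindows' must be >= 2")
  if (length(object@featureWindowMb) != 1L || object@featureWindowMb <= 0)
    msg <- c(msg, "'featureWindowMb' must be > 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# BandModel
# ---------------------------------------------------------------------------

#' Ground-truth band model
#'
#' Parametric description of immunofluorescent bands along a chromosome:
#' a nonnegative baseline plus a sum of smooth Gaussian bumps, one per band.
#' Band width is given as full width at half maximum (FWHM) in megabases.
#' An optional centromere gap forces the model down to baseline across a
#' stated region, mimicking the unstained centric heterochromatin block.
#'
#' @slot bands data.frame with columns \code{center_mb}, \code{width_mb}
#'   (FWHM) and \code{amplitude}; zero rows give a flat baseline model.
#' @slot baseline nonnegative background intensity.
#' @slot lengthMb chromosome length the model is defined over.
#' @slot centromereGap logical; if \code{TRUE} the model returns baseline
#'   inside \code{gapMb}.
#' @slot gapMb numeric of length 2 (\code{c(from, to)} in Mb) when
#'   \code{centromereGap} is set, else \code{numeric(0)}.
#'
#' @seealso [BandModel()], [bandIntensity()], [fiveBandModel()]
#' @exportClass BandModel
setClass("BandModel",
  representation(
    bands = "data.frame",
    baseline = "numeric",
    lengthMb = "numeric",
    centromereGap = "logical",
    gapMb = "numeric"
  )
)

setValidity("BandModel", function(object) {
  msg <- character()
  b <- object@bands
  need <- c("center_mb", "width_mb", "amplitude")
  if (!all(need %in% names(b)))
    return(sprintf("'bands' must have columns %s", paste(need, collapse = ", ")))
  if (nrow(b)) {
    if (any(b$amplitude < 0)) msg <- c(msg, "band amplitudes must be >= 0")
    if (any(b$width_mb <= 0)) msg <- c(msg, "band widths must be > 0")
    if (any(b$center_mb < 0 | b$center_mb > object@lengthMb))
      msg <- c(msg, "band centers must lie within [0, lengthMb]")
  }
  if (object@baseline < 0) msg <- c(msg, "'baseline' must be >= 0")
  if (object@lengthMb <= 0) msg <- c(msg, "'lengthMb' must be > 0")
  if (object@centromereGap) {
    if (length(object@gapMb) != 2L || object@gapMb[1] >= object@gapMb[2])
      msg <- c(msg, "'gapMb' must be c(from, to) with from < to when centromereGap is set")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# WarpModel
# ---------------------------------------------------------------------------

#' Per-arm linear stretch model
#'
#' Maps true genomic position (Mb) to arc-length fraction along the rendered
#' chromatid. Each arm stretches by its own positive factor and the map is
#' renormalized so that pter maps to 0 and qter to 1; the centromere's image
#' position follows from the two stretch factors. This emulates the
#' differential stretching of chromosome arms during spread preparation, the
#' artifact that centromere-anchored calibration corrects.
#'
#' @slot pStretch positive stretch factor of the p arm.
#' @slot qStretch positive stretch factor of the q arm.
#' @slot centromereMb centromere position in Mb of the underlying chromosome.
#' @slot lengthMb chromosome length in Mb.
#'
#' @seealso [WarpModel()], [warpPosition()], [identityWarp()]
#' @exportClass WarpModel
setClass("WarpModel",
  representation(
    pStretch = "numeric",
    qStretch = "numeric",
    centromereMb = "numeric",
    lengthMb = "numeric"
  )
)

setValidity("WarpModel", function(object) {
  msg <- character()
  if (object@pStretch <= 0 || object@qStretch <= 0)
    msg <- c(msg, "stretch factors must be > 0")
  if (object@centromereMb <= 0 || object@centromereMb >= object@lengthMb)
    msg <- c(msg, "'centromereMb' must lie strictly inside (0, lengthMb)")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# ChromImage
# ---------------------------------------------------------------------------

#' Rendered three-channel chromatid image
#'
#' Raster image of a single chromatid with a green immunostain channel, a
#' red DAPI-like morphology channel and a blue centromere marker line, plus
#' the ground truth used to render it (band model, warp, medial-axis
#' polyline with per-point ideal intensities). Channel matrices are indexed
#' \code{[row = y, col = x]} with values in [0, 1].
#'
#' @slot green,red,blue numeric matrices of identical dimension, values in
#'   [0, 1]; blue is nonzero only on the marker line.
#' @slot pixelSize micrometres per pixel (informational).
#' @slot truth list with elements \code{spec}, \code{model}, \code{warp},
#'   \code{axis} (data.frame x, y, arc_fraction, position_mb, intensity),
#'   \code{centromereArcFraction}, \code{radiusPx}, \code{pter}, \code{id}.
#'   Empty list for images loaded without a truth sidecar.
#'
#' @seealso [renderChromatid()], [writeChromImage()]
#' @exportClass ChromImage
setClass("ChromImage",
  representation(
    green = "matrix",
    red = "matrix",
    blue = "matrix",
    pixelSize = "numeric",
    truth = "list"
  )
)

setValidity("ChromImage", function(object) {
  msg <- character()
  d <- dim(object@green)
  if (!identical(d, dim(object@red)) || !identical(d, dim(object@blue)))
    msg <- c(msg, "channel matrices must share dimensions")
  rng <- range(object@green, object@red, object@blue)
  if (rng[1] < 0 || rng[2] > 1)
    msg <- c(msg, "channel values must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# MedialPath
# ---------------------------------------------------------------------------

#' Medial-axis polyline of a chromatid
#'
#' Ordered polyline of pixel coordinates from pter to qter with cumulative
#' arc length per vertex.
#'
#' @slot coords numeric matrix with columns \code{x}, \code{y} (pixel
#'   coordinates, 1-based, x = column, y = row).
#' @slot arc cumulative arc length per vertex, starting at 0, strictly
#'   increasing.
#'
#' @seealso [medialPath()], [traceMedialAxis()]
#' @exportClass MedialPath
setClass("MedialPath",
  representation(coords = "matrix", arc = "numeric")
)

setValidity("MedialPath", function(object) {
  msg <- character()
  if (nrow(object@coords) < 2L)
    msg <- c(msg, "a path needs at least 2 vertices")
  if (!identical(colnames(object@coords), c("x", "y")))
    msg <- c(msg, "'coords' must have columns x, y")
  if (length(object@arc) != nrow(object@coords))
    msg <- c(msg, "'arc' length must match the vertex count")
  if (length(object@arc) >= 2L && any(diff(object@arc) <= 0))
    msg <- c(msg, "arc length must be strictly increasing")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# RawScan
# ---------------------------------------------------------------------------

#' Raw chromatid scan
#'
#' Per-segment mean pixel intensities along a traced chromatid, before any
#' genomic calibration. One record per sampled axis point, ordered from pter
#' to qter; arc fractions run from 0 to 1.
#'
#' @slot data data.frame with columns \code{arc_fraction}, \code{mean_green},
#'   \code{mean_red}, \code{mean_blue}.
#' @slot widthPx width in pixels of the perpendicular sampling segment.
#' @slot source identifier of the source image.
#'
#' @seealso [scanProfile()], [locateCentromere()], [calibrateScan()]
#' @exportClass RawScan
setClass("RawScan",
  representation(data = "data.frame", widthPx = "numeric", source = "character")
)

setValidity("RawScan", function(object) {
  msg <- character()
  d <- object@data
  need <- c("arc_fraction", "mean_green", "mean_red", "mean_blue")
  if (!all(need %in% names(d)))
    return(sprintf("'data' must have columns %s", paste(need, collapse = ", ")))
  if (nrow(d) < 2L) msg <- c(msg, "a scan needs at least 2 segments")
  if (any(diff(d$arc_fraction) <= 0))
    msg <- c(msg, "arc fractions must be strictly increasing")
  if (abs(d$arc_fraction[1]) > 1e-9 || abs(d$arc_fraction[nrow(d)] - 1) > 1e-9)
    msg <- c(msg, "arc fractions must run from 0 to 1")
  if (any(d$mean_green < 0 | d$mean_red < 0 | d$mean_blue < 0))
    msg <- c(msg, "channel means must be >= 0")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CalibratedScan
# ---------------------------------------------------------------------------

#' Centromere-anchored, percent-normalized scan
#'
#' A [RawScan-class] after genomic calibration: segment positions are mapped
#' piecewise-linearly per arm so the centromere segment sits exactly at the
#' spec's centromere position, and each channel is rescaled to percent of its
#' own maximum.
#'
#' @slot data data.frame with columns \code{position_mb}, \code{pct_green},
#'   \code{pct_red}.
#' @slot centromereSegment index (1-based) of the centromere segment.
#' @slot spec the [ChromSpec-class] used for calibration.
#'
#' @seealso [calibrateScan()], [binProfile()]
#' @exportClass CalibratedScan
setClass("CalibratedScan",
  representation(data = "data.frame", centromereSegment = "integer",
                 spec = "ChromSpec")
)

setValidity("CalibratedScan", function(object) {
  msg <- character()
  d <- object@data
  need <- c("position_mb", "pct_green", "pct_red")
  if (!all(need %in% names(d)))
    return(sprintf("'data' must have columns %s", paste(need, collapse = ", ")))
  if (any(diff(d$position_mb) < 0))
    msg <- c(msg, "positions must be nondecreasing")
  if (any(d$position_mb < -1e-9 | d$position_mb > object@spec@lengthMb + 1e-9))
    msg <- c(msg, "positions must lie within [0, lengthMb]")
  i <- object@centromereSegment
  if (i < 1L || i > nrow(d))
    msg <- c(msg, "'centromereSegment' out of range")
  else if (abs(d$position_mb[i] - object@spec@centromereMb) > 1e-6)
    msg <- c(msg, "the centromere segment must sit at centromereMb")
  for (ch in c("pct_green", "pct_red")) {
    if (abs(max(d[[ch]]) - 100) > 1e-6)
      msg <- c(msg, sprintf("max(%s) must be exactly 100", ch))
    if (any(d[[ch]] < 0)) msg <- c(msg, sprintf("%s must be >= 0", ch))
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# WindowProfile / MeanProfile
# ---------------------------------------------------------------------------

#' Single-chromatid windowed profile
#'
#' Normalized fluorescence aggregated into the spec's equal scan windows for
#' one chromatid, per channel.
#'
#' @slot values numeric matrix, \code{nScanWindows} rows, columns
#'   \code{green} and \code{red}; all values >= 0.
#' @slot spec the [ChromSpec-class].
#' @slot chromatid identifier of the source chromatid.
#' @slot stat \code{"sum"} or \code{"mean"}: the within-window statistic.
#'
#' @seealso [binProfile()], [averageProfiles()]
#' @exportClass WindowProfile
setClass("WindowProfile",
  representation(values = "matrix", spec = "ChromSpec", chromatid = "character",
                 stat = "character")
)

setValidity("WindowProfile", function(object) {
  msg <- character()
  if (nrow(object@values) != object@spec@nScanWindows)
    msg <- c(msg, "'values' must have one row per scan window")
  if (!identical(colnames(object@values), c("green", "red")))
    msg <- c(msg, "'values' must have columns green, red")
  if (any(object@values < 0)) msg <- c(msg, "window values must be >= 0")
  if (!object@stat %in% c("sum", "mean"))
    msg <- c(msg, "'stat' must be 'sum' or 'mean'")
  if (length(msg)) msg else TRUE
})

#' Chromatid-averaged windowed band profile
#'
#' Per-window mean and standard deviation across chromatids, optionally
#' background-subtracted at the centromere window. This is the quantitative
#' banding pattern object the pipeline produces from a set of scans.
#'
#' @slot mean,sd numeric matrices (windows x channels \code{green},
#'   \code{red}); \code{sd} is the sample standard deviation across
#'   chromatids (all zero when only one chromatid was averaged).
#' @slot nChromatids number of chromatids averaged.
#' @slot backgroundValue named numeric: per-channel background subtracted
#'   (NA before [subtractBackground()]).
#' @slot backgroundWindow window index used as background (NA before
#'   subtraction).
#' @slot spec the [ChromSpec-class].
#'
#' @seealso [averageProfiles()], [subtractBackground()], [profileTrack()]
#' @exportClass MeanProfile
setClass("MeanProfile",
  representation(mean = "matrix", sd = "matrix", nChromatids = "integer",
                 backgroundValue = "numeric", backgroundWindow = "integer",
                 spec = "ChromSpec")
)

setValidity("MeanProfile", function(object) {
  msg <- character()
  if (!identical(dim(object@mean), dim(object@sd)))
    msg <- c(msg, "'mean' and 'sd' must share dimensions")
  if (nrow(object@mean) != object@spec@nScanWindows)
    msg <- c(msg, "'mean' must have one row per scan window")
  if (any(object@sd < 0)) msg <- c(msg, "'sd' must be >= 0")
  if (object@nChromatids < 1L) msg <- c(msg, "'nChromatids' must be >= 1")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# WindowScheme / WindowTrack
# ---------------------------------------------------------------------------

#' Fixed-window tiling of a chromosome
#'
#' Half-open windows \code{[start, end)} in base pairs tiling one chromosome
#' exactly once; the last window is closed (and may be partial when built by
#' width). Built either by window width or by an exact window count.
#'
#' @slot chrom chromosome name.
#' @slot boundaries numeric vector of bp boundaries, length
#'   \code{nWindows + 1}, starting at 0 and ending at the chromosome length.
#'
#' @seealso [makeWindows()], [windowRanges()]
#' @exportClass WindowScheme
setClass("WindowScheme",
  representation(chrom = "character", boundaries = "numeric")
)

setValidity("WindowScheme", function(object) {
  msg <- character()
  b <- object@boundaries
  if (length(b) < 2L) msg <- c(msg, "need at least one window")
  if (b[1] != 0) msg <- c(msg, "boundaries must start at 0")
  if (any(diff(b) <= 0)) msg <- c(msg, "boundaries must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Per-window numeric track
#'
#' One number per window of a [WindowScheme-class]: gene/CGI/SINE counts,
#' window signal means, expression sums or a windowed scan profile. The
#' common currency of the comparison module.
#'
#' @slot scheme the [WindowScheme-class].
#' @slot values numeric vector, one value per window.
#' @slot kind one of \code{gene_count}, \code{cgi_count}, \code{sine_count},
#'   \code{line_count}, \code{other_count}, \code{signal_mean},
#'   \code{expression_sum}, \code{scan_profile}.
#' @slot units free-text unit label.
#'
#' @seealso [countFeatures()], [binSignal()], [sumExpression()],
#'   [profileTrack()], [correlateTracks()]
#' @exportClass WindowTrack
setClass("WindowTrack",
  representation(scheme = "WindowScheme", values = "numeric",
                 kind = "character", units = "character")
)

.trackKinds <- c("gene_count", "cgi_count", "sine_count", "line_count",
                 "other_count", "signal_mean", "expression_sum", "scan_profile")

setValidity("WindowTrack", function(object) {
  msg <- character()
  nw <- length(object@scheme@boundaries) - 1L
  if (length(object@values) != nw)
    msg <- c(msg, "'values' length must equal the window count")
  if (!object@kind %in% .trackKinds)
    msg <- c(msg, sprintf("'kind' must be one of %s",
                          paste(.trackKinds, collapse = ", ")))
  if (grepl("_count$", object@kind) && length(object@values) &&
      any(object@values < 0 | object@values != round(object@values)))
    msg <- c(msg, "count tracks must hold nonnegative integers")
  if (object@kind %in% c("signal_mean", "expression_sum") &&
      length(object@values) && any(object@values < 0))
    msg <- c(msg, "signal/expression tracks must be nonnegative")
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# CorrelationResult / CorrelationMatrix
# ---------------------------------------------------------------------------

#' Correlation between two window tracks
#'
#' @slot r Pearson (or Spearman) correlation coefficient in [-1, 1].
#' @slot p two-sided significance from the t transform
#'   \eqn{t = r \sqrt{(n-2)/(1-r^2)}} with \eqn{n-2} degrees of freedom.
#' @slot n number of windows used (after exclusions).
#' @slot excluded window indices excluded from the computation.
#' @slot method \code{"pearson"} or \code{"spearman"}.
#'
#' @seealso [correlateTracks()]
#' @exportClass CorrelationResult
setClass("CorrelationResult",
  representation(r = "numeric", p = "numeric", n = "integer",
                 excluded = "integer", method = "character")
)

setValidity("CorrelationResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "|r| must be <= 1")
  if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must lie in (0, 1]")
  if (object@n < 3L) msg <- c(msg, "n must be >= 3")
  if (length(msg)) msg else TRUE
})

#' Pairwise correlation table of window tracks
#'
#' Symmetric matrices of pairwise correlations, raw p-values,
#' Benjamini-Hochberg adjusted p-values and window counts across a named set
#' of tracks; cells whose computation failed (e.g. zero variance) are NA and
#' listed with reasons.
#'
#' @slot r,p,q,n matrices (r symmetric with unit diagonal; q is BH-adjusted
#'   p over the off-diagonal cells).
#' @slot failures data.frame with columns \code{track1}, \code{track2},
#'   \code{reason}.
#'
#' @seealso [correlationMatrix()]
#' @exportClass CorrelationMatrix
setClass("CorrelationMatrix",
  representation(r = "matrix", p = "matrix", q = "matrix", n = "matrix",
                 failures = "data.frame")
)
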