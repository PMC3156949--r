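#' @include AllClasses.R
NULL

#' Scan a chromatid along its medial axis
#'
#' Resamples the medial path at 1-px arc steps and, at each axis point,
#' averages each channel over a perpendicular segment of the given width
#' (bilinear interpolation at 1-px spacing along the segment). Pixels lying
#' on the blue centromere marker line are excluded from the green/red
#' averages so the marker does not distort the fluorescence profile; the
#' blue mean itself uses all samples. Segments reaching outside the image
#' are clamped to its bounds with a single logged warning.
#'
#' @param image a [ChromImage-class].
#' @param path a [MedialPath-class] from pter to qter.
#' @param widthPx width of the perpendicular sampling segment in pixels
#'   (>= 1); choose slightly less than the chromatid width.
#' @return a [RawScan-class] with one record per axis point.
#' @examples
#' img <- renderChromatid(chr1Spec(), fiveBandModel(), seed = 1,
#'                        lengthPx = 150, radiusPx = 5)
#' scan <- scanProfile(img, traceMedialAxis(img), widthPx = 5)
#' head(scan@data)
#' @export
scanProfile <- function(image, path, widthPx = 9) {
  stopifnot(is(image, "ChromImage"), is(path, "MedialPath"), widthPx >= 1)
  # resample the path at 1-px arc steps
  s <- seq(0, max(path@arc), by = 1)
  if (length(s) < 2L) stop("path too short to scan", call. = FALSE)
  x <- approx(path@arc, path@coords[, "x"], xout = s)$y
  y <- approx(path@arc, path@coords[, "y"], xout = s)$y
  n <- length(s)
  # tangent by central differences, normal perpendicular to it
  tx <- c(x[2] - x[1], (x[-(1:2)] - x[1:(n - 2)]) / 2, x[n] - x[n - 1])
  ty <- c(y[2] - y[1], (y[-(1:2)] - y[1:(n - 2)]) / 2, y[n] - y[n - 1])
  nrm <- sqrt(tx^2 + ty^2)
  nxv <- -ty / nrm; nyv <- tx / nrm

  offs <- seq(-(widthPx - 1) / 2, (widthPx - 1) / 2, by = 1)
  sx <- outer(nxv, offs) + x # n x length(offs)
  sy <- outer(nyv, offs) + y
  g <- .bilinear(image@green, sx, sy)
  r <- .bilinear(image@red, sx, sy)
  b <- .bilinear(image@blue, sx, sy)
  nClamp <- attr(g, "clamped")
  if (nClamp > 0)
    warning(sprintf("%d perpendicular sample(s) outside image bounds; clamped",
                    nClamp), call. = FALSE)
  dim(g) <- dim(r) <- dim(b) <- dim(sx)

  onMarker <- b > 0.1
  meanMasked <- function(m) {
    allv <- rowMeans(m)
    masked <- rowSums(m * !onMarker) / pmax(rowSums(!onMarker), 1)
    ifelse(rowSums(!onMarker) > 0, masked, allv)
  }
  d <- data.frame(
    arc_fraction = s / max(s),
    mean_green = meanMasked(g),
    mean_red = meanMasked(r),
    mean_blue = rowMeans(b)
  )
  srcId <- if (length(image@truth) && !is.null(image@truth$id))
    image@truth$id else ""
  new("RawScan", data = d, widthPx = as.numeric(widthPx), source = srcId)
}

#' Locate the centromere segment of a raw scan
#'
#' The centromere is the segment with the maximal blue-channel mean (the
#' manually added marker line); ties resolve to the lowest index with a
#' logged message.
#'
#' @param scan a [RawScan-class].
#' @return integer segment index (1-based).
#' @examples
#' d <- data.frame(arc_fraction = c(0, 0.4, 0.6, 1), mean_green = 1,
#'                 mean_red = 1, mean_blue = c(0, 0, 5, 0))
#' locateCentromere(new("RawScan", data = d, widthPx = 1, source = ""))
#' @export
locateCentromere <- function(scan) {
  stopifnot(is(scan, "RawScan"))
  b <- scan@data$mean_blue
  if (all(b <= 0))
    stop("centromere marker missing: blue channel is identically zero",
         call. = FALSE)
  .argmaxLow(b, "blue channel")
}

#' Calibrate a raw scan to genomic coordinates
#'
#' Anchors the scan at the centromere and maps arc fractions
#' piecewise-linearly per arm onto megabases: fractions in \code{[0, fc]}
#' (where \code{fc} is the centromere segment's arc fraction) map linearly
#' onto \code{[0, centromereMb]} and fractions in \code{[fc, 1]} onto
#' \code{[centromereMb, lengthMb]}. Each channel is then rescaled to percent
#' of its own maximum, so each attains exactly 100. This exactly inverts any
#' per-arm linear differential stretching of the preparation.
#'
#' @param scan a [RawScan-class] (pter first).
#' @param centromereIdx centromere segment index from [locateCentromere()];
#'   must not be the first or last segment.
#' @param spec a [ChromSpec-class].
#' @return a [CalibratedScan-class].
#' @export
calibrateScan <- function(scan, centromereIdx, spec) {
  stopifnot(is(scan, "RawScan"), is(spec, "ChromSpec"))
  d <- scan@data
  n <- nrow(d)
  centromereIdx <- as.integer(centromereIdx)
  if (centromereIdx <= 1L || centromereIdx >= n)
    stop("calibration error: centromere at a scan endpoint leaves no arm",
         call. = FALSE)
  f <- d$arc_fraction
  fc <- f[centromereIdx]
  cen <- spec@centromereMb; L <- spec@lengthMb
  pos <- ifelse(f <= fc, cen * f / fc, cen + (L - cen) * (f - fc) / (1 - fc))
  pos[centromereIdx] <- cen # exact anchor
  pct <- function(v) 100 * v / max(v)
  out <- data.frame(position_mb = pos,
                    pct_green = pct(d$mean_green),
                    pct_red = pct(d$mean_red))
  new("CalibratedScan", data = out, centromereSegment = centromereIdx,
      spec = spec)
}

#' Bin a calibrated scan into equal windows
#'
#' Splits the chromosome into \code{nScanWindows} equal windows (half-open,
#' the last closed) and aggregates each channel's normalized values within
#' each window, summing by default. Empty windows get 0 with a logged
#' warning.
#'
#' @param cal a [CalibratedScan-class].
#' @param stat within-window statistic, \code{"sum"} (default) or
#'   \code{"mean"}. With near-uniform sampling along the axis the two differ
#'   only by a constant factor.
#' @param chromatid identifier recorded in the profile (defaults to the
#'   scan's source image id when available).
#' @return a [WindowProfile-class].
#' @export
binProfile <- function(cal, stat = c("sum", "mean"), chromatid = NULL) {
  stat <- match.arg(stat)
  stopifnot(is(cal, "CalibratedScan"))
  spec <- cal@spec
  nw <- spec@nScanWindows
  edges <- seq(0, spec@lengthMb, length.out = nw + 1L)
  idx <- findInterval(cal@data$position_mb, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nw)
  fidx <- factor(idx, levels = seq_len(nw))
  agg <- function(v) {
    out <- if (stat == "sum") tapply(v, fidx, sum) else tapply(v, fidx, mean)
    out[is.na(out)] <- 0
    as.numeric(out)
  }
  if (any(tabulate(idx, nbins = nw) == 0L))
    warning("empty scan window(s) set to 0", call. = FALSE)
  vals <- cbind(green = agg(cal@data$pct_green), red = agg(cal@data$pct_red))
  if (is.null(chromatid)) chromatid <- "chromatid"
  new("WindowProfile", values = vals, spec = spec,
      chromatid = as.character(chromatid), stat = stat)
}

#' Average windowed profiles across chromatids
#'
#' Per-window arithmetic mean and sample standard deviation across
#' chromatids, per channel.
#'
#' @param profiles list of [WindowProfile-class] objects on the same spec.
#' @return a [MeanProfile-class] (background not yet subtracted).
#' @seealso [subtractBackground()]
#' @export
averageProfiles <- function(profiles) {
  stopifnot(is.list(profiles), length(profiles) >= 1L,
            all(vapply(profiles, is, logical(1), "WindowProfile")))
  spec <- profiles[[1]]@spec
  same <- vapply(profiles, function(p) {
    identical(p@spec@name, spec@name) &&
      isTRUE(all.equal(p@spec@lengthMb, spec@lengthMb)) &&
      identical(p@spec@nScanWindows, spec@nScanWindows)
  }, logical(1))
  if (!all(same))
    stop("profiles were binned on different chromosome specs", call. = FALSE)
  n <- length(profiles)
  arr <- vapply(profiles, function(p) p@values,
                matrix(0, spec@nScanWindows, 2))
  mu <- apply(arr, c(1, 2), mean)
  sdv <- if (n >= 2L) apply(arr, c(1, 2), sd) else mu * 0
  dimnames(mu) <- dimnames(sdv) <- list(NULL, c("green", "red"))
  new("MeanProfile", mean = mu, sd = sdv, nChromatids = as.integer(n),
      backgroundValue = c(green = NA_real_, red = NA_real_),
      backgroundWindow = NA_integer_, spec = spec)
}

#' Subtract the centromere background from a mean profile
#'
#' Subtracts, per channel, the value of the background window from every
#' window's mean; results are clipped at 0 (fluorescence is nonnegative) and
#' standard deviations are unchanged. By default the background window is
#' the window containing the centromere, whose residual staining acts as the
#' background level of the preparation.
#'
#' @param profile a [MeanProfile-class].
#' @param backgroundWindow window index (1-based) or \code{"centromere"}
#'   (default) for the window containing \code{centromereMb}.
#' @return a [MeanProfile-class] with the background window's mean exactly 0.
#' @export
subtractBackground <- function(profile, backgroundWindow = "centromere") {
  stopifnot(is(profile, "MeanProfile"))
  spec <- profile@spec
  if (identical(backgroundWindow, "centromere")) {
    bw <- .scanWindowOf(spec, spec@centromereMb)
  } else {
    bw <- as.integer(backgroundWindow)
  }
  if (bw < 1L || bw > spec@nScanWindows)
    stop("background window out of range", call. = FALSE)
  bg <- profile@mean[bw, ]
  mu <- sweep(profile@mean, 2, bg)
  mu <- pmax(mu, 0)
  new("MeanProfile", mean = mu, sd = profile@sd,
      nChromatids = profile@nChromatids,
      backgroundValue = c(green = unname(bg["green"]),
                          red = unname(bg["red"])),
      backgroundWindow = bw, spec = spec)
}

#' Window track of one channel of a mean profile
#'
#' Converts a [MeanProfile-class] channel into a [WindowTrack-class] on the
#' spec's equal-window scheme, the form the comparison module consumes.
#'
#' @param profile a [MeanProfile-class].
#' @param channel \code{"green"} (default) or \code{"red"}.
#' @return a [WindowTrack-class] of kind \code{scan_profile}.
#' @export
profileTrack <- function(profile, channel = c("green", "red")) {
  channel <- match.arg(channel)
  stopifnot(is(profile, "MeanProfile"))
  spec <- profile@spec
  scheme <- makeWindows(spec, nWindows = spec@nScanWindows)
  new("WindowTrack", scheme = scheme,
      values = as.numeric(profile@mean[, channel]),
      kind = "scan_profile", units = "% of max, windowed")
}

#' @describeIn trackValues window matrix of a single-chromatid profile.
#' @export
setMethod("trackValues", "WindowProfile", function(x) x@values)

#' @describeIn trackValues per-window mean matrix of an averaged profile.
#' @export
setMethod("trackValues", "MeanProfile", function(x) x@mean)

setMethod("show", "RawScan", function(object) {
  cat(sprintf("RawScan: %d segments, sampling width %.3g px, source '%s'\n",
              nrow(object@data), object@widthPx, object@source))
})

setMethod("show", "CalibratedScan", function(object) {
  cat(sprintf(
    "CalibratedScan on %s: %d segments, centromere at segment %d (%.6g Mb)\n",
    object@spec@name, nrow(object@data), object@centromereSegment,
    object@spec@centromereMb))
})

setMethod("show", "WindowProfile", function(object) {
  cat(sprintf("WindowProfile '%s': %d windows (%s within window)\n",
              object@chromatid, nrow(object@values), object@stat))
})

setMethod("show", "MeanProfile", function(object) {
  cat(sprintf("MeanProfile on %s: %d windows, %d chromatid(s)%s\n",
              object@spec@name, nrow(object@mean), object@nChromatids,
              if (!is.na(object@backgroundWindow))
                sprintf(", background window %d subtracted",
                        object@backgroundWindow)
              else ", background not subtracted"))
})
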