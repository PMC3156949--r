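#' @include AllClasses.R
NULL

#' Render a synthetic chromatid image
#'
#' Draws a single chromatid as a constant-width tube around a smooth, gently
#' bent medial axis on a dark background. Along the axis the green
#' (immunostain) channel equals the band model evaluated at the warped
#' genomic position; the red channel carries a uniform DAPI-like level over
#' the chromatid body; a short blue marker line crosses the axis
#' perpendicularly at the warped centromere position. Zero-mean Gaussian
#' noise (clipped to [0, 1]) is added to green and red. The generating truth
#' (band model, warp, axis polyline with per-point ideal intensities) is
#' stored in the image for recovery tests.
#'
#' The pter telomere is always rendered at the left end; orientation is
#' recorded in the truth block.
#'
#' @param spec a [ChromSpec-class].
#' @param model a [BandModel-class] over the same length.
#' @param warp a [WarpModel-class] (default: identity).
#' @param noiseSd standard deviation of the additive intensity noise
#'   (channels are scaled 0-1; default 0.02).
#' @param bendAmplitude peak deviation of the axis from a straight line, in
#'   pixels (default 5).
#' @param seed integer; fixes all randomness.
#' @param lengthPx axis length in pixels (default 500).
#' @param radiusPx chromatid half-width in pixels (default 9).
#' @param pixelSize micrometres per pixel, informational (default 0.1).
#' @param dapiLevel red-channel plateau over the chromatid body
#'   (default 0.75).
#' @param markerThicknessPx thickness of the blue centromere line in pixels
#'   (default 2).
#' @return a [ChromImage-class] with a complete \code{truth} block.
#' @examples
#' img <- renderChromatid(chr1Spec(), fiveBandModel(), seed = 1,
#'                        lengthPx = 200, radiusPx = 5)
#' dim(img@green)
#' @export
renderChromatid <- function(spec, model, warp = identityWarp(spec),
                            noiseSd = 0.02, bendAmplitude = 5, seed = 1L,
                            lengthPx = 500L, radiusPx = 9L, pixelSize = 0.1,
                            dapiLevel = 0.75, markerThicknessPx = 2L) {
  stopifnot(is(spec, "ChromSpec"), is(model, "BandModel"),
            is(warp, "WarpModel"), noiseSd >= 0, lengthPx >= 20,
            radiusPx >= 2)
  if (abs(model@lengthMb - spec@lengthMb) > 1e-9)
    stop("band model length does not match the spec", call. = FALSE)
  # warp validity (monotonicity) is enforced by the WarpModel class itself

  margin <- radiusPx + 8L
  nx <- as.integer(lengthPx + 2L * margin)
  ny <- as.integer(2L * (radiusPx + ceiling(abs(bendAmplitude)) + 8L) + 1L)
  cy <- (ny + 1) / 2

  # medial axis: one vertex per x pixel step, single gentle bend
  tt <- seq(0, 1, length.out = lengthPx + 1L)
  xs <- margin + 1 + tt * lengthPx
  ys <- cy + bendAmplitude * sin(pi * tt)
  seg <- sqrt(diff(xs)^2 + diff(ys)^2)
  arc <- c(0, cumsum(seg))
  f <- arc / arc[length(arc)]
  gpos <- unwarpPosition(warp, f)
  ideal <- bandIntensity(model, gpos)

  # nearest-axis-point assignment by stamping discs around each axis vertex
  bestd <- matrix(Inf, ny, nx)
  besti <- matrix(0L, ny, nx)
  R <- radiusPx + 1L
  for (k in seq_along(xs)) {
    r0 <- max(1L, floor(ys[k] - R)); r1 <- min(ny, ceiling(ys[k] + R))
    c0 <- max(1L, floor(xs[k] - R)); c1 <- min(nx, ceiling(xs[k] + R))
    rows <- r0:r1; cols <- c0:c1
    d <- outer((rows - ys[k])^2, (cols - xs[k])^2, "+")
    upd <- d < bestd[rows, cols]
    if (any(upd)) {
      sub <- bestd[rows, cols]; sub[upd] <- d[upd]; bestd[rows, cols] <- sub
      subi <- besti[rows, cols]; subi[upd] <- k; besti[rows, cols] <- subi
    }
  }
  mask <- bestd <= radiusPx^2

  green <- matrix(0, ny, nx)
  red <- matrix(0, ny, nx)
  green[mask] <- ideal[besti[mask]]
  red[mask] <- dapiLevel

  if (noiseSd > 0) {
    nMask <- sum(mask)
    noise <- .withSeed(seed, list(g = rnorm(nMask, 0, noiseSd),
                                  r = rnorm(nMask, 0, noiseSd)))
    green[mask] <- green[mask] + noise$g
    red[mask] <- red[mask] + noise$r
  }
  green <- pmin(pmax(green, 0), 1)
  red <- pmin(pmax(red, 0), 1)

  # blue marker: a thin line perpendicular to the axis at the centromere
  blue <- matrix(0, ny, nx)
  fc <- centromereFraction(warp)
  kc <- which.min(abs(f - fc))
  kl <- max(1L, kc - 2L); kr <- min(length(xs), kc + 2L)
  tx <- (xs[kr] - xs[kl]) / sqrt((xs[kr] - xs[kl])^2 + (ys[kr] - ys[kl])^2)
  ty <- (ys[kr] - ys[kl]) / sqrt((xs[kr] - xs[kl])^2 + (ys[kr] - ys[kl])^2)
  nxn <- -ty; nyn <- tx
  for (s in seq(-(radiusPx + 1), radiusPx + 1, by = 0.25)) {
    for (u in seq(-(markerThicknessPx - 1) / 2, (markerThicknessPx - 1) / 2,
                  by = 0.25)) {
      px <- round(xs[kc] + s * nxn + u * tx)
      py <- round(ys[kc] + s * nyn + u * ty)
      if (px >= 1 && px <= nx && py >= 1 && py <= ny) blue[py, px] <- 1
    }
  }

  truth <- list(
    spec = spec, model = model, warp = warp,
    axis = data.frame(x = xs, y = ys, arc_fraction = f, position_mb = gpos,
                      intensity = ideal),
    centromereArcFraction = fc, radiusPx = radiusPx, pter = "left",
    id = sprintf("sim-%s-seed%d", spec@name, as.integer(seed))
  )
  new("ChromImage", green = green, red = red, blue = blue,
      pixelSize = as.numeric(pixelSize), truth = truth)
}

setMethod("show", "ChromImage", function(object) {
  d <- dim(object@green)
  cat(sprintf("ChromImage: %d x %d px (y x x), pixel size %.3g um%s\n",
              d[1], d[2], object@pixelSize,
              if (length(object@truth)) sprintf(", truth '%s'", object@truth$id)
              else ", no truth"))
})
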