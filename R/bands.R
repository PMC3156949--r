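#' @include AllClasses.R
NULL

#' Construct a band model
#'
#' @param bands data.frame with columns \code{center_mb}, \code{width_mb}
#'   (full width at half maximum, Mb) and \code{amplitude}; may have zero
#'   rows for a flat baseline-only model.
#' @param baseline nonnegative background intensity (default 0).
#' @param lengthMb chromosome length the model spans.
#' @param centromereGap if \code{TRUE}, the model returns baseline inside
#'   \code{gapMb}.
#' @param gapMb numeric \code{c(from, to)} in Mb delimiting the centromere
#'   gap; required when \code{centromereGap} is set.
#' @return a [BandModel-class].
#' @examples
#' BandModel(data.frame(center_mb = 60, width_mb = 10, amplitude = 1),
#'           baseline = 0.05, lengthMb = 247)
#' @export
BandModel <- function(bands = data.frame(center_mb = numeric(),
                                         width_mb = numeric(),
                                         amplitude = numeric()),
                      baseline = 0, lengthMb, centromereGap = FALSE,
                      gapMb = numeric(0)) {
  new("BandModel", bands = as.data.frame(bands), baseline = as.numeric(baseline),
      lengthMb = as.numeric(lengthMb), centromereGap = isTRUE(centromereGap),
      gapMb = as.numeric(gapMb))
}

#' Five-band reference model for a chromosome spec
#'
#' A ground-truth model with five Gaussian bands of 15-25 Mb width spread
#' over both arms, a low uniform baseline, and a centromere gap of zero band
#' amplitude around the centromere. Emulates the observed banding scale
#' (sharply defined bands spanning roughly 10-50 Mb) on a chromosome-1-like
#' geometry and is the default simulation truth throughout the package.
#'
#' @param spec a [ChromSpec-class]; band positions scale with its length.
#' @return a [BandModel-class] with 5 bands.
#' @examples
#' fiveBandModel(chr1Spec())
#' @export
fiveBandModel <- function(spec = chr1Spec()) {
  L <- spec@lengthMb
  s <- L / 247 # positions stated for the chr1 geometry, scaled to others
  BandModel(
    bands = data.frame(
      center_mb = c(25, 60, 95, 160, 205) * s,
      width_mb = c(18, 22, 15, 25, 20) * s,
      amplitude = c(0.90, 0.70, 1.00, 0.80, 0.60)
    ),
    baseline = 0.05, lengthMb = L, centromereGap = TRUE,
    gapMb = spec@centromereMb + c(-5, 5) * s
  )
}

#' Evaluate a band model at genomic positions
#'
#' Returns baseline plus the sum of Gaussian band contributions. Each band
#' contributes \code{amplitude * exp(-(x - center)^2 / (2 sigma^2))} with
#' \code{sigma = width_mb / (2 sqrt(2 log 2))} so that \code{width_mb} is the
#' full width at half maximum. Inside the centromere gap (when set) the
#' model returns baseline.
#'
#' @param model a [BandModel-class].
#' @param positionMb numeric vector of genomic positions in Mb, all within
#'   \code{[0, lengthMb]}.
#' @return numeric vector of nonnegative intensities.
#' @examples
#' m <- fiveBandModel()
#' bandIntensity(m, c(0, 60, 120, 200))
#' @export
bandIntensity <- function(model, positionMb) {
  stopifnot(is(model, "BandModel"))
  if (any(positionMb < 0 | positionMb > model@lengthMb))
    stop("position outside [0, ", model@lengthMb, "] Mb", call. = FALSE)
  v <- rep(model@baseline, length(positionMb))
  if (nrow(model@bands)) {
    for (i in seq_len(nrow(model@bands))) {
      b <- model@bands[i, ]
      sigma <- b$width_mb / (2 * sqrt(2 * log(2)))
      v <- v + b$amplitude * exp(-(positionMb - b$center_mb)^2 / (2 * sigma^2))
    }
  }
  if (model@centromereGap && length(model@gapMb) == 2L) {
    gap <- positionMb >= model@gapMb[1] & positionMb <= model@gapMb[2]
    v[gap] <- model@baseline
  }
  v
}

#' Truth window track of a band model
#'
#' Evaluates the band model on a fine grid and aggregates it into the
#' windows of a scheme, yielding the ground-truth per-window profile that
#' recovery tests compare against.
#'
#' @param model a [BandModel-class].
#' @param scheme a [WindowScheme-class] over the same chromosome length.
#' @param stepMb grid step in Mb (default 0.01).
#' @param stat \code{"mean"} (default) or \code{"sum"} within windows.
#' @return a [WindowTrack-class] of kind \code{scan_profile}.
#' @export
truthTrack <- function(model, scheme, stepMb = 0.01, stat = c("mean", "sum")) {
  stat <- match.arg(stat)
  stopifnot(is(scheme, "WindowScheme"))
  edges <- scheme@boundaries / 1e6
  g <- seq(stepMb / 2, model@lengthMb - stepMb / 2, by = stepMb)
  v <- bandIntensity(model, g)
  idx <- findInterval(g, edges, rightmost.closed = TRUE)
  agg <- if (stat == "mean") tapply(v, factor(idx, seq_len(length(edges) - 1L)), mean)
         else tapply(v, factor(idx, seq_len(length(edges) - 1L)), sum)
  agg[is.na(agg)] <- 0
  new("WindowTrack", scheme = scheme, values = as.numeric(agg),
      kind = "scan_profile", units = "model intensity")
}

setMethod("show", "BandModel", function(object) {
  cat(sprintf("BandModel: %d band(s) over %.6g Mb, baseline %.3g%s\n",
              nrow(object@bands), object@lengthMb, object@baseline,
              if (object@centromereGap)
                sprintf(", centromere gap %.4g-%.4g Mb",
                        object@gapMb[1], object@gapMb[2]) else ""))
  if (nrow(object@bands)) print(object@bands, row.names = FALSE)
})
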