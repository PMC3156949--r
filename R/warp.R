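#' @include AllClasses.R
NULL

#' Construct a per-arm stretch model
#'
#' @param spec a [ChromSpec-class] giving centromere and length.
#' @param pStretch,qStretch positive stretch factors of the p and q arms.
#' @return a [WarpModel-class].
#' @examples
#' WarpModel(chr1Spec(), pStretch = 2, qStretch = 1)
#' @export
WarpModel <- function(spec, pStretch = 1, qStretch = 1) {
  new("WarpModel", pStretch = as.numeric(pStretch),
      qStretch = as.numeric(qStretch),
      centromereMb = spec@centromereMb, lengthMb = spec@lengthMb)
}

#' Identity warp (no differential stretching)
#' @param spec a [ChromSpec-class].
#' @return a [WarpModel-class] with both stretch factors 1.
#' @export
identityWarp <- function(spec) WarpModel(spec, 1, 1)

#' Arc fraction of the centromere under a warp
#' @param warp a [WarpModel-class].
#' @return the arc-length fraction in (0, 1) at which the centromere sits on
#'   the rendered chromatid.
#' @export
centromereFraction <- function(warp) {
  stopifnot(is(warp, "WarpModel"))
  pc <- warp@pStretch * warp@centromereMb
  qc <- warp@qStretch * (warp@lengthMb - warp@centromereMb)
  pc / (pc + qc)
}

#' Map genomic position to arc fraction
#'
#' Piecewise-linear per arm: positions in \code{[0, centromereMb]} map
#' linearly onto \code{[0, fc]} and positions in
#' \code{[centromereMb, lengthMb]} onto \code{[fc, 1]}, where \code{fc} is
#' [centromereFraction()]. Strictly monotone with endpoints 0 and 1.
#'
#' @param warp a [WarpModel-class].
#' @param positionMb numeric genomic positions in Mb within
#'   \code{[0, lengthMb]}.
#' @return arc fractions in [0, 1].
#' @examples
#' w <- WarpModel(chr1Spec(), pStretch = 2)
#' warpPosition(w, c(0, 120, 247))
#' @export
warpPosition <- function(warp, positionMb) {
  stopifnot(is(warp, "WarpModel"))
  if (any(positionMb < 0 | positionMb > warp@lengthMb))
    stop("position outside [0, ", warp@lengthMb, "] Mb", call. = FALSE)
  fc <- centromereFraction(warp)
  cen <- warp@centromereMb; L <- warp@lengthMb
  ifelse(positionMb <= cen,
         fc * positionMb / cen,
         fc + (1 - fc) * (positionMb - cen) / (L - cen))
}

#' Map arc fraction back to genomic position
#'
#' Exact inverse of [warpPosition()].
#'
#' @param warp a [WarpModel-class].
#' @param arcFraction numeric arc fractions in [0, 1].
#' @return genomic positions in Mb.
#' @export
unwarpPosition <- function(warp, arcFraction) {
  stopifnot(is(warp, "WarpModel"))
  if (any(arcFraction < -1e-12 | arcFraction > 1 + 1e-12))
    stop("arc fraction outside [0, 1]", call. = FALSE)
  arcFraction <- pmin(pmax(arcFraction, 0), 1)
  fc <- centromereFraction(warp)
  cen <- warp@centromereMb; L <- warp@lengthMb
  ifelse(arcFraction <= fc,
         cen * arcFraction / fc,
         cen + (L - cen) * (arcFraction - fc) / (1 - fc))
}

setMethod("show", "WarpModel", function(object) {
  cat(sprintf(
    "WarpModel: p-arm stretch %.3g, q-arm stretch %.3g (centromere at arc fraction %.4f)\n",
    object@pStretch, object@qStretch, centromereFraction(object)))
})
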