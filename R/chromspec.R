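#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a chromosome specification
#'
#' @param name chromosome label.
#' @param lengthMb chromosome length in megabases.
#' @param centromereMb centromere position in megabases.
#' @param nScanWindows number of equal windows for scan binning (default 25).
#' @param featureWindowMb feature-binning window width in Mb (default 10).
#' @return a [ChromSpec-class] object.
#' @examples
#' ChromSpec("chr1", 247, 120)
#' @export
ChromSpec <- function(name, lengthMb, centromereMb, nScanWindows = 25L,
                      featureWindowMb = 10) {
  new("ChromSpec", name = as.character(name), lengthMb = as.numeric(lengthMb),
      centromereMb = as.numeric(centromereMb),
      nScanWindows = as.integer(nScanWindows),
      featureWindowMb = as.numeric(featureWindowMb))
}

#' Human chromosome 1 specification
#'
#' The geometry the quantitative banding analysis is anchored to: 247 Mb
#' long, centromere at 120 Mb, 25 equal scan windows (nominally 10 Mb each)
#' and 10-Mb feature windows.
#'
#' @return a [ChromSpec-class] for chromosome 1.
#' @examples
#' chr1Spec()
#' @export
chr1Spec <- function() ChromSpec("chr1", 247, 120)

#' @describeIn lengthMb chromosome length of a spec.
#' @export
setMethod("lengthMb", "ChromSpec", function(x) x@lengthMb)

#' @describeIn centromereMb centromere position of a spec.
#' @export
setMethod("centromereMb", "ChromSpec", function(x) x@centromereMb)

#' @describeIn nScanWindows scan window count of a spec.
#' @export
setMethod("nScanWindows", "ChromSpec", function(x) x@nScanWindows)

setMethod("show", "ChromSpec", function(object) {
  cat(sprintf("ChromSpec '%s': %.6g Mb, centromere at %.6g Mb\n",
              object@name, object@lengthMb, object@centromereMb))
  cat(sprintf("  %d scan windows (%.4g Mb each); %.4g-Mb feature windows\n",
              object@nScanWindows, object@lengthMb / object@nScanWindows,
              object@featureWindowMb))
})

# Width of one equal scan window, in Mb.
.scanWindowMb <- function(spec) spec@lengthMb / spec@nScanWindows

# 1-based index of the equal scan window containing a position (Mb).
.scanWindowOf <- function(spec, positionMb) {
  w <- .scanWindowMb(spec)
  as.integer(pmin(spec@nScanWindows, floor(positionMb / w) + 1L))
}
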