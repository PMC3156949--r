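#' @include AllClasses.R
NULL

#' Chromosome length in megabases
#' @param x an object with a chromosome geometry.
#' @return numeric length in Mb.
#' @export
setGeneric("lengthMb", function(x) standardGeneric("lengthMb"))

#' Centromere position in megabases
#' @param x an object with a chromosome geometry.
#' @return numeric position in Mb.
#' @export
setGeneric("centromereMb", function(x) standardGeneric("centromereMb"))

#' Number of equal scan windows
#' @param x a [ChromSpec-class] (or object carrying one).
#' @return integer window count.
#' @export
setGeneric("nScanWindows", function(x) standardGeneric("nScanWindows"))

#' Per-window values of a track or profile
#' @param x a [WindowTrack-class], [WindowProfile-class] or
#'   [MeanProfile-class].
#' @return numeric vector or matrix of window values.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' Window scheme of a track
#' @param x a [WindowTrack-class].
#' @return the [WindowScheme-class].
#' @export
setGeneric("trackScheme", function(x) standardGeneric("trackScheme"))
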