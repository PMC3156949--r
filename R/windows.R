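#' @include AllClasses.R AllGenerics.R
NULL

#' Build a fixed-window scheme over a chromosome
#'
#' Windows are defined in base pairs internally (1 Mb = 1,000,000 bp
#' exactly) and tile the chromosome exactly once. Give either a window width
#' (\code{widthMb}; the last window may be partial) or an exact window count
#' (\code{nWindows}; equal windows), not both.
#'
#' @param spec a [ChromSpec-class].
#' @param widthMb window width in Mb.
#' @param nWindows exact window count.
#' @return a [WindowScheme-class].
#' @examples
#' makeWindows(chr1Spec(), widthMb = 10)   # 25 windows, last 240-247 Mb
#' makeWindows(chr1Spec(), nWindows = 25)  # 25 equal 9.88-Mb windows
#' @export
makeWindows <- function(spec, widthMb = NULL, nWindows = NULL) {
  stopifnot(is(spec, "ChromSpec"))
  if (is.null(widthMb) == is.null(nWindows))
    stop("give exactly one of 'widthMb' or 'nWindows'", call. = FALSE)
  lengthBp <- round(spec@lengthMb * 1e6)
  if (!is.null(widthMb)) {
    stopifnot(widthMb > 0)
    widthBp <- widthMb * 1e6
    if (widthBp > lengthBp) {
      warning("window width exceeds chromosome length; using a single window",
              call. = FALSE)
      b <- c(0, lengthBp)
    } else {
      b <- unique(c(seq(0, lengthBp, by = widthBp), lengthBp))
    }
  } else {
    nWindows <- as.integer(nWindows)
    stopifnot(nWindows >= 1L)
    b <- seq(0, lengthBp, length.out = nWindows + 1L)
  }
  new("WindowScheme", chrom = spec@name, boundaries = as.numeric(b))
}

#' Windows of a scheme as genomic ranges
#'
#' @param scheme a [WindowScheme-class].
#' @return a \link[GenomicRanges]{GRanges} with one range per window
#'   (1-based closed coordinates; fractional bp boundaries are rounded).
#' @export
windowRanges <- function(scheme) {
  stopifnot(is(scheme, "WindowScheme"))
  b <- round(scheme@boundaries)
  GRanges(scheme@chrom, IRanges(start = b[-length(b)] + 1, end = b[-1]))
}

#' Number of windows in a scheme
#' @param scheme a [WindowScheme-class].
#' @return integer count.
#' @export
windowCount <- function(scheme) length(scheme@boundaries) - 1L

# Assign bp positions to windows: half-open [start, end), last window
# closed. Errors on positions outside the chromosome.
.windowIndex <- function(scheme, posBp, what = "position") {
  b <- scheme@boundaries
  L <- b[length(b)]
  bad <- which(posBp < 0 | posBp > L)
  if (length(bad))
    stop(sprintf("%s(s) outside chromosome bounds at record(s) %s", what,
                 paste(head(bad, 10), collapse = ", ")), call. = FALSE)
  idx <- findInterval(posBp, b, rightmost.closed = TRUE)
  pmin(pmax(idx, 1L), length(b) - 1L)
}

#' Count features per window
#'
#' Each feature is counted in exactly one window, by its midpoint (default)
#' or start; totals are conserved exactly. Features on other chromosomes are
#' dropped with a logged count; features outside the chromosome bounds are
#' an error.
#'
#' @param features a \link[GenomicRanges]{GRanges} of features (1-based
#'   closed, as read by [readBed()] or made by [simulateFeatures()]).
#' @param scheme a [WindowScheme-class].
#' @param assignBy \code{"midpoint"} (default) or \code{"start"}.
#' @param kind track kind label; by default derived from the features'
#'   \code{feature_class} column (e.g. \code{gene_count}).
#' @return a [WindowTrack-class] of counts.
#' @examples
#' gr <- simulateFeatures(chr1Spec(), fiveBandModel(), 1000, seed = 1)
#' countFeatures(gr, makeWindows(chr1Spec(), widthMb = 10))
#' @export
countFeatures <- function(features, scheme, assignBy = c("midpoint", "start"),
                          kind = NULL) {
  assignBy <- match.arg(assignBy)
  stopifnot(is(features, "GRanges"), is(scheme, "WindowScheme"))
  onChrom <- as.character(seqnames(features)) == scheme@chrom
  if (any(!onChrom))
    message(sprintf("dropping %d feature(s) on other chromosomes",
                    sum(!onChrom)))
  features <- features[onChrom]
  if (is.null(kind)) {
    fc <- unique(mcols(features)$feature_class)
    kind <- if (length(fc) == 1L && paste0(fc, "_count") %in% .trackKinds)
      paste0(fc, "_count") else "other_count"
  }
  nw <- windowCount(scheme)
  if (length(features) == 0L)
    return(new("WindowTrack", scheme = scheme, values = numeric(nw),
               kind = kind, units = "features per window"))
  s0 <- start(features) - 1 # back to 0-based half-open bp
  e0 <- end(features)
  pos <- if (assignBy == "midpoint") (s0 + e0) / 2 else s0
  idx <- .windowIndex(scheme, pos, "feature")
  counts <- tabulate(idx, nbins = nw)
  new("WindowTrack", scheme = scheme, values = as.numeric(counts),
      kind = kind, units = "features per window")
}

#' Average a signal track within windows
#'
#' Per-window mean of per-base signal, length-weighted across intervals that
#' straddle a window boundary; positions not covered by any interval count
#' as 0, so the mean is always over the full window width.
#'
#' @param signal a \link[GenomicRanges]{GRanges} with a numeric
#'   \code{score} column (bedGraph semantics; 1-based closed after import).
#' @param scheme a [WindowScheme-class].
#' @return a [WindowTrack-class] of kind \code{signal_mean}.
#' @examples
#' sig <- simulateSignal(chr1Spec(), fiveBandModel(), 30, seed = 1)
#' binSignal(sig, makeWindows(chr1Spec(), widthMb = 10))
#' @export
binSignal <- function(signal, scheme) {
  stopifnot(is(signal, "GRanges"), is(scheme, "WindowScheme"))
  score <- mcols(signal)$score
  if (is.null(score)) stop("signal track has no 'score' column", call. = FALSE)
  if (any(score < 0))
    stop("negative signal values are not allowed", call. = FALSE)
  onChrom <- as.character(seqnames(signal)) == scheme@chrom
  if (any(!onChrom))
    message(sprintf("dropping %d signal interval(s) on other chromosomes",
                    sum(!onChrom)))
  signal <- signal[onChrom]
  score <- mcols(signal)$score
  win <- windowRanges(scheme)
  nw <- length(win)
  sums <- numeric(nw)
  if (length(signal)) {
    ov <- findOverlaps(win, signal)
    if (length(ov)) {
      pi <- pintersect(win[queryHits(ov)], signal[subjectHits(ov)])
      contrib <- width(pi) * score[subjectHits(ov)]
      sums <- as.numeric(tapply(contrib, factor(queryHits(ov), seq_len(nw)),
                                sum))
      sums[is.na(sums)] <- 0
    }
  }
  widths <- diff(scheme@boundaries)
  new("WindowTrack", scheme = scheme, values = sums / widths,
      kind = "signal_mean", units = "mean signal per bp")
}

#' Sum gene expression within windows
#'
#' Assigns each gene to the window containing its representative position
#' and sums the normalized expression values; the grand total is conserved
#' exactly. Duplicate gene ids are an error.
#'
#' @param expression data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{pos} (bp) and \code{value} (>= 0), as produced by
#'   [simulateExpression()] or [readExpression()].
#' @param scheme a [WindowScheme-class].
#' @return a [WindowTrack-class] of kind \code{expression_sum}.
#' @export
sumExpression <- function(expression, scheme) {
  stopifnot(is.data.frame(expression), is(scheme, "WindowScheme"))
  need <- c("gene_id", "chrom", "pos", "value")
  if (!all(need %in% names(expression)))
    stop("expression table must have columns gene_id, chrom, pos, value",
         call. = FALSE)
  if (anyDuplicated(expression$gene_id))
    stop("duplicate gene ids in expression table", call. = FALSE)
  if (any(expression$value < 0))
    stop("expression values must be >= 0", call. = FALSE)
  onChrom <- expression$chrom == scheme@chrom
  if (any(!onChrom))
    message(sprintf("dropping %d gene(s) on other chromosomes", sum(!onChrom)))
  expression <- expression[onChrom, , drop = FALSE]
  nw <- windowCount(scheme)
  vals <- numeric(nw)
  if (nrow(expression)) {
    idx <- .windowIndex(scheme, expression$pos, "gene position")
    vals <- as.numeric(tapply(expression$value,
                              factor(idx, seq_len(nw)), sum))
    vals[is.na(vals)] <- 0
  }
  new("WindowTrack", scheme = scheme, values = vals,
      kind = "expression_sum", units = "summed normalized expression")
}

#' @describeIn trackValues values of a window track.
#' @export
setMethod("trackValues", "WindowTrack", function(x) x@values)

#' @describeIn trackScheme scheme of a window track.
#' @export
setMethod("trackScheme", "WindowTrack", function(x) x@scheme)

setMethod("show", "WindowScheme", function(object) {
  nw <- windowCount(object)
  w <- diff(object@boundaries)
  cat(sprintf("WindowScheme on %s: %d windows of %.4g%s Mb\n", object@chrom,
              nw, w[1] / 1e6,
              if (length(unique(round(w))) > 1L)
                sprintf(" (last %.4g)", w[nw] / 1e6) else ""))
})

setMethod("show", "WindowTrack", function(object) {
  cat(sprintf("WindowTrack [%s] on %s: %d windows (%s)\n", object@kind,
              object@scheme@chrom, windowCount(object@scheme), object@units))
})
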