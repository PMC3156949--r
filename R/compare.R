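#' @include AllClasses.R
NULL

# Check two schemes describe the same tiling of the same chromosome.
.sameScheme <- function(a, b) {
  identical(a@chrom, b@chrom) &&
    length(a@boundaries) == length(b@boundaries) &&
    max(abs(a@boundaries - b@boundaries)) < 0.5
}

# Core Pearson/Spearman correlation with the t-transform p-value.
.corWithP <- function(x, y, method = "pearson") {
  if (method == "spearman") {
    x <- rank(x); y <- rank(y)
  }
  n <- length(x)
  sx <- sd(x); sy <- sd(y)
  if (sx == 0 || sy == 0)
    stop("degenerate input: zero variance in one of the tracks",
         call. = FALSE)
  r <- sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
  r <- min(max(r, -1), 1)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p <- min(max(p, .Machine$double.xmin), 1)
  list(r = r, p = p, n = n)
}

#' Correlate two window tracks
#'
#' Pearson product-moment correlation over the included windows, with the
#' two-sided significance from the t transform
#' \eqn{t = r \sqrt{(n-2)/(1-r^2)}} on \eqn{n-2} degrees of freedom.
#' Spearman rank correlation is available as an option.
#'
#' @param x,y [WindowTrack-class] objects on the same scheme.
#' @param exclude integer window indices to drop before correlating (e.g.
#'   the centromere window, where both tracks sit near zero).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return a [CorrelationResult-class].
#' @examples
#' sch <- makeWindows(chr1Spec(), nWindows = 25)
#' a <- new("WindowTrack", scheme = sch, values = as.numeric(1:25),
#'          kind = "scan_profile", units = "")
#' b <- new("WindowTrack", scheme = sch, values = as.numeric(2 * (1:25) + 3),
#'          kind = "scan_profile", units = "")
#' correlateTracks(a, b)
#' @export
correlateTracks <- function(x, y, exclude = integer(0),
                            method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(x, "WindowTrack"), is(y, "WindowTrack"))
  if (!.sameScheme(x@scheme, y@scheme))
    stop("tracks are on different window schemes", call. = FALSE)
  nw <- windowCount(x@scheme)
  exclude <- as.integer(exclude)
  if (length(exclude) && (min(exclude) < 1L || max(exclude) > nw))
    stop("exclusion indices out of range", call. = FALSE)
  keep <- setdiff(seq_len(nw), exclude)
  if (length(keep) < 3L)
    stop("fewer than 3 windows left after exclusions", call. = FALSE)
  res <- .corWithP(x@values[keep], y@values[keep], method)
  new("CorrelationResult", r = res$r, p = res$p, n = as.integer(res$n),
      excluded = sort(exclude), method = method)
}

#' Pairwise correlation matrix of window tracks
#'
#' Computes [correlateTracks()] for every pair of a named list of tracks,
#' returning symmetric matrices of r, raw p, Benjamini-Hochberg adjusted p
#' and window counts. Cells whose computation fails (zero variance, scheme
#' mismatch) are NA and recorded with a reason.
#'
#' @param tracks named list of [WindowTrack-class] objects sharing one
#'   scheme.
#' @param exclude window indices excluded from every pairwise computation.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return a [CorrelationMatrix-class].
#' @export
correlationMatrix <- function(tracks, exclude = integer(0),
                              method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is.list(tracks), length(tracks) >= 2L)
  nms <- names(tracks)
  if (is.null(nms) || any(!nzchar(nms)) || anyDuplicated(nms))
    stop("'tracks' must be a uniquely named list", call. = FALSE)
  k <- length(tracks)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nms, nms))
  diag(r) <- 1
  fails <- data.frame(track1 = character(0), track2 = character(0),
                      reason = character(0))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    res <- tryCatch(correlateTracks(tracks[[i]], tracks[[j]],
                                    exclude = exclude, method = method),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      fails <- rbind(fails, data.frame(track1 = nms[i], track2 = nms[j],
                                       reason = res))
    } else {
      r[i, j] <- r[j, i] <- res@r
      p[i, j] <- p[j, i] <- res@p
      n[i, j] <- n[j, i] <- res@n
    }
  }
  q <- p
  off <- upper.tri(p)
  q[off] <- p.adjust(p[off], method = "BH")
  q[lower.tri(q)] <- t(q)[lower.tri(q)]
  new("CorrelationMatrix", r = r, p = p, q = q, n = n, failures = fails)
}

#' Align a metaphase profile with an interphase window track
#'
#' Reconciles a chromatid-averaged metaphase profile (on the spec's
#' equal-window scheme, e.g. 25 windows of 9.88 Mb) with an interphase
#' track binned on a possibly different scheme (e.g. 10-Mb windows) by
#' length-weighted averaging of the interphase track onto the metaphase
#' scheme, then correlates the aligned pair.
#'
#' @param meta a [MeanProfile-class] (green channel used).
#' @param inter a [WindowTrack-class] on the same chromosome.
#' @param exclude window indices (on the metaphase scheme) to exclude from
#'   the correlation.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return a list with elements \code{pairs} (data.frame of window
#'   midpoints and the two aligned values), \code{correlation} (a
#'   [CorrelationResult-class]) and \code{resampled} (logical: whether the
#'   interphase track needed resampling).
#' @export
alignMetaphaseInterphase <- function(meta, inter, exclude = integer(0),
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(is(meta, "MeanProfile"), is(inter, "WindowTrack"))
  if (!identical(meta@spec@name, inter@scheme@chrom))
    stop("metaphase profile and interphase track are on different chromosomes",
         call. = FALSE)
  metaTrack <- profileTrack(meta, "green")
  sch <- metaTrack@scheme
  resampled <- !.sameScheme(sch, inter@scheme)
  interVals <- if (resampled) {
    .resampleTrack(inter, sch)
  } else {
    inter@values
  }
  # a resampled count/sum track holds length-weighted means; relabel kind
  alignedKind <- if (resampled && inter@kind != "signal_mean") "signal_mean"
                 else inter@kind
  interAligned <- new("WindowTrack", scheme = sch, values = interVals,
                      kind = alignedKind, units = inter@units)
  res <- correlateTracks(metaTrack, interAligned, exclude = exclude,
                         method = method)
  mids <- (head(sch@boundaries, -1) + tail(sch@boundaries, -1)) / 2 / 1e6
  list(pairs = data.frame(window = seq_along(mids), midpoint_mb = mids,
                          metaphase = metaTrack@values,
                          interphase = interVals),
       correlation = res, resampled = resampled)
}

# Length-weighted resampling of a track's per-window values onto a target
# scheme (treats values as piecewise-constant over their source windows).
.resampleTrack <- function(track, targetScheme) {
  src <- track@scheme@boundaries
  tgt <- targetScheme@boundaries
  nT <- length(tgt) - 1L
  out <- numeric(nT)
  for (i in seq_len(nT)) {
    lo <- tgt[i]; hi <- tgt[i + 1]
    j0 <- findInterval(lo, src, rightmost.closed = TRUE)
    j1 <- findInterval(hi, src, rightmost.closed = TRUE)
    j0 <- min(max(j0, 1L), length(src) - 1L)
    j1 <- min(max(j1, 1L), length(src) - 1L)
    acc <- 0
    for (j in j0:j1) {
      w <- min(hi, src[j + 1]) - max(lo, src[j])
      if (w > 0) acc <- acc + w * track@values[j]
    }
    out[i] <- acc / (hi - lo)
  }
  out
}

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult (%s): r = %.4f, p = %.3g, n = %d%s\n",
              object@method, object@r, object@p, object@n,
              if (length(object@excluded))
                sprintf(" (excluded windows: %s)",
                        paste(object@excluded, collapse = ", ")) else ""))
})

setMethod("show", "CorrelationMatrix", function(object) {
  cat(sprintf("CorrelationMatrix over %d tracks\n", nrow(object@r)))
  print(round(object@r, 3))
  if (nrow(object@failures))
    cat(sprintf("%d pair(s) failed; see @failures\n", nrow(object@failures)))
})
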