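#' @include AllClasses.R
#' @importFrom GenomicRanges GRanges start end width mcols mcols<- findOverlaps
#'   pintersect
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom GenomeInfoDb seqlengths seqlengths<- seqnames
NULL

# Inverse-CDF sampler from a density proportional to the band model,
# evaluated on a fine grid. Returns positions in Mb.
.sampleFromModel <- function(model, n, gridMb = 0.05) {
  if (n == 0L) return(numeric(0))
  g <- seq(gridMb / 2, model@lengthMb - gridMb / 2, by = gridMb)
  w <- bandIntensity(model, g)
  if (all(w <= 0)) w <- rep(1, length(w))
  cdf <- cumsum(w) / sum(w)
  u <- runif(n)
  idx <- findInterval(u, cdf) + 1L
  # uniform jitter within the selected grid cell
  g[idx] - gridMb / 2 + runif(n) * gridMb
}

# Default feature interval widths in bp, by class (lognormal scales).
.featureWidthBp <- c(gene = 25000, cgi = 1000, sine = 300, line = 3000,
                     other = 1000)

#' Simulate a feature annotation table
#'
#' Draws \code{nFeatures} intervals of one class on a chromosome. Each
#' feature's midpoint comes from a mixture: with probability \code{coupling}
#' from a density proportional to the band model's intensity, otherwise
#' uniform over the chromosome. Window counts of the result therefore
#' correlate with the band model with a strength controlled by
#' \code{coupling} (0 = uncoupled, 1 = fully coupled). Interval widths are
#' lognormal around a class-specific scale and clipped to the chromosome.
#'
#' @param spec a [ChromSpec-class].
#' @param model a [BandModel-class] over the same length.
#' @param nFeatures number of features to draw (>= 0).
#' @param coupling mixture weight in [0, 1].
#' @param featureClass one of \code{"gene"}, \code{"cgi"}, \code{"sine"},
#'   \code{"line"}, \code{"other"}.
#' @param seed integer seed; fixes all randomness.
#' @return a \link[GenomicRanges]{GRanges} (1-based closed intervals, with
#'   \code{seqlengths} set) carrying metadata columns \code{feature_class}
#'   and \code{feature_id}, sorted by start.
#' @examples
#' gr <- simulateFeatures(chr1Spec(), fiveBandModel(), 100, coupling = 1,
#'                        seed = 1)
#' head(gr)
#' @export
simulateFeatures <- function(spec, model, nFeatures, coupling = 1,
                             featureClass = c("gene", "cgi", "sine", "line",
                                              "other"),
                             seed = 1L) {
  featureClass <- match.arg(featureClass)
  stopifnot(is(spec, "ChromSpec"), is(model, "BandModel"), nFeatures >= 0,
            coupling >= 0, coupling <= 1)
  nFeatures <- as.integer(nFeatures)
  lengthBp <- round(spec@lengthMb * 1e6)
  if (nFeatures == 0L) {
    gr <- GRanges(character(0), IRanges())
    mcols(gr)$feature_class <- character(0)
    mcols(gr)$feature_id <- character(0)
    return(gr)
  }
  res <- .withSeed(seed, {
    fromBand <- runif(nFeatures) < coupling
    mid <- numeric(nFeatures)
    mid[fromBand] <- .sampleFromModel(model, sum(fromBand))
    mid[!fromBand] <- runif(sum(!fromBand), 0, spec@lengthMb)
    wscale <- .featureWidthBp[[featureClass]]
    widths <- pmax(1, round(exp(rnorm(nFeatures, log(wscale), 0.6))))
    list(mid = mid, widths = widths)
  })
  midBp <- res$mid * 1e6
  startBp <- pmax(0, pmin(round(midBp - res$widths / 2), lengthBp - 1))
  endBp <- pmin(lengthBp, startBp + res$widths)
  o <- order(startBp, endBp)
  gr <- GRanges(spec@name, IRanges(start = startBp[o] + 1, end = endBp[o]))
  seqlengths(gr) <- setNames(lengthBp, spec@name)
  mcols(gr)$feature_class <- rep(featureClass, nFeatures)
  mcols(gr)$feature_id <- sprintf("%s_%06d", featureClass, seq_len(nFeatures))
  gr
}

#' Simulate a coverage signal track
#'
#' Generates Poisson per-step counts whose expectation is proportional to
#' the band model's intensity, rescaled so the mean over all steps equals
#' \code{meanDepth}. Emulates a ChIP-seq-like windowed coverage track over
#' one chromosome.
#'
#' @param spec a [ChromSpec-class].
#' @param model a [BandModel-class].
#' @param meanDepth mean counts per step (> 0).
#' @param stepBp fixed step size in bp (default 1e5).
#' @param seed integer seed.
#' @return a \link[GenomicRanges]{GRanges} of adjacent fixed-step intervals
#'   spanning the chromosome without gaps, with integer \code{score} >= 0.
#' @examples
#' sig <- simulateSignal(chr1Spec(), fiveBandModel(), meanDepth = 30,
#'                       seed = 1)
#' head(sig)
#' @export
simulateSignal <- function(spec, model, meanDepth, stepBp = 1e5, seed = 1L) {
  stopifnot(is(spec, "ChromSpec"), is(model, "BandModel"), meanDepth > 0)
  lengthBp <- round(spec@lengthMb * 1e6)
  starts <- seq(0, lengthBp - 1, by = stepBp)
  ends <- pmin(starts + stepBp, lengthBp)
  midsMb <- (starts + ends) / 2 / 1e6
  mu <- bandIntensity(model, midsMb)
  mu <- meanDepth * mu / mean(mu)
  counts <- .withSeed(seed, rpois(length(mu), mu))
  gr <- GRanges(spec@name, IRanges(start = starts + 1, end = ends))
  seqlengths(gr) <- setNames(lengthBp, spec@name)
  mcols(gr)$score <- as.numeric(counts)
  gr
}

#' Simulate per-gene expression values
#'
#' Assigns each gene a nonnegative expression value drawn from a gamma
#' distribution whose mean interpolates, with weight \code{coupling},
#' between a flat level and a level proportional to the band model's
#' intensity at the gene midpoint. At \code{coupling = 0} values are
#' exchangeable across positions; at \code{coupling = 1} window sums track
#' the band model.
#'
#' @param features a \link[GenomicRanges]{GRanges} of genes as produced by
#'   [simulateFeatures()]; all \code{feature_class} entries must be
#'   \code{"gene"}.
#' @param model a [BandModel-class].
#' @param coupling mixture weight in [0, 1].
#' @param meanLevel mean normalized expression level (default 5).
#' @param seed integer seed.
#' @return a data.frame with columns \code{gene_id}, \code{chrom},
#'   \code{pos} (bp, interval midpoint) and \code{value}.
#' @examples
#' genes <- simulateFeatures(chr1Spec(), fiveBandModel(), 50, seed = 1)
#' expr <- simulateExpression(genes, fiveBandModel(), coupling = 1, seed = 2)
#' head(expr)
#' @export
simulateExpression <- function(features, model, coupling = 1, meanLevel = 5,
                               seed = 1L) {
  stopifnot(is(features, "GRanges"), is(model, "BandModel"),
            coupling >= 0, coupling <= 1)
  fc <- mcols(features)$feature_class
  if (!is.null(fc) && length(fc) && any(fc != "gene"))
    stop("expression can only be simulated for 'gene' features", call. = FALSE)
  n <- length(features)
  if (n == 0L)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      pos = numeric(0), value = numeric(0)))
  posBp <- (start(features) - 1 + end(features)) / 2
  posMb <- pmin(pmax(posBp / 1e6, 0), model@lengthMb)
  rel <- bandIntensity(model, posMb)
  rel <- rel / mean(rel)
  mu <- meanLevel * ((1 - coupling) + coupling * rel)
  shape <- 2
  values <- .withSeed(seed, rgamma(n, shape = shape, scale = mu / shape))
  ids <- mcols(features)$feature_id
  if (is.null(ids)) ids <- sprintf("gene_%06d", seq_len(n))
  data.frame(gene_id = ids,
             chrom = as.character(seqnames(features)),
             pos = posBp, value = values)
}
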