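#' @include AllClasses.R
#' @importFrom EBImage otsu bwlabel distmap
#' @importFrom igraph graph_from_data_frame distances shortest_paths V
NULL

#' Construct a medial path from coordinates
#'
#' @param x,y numeric vectors of pixel coordinates (x = column, y = row),
#'   ordered from pter to qter.
#' @return a [MedialPath-class] with cumulative arc lengths.
#' @export
medialPath <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2L)
  coords <- cbind(x = as.numeric(x), y = as.numeric(y))
  arc <- c(0, cumsum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2)))
  keep <- c(TRUE, diff(arc) > 0)
  new("MedialPath", coords = coords[keep, , drop = FALSE], arc = arc[keep])
}

# Zhang-Suen morphological thinning of a logical matrix. Iterates the two
# standard sub-passes until no pixel changes; preserves 8-connectivity.
.thinMask <- function(mask) {
  m <- mask * 1L
  shift <- function(a, dr, dc) {
    ny <- nrow(a); nx <- ncol(a)
    out <- matrix(0L, ny, nx)
    rs <- max(1, 1 + dr):min(ny, ny + dr)
    cs <- max(1, 1 + dc):min(nx, nx + dc)
    out[rs, cs] <- a[rs - dr, cs - dc]
    out
  }
  repeat {
    changedAny <- FALSE
    for (pass in 1:2) {
      # neighbours P2..P9 clockwise from north
      p2 <- shift(m, 1, 0); p3 <- shift(m, 1, -1); p4 <- shift(m, 0, -1)
      p5 <- shift(m, -1, -1); p6 <- shift(m, -1, 0); p7 <- shift(m, -1, 1)
      p8 <- shift(m, 0, 1); p9 <- shift(m, 1, 1)
      B <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      A <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
        (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
        (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
      if (pass == 1) {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- m == 1L & B >= 2 & B <= 6 & A == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        m[cond] <- 0L
        changedAny <- TRUE
      }
    }
    if (!changedAny) break
  }
  m == 1L
}

# Prolong a polyline at both ends along its end tangents while the mask's
# distance transform stays near the typical tube radius.
.extendToTips <- function(co, dm) {
  dmAt <- function(x, y) {
    yi <- pmin(pmax(round(y), 1), nrow(dm))
    xi <- pmin(pmax(round(x), 1), ncol(dm))
    dm[cbind(yi, xi)]
  }
  radius <- stats::median(dmAt(co[, 1], co[, 2]))
  extend <- function(co, atStart) {
    if (atStart) co <- co[rev(seq_len(nrow(co))), , drop = FALSE]
    n <- nrow(co)
    u <- co[n, ] - co[n - min(5L, n - 1L), ]
    u <- u / sqrt(sum(u^2))
    pt <- co[n, ]
    for (k in 1:50) {
      cand <- pt + u
      if (dmAt(cand[1], cand[2]) < 0.85 * radius) break
      pt <- cand
      co <- rbind(co, pt)
    }
    if (atStart) co <- co[rev(seq_len(nrow(co))), , drop = FALSE]
    co
  }
  co <- extend(co, atStart = FALSE)
  extend(co, atStart = TRUE)
}

# Longest geodesic path through an 8-connected skeleton, via a double
# breadth-first sweep on the pixel adjacency graph.
.skeletonPath <- function(skel) {
  px <- which(skel, arr.ind = TRUE) # rows = y, cols = x
  n <- nrow(px)
  if (n < 2L) stop("skeleton has fewer than 2 pixels", call. = FALSE)
  id <- matrix(0L, nrow(skel), ncol(skel))
  id[px] <- seq_len(n)
  from <- integer(0); to <- integer(0); wt <- numeric(0)
  offs <- rbind(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  for (k in seq_len(nrow(offs))) {
    nr <- px[, 1] + offs[k, 1]; nc <- px[, 2] + offs[k, 2]
    ok <- nr >= 1 & nr <= nrow(skel) & nc >= 1 & nc <= ncol(skel)
    ok[ok] <- skel[cbind(nr[ok], nc[ok])]
    if (any(ok)) {
      from <- c(from, id[px[ok, , drop = FALSE]])
      to <- c(to, id[cbind(nr[ok], nc[ok])])
      wt <- c(wt, rep(sqrt(sum(offs[k, ]^2)), sum(ok)))
    }
  }
  g <- graph_from_data_frame(
    data.frame(from = as.character(from), to = as.character(to), weight = wt),
    directed = FALSE,
    vertices = data.frame(name = as.character(seq_len(n))))
  d1 <- distances(g, v = "1")
  d1[!is.finite(d1)] <- -1
  u <- colnames(d1)[which.max(d1[1, ])]
  d2 <- distances(g, v = u)
  d2[!is.finite(d2)] <- -1
  v <- colnames(d2)[which.max(d2[1, ])]
  sp <- shortest_paths(g, from = u, to = v)$vpath[[1]]
  idx <- as.integer(names(sp))
  cbind(x = px[idx, 2], y = px[idx, 1])
}

#' Trace the medial axis of a chromatid
#'
#' Automates the manual axis tracking of the scanning procedure: the
#' DAPI-like (red) channel is thresholded by Otsu's method, the largest
#' connected component retained, morphologically thinned to a skeleton, the
#' skeleton pruned to its longest geodesic path, and the path smoothed by
#' spline and resampled at 1-px arc steps. In \code{provided} mode a
#' user-supplied polyline is validated against the chromatid mask and
#' returned unchanged, reproducing the manual workflow.
#'
#' @param image a [ChromImage-class].
#' @param mode \code{"auto"} (default) or \code{"provided"}.
#' @param providedPath a [MedialPath-class], required in \code{provided}
#'   mode.
#' @param pter which image end is the pter telomere: \code{"left"} or
#'   \code{"right"}; the returned path runs pter to qter. Defaults to the
#'   truth metadata when present, else \code{"left"}.
#' @return a [MedialPath-class] from pter to qter.
#' @examples
#' img <- renderChromatid(chr1Spec(), fiveBandModel(), seed = 1,
#'                        lengthPx = 150, radiusPx = 5)
#' path <- traceMedialAxis(img)
#' nrow(path@coords)
#' @export
traceMedialAxis <- function(image, mode = c("auto", "provided"),
                            providedPath = NULL, pter = NULL) {
  mode <- match.arg(mode)
  stopifnot(is(image, "ChromImage"))
  if (is.null(pter))
    pter <- if (length(image@truth) && !is.null(image@truth$pter))
      image@truth$pter else "left"
  pter <- match.arg(pter, c("left", "right"))

  red <- image@red
  if (max(red) <= 0)
    stop("segmentation error: no object found in the DAPI channel",
         call. = FALSE)
  thr <- otsu(red, range = c(0, 1))
  mask <- red > thr
  if (!any(mask))
    stop("segmentation error: no object above threshold", call. = FALSE)
  lab <- bwlabel(mask)
  nObj <- max(lab)
  if (nObj > 1L) {
    sizes <- tabulate(lab[lab > 0], nbins = nObj)
    # small noise specks are tolerated; comparable objects are ambiguous
    if (sort(sizes, decreasing = TRUE)[2] > 0.25 * max(sizes))
      stop("segmentation error: multiple chromatid-sized objects found",
           call. = FALSE)
    mask <- lab == which.max(sizes)
  }

  if (mode == "provided") {
    if (is.null(providedPath) || !is(providedPath, "MedialPath"))
      stop("provided mode needs a MedialPath in 'providedPath'", call. = FALSE)
    co <- providedPath@coords
    inside <- mask[cbind(pmin(pmax(round(co[, "y"]), 1), nrow(mask)),
                         pmin(pmax(round(co[, "x"]), 1), ncol(mask)))]
    if (!all(inside))
      stop("provided path exits the chromatid mask", call. = FALSE)
    return(providedPath)
  }

  skel <- .thinMask(mask)
  co <- .skeletonPath(skel)
  if (nrow(co) < 10L)
    stop("segmentation error: skeleton path too short", call. = FALSE)

  # smooth and resample at ~1-px arc steps
  arc <- c(0, cumsum(sqrt(diff(co[, 1])^2 + diff(co[, 2])^2)))
  df <- max(5, min(25, round(nrow(co) / 15)))
  sx <- smooth.spline(arc, co[, 1], df = df)
  sy <- smooth.spline(arc, co[, 2], df = df)
  s <- seq(0, max(arc), by = 1)
  co2 <- cbind(x = predict(sx, s)$y, y = predict(sy, s)$y)

  # thinning retracts the skeleton from the rounded chromatid tips; extend
  # both ends along the local tangent while the distance-to-boundary stays
  # near the tube radius (the medial axis of a capped tube runs to the cap
  # centers)
  dm <- distmap(mask)
  co2 <- .extendToTips(co2, dm)
  path <- medialPath(co2[, "x"], co2[, "y"])

  # orient pter first
  co2 <- path@coords
  if ((pter == "left" && co2[1, "x"] > co2[nrow(co2), "x"]) ||
      (pter == "right" && co2[1, "x"] < co2[nrow(co2), "x"]))
    path <- medialPath(rev(co2[, "x"]), rev(co2[, "y"]))
  path
}

setMethod("show", "MedialPath", function(object) {
  cat(sprintf("MedialPath: %d vertices, arc length %.1f px\n",
              nrow(object@coords), max(object@arc)))
})
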