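#' @include AllClasses.R
#' @importFrom rtracklayer import export
#' @importFrom jsonlite write_json read_json
#' @importFrom grDevices col2rgb
NULL

# Light pre-validation of a BED-like file so parse errors carry line
# numbers; actual parsing is done by rtracklayer::import.
.checkBedLines <- function(path, minCols, what) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con)
  close(con)
  dataLine <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  for (i in which(dataLine)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < minCols)
      stop(sprintf("%s parse error at line %d: expected >= %d columns",
                   what, i, minCols), call. = FALSE)
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("%s parse error at line %d: non-numeric coordinates",
                   what, i), call. = FALSE)
    if (s >= e)
      stop(sprintf("%s parse error at line %d: start (%s) >= end (%s)",
                   what, i, f[2], f[3]), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a BED feature table
#'
#' BED3+ with 0-based half-open coordinates (the on-disk convention);
#' returned as 1-based closed \link[GenomicRanges]{GRanges}. The BED name
#' column, when present, is taken as the \code{feature_class}. Track and
#' browser lines are skipped; gzip files are read transparently. Malformed
#' records raise a parse error naming the offending line.
#'
#' @param path BED file (optionally .gz).
#' @return a \link[GenomicRanges]{GRanges} with a \code{feature_class}
#'   metadata column.
#' @seealso [writeBed()]
#' @export
readBed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .checkBedLines(path, 3L, "BED")
  gr <- import(path, format = "bed")
  fc <- mcols(gr)$name
  if (is.null(fc)) fc <- rep("other", length(gr))
  mcols(gr) <- NULL
  mcols(gr)$feature_class <- as.character(fc)
  gr
}

#' Write features as BED
#'
#' Writes 0-based half-open BED with the \code{feature_class} (or
#' \code{feature_id}, if requested) in the name column.
#'
#' @param features a \link[GenomicRanges]{GRanges}.
#' @param path output BED path.
#' @param nameColumn metadata column to place in the BED name field
#'   (default \code{feature_class}).
#' @export
writeBed <- function(features, path, nameColumn = "feature_class") {
  stopifnot(is(features, "GRanges"))
  out <- features
  nm <- mcols(out)[[nameColumn]]
  mcols(out) <- NULL
  if (!is.null(nm)) mcols(out)$name <- as.character(nm)
  export(out, path, format = "bed")
  invisible(path)
}

#' Read a bedGraph signal track
#'
#' Fixed-step or variable-step nonnegative coverage over one chromosome;
#' overlapping intervals are an error (naming the records involved),
#' uncovered positions are implicitly 0.
#'
#' @param path bedGraph file (optionally .gz).
#' @return a \link[GenomicRanges]{GRanges} with a numeric \code{score}.
#' @seealso [writeBedGraph()]
#' @export
readBedGraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  .checkBedLines(path, 4L, "bedGraph")
  gr <- import(path, format = "bedGraph")
  ov <- findOverlaps(gr, drop.self = TRUE, drop.redundant = TRUE)
  if (length(ov))
    stop(sprintf("overlapping bedGraph records: %s",
                 paste(sprintf("%d/%d", queryHits(ov), subjectHits(ov))[
                   seq_len(min(5, length(ov)))], collapse = ", ")),
         call. = FALSE)
  gr
}

#' Write a signal track as bedGraph
#' @param signal a \link[GenomicRanges]{GRanges} with \code{score}.
#' @param path output path.
#' @export
writeBedGraph <- function(signal, path) {
  stopifnot(is(signal, "GRanges"))
  export(signal, path, format = "bedGraph")
  invisible(path)
}

#' Read a per-gene expression table
#'
#' Tab-separated with header \code{gene_id}, \code{chrom}, \code{pos},
#' \code{value}.
#'
#' @param path TSV file (optionally .gz).
#' @return a data.frame validated for the expression-table contract.
#' @seealso [writeExpression()]
#' @export
readExpression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  d <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "pos", "value")
  if (!all(need %in% names(d)))
    stop("expression TSV must have header gene_id, chrom, pos, value",
         call. = FALSE)
  if (anyDuplicated(d$gene_id))
    stop("duplicate gene ids in expression table", call. = FALSE)
  if (any(d$value < 0)) stop("expression values must be >= 0", call. = FALSE)
  d[need]
}

#' Write a per-gene expression table
#' @param expression data.frame with columns gene_id, chrom, pos, value.
#' @param path output TSV path.
#' @export
writeExpression <- function(expression, path) {
  out <- expression
  out$pos <- .fmtNum(out$pos)
  out$value <- .fmtNum(out$value)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# JSON sidecar path for a data file.
.sidecar <- function(path) paste0(path, ".json")

#' Write a window track as TSV with a JSON sidecar
#'
#' TSV columns: \code{window_start_bp}, \code{window_end_bp}, \code{value}
#' (9 significant digits, \code{"."} for missing). The sidecar records
#' chromosome, kind and units.
#'
#' @param track a [WindowTrack-class].
#' @param path output TSV path.
#' @seealso [readWindowTrack()]
#' @export
writeWindowTrack <- function(track, path) {
  stopifnot(is(track, "WindowTrack"))
  b <- track@scheme@boundaries
  d <- data.frame(window_start_bp = .fmtNum(head(b, -1)),
                  window_end_bp = .fmtNum(tail(b, -1)),
                  value = .fmtNum(track@values))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(chrom = track@scheme@chrom, kind = track@kind,
                  units = track@units),
             .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a window track written by [writeWindowTrack()]
#' @param path TSV path (the \code{.json} sidecar must sit alongside).
#' @return a [WindowTrack-class].
#' @export
readWindowTrack <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  meta <- read_json(.sidecar(path), simplifyVector = TRUE)
  b <- c(as.numeric(d$window_start_bp), as.numeric(
    d$window_end_bp[nrow(d)]))
  scheme <- new("WindowScheme", chrom = meta$chrom, boundaries = b)
  new("WindowTrack", scheme = scheme, values = as.numeric(d$value),
      kind = meta$kind, units = meta$units)
}

#' Write an averaged profile as TSV with a JSON sidecar
#'
#' TSV columns: window bounds plus per-channel mean and SD. The sidecar
#' records the spec, chromatid count, background window and value.
#'
#' @param profile a [MeanProfile-class].
#' @param path output TSV path.
#' @export
writeMeanProfile <- function(profile, path) {
  stopifnot(is(profile, "MeanProfile"))
  spec <- profile@spec
  edges <- seq(0, spec@lengthMb * 1e6, length.out = spec@nScanWindows + 1L)
  d <- data.frame(window_start_bp = .fmtNum(head(edges, -1)),
                  window_end_bp = .fmtNum(tail(edges, -1)),
                  mean_green = .fmtNum(profile@mean[, "green"]),
                  sd_green = .fmtNum(profile@sd[, "green"]),
                  mean_red = .fmtNum(profile@mean[, "red"]),
                  sd_red = .fmtNum(profile@sd[, "red"]))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  write_json(list(
    spec = list(name = spec@name, length_mb = spec@lengthMb,
                centromere_mb = spec@centromereMb,
                n_scan_windows = spec@nScanWindows,
                feature_window_mb = spec@featureWindowMb),
    n_chromatids = profile@nChromatids,
    background_window = if (is.na(profile@backgroundWindow)) NULL
      else profile@backgroundWindow,
    background_value = as.list(profile@backgroundValue[
      !is.na(profile@backgroundValue)])),
    .sidecar(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a chromatid image as multi-channel TIFF with truth sidecar
#'
#' Channels are written as a 32-bit float RGB TIFF (R = DAPI-like, G =
#' immunostain, B = marker); the truth block (spec, band model, warp, axis
#' polyline) goes to a JSON sidecar so images round-trip losslessly in
#' plain-text-friendly form. An 8-bit PNG preview can be written alongside.
#'
#' @param image a [ChromImage-class].
#' @param path output TIFF path.
#' @param png optional path for an 8-bit RGB PNG preview.
#' @seealso [readChromImage()]
#' @export
writeChromImage <- function(image, path, png = NULL) {
  stopifnot(is(image, "ChromImage"))
  a <- array(0, c(nrow(image@green), ncol(image@green), 3))
  a[, , 1] <- image@red; a[, , 2] <- image@green; a[, , 3] <- image@blue
  tiff::writeTIFF(a, path, bits.per.sample = 32L)
  tr <- image@truth
  side <- list(pixel_size = image@pixelSize)
  if (length(tr)) {
    side$truth <- list(
      id = tr$id, pter = tr$pter, radius_px = tr$radiusPx,
      centromere_arc_fraction = tr$centromereArcFraction,
      spec = list(name = tr$spec@name, length_mb = tr$spec@lengthMb,
                  centromere_mb = tr$spec@centromereMb,
                  n_scan_windows = tr$spec@nScanWindows,
                  feature_window_mb = tr$spec@featureWindowMb),
      model = list(bands = tr$model@bands, baseline = tr$model@baseline,
                   length_mb = tr$model@lengthMb,
                   centromere_gap = tr$model@centromereGap,
                   gap_mb = tr$model@gapMb),
      warp = list(p_stretch = tr$warp@pStretch, q_stretch = tr$warp@qStretch),
      axis = tr$axis)
  }
  write_json(side, .sidecar(path), auto_unbox = TRUE, digits = NA)
  if (!is.null(png)) {
    png::writePNG(a, png)
  }
  invisible(path)
}

#' Read a chromatid image written by [writeChromImage()]
#' @param path TIFF path; a \code{.json} truth sidecar is read when present.
#' @return a [ChromImage-class].
#' @export
readChromImage <- function(path) {
  a <- tiff::readTIFF(path)
  side <- if (file.exists(.sidecar(path)))
    read_json(.sidecar(path), simplifyVector = TRUE) else list()
  truth <- list()
  if (!is.null(side$truth)) {
    tr <- side$truth
    spec <- ChromSpec(tr$spec$name, tr$spec$length_mb, tr$spec$centromere_mb,
                      tr$spec$n_scan_windows, tr$spec$feature_window_mb)
    model <- BandModel(as.data.frame(tr$model$bands), tr$model$baseline,
                       tr$model$length_mb, tr$model$centromere_gap,
                       unlist(tr$model$gap_mb))
    warp <- WarpModel(spec, tr$warp$p_stretch, tr$warp$q_stretch)
    truth <- list(spec = spec, model = model, warp = warp,
                  axis = as.data.frame(tr$axis),
                  centromereArcFraction = tr$centromere_arc_fraction,
                  radiusPx = tr$radius_px, pter = tr$pter, id = tr$id)
  }
  ps <- if (!is.null(side$pixel_size)) side$pixel_size else 1
  new("ChromImage", green = a[, , 2], red = a[, , 1], blue = a[, , 3],
      pixelSize = as.numeric(ps), truth = truth)
}

#' Read a medial path polyline from TSV
#'
#' Two tab-separated columns \code{x}, \code{y} (pixel coordinates), one
#' vertex per row, ordered pter to qter — the format for supplying a
#' manually tracked axis.
#'
#' @param path TSV path.
#' @return a [MedialPath-class].
#' @export
readMedialPath <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("x", "y") %in% names(d)))
    stop("path TSV must have columns x, y", call. = FALSE)
  medialPath(d$x, d$y)
}

#' Write a medial path polyline as TSV
#' @param path a [MedialPath-class].
#' @param file output TSV path.
#' @export
writeMedialPath <- function(path, file) {
  stopifnot(is(path, "MedialPath"))
  d <- data.frame(x = .fmtNum(path@coords[, "x"]),
                  y = .fmtNum(path@coords[, "y"]))
  write.table(d, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
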