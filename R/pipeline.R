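#' @include AllClasses.R
NULL

#' Demonstration pipeline configuration
#'
#' A self-contained configuration that simulates a chromosome-1-like study:
#' chromatid images rendered from the five-band reference model with
#' per-chromatid differential stretching and photometric noise, plus
#' coupled gene/CGI/SINE annotations, a ChIP-seq-like signal track and
#' per-gene expression. The defaults mirror the study conditions the
#' analysis was designed for: 24 chromatids averaged, 25 equal scan
#' windows, 10-Mb feature windows, 3,071 genes.
#'
#' @param nChromatids number of chromatids to simulate (default 24).
#' @param seed master seed (default 1).
#' @param lengthPx rendered axis length in pixels (default 400).
#' @return a nested list understood by [runPipeline()].
#' @export
demoConfig <- function(nChromatids = 24L, seed = 1L, lengthPx = 400L) {
  list(
    spec = list(name = "chr1", length_mb = 247, centromere_mb = 120,
                n_scan_windows = 25L, feature_window_mb = 10),
    seed = as.integer(seed),
    simulate = list(
      n_chromatids = as.integer(nChromatids),
      bands = "five_band", # the packaged reference model
      noise_sd = 0.02,
      bend_amplitude = 5,
      warp_log_sd = 0.15, # lognormal sd of per-chromatid arm stretches
      length_px = as.integer(lengthPx),
      radius_px = 9L,
      n_genes = 3071L,
      n_cgi = 2000L,
      n_sine = 8000L,
      coupling = list(gene = 0.9, cgi = 0.85, sine = 0.7, expression = 0.9),
      signal_depth = 30
    ),
    scan = list(width_px = 11, window_stat = "sum", background = "centromere"),
    windows = list(width_mb = 10)
  )
}

.configSpec <- function(config) {
  s <- config$spec
  ChromSpec(s$name, s$length_mb, s$centromere_mb,
            if (is.null(s$n_scan_windows)) 25L else s$n_scan_windows,
            if (is.null(s$feature_window_mb)) 10 else s$feature_window_mb)
}

.configModel <- function(config, spec) {
  b <- config$simulate$bands
  if (identical(b, "five_band")) return(fiveBandModel(spec))
  BandModel(as.data.frame(do.call(rbind, lapply(b, as.data.frame))),
            baseline = config$simulate$baseline %||% 0.05,
            lengthMb = spec@lengthMb,
            centromereGap = isTRUE(config$simulate$centromere_gap),
            gapMb = unlist(config$simulate$gap_mb))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a pipeline configuration
#'
#' Checks required fields, parameter ranges and — when the configuration
#' references input files instead of simulating them — that every
#' referenced path exists. Called by [runPipeline()] before any stage runs.
#'
#' @param config nested list (or YAML path) as produced by [demoConfig()].
#' @return the normalized config list, invisibly erroring on problems.
#' @export
validatePipelineConfig <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$spec))
    stop("config validation: missing 'spec' block", call. = FALSE)
  spec <- .configSpec(config) # errors on bad geometry
  if (is.null(config$seed) || config$seed != round(config$seed))
    stop("config validation: 'seed' must be an integer", call. = FALSE)
  sim <- config$simulate
  inp <- config$inputs
  if (is.null(sim) && is.null(inp))
    stop("config validation: need a 'simulate' or 'inputs' block",
         call. = FALSE)
  if (!is.null(inp)) {
    paths <- unlist(inp[c("images", "features", "signal", "expression")])
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("config validation: missing input file(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!is.null(sim)) {
    if (sim$n_chromatids < 1L)
      stop("config validation: n_chromatids must be >= 1", call. = FALSE)
    if (sim$noise_sd < 0)
      stop("config validation: noise_sd must be >= 0", call. = FALSE)
  }
  ws <- config$scan$window_stat %||% "sum"
  if (!ws %in% c("sum", "mean"))
    stop("config validation: window_stat must be 'sum' or 'mean'",
         call. = FALSE)
  invisible(config)
}

#' Run the full banding analysis pipeline
#'
#' Executes simulate (optional) -> scan each image -> aggregate ->
#' bin features/signal/expression -> correlate, writing every intermediate
#' (images with truth sidecars, BED/bedGraph/TSV tables, per-chromatid
#' profiles, the averaged profile, window tracks, the correlation matrix)
#' plus a JSON provenance manifest under \code{outdir}. Reruns with an
#' identical configuration and seed produce byte-identical outputs.
#'
#' @param config nested list or YAML file path; see [demoConfig()].
#' @param outdir output directory (created if needed).
#' @param quiet suppress progress messages (default TRUE).
#' @return invisibly, a report list: the [MeanProfile-class], the
#'   per-chromatid [WindowProfile-class] list, the named
#'   [WindowTrack-class] list, the [CorrelationMatrix-class], the truth
#'   recovery correlation (when simulating) and the output paths.
#' @examples
#' \donttest{
#' rep <- runPipeline(demoConfig(nChromatids = 2, lengthPx = 150),
#'                    outdir = tempfile())
#' rep$recovery
#' }
#' @export
runPipeline <- function(config, outdir, quiet = TRUE) {
  config <- validatePipelineConfig(config)
  say <- function(stage, ...) if (!quiet)
    message(sprintf("[%s] %s", stage, sprintf(...)))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  spec <- .configSpec(config)
  seed <- as.integer(config$seed)
  sim <- config$simulate
  scanCfg <- config$scan %||% list()
  widthPx <- scanCfg$width_px %||% 11
  windowStat <- scanCfg$window_stat %||% "sum"
  background <- scanCfg$background %||% "centromere"

  paths <- list()
  report <- list(seed = seed)

  withStage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", stage,
                   conditionMessage(e)), call. = FALSE))
  }

  # ---- stage: simulate -----------------------------------------------------
  images <- NULL; model <- NULL
  features <- list(); signal <- NULL; expression <- NULL
  if (!is.null(sim)) {
    model <- .configModel(config, spec)
    withStage("simulate", {
      say("simulate", "rendering %d chromatids", sim$n_chromatids)
      imgDir <- file.path(outdir, "images")
      dir.create(imgDir, showWarnings = FALSE)
      images <- lapply(seq_len(sim$n_chromatids), function(i) {
        cseed <- childSeed(seed, sprintf("chromatid-%d", i))
        warpPars <- .withSeed(childSeed(seed, sprintf("warp-%d", i)),
                              exp(rnorm(2, 0, sim$warp_log_sd %||% 0.15)))
        bend <- .withSeed(childSeed(seed, sprintf("bend-%d", i)),
                          runif(1, -1, 1)) * (sim$bend_amplitude %||% 5)
        img <- renderChromatid(
          spec, model, WarpModel(spec, warpPars[1], warpPars[2]),
          noiseSd = sim$noise_sd %||% 0.02, bendAmplitude = bend,
          seed = cseed, lengthPx = sim$length_px %||% 400L,
          radiusPx = sim$radius_px %||% 9L)
        writeChromImage(img, file.path(imgDir, sprintf("chromatid_%02d.tif", i)))
        img
      })
      paths$images <- imgDir
      fcls <- list(gene = sim$n_genes %||% 3071L,
                   cgi = sim$n_cgi %||% 2000L,
                   sine = sim$n_sine %||% 8000L)
      for (cls in names(fcls)) {
        cp <- sim$coupling[[cls]] %||% 0.9
        features[[cls]] <- simulateFeatures(
          spec, model, fcls[[cls]], coupling = cp, featureClass = cls,
          seed = childSeed(seed, paste0("features-", cls)))
        p <- file.path(outdir, paste0(cls, ".bed"))
        writeBed(features[[cls]], p)
        paths[[paste0(cls, "_bed")]] <- p
      }
      signal <- simulateSignal(spec, model, sim$signal_depth %||% 30,
                               seed = childSeed(seed, "signal"))
      paths$signal <- file.path(outdir, "signal.bedGraph")
      writeBedGraph(signal, paths$signal)
      expression <- simulateExpression(
        features$gene, model, coupling = sim$coupling$expression %||% 0.9,
        seed = childSeed(seed, "expression"))
      paths$expression <- file.path(outdir, "expression.tsv")
      writeExpression(expression, paths$expression)
    })
  } else {
    withStage("load-inputs", {
      inp <- config$inputs
      images <- lapply(inp$images, readChromImage)
      for (cls in names(inp$features %||% list()))
        features[[cls]] <- readBed(inp$features[[cls]])
      if (!is.null(inp$signal)) signal <- readBedGraph(inp$signal)
      if (!is.null(inp$expression)) expression <- readExpression(inp$expression)
    })
  }

  # ---- stage: scan ---------------------------------------------------------
  profiles <- withStage("scan", {
    say("scan", "scanning %d images", length(images))
    lapply(seq_along(images), function(i) {
      img <- images[[i]]
      path <- traceMedialAxis(img)
      raw <- scanProfile(img, path, widthPx = widthPx)
      cen <- locateCentromere(raw)
      cal <- calibrateScan(raw, cen, spec)
      binProfile(cal, stat = windowStat,
                 chromatid = sprintf("chromatid_%02d", i))
    })
  })

  # ---- stage: aggregate ----------------------------------------------------
  meanProfile <- withStage("aggregate", {
    mp <- averageProfiles(profiles)
    mp <- subtractBackground(mp, background)
    paths$profile <- file.path(outdir, "mean_profile.tsv")
    writeMeanProfile(mp, paths$profile)
    mp
  })

  # ---- stage: bin ----------------------------------------------------------
  wcfg <- config$windows %||% list()
  scheme <- if (!is.null(wcfg$n_windows))
    makeWindows(spec, nWindows = wcfg$n_windows)
  else makeWindows(spec, widthMb = wcfg$width_mb %||% spec@featureWindowMb)
  tracks <- withStage("bin", {
    tr <- list()
    for (cls in names(features))
      tr[[paste0(cls, "_density")]] <- countFeatures(features[[cls]], scheme)
    if (!is.null(signal)) tr$interphase_signal <- binSignal(signal, scheme)
    if (!is.null(expression)) tr$expression <- sumExpression(expression, scheme)
    trackDir <- file.path(outdir, "tracks")
    dir.create(trackDir, showWarnings = FALSE)
    for (nm in names(tr))
      writeWindowTrack(tr[[nm]], file.path(trackDir, paste0(nm, ".tsv")))
    paths$tracks <- trackDir
    tr
  })

  # ---- stage: correlate ----------------------------------------------------
  results <- withStage("correlate", {
    aligned <- lapply(tracks, function(tr)
      alignMetaphaseInterphase(meanProfile, tr))
    allTracks <- c(list(metaphase_profile = profileTrack(meanProfile)),
                   lapply(aligned, function(a)
                     new("WindowTrack",
                         scheme = profileTrack(meanProfile)@scheme,
                         values = a$pairs$interphase, kind = "signal_mean",
                         units = "resampled")))
    cm <- correlationMatrix(allTracks)
    corTab <- data.frame(
      track = names(aligned),
      r = vapply(aligned, function(a) a$correlation@r, numeric(1)),
      p = vapply(aligned, function(a) a$correlation@p, numeric(1)),
      n = vapply(aligned, function(a) a$correlation@n, numeric(1)))
    ct <- corTab
    ct$r <- .fmtNum(ct$r); ct$p <- .fmtNum(ct$p)
    paths$correlations <- file.path(outdir, "correlations.tsv")
    write.table(ct, paths$correlations, sep = "\t", quote = FALSE,
                row.names = FALSE)
    rOut <- cm@r; rOut[] <- signif(rOut, 9)
    paths$matrix <- file.path(outdir, "correlation_matrix.tsv")
    write.table(data.frame(track = rownames(rOut), rOut,
                           check.names = FALSE),
                paths$matrix, sep = "\t", quote = FALSE, row.names = FALSE)
    list(matrix = cm, table = corTab)
  })

  # ---- recovery vs simulation truth ---------------------------------------
  recovery <- NULL
  if (!is.null(model)) {
    truth <- truthTrack(model, makeWindows(spec, nWindows = spec@nScanWindows))
    recovery <- correlateTracks(profileTrack(meanProfile), truth)
  }

  relPaths <- lapply(paths, function(p)
    sub(paste0("^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", outdir), "/?"),
        "", p))
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromoband")),
    seed = seed,
    config = config,
    outputs = relPaths)
  write_json(manifest, file.path(outdir, "manifest.json"),
             auto_unbox = TRUE, digits = NA, pretty = TRUE)

  report <- list(profile = meanProfile, chromatidProfiles = profiles,
                 tracks = tracks,
                 correlations = results$table, matrix = results$matrix,
                 recovery = recovery, paths = paths)
  invisible(report)
}
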