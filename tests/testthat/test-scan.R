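# Perpendicular-segment scanning, centromere anchoring, normalization,
# window binning, chromatid averaging and background subtraction.

test_that("scanning a uniform chromatid gives a flat profile, width-invariantly", {
  spec <- chr1Spec()
  flat <- BandModel(baseline = 0.5, lengthMb = 247)
  img <- quickImage(spec, flat)
  path <- traceMedialAxis(img)
  s1 <- scanProfile(img, path, widthPx = 1)
  s5 <- scanProfile(img, path, widthPx = 5)
  expect_lt(diff(range(s1@data$mean_green)), 0.02)
  expect_lt(max(abs(s1@data$mean_green - s5@data$mean_green)), 0.02)
})

test_that("the scan argmax sits at the band's arc fraction", {
  spec <- chr1Spec()
  m <- BandModel(data.frame(center_mb = 60, width_mb = 6, amplitude = 1),
                 baseline = 0.02, lengthMb = 247)
  img <- quickImage(spec, m, lengthPx = 250)
  scan <- scanProfile(img, traceMedialAxis(img), widthPx = 5)
  fHat <- scan@data$arc_fraction[which.max(scan@data$mean_green)]
  expect_lt(abs(fHat - 60 / 247), 2 / nrow(scan@data))
})

test_that("locateCentromere takes the blue argmax with low-index tie rule", {
  expect_equal(locateCentromere(rawScan(rep(1, 4), blue = c(0, 0, 5, 0))), 3)
  expect_message(
    idx <- locateCentromere(rawScan(rep(1, 4), blue = c(0, 7, 7, 0))),
    "tie")
  expect_equal(idx, 2)
  expect_error(locateCentromere(rawScan(rep(1, 4), blue = rep(0, 4))),
               "marker missing")
})

test_that("the located centromere matches the rendered marker position", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  img <- quickImage(spec, model, lengthPx = 250)
  scan <- scanProfile(img, traceMedialAxis(img), widthPx = 5)
  idx <- locateCentromere(scan)
  expect_lt(abs(scan@data$arc_fraction[idx] - 120 / 247),
            2 / nrow(scan@data))
})

test_that("calibration is globally linear when the anchor is consistent", {
  spec <- chr1Spec()
  n <- 201
  f <- seq(0, 1, length.out = n)
  idx <- which.min(abs(f - 120 / 247))
  blue <- numeric(n); blue[idx] <- 1
  # put the anchor exactly at 120/247 so both arms share one scale
  scan <- new("RawScan",
              data = data.frame(arc_fraction = replace(f, idx, 120 / 247),
                                mean_green = runif(n), mean_red = runif(n),
                                mean_blue = blue),
              widthPx = 1, source = "synthetic")
  cal <- calibrateScan(scan, idx, spec)
  expect_equal(cal@data$position_mb, scan@data$arc_fraction * 247,
               tolerance = 1e-9)
})

test_that("calibration inverts per-arm linear stretching exactly", {
  spec <- chr1Spec()
  for (p in c(0.5, 2)) {
    w <- WarpModel(spec, p, 1)
    truePos <- as.numeric(0:247) # one segment exactly at the centromere
    f <- warpPosition(w, truePos)
    idx <- which(truePos == 120)
    scan <- new("RawScan",
                data = data.frame(arc_fraction = f, mean_green = 1,
                                  mean_red = 1,
                                  mean_blue = replace(numeric(248), idx, 1)),
                widthPx = 1, source = "synthetic")
    cal <- calibrateScan(scan, idx, spec)
    expect_equal(cal@data$position_mb[idx], 120)
    expect_equal(cal@data$position_mb, truePos, tolerance = 1e-6)
  }
})

test_that("each calibrated channel attains exactly 100 at its maximum", {
  set.seed(17)
  for (i in 1:20) {
    n <- sample(50:200, 1)
    scan <- rawScan(runif(n, 0, 5), red = runif(n, 0, 3))
    cal <- calibrateScan(scan, sample(2:(n - 1), 1), chr1Spec())
    expect_equal(max(cal@data$pct_green), 100)
    expect_equal(max(cal@data$pct_red), 100)
    expect_true(all(cal@data$pct_green >= 0 & cal@data$pct_red >= 0))
  }
})

test_that("a centromere at a scan endpoint is a calibration error", {
  scan <- rawScan(runif(10), blue = c(1, rep(0, 9)))
  expect_error(calibrateScan(scan, 1, chr1Spec()), "calibration error")
  expect_error(calibrateScan(scan, 10, chr1Spec()), "calibration error")
})

test_that("uniform sampling fills all 25 windows nearly equally", {
  spec <- chr1Spec()
  n <- 1000
  scan <- rawScan(rep(2, n), red = rep(1, n),
                  blue = replace(numeric(n), 486, 1)) # ~120/247 of the way
  cal <- calibrateScan(scan, 486L, spec)
  wp <- binProfile(cal)
  v <- trackValues(wp)[, "green"]
  # each window holds 40 +/- 1 samples' worth of the constant value 100
  expect_lt(diff(range(v)), 2 * 100 + 1e-9)
  expect_equal(sum(v), n * 100)
})

test_that("a single nonzero sample lands in the window containing 60 Mb", {
  spec <- chr1Spec()
  pos <- c(0, 10, 60, 200, 247)
  d <- data.frame(position_mb = pos,
                  pct_green = c(0, 0, 100, 0, 0),
                  pct_red = c(0, 0, 0, 0, 100))
  cal <- new("CalibratedScan",
             data = within(d, position_mb <- pos), centromereSegment = 4L,
             spec = ChromSpec("chr1", 247, 200))
  wp <- suppressWarnings(binProfile(cal)) # most windows are empty here
  g <- trackValues(wp)[, "green"]
  expect_equal(which(g > 0), 7) # 60 / 9.88 = 6.07 -> 7th window (1-based)
  expect_equal(sum(g), 100)
})

test_that("binProfile matches per-sample brute-force assignment", {
  spec <- chr1Spec()
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(80:300, 1)
    scan <- rawScan(runif(n, 0, 4), red = runif(n, 0, 2))
    cen <- sample(2:(n - 1), 1)
    cal <- calibrateScan(scan, cen, spec)
    wp <- suppressWarnings(binProfile(cal)) # short scans leave empty windows
    # brute force: assign each sample individually
    nw <- 25
    width <- 247 / nw
    oracle <- numeric(nw)
    for (i in seq_len(n)) {
      k <- min(nw, floor(cal@data$position_mb[i] / width) + 1)
      oracle[k] <- oracle[k] + cal@data$pct_green[i]
    }
    expect_equal(unname(trackValues(wp)[, "green"]), oracle,
                 tolerance = 1e-9)
  }
})

test_that("window means are available as the alternative statistic", {
  spec <- chr1Spec()
  scan <- rawScan(runif(500, 0, 3))
  cal <- calibrateScan(scan, 250L, spec)
  s <- trackValues(binProfile(cal, stat = "sum"))[, "green"]
  m <- trackValues(binProfile(cal, stat = "mean"))[, "green"]
  counts <- tabulate(findInterval(cal@data$position_mb,
                                  seq(0, 247, length.out = 26),
                                  rightmost.closed = TRUE), 25)
  expect_equal(s[counts > 0] / counts[counts > 0], m[counts > 0])
})

test_that("averaging identical profiles returns them with zero SD", {
  spec <- chr1Spec()
  cal <- calibrateScan(rawScan(runif(300, 0, 2)), 150L, spec)
  wp <- binProfile(cal)
  mp <- averageProfiles(rep(list(wp), 24))
  expect_equal(mp@nChromatids, 24L)
  expect_equal(unname(mp@mean), unname(wp@values))
  expect_true(all(mp@sd == 0))
})

test_that("two-profile mean and SD follow the closed forms", {
  spec <- chr1Spec()
  calA <- calibrateScan(rawScan(runif(300, 0, 2)), 150L, spec)
  calB <- calibrateScan(rawScan(runif(300, 0, 2)), 150L, spec)
  a <- binProfile(calA); b <- binProfile(calB)
  mp <- averageProfiles(list(a, b))
  expect_equal(mp@mean, (a@values + b@values) / 2)
  expect_equal(mp@sd, abs(a@values - b@values) / sqrt(2), tolerance = 1e-12)
})

test_that("mixed chromosome specs refuse to average", {
  calA <- calibrateScan(rawScan(runif(100)), 50L, chr1Spec())
  calB <- calibrateScan(rawScan(runif(100)), 50L, smallSpec())
  expect_error(averageProfiles(list(binProfile(calA), binProfile(calB))),
               "different chromosome specs")
})

test_that("background subtraction zeroes its window, clips, keeps SD", {
  spec <- chr1Spec()
  set.seed(5)
  profs <- lapply(1:6, function(i)
    binProfile(calibrateScan(rawScan(runif(400, 0, 2)), 200L, spec)))
  mp <- averageProfiles(profs)
  out <- subtractBackground(mp, backgroundWindow = 2L)
  expect_equal(unname(out@mean[2, ]), c(0, 0))
  expect_true(all(out@mean >= 0))
  expect_identical(out@sd, mp@sd)
  expect_equal(unname(out@backgroundValue), unname(mp@mean[2, ]))
  # arithmetic on an explicit case
  expect_equal(unname(out@mean[5, "green"]),
               unname(max(mp@mean[5, "green"] - mp@mean[2, "green"], 0)))
})

test_that("'centromere' resolves to the window containing 120 Mb on chr1", {
  spec <- chr1Spec()
  mp <- averageProfiles(list(
    binProfile(calibrateScan(rawScan(runif(300, 1, 2)), 150L, spec))))
  out <- subtractBackground(mp)
  # 25 equal windows of 9.88 Mb: 120 Mb falls in window 13 (118.56-128.44)
  expect_equal(out@backgroundWindow, 13L)
  expect_equal(unname(out@mean[13, ]), c(0, 0))
})

test_that("a zero background leaves the profile unchanged", {
  spec <- chr1Spec()
  v <- matrix(runif(50, 1, 3), 25, 2, dimnames = list(NULL, c("green", "red")))
  v[4, ] <- 0
  mp <- new("MeanProfile", mean = v, sd = v * 0, nChromatids = 1L,
            backgroundValue = c(green = NA_real_, red = NA_real_),
            backgroundWindow = NA_integer_, spec = spec)
  out <- subtractBackground(mp, backgroundWindow = 4L)
  expect_equal(out@mean, v)
})
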