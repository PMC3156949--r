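# Correlation of window tracks and metaphase/interphase alignment.

test_that("correlation is affine-invariant and antisymmetric under negation", {
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  set.seed(3)
  x <- makeTrack(sch, rnorm(25))
  up <- makeTrack(sch, 2 * trackValues(x) + 3)
  down <- makeTrack(sch, -trackValues(x))
  expect_equal(correlateTracks(x, up)@r, 1, tolerance = 1e-12)
  expect_equal(correlateTracks(x, down)@r, -1, tolerance = 1e-12)
  y <- makeTrack(sch, rnorm(25))
  expect_equal(correlateTracks(x, y)@r,
               -correlateTracks(x, makeTrack(sch, -trackValues(y)))@r,
               tolerance = 1e-12)
  expect_equal(correlateTracks(makeTrack(sch, 5 * trackValues(x) + 1), y)@r,
               correlateTracks(x, y)@r, tolerance = 1e-12)
})

test_that("r matches the textbook covariance-formula oracle to 1e-12", {
  sch <- new("WindowScheme", chrom = "chrT",
             boundaries = as.numeric(0:5) * 1e6)
  x <- c(1, 2, 3, 4, 5); y <- c(2, 1, 4, 3, 6)
  res <- correlateTracks(makeTrack(sch, x), makeTrack(sch, y))
  # independent scalar oracle: product-moment form E[xy] - E[x]E[y]
  n <- 5
  oracle <- (mean(x * y) - mean(x) * mean(y)) /
    sqrt((mean(x^2) - mean(x)^2) * (mean(y^2) - mean(y)^2))
  expect_equal(res@r, oracle, tolerance = 1e-12)
  # p from the t transform with n - 2 degrees of freedom
  tstat <- oracle * sqrt((n - 2) / (1 - oracle^2))
  expect_equal(res@p, 2 * pt(abs(tstat), n - 2, lower.tail = FALSE),
               tolerance = 1e-12)
  # cross-check against the reference implementation
  ct <- cor.test(x, y)
  expect_equal(res@r, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(res@p, ct$p.value, tolerance = 1e-12)
})

test_that("degenerate and mismatched inputs raise the contracted errors", {
  schA <- makeWindows(chr1Spec(), nWindows = 25)
  schB <- makeWindows(chr1Spec(), widthMb = 10)
  x <- makeTrack(schA, rnorm(25))
  expect_error(correlateTracks(x, makeTrack(schA, rep(1, 25))), "variance")
  expect_error(correlateTracks(x, makeTrack(schB, rnorm(25))),
               "different window schemes")
  expect_error(correlateTracks(x, x, exclude = 1:23), "fewer than 3")
  expect_error(correlateTracks(x, x, exclude = 26L), "out of range")
})

test_that("window exclusions drop exactly the named windows", {
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  set.seed(8)
  xv <- rnorm(25); yv <- rnorm(25)
  res <- correlateTracks(makeTrack(sch, xv), makeTrack(sch, yv),
                         exclude = c(13L, 1L))
  expect_equal(res@n, 23L)
  expect_equal(res@excluded, c(1L, 13L))
  expect_equal(res@r, cor(xv[-c(1, 13)], yv[-c(1, 13)]), tolerance = 1e-12)
})

test_that("spearman option ranks before correlating", {
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  set.seed(9)
  xv <- rexp(25); yv <- xv^3 + rnorm(25, 0, 1e-6) # monotone, nonlinear
  res <- correlateTracks(makeTrack(sch, xv), makeTrack(sch, yv),
                         method = "spearman")
  expect_equal(res@r, 1, tolerance = 1e-9)
})

test_that("the correlation matrix is symmetric with unit diagonal", {
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  set.seed(12)
  tracks <- list(a = makeTrack(sch, rnorm(25)),
                 b = makeTrack(sch, rnorm(25)),
                 c = makeTrack(sch, rnorm(25)),
                 dup = NULL)
  tracks$dup <- tracks$a
  cm <- correlationMatrix(tracks)
  expect_equal(diag(cm@r), setNames(rep(1, 4), names(tracks)))
  expect_equal(cm@r, t(cm@r))
  expect_equal(cm@p, t(cm@p))
  expect_equal(cm@r["a", "dup"], 1, tolerance = 1e-12)
  expect_equal(nrow(cm@failures), 0)
})

test_that("failed cells are recorded with reasons, not propagated", {
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  set.seed(2)
  cm <- correlationMatrix(list(a = makeTrack(sch, rnorm(25)),
                               flat = makeTrack(sch, rep(1, 25))))
  expect_true(is.na(cm@r["a", "flat"]))
  expect_equal(nrow(cm@failures), 1)
  expect_match(cm@failures$reason, "variance")
})

test_that("estimated r recovers a known generating correlation", {
  # bivariate normal pairs with known rho; modest replicate count here,
  # the full calibration lives in the acceptance suite
  sch <- makeWindows(chr1Spec(), nWindows = 25)
  reps <- 2000
  for (rho in c(0.3, 0.8)) {
    rs <- withr::with_seed(100 + round(100 * rho), {
      vapply(seq_len(reps), function(i) {
        z1 <- rnorm(25); z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(25)
        correlateTracks(makeTrack(sch, z1), makeTrack(sch, z2))@r
      }, numeric(1))
    })
    expect_lt(abs(mean(rs) - rho), 0.05)
  }
})

test_that("metaphase/interphase alignment resamples 10-Mb tracks onto 25 windows", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  profs <- lapply(1:3, function(i) {
    img <- quickImage(spec, model, noiseSd = 0.02, seed = i, lengthPx = 250)
    cal <- calibrateScan(scanProfile(img, traceMedialAxis(img), 5),
                         locateCentromere(scanProfile(
                           img, traceMedialAxis(img), 5)), spec)
    binProfile(cal, chromatid = paste0("c", i))
  })
  mp <- subtractBackground(averageProfiles(profs))
  inter <- binSignal(simulateSignal(spec, model, 40, seed = 3),
                     makeWindows(spec, widthMb = 10))
  out <- alignMetaphaseInterphase(mp, inter)
  expect_true(out$resampled)
  expect_equal(nrow(out$pairs), 25)
  expect_gt(out$correlation@r, 0.8) # same generating band model
  # a track already on the 25-window scheme passes through unresampled
  same <- profileTrack(mp)
  out2 <- alignMetaphaseInterphase(mp, same)
  expect_false(out2$resampled)
  expect_equal(out2$correlation@r, 1, tolerance = 1e-12)
})

test_that("alignment refuses tracks from another chromosome", {
  spec <- chr1Spec()
  mp <- averageProfiles(list(binProfile(calibrateScan(
    rawScan(runif(300, 1, 2)), 150L, spec))))
  other <- countFeatures(GenomicRanges::GRanges(),
                         makeWindows(smallSpec(), widthMb = 10))
  expect_error(alignMetaphaseInterphase(mp, other), "different chromosomes")
})
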