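# Synthetic annotation, signal and expression generators.

test_that("simulateFeatures returns exactly n features, reproducibly", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  expect_length(simulateFeatures(spec, model, 0, seed = 1), 0)
  a <- simulateFeatures(spec, model, 500, coupling = 0.5, seed = 7)
  b <- simulateFeatures(spec, model, 500, coupling = 0.5, seed = 7)
  c2 <- simulateFeatures(spec, model, 500, coupling = 0.5, seed = 8)
  expect_length(a, 500)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
  expect_true(all(GenomicRanges::start(a) >= 1))
  expect_true(all(GenomicRanges::end(a) <= 247e6))
})

test_that("uncoupled features are uniform across 10-Mb windows", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  gr <- simulateFeatures(spec, model, 100000, coupling = 0, seed = 11)
  counts <- trackValues(countFeatures(gr, makeWindows(spec, widthMb = 10)))
  widths <- diff(makeWindows(spec, widthMb = 10)@boundaries)
  # chi-square goodness of fit against window-width-proportional expectation
  expected <- sum(counts) * widths / sum(widths)
  stat <- sum((counts - expected)^2 / expected)
  pval <- pchisq(stat, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(pval, 0.01)
})

test_that("fully coupled features pile up in the dominant band's window", {
  spec <- chr1Spec()
  m <- BandModel(data.frame(center_mb = 95, width_mb = 8, amplitude = 5),
                 baseline = 0.01, lengthMb = 247)
  gr <- simulateFeatures(spec, m, 20000, coupling = 1, seed = 3)
  counts <- trackValues(countFeatures(gr, makeWindows(spec, widthMb = 10)))
  expect_equal(which.max(counts), 10) # window 90-100 Mb holds 95 Mb
})

test_that("signal simulation is seeded, nonnegative-integer and gap-free", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  s1 <- simulateSignal(spec, model, meanDepth = 20, seed = 5)
  s2 <- simulateSignal(spec, model, meanDepth = 20, seed = 5)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  v <- S4Vectors::mcols(s1)$score
  expect_true(all(v >= 0 & v == round(v)))
  # adjacent steps tile the chromosome without gaps
  expect_true(all(GenomicRanges::start(s1)[-1] ==
                    GenomicRanges::end(s1)[-length(s1)] + 1))
  expect_equal(GenomicRanges::end(s1)[length(s1)], 247e6)
})

test_that("flat model gives equal window signal means; a band stands out", {
  spec <- chr1Spec()
  flat <- BandModel(baseline = 0.3, lengthMb = 247)
  sch <- makeWindows(spec, widthMb = 10)
  mFlat <- trackValues(binSignal(simulateSignal(spec, flat, 50, seed = 2), sch))
  expect_lt(diff(range(mFlat)) / mean(mFlat), 0.15)
  band <- BandModel(data.frame(center_mb = 45, width_mb = 8, amplitude = 3),
                    baseline = 0.1, lengthMb = 247)
  mBand <- trackValues(binSignal(simulateSignal(spec, band, 50, seed = 2), sch))
  expect_equal(which.max(mBand), 5)
  expect_gt(mBand[5], 2 * stats::median(mBand))
})

test_that("expression simulation respects gene class, coupling and seed", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  genes <- simulateFeatures(spec, model, 800, coupling = 0.8, seed = 21)
  sines <- simulateFeatures(spec, model, 10, featureClass = "sine", seed = 1)
  expect_error(simulateExpression(sines, model, seed = 1), "gene")
  empty <- simulateFeatures(spec, model, 0, seed = 1)
  expect_equal(nrow(simulateExpression(empty, model, seed = 1)), 0)
  e1 <- simulateExpression(genes, model, coupling = 1, seed = 4)
  e2 <- simulateExpression(genes, model, coupling = 1, seed = 4)
  expect_identical(e1, e2)
  expect_true(all(e1$value >= 0))
  expect_equal(nrow(e1), 800)
})

test_that("strongly coupled expression sums peak at the dominant band", {
  spec <- chr1Spec()
  m <- BandModel(data.frame(center_mb = 205, width_mb = 8, amplitude = 6),
                 baseline = 0.01, lengthMb = 247)
  genes <- simulateFeatures(spec, m, 3000, coupling = 0, seed = 9)
  expr <- simulateExpression(genes, m, coupling = 1, seed = 10)
  sums <- trackValues(sumExpression(expr, makeWindows(spec, widthMb = 10)))
  expect_equal(which.max(sums), 21) # window 200-210 Mb
})

test_that("uncoupled expression shows no positive association with the model", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  sch <- makeWindows(spec, widthMb = 10)
  genes <- simulateFeatures(spec, model, 5000, coupling = 0, seed = 31)
  expr <- simulateExpression(genes, model, coupling = 0, seed = 32)
  sums <- sumExpression(expr, sch)
  res <- correlateTracks(sums, truthTrack(model, sch))
  # two-sided p converted to the one-sided "greater" probability
  pGreater <- if (res@r > 0) res@p / 2 else 1 - res@p / 2
  expect_gt(pGreater, 0.01)
})

test_that("feature-count coupling to the band model rises with the mixture weight", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  sch <- makeWindows(spec, widthMb = 10)
  truth <- truthTrack(model, sch)
  r <- vapply(c(0, 0.5, 1), function(cp) {
    gr <- simulateFeatures(spec, model, 30000, coupling = cp,
                           seed = childSeed(99, sprintf("cp-%g", cp)))
    correlateTracks(countFeatures(gr, sch), truth)@r
  }, numeric(1))
  expect_true(all(diff(r) > 0))
})

test_that("child seeds differ across streams and stay reproducible", {
  expect_identical(childSeed(1, "genes"), childSeed(1, "genes"))
  expect_false(childSeed(1, "genes") == childSeed(1, "signal"))
  expect_false(childSeed(1, "genes") == childSeed(2, "genes"))
  expect_true(childSeed(2147483646, "x") >= 0)
})
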