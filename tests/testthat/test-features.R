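# Fixed-window aggregation of annotations, signal and expression.

library(GenomicRanges)

test_that("window schemes tile the chromosome by width or by count", {
  spec <- chr1Spec()
  byWidth <- makeWindows(spec, widthMb = 10)
  expect_equal(windowCount(byWidth), 25)
  expect_equal(tail(diff(byWidth@boundaries), 1), 7e6) # last window 240-247
  byCount <- makeWindows(spec, nWindows = 25)
  expect_equal(windowCount(byCount), 25)
  expect_true(all(abs(diff(byCount@boundaries) - 9.88e6) < 1e-6))
  exact <- makeWindows(ChromSpec("chrX", 100, 50), widthMb = 10)
  expect_equal(windowCount(exact), 10)
  expect_true(all(diff(exact@boundaries) == 1e7))
  expect_error(makeWindows(spec, widthMb = 10, nWindows = 25), "exactly one")
  expect_warning(w1 <- makeWindows(ChromSpec("chrY", 5, 2), widthMb = 10),
                 "single window")
  expect_equal(windowCount(w1), 1)
})

test_that("an empty feature table gives an all-zero count track", {
  gr <- GRanges()
  tr <- countFeatures(gr, makeWindows(chr1Spec(), widthMb = 10))
  expect_equal(trackValues(tr), rep(0, 25))
})

test_that("features land in the windows containing their midpoints", {
  gr <- GRanges("chr1", IRanges(start = c(5e6, 15e6, 25e6) - 5e5 + 1,
                                width = 1e6))
  tr <- countFeatures(gr, makeWindows(chr1Spec(), widthMb = 10))
  expect_equal(trackValues(tr), c(1, 1, 1, rep(0, 22)))
})

test_that("window counts match a brute-force loop and conserve the total", {
  spec <- chr1Spec()
  scheme <- makeWindows(spec, widthMb = 10)
  set.seed(41)
  n <- 10000
  starts <- sort(sample(0:(247e6 - 1000), n))
  widths <- sample(100:50000, n, replace = TRUE)
  ends <- pmin(starts + widths, 247e6)
  gr <- GRanges("chr1", IRanges(start = starts + 1, end = ends))
  tr <- countFeatures(gr, scheme)
  oracle <- numeric(25)
  for (i in seq_len(n)) {
    mid <- (starts[i] + ends[i]) / 2
    k <- min(25, floor(mid / 1e7) + 1)
    oracle[k] <- oracle[k] + 1
  }
  expect_equal(trackValues(tr), oracle)
  expect_equal(sum(trackValues(tr)), n)
})

test_that("start assignment is available and differs where expected", {
  # a feature straddling a boundary: midpoint in window 2, start in window 1
  gr <- GRanges("chr1", IRanges(start = 9.8e6 + 1, end = 10.4e6))
  scheme <- makeWindows(chr1Spec(), widthMb = 10)
  expect_equal(which(trackValues(countFeatures(gr, scheme)) > 0), 2)
  expect_equal(which(trackValues(
    countFeatures(gr, scheme, assignBy = "start")) > 0), 1)
})

test_that("out-of-bounds features error; other chromosomes are dropped", {
  scheme <- makeWindows(chr1Spec(), widthMb = 10)
  bad <- GRanges("chr1", IRanges(start = 250e6, width = 100))
  expect_error(countFeatures(bad, scheme), "outside chromosome bounds")
  mixed <- GRanges(c("chr1", "chr2"), IRanges(start = c(1e6, 1e6), width = 10))
  expect_message(tr <- countFeatures(mixed, scheme), "dropping 1")
  expect_equal(sum(trackValues(tr)), 1)
})

test_that("constant signal averages to itself in every window", {
  spec <- chr1Spec()
  sig <- GRanges("chr1", IRanges(start = seq(1, 247e6, by = 1e6),
                                 width = 1e6))
  mcols(sig)$score <- 2.5
  tr <- binSignal(sig, makeWindows(spec, widthMb = 10))
  expect_equal(trackValues(tr), rep(2.5, 25), tolerance = 1e-12)
})

test_that("signal covering half of window 1 gives mean 0.5 there", {
  sig <- GRanges("chr1", IRanges(start = 1, end = 5e6))
  mcols(sig)$score <- 1
  tr <- binSignal(sig, makeWindows(chr1Spec(), widthMb = 10))
  expect_equal(trackValues(tr)[1], 0.5)
  expect_equal(trackValues(tr)[-1], rep(0, 24))
})

test_that("length-weighted window means match a per-base oracle", {
  spec <- ChromSpec("chrT", 1, 0.5) # 1 Mb so a per-base oracle is feasible
  scheme <- makeWindows(spec, widthMb = 0.1)
  set.seed(13)
  # random non-overlapping step track with gaps
  cuts <- sort(sample(0:1e6, 60))
  starts <- head(cuts, -1); ends <- tail(cuts, -1)
  keep <- runif(length(starts)) < 0.7
  gr <- GRanges("chrT", IRanges(start = starts[keep] + 1, end = ends[keep]))
  mcols(gr)$score <- round(runif(sum(keep), 0, 10), 3)
  tr <- binSignal(gr, scheme)
  perBase <- numeric(1e6)
  for (i in seq_along(gr))
    perBase[(starts[keep][i] + 1):ends[keep][i]] <- mcols(gr)$score[i]
  oracle <- colMeans(matrix(perBase, nrow = 1e5))
  expect_equal(trackValues(tr), oracle, tolerance = 1e-9)
})

test_that("negative signal is rejected", {
  gr <- GRanges("chr1", IRanges(1, 100)); mcols(gr)$score <- -1
  expect_error(binSignal(gr, makeWindows(chr1Spec(), widthMb = 10)),
               "negative")
})

test_that("expression sums assign by position and conserve the total", {
  spec <- chr1Spec()
  scheme <- makeWindows(spec, widthMb = 10)
  one <- data.frame(gene_id = "g1", chrom = "chr1", pos = 60e6, value = 7)
  tr <- sumExpression(one, scheme)
  expect_equal(which(trackValues(tr) > 0), 7)
  expect_equal(sum(trackValues(tr)), 7)
  zero <- data.frame(gene_id = c("a", "b"), chrom = "chr1",
                     pos = c(1e6, 2e6), value = 0)
  expect_equal(trackValues(sumExpression(zero, scheme)), rep(0, 25))
})

test_that("3,071 simulated genes sum like the brute-force oracle", {
  spec <- chr1Spec(); model <- fiveBandModel(spec)
  scheme <- makeWindows(spec, widthMb = 10)
  genes <- simulateFeatures(spec, model, 3071, coupling = 0.8, seed = 6)
  expr <- simulateExpression(genes, model, coupling = 0.8, seed = 7)
  tr <- sumExpression(expr, scheme)
  oracle <- numeric(25)
  for (i in seq_len(nrow(expr))) {
    k <- min(25, floor(expr$pos[i] / 1e7) + 1)
    oracle[k] <- oracle[k] + expr$value[i]
  }
  expect_equal(trackValues(tr), oracle, tolerance = 1e-9)
  expect_equal(sum(trackValues(tr)), sum(expr$value), tolerance = 1e-9)
})

test_that("duplicate gene ids are a validation error", {
  d <- data.frame(gene_id = c("g", "g"), chrom = "chr1",
                  pos = c(1e6, 2e6), value = 1)
  expect_error(sumExpression(d, makeWindows(chr1Spec(), widthMb = 10)),
               "duplicate")
})

test_that("merging adjacent 5-Mb windows reproduces the 10-Mb counts", {
  spec <- ChromSpec("chrE", 240, 120) # length divisible by both widths
  model <- fiveBandModel(spec)
  gr <- simulateFeatures(spec, model, 5000, coupling = 0.7, seed = 15)
  fine <- trackValues(countFeatures(gr, makeWindows(spec, widthMb = 5)))
  coarse <- trackValues(countFeatures(gr, makeWindows(spec, widthMb = 10)))
  merged <- fine[seq(1, 47, by = 2)] + fine[seq(2, 48, by = 2)]
  expect_equal(merged, coarse)
})
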