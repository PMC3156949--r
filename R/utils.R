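#' @include AllClasses.R
NULL

#' Derive a reproducible child seed for a named substream
#'
#' Expands one master seed into independent per-component seeds so that
#' adding a generator to a pipeline does not perturb the streams of the
#' others. The derivation is a fixed integer hash of the master seed and the
#' stream label; it involves no RNG state.
#'
#' @param seed master seed (single integer-valued number).
#' @param stream character label of the substream, e.g. \code{"chromatid-3"}.
#' @return a single integer seed in \code{[0, 2^31 - 2]}.
#' @examples
#' childSeed(1, "genes")
#' childSeed(1, "signal")
#' @export
childSeed <- function(seed, stream) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            length(stream) == 1L, is.character(stream))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  h <- (as.numeric(seed) %% m) * 48271 %% m
  for (k in utf8ToInt(stream)) h <- (h * 31 + k) %% m
  as.integer(h)
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code, .rng_kind = "Mersenne-Twister",
                   .rng_normal_kind = "Inversion", .rng_sample_kind = "Rejection")
}

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at continuous
# 1-based coordinates; coordinates are clamped to the image bounds and the
# number of clamped points is returned via attribute "clamped".
.bilinear <- function(m, x, y) {
  x <- as.vector(x); y <- as.vector(y)
  nx <- ncol(m); ny <- nrow(m)
  clamped <- sum(x < 1 | x > nx | y < 1 | y > ny)
  x <- pmin(pmax(x, 1), nx)
  y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  v <- m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
  attr(v, "clamped") <- clamped
  v
}

# Format numbers for TSV output at 9 significant digits (bit-stable reruns).
.fmtNum <- function(x) {
  out <- formatC(signif(x, 9), format = "g", digits = 9)
  out[is.na(x)] <- "."
  out
}

# Lowest-index argmax with a logged message on ties.
.argmaxLow <- function(x, what = "value") {
  mx <- max(x)
  idx <- which(x == mx)
  if (length(idx) > 1L)
    message(sprintf("tie in %s argmax at indices %s; using the lowest",
                    what, paste(idx, collapse = ", ")))
  idx[1L]
}
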