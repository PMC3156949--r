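# Shared fixtures built in code: small geometries and scan constructors so
# individual tests stay fast.

smallSpec <- function() ChromSpec("chrT", 100, 40, nScanWindows = 10,
                                  featureWindowMb = 10)

# a raw scan straight from channel vectors (equal arc spacing)
rawScan <- function(green, red = green, blue = NULL, widthPx = 1) {
  n <- length(green)
  if (is.null(blue)) {
    blue <- numeric(n)
    blue[ceiling(n / 2)] <- 1
  }
  new("RawScan",
      data = data.frame(arc_fraction = seq(0, 1, length.out = n),
                        mean_green = green, mean_red = red, mean_blue = blue),
      widthPx = widthPx, source = "synthetic")
}

# a window track on a scheme from bare values (no validity shortcuts)
makeTrack <- function(scheme, values, kind = "scan_profile") {
  new("WindowTrack", scheme = scheme, values = as.numeric(values),
      kind = kind, units = "test")
}

# small, quick-to-render image
quickImage <- function(spec = chr1Spec(), model = fiveBandModel(spec),
                       warp = identityWarp(spec), noiseSd = 0,
                       bendAmplitude = 0, seed = 1, lengthPx = 200,
                       radiusPx = 5) {
  renderChromatid(spec, model, warp, noiseSd = noiseSd,
                  bendAmplitude = bendAmplitude, seed = seed,
                  lengthPx = lengthPx, radiusPx = radiusPx)
}
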