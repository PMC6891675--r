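# Shared fixtures: all test data is generated in code.

# seeded random SpectralMatrix
randomSpectra <- function(n = 4, p = 6, seed = 42, wavenumbers = NULL) {
  set.seed(seed)
  if (is.null(wavenumbers)) wavenumbers <- seq(400, 400 + 10 * (p - 1), by = 10)
  SpectralMatrix(matrix(rnorm(n * p), n, p), wavenumbers,
                 sampleIds = rep(sprintf("s%d", seq_len(ceiling(n / 2))),
                                 each = 2)[seq_len(n)],
                 replicateIds = rep(1:2, length.out = n))
}

# small, fast synthetic config (reduced grid keeps preprocessing cheap)
tinyConfig <- function(nSamples = 24, gridPoints = 300, seed = 11, ...) {
  syntheticConfig(nSamples = nSamples, gridPoints = gridPoints,
                  seed = seed, ...)
}

# a config with a single band coupled to one property and no nuisance terms
singleBandConfig <- function(property = "moisture", coupling = 0.5,
                             centerIdx = 150, gridPoints = 300,
                             nSamples = 20, seed = 5) {
  cfg <- syntheticConfig(nSamples = nSamples, gridPoints = gridPoints,
                         seed = seed, scenario = "noiseless")
  w <- wavenumbers0 <- cfg@wavenumbers
  bd <- data.frame(center = w[centerIdx], width = 30, baseAmplitude = 1)
  for (p in honeyProperties()$name) bd[[paste0("coupling_", p)]] <- 0
  bd[[paste0("coupling_", property)]] <- coupling
  cfg@bands <- bd
  cfg
}

# write a minimal AFFN JCAMP-DX file for a spectrum; returns the path
writeJcampFixture <- function(x, y, path, xfactor = 1, yfactor = 1,
                              perLine = 4) {
  n <- length(x)
  dx <- (x[n] - x[1]) / (n - 1)
  starts <- seq(1, n, by = perLine)
  dataLines <- vapply(starts, function(s) {
    idx <- s:min(s + perLine - 1, n)
    paste(c(format(x[s] / xfactor, digits = 12),
            format(y[idx] / yfactor, digits = 12)), collapse = " ")
  }, "")
  writeLines(c(
    "##TITLE=synthetic honey spectrum (test fixture)",
    "##JCAMP-DX=4.24",
    "##DATA TYPE=RAMAN SPECTRUM",
    sprintf("##XFACTOR=%g", xfactor),
    sprintf("##YFACTOR=%g", yfactor),
    sprintf("##FIRSTX=%.10g", x[1] / xfactor),
    sprintf("##LASTX=%.10g", x[n] / xfactor),
    sprintf("##NPOINTS=%d", n),
    "##XYDATA=(X++(Y..Y))",
    dataLines,
    "##END="), path)
  path
}
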