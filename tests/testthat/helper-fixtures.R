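# shared fixtures, all built in code

agilentCy3 <- function() ScannerModel(106, 0.95, 11.90,
                                      channel = "Cy3", pmtGain = 100)

# the vendor-printed dilution densities (3 significant figures), series 1-27
printedDensities <- c(1.47e5, 7.35e4, 3.68e4, 1.84e4, 9.19e3, 4.59e3,
                      2.30e3, 1.15e3, 5.74e2, 2.87e2, 1.44e2, 7.18e1,
                      3.59e1, 1.79e1, 8.97, 4.49, 2.24, 1.12, 5.61e-1,
                      2.80e-1, 1.40e-1, 7.01e-2, 3.50e-2, 1.75e-2,
                      8.76e-3, 4.38e-3, 2.19e-3)

# the published scanner characteristics used as simulation ground truths
scannerTable <- data.frame(
  scanner = c(rep("Agilent", 6), "GenePix", "Bio-Rad", "Bio-Rad"),
  channel = c(rep("Cy3", 3), rep("Cy5", 3), "Cy3", "Cy3", "Cy5"),
  pmt = c(100, 50, 20, 100, 50, 20, 500, 500, 500),
  B = c(106, 52, 21, 54, 28, 11, 208, 4, 11),
  a = c(0.95, 0.95, 0.94, 0.98, 0.98, 0.99, 0.74, 0.84, 0.86),
  g = c(11.90, 12.14, 12.12, 3.90, 4.04, 4.76, 7.45, 8.33, 3.85))

simObs <- function(seed, model = agilentCy3(), noiseCV = 0.10,
                   replicates = 20, ceiling = 65535, ...) {
  layout <- makeSlideLayout(replicatesPerColumn = replicates)
  cfg <- SimulationConfig(model, noiseCV = noiseCV, ceiling = ceiling,
                          seed = seed, ...)
  simulateScan(layout, cfg)
}

# a FitResult wrapper around bare parameter values (for invariance checks
# fed from published tables rather than from refitting)
fitFromParams <- function(B, a, g, channel = "Cy3", pmt = NA_real_,
                          ci = NULL) {
  fit <- new("FitResult",
             model = ScannerModel(B, a, g, channel = channel, pmtGain = pmt),
             merit = 0, nUsed = 0L, nExcludedSaturated = 0L,
             residuals = numeric(0), converged = TRUE, message = "")
  if (!is.null(ci)) fit <- methods::initialize(fit, bootstrapCI = ci,
                                               bootstrapLevel = 0.95,
                                               nBoot = 1L)
  fit
}
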