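## Standard calibration-slide column roles: 27 two-fold dilution columns,
## one buffer column (intended negative control), three blanks, one marker.
.SLIDE_ROLES <- c(rep("dilution", 27), "buffer", rep("blank", 3), "marker")
.TOP_DENSITY <- 1.47e5

#' Nominal density of a dilution-series column
#'
#' The dilution columns form a geometric series with ratio 1/2:
#' `topDensity / 2^(k-1)`, from 1.47e5 fluorophores/um^2 at series 1 down
#' to 2.19e-3 at series 27 (matching the vendor's printed description to
#' 3 significant figures).
#'
#' @param k integer vector of series indices in 1..27. Indices 28-32 are
#'   not dilution columns (buffer, blanks, marker) and are rejected.
#' @param topDensity density of series 1 (default 1.47e5).
#' @return Numeric vector of surface densities (fluorophores/um^2).
#' @examples
#' densityForSeries(c(1, 2, 27))
#' @export
densityForSeries <- function(k, topDensity = .TOP_DENSITY) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 1L) || any(k > 27L))
    .scError("scancal_domain_error", paste(
      "densityForSeries: series index must be in 1..27",
      "(28 is buffer, 29-31 blank, 32 position marker)"))
  topDensity / 2^(k - 1)
}

#' Build the standard 32-column calibration-slide layout
#'
#' Columns 1-27 carry the two-fold dilution series from
#' [densityForSeries()], column 28 is spotting buffer (nominal density
#' undefined), columns 29-31 are blanks (density exactly 0) and column 32
#' a position marker.
#'
#' @param replicatesPerColumn replicate spots per column (default 20).
#' @param topDensity density of series 1 (default 1.47e5).
#' @param dye dye label applied to every column (default "Cy3").
#' @return A [SlideLayout-class].
#' @export
makeSlideLayout <- function(replicatesPerColumn = 20,
                            topDensity = .TOP_DENSITY, dye = "Cy3") {
  if (replicatesPerColumn < 1)
    .scError("scancal_validation_error",
             "makeSlideLayout: 'replicatesPerColumn' must be >= 1")
  role <- .SLIDE_ROLES
  density <- rep(NA_real_, 32)
  density[1:27] <- densityForSeries(1:27, topDensity)
  density[role == "blank"] <- 0
  new("SlideLayout",
      columns = data.frame(series = 1:32, role = role, dye = dye,
                           density = density, stringsAsFactors = FALSE),
      replicatesPerColumn = as.integer(replicatesPerColumn))
}

#' Simulate a calibration-slide scan
#'
#' Draws one virtual scan of `layout` under the ground-truth model in
#' `config`. Each spot's signal is
#' `applySaturation(predictSignal(x) * L + N, ceiling)` where L is mean-1
#' lognormal multiplicative noise with coefficient of variation `noiseCV`
#' and N is centred Gaussian additive noise; negatives are clamped to 0.
#' Blank spots use x = 0; buffer spots use x = 0 plus
#' `bufferAutofluorescence` counts before noise; marker spots use the fixed
#' `markerSignal` base. The saturated flag marks spots at the ceiling.
#' Bit-for-bit reproducible for a fixed `seed` (the global RNG state is
#' left untouched).
#'
#' @param layout a [SlideLayout-class].
#' @param config a [SimulationConfig-class].
#' @return Spot-level data.frame in the intensity-table dialect (one row
#'   per spot; see [readIntensityTable()]).
#' @examples
#' layout <- makeSlideLayout(replicatesPerColumn = 4)
#' cfg <- SimulationConfig(ScannerModel(106, 0.95, 11.90, "Cy3", 100),
#'                         seed = 42)
#' head(simulateScan(layout, cfg))
#' @export
simulateScan <- function(layout, config) {
  stopifnot(is(layout, "SlideLayout"), is(config, "SimulationConfig"))
  cols <- layout@columns
  nrep <- layout@replicatesPerColumn
  n <- nrow(cols) * nrep
  series <- rep(cols$series, each = nrep)
  role <- rep(cols$role, each = nrep)
  density <- rep(cols$density, each = nrep)
  truth <- config@truth

  base <- numeric(n)
  base[role == "dilution"] <- predictSignal(density[role == "dilution"], truth)
  base[role == "blank"] <- predictSignal(0, truth)
  base[role == "buffer"] <- predictSignal(0, truth) +
    config@bufferAutofluorescence
  base[role == "marker"] <- config@markerSignal

  signal <- withr::with_seed(config@seed, {
    L <- if (config@noiseCV > 0) {
      s <- sqrt(log1p(config@noiseCV^2))
      stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    } else rep(1, n)
    N <- if (config@additiveSD > 0)
      stats::rnorm(n, 0, config@additiveSD) else rep(0, n)
    pmax(base * L + N, 0)
  })
  if (config@quantize) signal <- round(signal)
  signal <- applySaturation(signal, config@ceiling)

  x_nominal <- density              # NA for buffer and marker columns
  x_nominal[role == "blank"] <- 0
  rowidx <- rep(seq_len(nrep), times = nrow(cols))
  data.frame(
    spot_id = sprintf("c%02dr%03d", series, rowidx),
    block = 1L, column = series, row = rowidx, series = series,
    channel = truth@channel, pmt_gain = truth@pmtGain,
    x_nominal = x_nominal, signal = signal,
    saturated = signal >= config@ceiling,
    stringsAsFactors = FALSE)
}

#' Write a simulated slide as an on-disk fixture bundle
#'
#' Emits a GAL layout file (`layout.gal`), a spot-intensity CSV
#' (`intensities.csv`) and a manual-style slide description CSV
#' (`slide_description.csv`) into `dir`. The files round-trip through
#' [readGal()], [readIntensityTable()] and [readSlideDescription()] back to
#' the in-memory objects.
#'
#' @param layout a [SlideLayout-class].
#' @param observations spot-level data.frame from [simulateScan()].
#' @param dir target directory (created if absent).
#' @param ceiling saturation ceiling recorded for re-reading (default 65535).
#' @return Invisibly, a named character vector of the paths written.
#' @export
writeFixtureBundle <- function(layout, observations, dir, ceiling = 65535) {
  if (!dir.exists(dir))
    if (!dir.create(dir, recursive = TRUE))
      .scError("scancal_io_error",
               paste("writeFixtureBundle: cannot create directory", dir))
  paths <- c(gal = file.path(dir, "layout.gal"),
             intensities = file.path(dir, "intensities.csv"),
             description = file.path(dir, "slide_description.csv"))
  writeGal(layout, paths[["gal"]])
  writeIntensityTable(observations, paths[["intensities"]])
  writeSlideDescription(layout, paths[["description"]])
  invisible(paths)
}
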