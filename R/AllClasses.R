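#' @import methods
NULL

## classed conditions so callers can discriminate failure modes
.scError <- function(class, msg, call. = FALSE) {
  stop(structure(
    class = c(class, "scancal_error", "error", "condition"),
    list(message = msg, call = if (call.) sys.call(-1) else NULL)
  ))
}

#' ScannerModel: the scanner response model
#'
#' Scanner response to fluorophore surface density \eqn{x}
#' (fluorophores/\eqn{\mu m^2}) is modelled as
#' \deqn{SI = B x^a + g}
#' where \eqn{B} is the photomultiplier sensitivity (counts per
#' (fluorophores/\eqn{\mu m^2})\eqn{^a}), \eqn{a} the dimensionless
#' curvature exponent (\eqn{a = 1} is a perfectly linear detector in
#' non-transformed coordinates), and \eqn{g} the autofluorescence offset of
#' the spotting buffer/slide in counts, independent of dye quantity.
#'
#' @slot B numeric(1), sensitivity; must be > 0.
#' @slot a numeric(1), curvature exponent; must be > 0.
#' @slot g numeric(1), autofluorescence offset in counts; must be >= 0.
#' @slot channel character(1), dye channel label (e.g. "Cy3", "Cy5").
#' @slot pmtGain numeric(1), photomultiplier gain setting; NA if unknown.
#'
#' @seealso [predictSignal()], [fitResponse()]
#' @export
setClass("ScannerModel",
  representation(B = "numeric", a = "numeric", g = "numeric",
                 channel = "character", pmtGain = "numeric"),
  prototype(B = 1, a = 1, g = 0, channel = NA_character_, pmtGain = NA_real_)
)

setValidity("ScannerModel", function(object) {
  msg <- character()
  if (length(object@B) != 1L || !is.finite(object@B) || object@B <= 0)
    msg <- c(msg, "'B' must be a single finite value > 0")
  if (length(object@a) != 1L || !is.finite(object@a) || object@a <= 0)
    msg <- c(msg, "'a' must be a single finite value > 0")
  if (length(object@g) != 1L || !is.finite(object@g) || object@g < 0)
    msg <- c(msg, "'g' must be a single finite value >= 0")
  if (length(object@channel) != 1L)
    msg <- c(msg, "'channel' must be length 1")
  if (length(object@pmtGain) != 1L)
    msg <- c(msg, "'pmtGain' must be length 1")
  if (length(msg)) msg else TRUE
})

#' Construct a ScannerModel
#'
#' @param B sensitivity, counts per (fluorophores/um^2)^a; > 0.
#' @param a curvature exponent; > 0, with 1 meaning a linear detector.
#' @param g autofluorescence offset in counts; >= 0.
#' @param channel channel label, e.g. "Cy3".
#' @param pmtGain photomultiplier gain setting, or NA.
#' @return A [ScannerModel-class] object.
#' @examples
#' m <- ScannerModel(B = 106, a = 0.95, g = 11.90,
#'                   channel = "Cy3", pmtGain = 100)
#' predictSignal(c(0, 1, 100), m)
#' @export
ScannerModel <- function(B, a, g, channel = NA_character_, pmtGain = NA_real_) {
  new("ScannerModel", B = as.numeric(B), a = as.numeric(a), g = as.numeric(g),
      channel = as.character(channel), pmtGain = as.numeric(pmtGain))
}

setMethod("show", "ScannerModel", function(object) {
  cat("ScannerModel: SI = B * x^a + g\n")
  cat(sprintf("  B = %g   a = %g   g = %g\n", object@B, object@a, object@g))
  cat(sprintf("  channel = %s   PMT gain = %s\n",
              object@channel, format(object@pmtGain)))
  invisible(NULL)
})

#' SlideLayout: calibration-slide column layout
#'
#' A calibration slide is a grid of replicate-spot columns. The standard
#' slide has 32 columns: 1-27 a two-fold dilution series of dye, 28 spotting
#' buffer (intended negative control), 29-31 blank, 32 a position marker.
#'
#' @slot columns data.frame with one row per column: `series` (1-based
#'   index), `role` ("dilution", "buffer", "blank" or "marker"), `dye`
#'   (label), `density` (nominal fluorophores/um^2; 0 for blanks, NA for
#'   buffer and marker columns).
#' @slot replicatesPerColumn integer(1), replicate spots per column (NA if
#'   unknown, e.g. when read from a description table with no spot list).
#' @export
setClass("SlideLayout",
  representation(columns = "data.frame", replicatesPerColumn = "integer"))

setValidity("SlideLayout", function(object) {
  cols <- object@columns
  need <- c("series", "role", "dye", "density")
  if (!all(need %in% names(cols)))
    return(paste("'columns' must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(cols$series))
    return("duplicated series indices in layout")
  if (!all(cols$role %in% c("dilution", "buffer", "blank", "marker")))
    return("unknown column role")
  if (any(cols$density[cols$role == "blank"] != 0, na.rm = TRUE))
    return("blank columns must have density 0")
  d <- cols$density[cols$role == "dilution"]
  if (any(!is.finite(d)) || any(d <= 0))
    return("dilution columns must have finite positive densities")
  TRUE
})

setMethod("show", "SlideLayout", function(object) {
  tab <- table(object@columns$role)
  cat(sprintf("SlideLayout: %d columns (%s), %s replicates/column\n",
              nrow(object@columns),
              paste(names(tab), tab, sep = ":", collapse = ", "),
              format(object@replicatesPerColumn)))
  d <- object@columns$density[object@columns$role == "dilution"]
  if (length(d))
    cat(sprintf("  dilution densities: %.3g .. %.3g fluorophores/um^2\n",
                max(d), min(d)))
  invisible(NULL)
})

#' SimulationConfig: ground truth and noise model for a simulated scan
#'
#' @slot truth [ScannerModel-class] used as the generating model.
#' @slot noiseCV numeric(1), coefficient of variation of mean-1 lognormal
#'   multiplicative noise; 0 disables it.
#' @slot additiveSD numeric(1), sd of centred additive Gaussian noise
#'   (counts); 0 disables it.
#' @slot bufferAutofluorescence numeric(1), extra offset (counts) applied to
#'   buffer-column spots on top of the slide-wide g, so the disputed
#'   "buffer carries dye" scenario can be simulated.
#' @slot markerSignal numeric(1), base signal of position-marker spots
#'   before noise; defaults to the ceiling (markers scan saturated).
#' @slot ceiling numeric(1), detector saturation ceiling in counts.
#' @slot quantize logical(1), round signals to integer counts.
#' @slot seed integer(1), RNG seed; mandatory, no silent global RNG use.
#' @export
setClass("SimulationConfig",
  representation(truth = "ScannerModel", noiseCV = "numeric",
                 additiveSD = "numeric", bufferAutofluorescence = "numeric",
                 markerSignal = "numeric", ceiling = "numeric",
                 quantize = "logical", seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  if (object@noiseCV < 0) msg <- c(msg, "'noiseCV' must be >= 0")
  if (object@additiveSD < 0) msg <- c(msg, "'additiveSD' must be >= 0")
  if (object@bufferAutofluorescence < 0)
    msg <- c(msg, "'bufferAutofluorescence' must be >= 0")
  if (!is.finite(object@ceiling) || object@ceiling <= 0)
    msg <- c(msg, "'ceiling' must be > 0")
  if (is.na(object@seed)) msg <- c(msg, "'seed' is mandatory")
  if (length(msg)) msg else TRUE
})

#' Construct a SimulationConfig
#'
#' @param truth a [ScannerModel-class]; the generating ground truth.
#' @param noiseCV multiplicative lognormal noise CV (default 0.10).
#' @param additiveSD additive Gaussian noise sd in counts (default 0).
#' @param bufferAutofluorescence extra counts on buffer spots (default 0).
#' @param markerSignal base marker-spot signal; default `ceiling`.
#' @param ceiling saturation ceiling in counts (default 65535, 16 bit).
#' @param quantize round to integer counts (default FALSE).
#' @param seed integer RNG seed (required).
#' @return A [SimulationConfig-class] object.
#' @export
SimulationConfig <- function(truth, noiseCV = 0.10, additiveSD = 0,
                             bufferAutofluorescence = 0,
                             markerSignal = ceiling, ceiling = 65535,
                             quantize = FALSE, seed) {
  if (missing(seed)) .scError("scancal_validation_error",
                              "SimulationConfig: 'seed' is mandatory")
  new("SimulationConfig", truth = truth, noiseCV = as.numeric(noiseCV),
      additiveSD = as.numeric(additiveSD),
      bufferAutofluorescence = as.numeric(bufferAutofluorescence),
      markerSignal = as.numeric(markerSignal), ceiling = as.numeric(ceiling),
      quantize = as.logical(quantize), seed = as.integer(seed))
}

setMethod("show", "SimulationConfig", function(object) {
  cat(sprintf(
    "SimulationConfig: CV=%g, additive sd=%g, buffer AF=%g, ceiling=%g, seed=%d\n",
    object@noiseCV, object@additiveSD, object@bufferAutofluorescence,
    object@ceiling, object@seed))
  cat("  truth: "); show(object@truth)
  invisible(NULL)
})

#' FitResult: a fitted scanner response model
#'
#' @slot model the fitted [ScannerModel-class].
#' @slot merit numeric(1), final merit value E (sum of squared relative
#'   residuals) at the optimum.
#' @slot nUsed integer(1), observations entering the fit.
#' @slot nExcludedSaturated integer(1), observations dropped as saturated.
#' @slot residuals numeric, per-used-observation relative residuals
#'   (observed - fitted)/fitted.
#' @slot converged logical(1), honest convergence status of the optimizer.
#' @slot message character(1), optimizer diagnostic message.
#' @slot bootstrapCI NULL, or a 3 x 2 matrix of percentile intervals
#'   (rows B, a, g; columns lower, upper).
#' @slot bootstrapLevel numeric(1), the interval level (e.g. 0.95).
#' @slot nBoot integer(1), bootstrap resamples used (0 = none).
#' @slot bootstrapStable logical(1), FALSE when fewer than half the
#'   bootstrap refits succeeded (unstable-fit warning).
#' @export
setClass("FitResult",
  representation(model = "ScannerModel", merit = "numeric",
                 nUsed = "integer", nExcludedSaturated = "integer",
                 residuals = "numeric", converged = "logical",
                 message = "character", bootstrapCI = "ANY",
                 bootstrapLevel = "numeric", nBoot = "integer",
                 bootstrapStable = "logical"),
  prototype(bootstrapCI = NULL, bootstrapLevel = NA_real_, nBoot = 0L,
            bootstrapStable = NA))

setValidity("FitResult", function(object) {
  msg <- character()
  if (object@merit < 0) msg <- c(msg, "'merit' must be >= 0")
  if (!is.null(object@bootstrapCI) &&
      (!is.matrix(object@bootstrapCI) ||
       !identical(dim(object@bootstrapCI), c(3L, 2L))))
    msg <- c(msg, "'bootstrapCI' must be NULL or a 3 x 2 matrix")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FitResult", function(object) {
  m <- object@model
  cat(sprintf("FitResult: B = %.6g, a = %.6g, g = %.6g\n", m@B, m@a, m@g))
  cat(sprintf("  merit E = %.6g over %d spots (%d saturated excluded); converged: %s\n",
              object@merit, object@nUsed, object@nExcludedSaturated,
              object@converged))
  if (!is.null(object@bootstrapCI)) {
    ci <- object@bootstrapCI
    cat(sprintf("  %g%% bootstrap CI (%d resamples):\n",
                100 * object@bootstrapLevel, object@nBoot))
    for (p in rownames(ci))
      cat(sprintf("    %s: [%.6g, %.6g]\n", p, ci[p, 1], ci[p, 2]))
    if (isFALSE(object@bootstrapStable))
      cat("  warning: unstable fit (under 50% of bootstrap refits succeeded)\n")
  }
  invisible(NULL)
})

#' ConsistencyReport: manual-vs-layout audit result
#'
#' @slot table data.frame with one row per audited column: `column`,
#'   `manual`, `gal` (what each source claims), `verdict` ("match",
#'   "mismatch" or "missing") and `detail`.
#' @slot counts named integer vector of verdicts.
#' @slot note character, extra remarks (e.g. differing column counts).
#' @export
setClass("ConsistencyReport",
  representation(table = "data.frame", counts = "integer", note = "character"))

setValidity("ConsistencyReport", function(object) {
  if (sum(object@counts) != nrow(object@table))
    return("verdict counts must sum to columns audited")
  TRUE
})

setMethod("show", "ConsistencyReport", function(object) {
  cat(sprintf("ConsistencyReport: %s\n",
              paste(names(object@counts), object@counts,
                    sep = " = ", collapse = ", ")))
  bad <- object@table[object@table$verdict != "match", , drop = FALSE]
  if (nrow(bad)) {
    cat("  flagged columns:\n")
    for (i in seq_len(nrow(bad)))
      cat(sprintf("    column %s: %s\n", bad$column[i], bad$detail[i]))
  }
  for (n in object@note) cat("  note:", n, "\n")
  invisible(NULL)
})

#' DiagnosticsReport: scanner characterisation across fits
#'
#' @slot parameterTable data.frame shaped like a scanner-characteristics
#'   table: one row per fit with channel, PMT gain, B, a, g, merit, nUsed.
#' @slot gainInvariance list of per-channel verdicts for g and B.
#' @slot curvatureInvariance list, the curvature (a) comparison verdict.
#' @slot usableRanges data.frame of per-fit usable density intervals.
#' @slot channelRatio list or NULL, optional two-channel ratio summary.
#' @export
setClass("DiagnosticsReport",
  representation(parameterTable = "data.frame", gainInvariance = "list",
                 curvatureInvariance = "list", usableRanges = "data.frame",
                 channelRatio = "ANY"),
  prototype(channelRatio = NULL))

setMethod("show", "DiagnosticsReport", function(object) {
  cat("DiagnosticsReport\n")
  cat("  fitted parameters:\n")
  print(object@parameterTable, row.names = FALSE)
  for (ch in names(object@gainInvariance)) {
    gi <- object@gainInvariance[[ch]]
    for (p in names(gi))
      cat(sprintf("  gain invariance of %s [%s]: %s (spread %.3g, values %s)\n",
                  p, ch, gi[[p]]$verdict, gi[[p]]$spread,
                  paste(signif(gi[[p]]$values, 4), collapse = ", ")))
  }
  ci <- object@curvatureInvariance
  if (length(ci))
    cat(sprintf("  curvature invariance: %s (spread %.3g)\n",
                ci$verdict, ci$spread))
  invisible(NULL)
})
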