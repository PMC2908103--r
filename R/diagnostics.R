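#' Usable density range of a calibration fit
#'
#' The density interval a scan can actually quantify. Below
#' \eqn{x_{low} = (k g / B)^{1/a}} the dye signal is less than k times the
#' autofluorescence floor and drowns in background (the lower-plateau
#' artifact); above \eqn{x_{high} = ((c - g)/B)^{1/a}} the predicted signal
#' exceeds the detector ceiling c and clips. With g = 0 there is no floor
#' and the lower bound is 0.
#'
#' @param model a [ScannerModel-class].
#' @param k signal-to-background factor defining the floor (> 1,
#'   default 3).
#' @param ceiling detector ceiling in counts (default 65535).
#' @return A list with `lower`, `upper` (fluorophores/um^2) and `empty`
#'   (TRUE when lower >= upper, i.e. no usable range).
#' @examples
#' usableRange(ScannerModel(106, 0.95, 11.90), k = 3)
#' @export
usableRange <- function(model, k = 3, ceiling = 65535) {
  stopifnot(is(model, "ScannerModel"))
  if (k <= 1)
    .scError("scancal_domain_error",
             "usableRange: the signal-to-background factor 'k' must be > 1")
  lower <- if (model@g == 0) 0 else (k * model@g / model@B)^(1 / model@a)
  upper <- if (ceiling <= model@g) lower else
    ((ceiling - model@g) / model@B)^(1 / model@a)
  list(lower = lower, upper = upper, empty = lower >= upper)
}

## spread and verdict shared by the invariance checks; spread is the
## maximum pairwise relative difference, measured against the smaller value
.spreadVerdict <- function(values, cis, threshold) {
  spread <- if (max(values) == min(values)) 0 else
    (max(values) - min(values)) / min(values)
  haveCI <- length(cis) && !any(vapply(cis, is.null, logical(1)))
  overlap <- NA
  if (haveCI) {
    lo <- vapply(cis, function(ci) ci[1], numeric(1))
    hi <- vapply(cis, function(ci) ci[2], numeric(1))
    overlap <- TRUE
    for (i in seq_along(lo)) for (j in seq_along(lo)) if (i < j)
      overlap <- overlap && lo[i] <= hi[j] && lo[j] <= hi[i]
    verdict <- if (overlap) "invariant" else "not invariant"
  } else {
    verdict <- if (spread < threshold) "invariant" else "not invariant"
  }
  list(verdict = verdict, spread = spread, values = values,
       intervalsUsed = haveCI, intervalsOverlap = overlap,
       threshold = threshold)
}

.paramCI <- function(fit, parameter) {
  ci <- bootstrapCI(fit)
  if (is.null(ci)) NULL else ci[parameter, ]
}

#' Is a fitted parameter invariant across PMT gain settings?
#'
#' Collects one parameter (typically the autofluorescence offset g, or the
#' sensitivity B as the expected counter-example) from several fits of the
#' same channel at different gains and reports the maximum pairwise
#' relative difference. When every fit carries bootstrap intervals the
#' verdict is "invariant" iff all intervals pairwise overlap; otherwise
#' iff the spread is below `threshold`. Autofluorescence is a property of
#' the slide, not the detector, so g should pass this check while B — an
#' amplification factor — should fail it.
#'
#' @param fits list of [FitResult-class] objects (>= 2) sharing a channel.
#' @param parameter one of "B", "a", "g".
#' @param threshold relative-spread threshold used without intervals
#'   (default 0.15).
#' @param checkChannel error if fits mix channels (default TRUE; set FALSE
#'   to override deliberately).
#' @return A list: `verdict`, `spread`, `values`, `intervalsUsed`,
#'   `intervalsOverlap`, `threshold`.
#' @export
gainInvariance <- function(fits, parameter = c("g", "B", "a"),
                           threshold = 0.15, checkChannel = TRUE) {
  parameter <- match.arg(parameter)
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, is, logical(1), "FitResult")))
    .scError("scancal_validation_error",
             "gainInvariance: need a list of >= 2 FitResult objects")
  ch <- unique(vapply(fits, channelName, character(1)))
  if (checkChannel && length(ch[!is.na(ch)]) > 1L)
    .scError("scancal_validation_error", paste(
      "gainInvariance: fits mix channels", paste(ch, collapse = ", "),
      "- pass checkChannel = FALSE to compare across channels deliberately"))
  values <- vapply(fits, function(f) modelParams(f)[[parameter]], numeric(1))
  cis <- lapply(fits, .paramCI, parameter)
  c(list(parameter = parameter),
    .spreadVerdict(values, cis, threshold))
}

#' Compare response curvature across channels and gains
#'
#' Applies the [gainInvariance()] spread machinery to the curvature
#' exponent a across any set of fits (channels may mix: curvature is
#' expected to be a property of the detector family, not the dye), and
#' additionally reports each fit's deviation from the straight line a = 1.
#'
#' @param fits list of [FitResult-class] objects (>= 2).
#' @param threshold relative-spread threshold (default 0.15).
#' @return As [gainInvariance()], plus `deviationFromUnity` (|a - 1| per
#'   fit).
#' @export
curvatureComparison <- function(fits, threshold = 0.15) {
  if (!is.list(fits) || length(fits) < 2L ||
      !all(vapply(fits, is, logical(1), "FitResult")))
    .scError("scancal_validation_error",
             "curvatureComparison: need a list of >= 2 FitResult objects")
  values <- vapply(fits, curvature, numeric(1))
  cis <- lapply(fits, .paramCI, "a")
  out <- c(list(parameter = "a"), .spreadVerdict(values, cis, threshold))
  out$deviationFromUnity <- abs(values - 1)
  out
}

#' Background-corrected two-channel ratio profile
#'
#' Computes the ratio of the g-free responses of two fitted models,
#' `idealSignal(x, model1) / idealSignal(x, model2)`, across a density
#' grid. When the two curvatures are equal the x^a terms cancel and the
#' ratio is exactly B1/B2 at every density — the condition under which
#' plain two-channel intensity ratios are meaningful without calibration.
#' The verdict is "constant" iff max/min of the profile is below
#' `threshold`.
#'
#' @param model1,model2 [ScannerModel-class] objects.
#' @param densities density grid; defaults to the standard slide's
#'   dilution densities restricted to the usable range both models share.
#' @param threshold constancy threshold on max/min (default 1.05).
#' @param k,ceiling passed to [usableRange()] for the default grid.
#' @return A list: `densities`, `ratio`, `maxOverMin`, `verdict`.
#' @export
channelRatioProfile <- function(model1, model2, densities = NULL,
                                threshold = 1.05, k = 3, ceiling = 65535) {
  stopifnot(is(model1, "ScannerModel"), is(model2, "ScannerModel"))
  if (is.null(densities)) {
    r1 <- usableRange(model1, k, ceiling)
    r2 <- usableRange(model2, k, ceiling)
    lo <- max(r1$lower, r2$lower); hi <- min(r1$upper, r2$upper)
    all27 <- densityForSeries(1:27)
    densities <- all27[all27 >= lo & all27 <= hi]
    if (!length(densities)) densities <- sqrt(lo * hi)
  }
  densities <- as.numeric(densities)
  if (!length(densities) || any(densities <= 0))
    .scError("scancal_domain_error",
             "channelRatioProfile: density grid must be nonempty and positive")
  ratio <- idealSignal(densities, model1) / idealSignal(densities, model2)
  mom <- max(ratio) / min(ratio)
  list(densities = densities, ratio = ratio, maxOverMin = mom,
       verdict = if (mom < threshold) "constant" else "not constant",
       threshold = threshold)
}

#' Characterise a scanner from several calibration fits
#'
#' Aggregates fits into a scanner-characteristics report: the per-fit
#' parameter table (channel, gain, B, a, g, merit), per-channel gain
#' invariance of g and of B, the cross-fit curvature comparison, and each
#' fit's usable density range. Inputs are not mutated; permuting the fit
#' order permutes report rows only.
#'
#' @param fits list of [FitResult-class] objects.
#' @param threshold invariance spread threshold (default 0.15).
#' @param k,ceiling usable-range parameters (defaults 3 and 65535).
#' @return A [DiagnosticsReport-class].
#' @export
diagnose <- function(fits, threshold = 0.15, k = 3, ceiling = 65535) {
  if (!is.list(fits) || !length(fits) ||
      !all(vapply(fits, is, logical(1), "FitResult")))
    .scError("scancal_validation_error",
             "diagnose: need a nonempty list of FitResult objects")
  ptab <- do.call(rbind, lapply(fits, function(f) data.frame(
    channel = channelName(f), pmt_gain = pmtGain(f),
    B = sensitivity(f), a = curvature(f), g = autofluorescence(f),
    merit = meritValue(f), n_used = f@nUsed, stringsAsFactors = FALSE)))
  gi <- list()
  for (ch in unique(ptab$channel)) {
    sub <- fits[vapply(fits, channelName, character(1)) %in% ch]
    if (length(sub) >= 2L)
      gi[[ch]] <- list(g = gainInvariance(sub, "g", threshold),
                       B = gainInvariance(sub, "B", threshold))
  }
  ci <- if (length(fits) >= 2L) curvatureComparison(fits, threshold)
  else list()
  ur <- do.call(rbind, lapply(fits, function(f) {
    r <- usableRange(fittedModel(f), k, ceiling)
    data.frame(channel = channelName(f), pmt_gain = pmtGain(f),
               lower = r$lower, upper = r$upper, empty = r$empty,
               stringsAsFactors = FALSE)
  }))
  new("DiagnosticsReport", parameterTable = ptab, gainInvariance = gi,
      curvatureInvariance = ci, usableRanges = ur)
}

#' Plot a calibration fit
#'
#' Log-log (default) or linear view of spot signals against nominal
#' density, with the fitted response curve and the g-free ideal line.
#' Blank spots (x = 0) are drawn at a nominal position left of the lowest
#' density in the log-log view.
#'
#' @param fit a [FitResult-class].
#' @param observations the spot-level data.frame the fit used.
#' @param log plot in log-log coordinates (default TRUE).
#' @param main plot title.
#' @return Invisibly, NULL. Called for its side effect.
#' @export
plotFit <- function(fit, observations, log = TRUE, main = "Scanner response") {
  stopifnot(is(fit, "FitResult"))
  .validateObservations(observations)
  m <- fittedModel(fit)
  obs <- observations[!is.na(observations$x_nominal), , drop = FALSE]
  pos <- obs$x_nominal > 0
  xr <- range(obs$x_nominal[pos])
  x0 <- xr[1] / 4    # plotting position for blanks in log coordinates
  grid <- exp(seq(log(xr[1]), log(xr[2]), length.out = 200))
  if (log) {
    graphics::plot(ifelse(pos, obs$x_nominal, x0), pmax(obs$signal, 0.1),
                   log = "xy", col = ifelse(obs$saturated, "red", "grey30"),
                   pch = 1, xlab = "surface density (fluorophores/um^2)",
                   ylab = "signal intensity (counts)", main = main)
  } else {
    graphics::plot(obs$x_nominal, obs$signal, pch = 1,
                   col = ifelse(obs$saturated, "red", "grey30"),
                   xlab = "surface density (fluorophores/um^2)",
                   ylab = "signal intensity (counts)", main = main)
  }
  graphics::lines(grid, predictSignal(grid, m), col = "magenta", lwd = 2)
  graphics::lines(grid, idealSignal(grid, m), col = "darkgreen", lwd = 2,
                  lty = 2)
  graphics::abline(h = autofluorescence(m), col = "grey60", lty = 3)
  graphics::legend("topleft", bty = "n", lwd = c(2, 2, 1),
                   lty = c(1, 2, 3),
                   col = c("magenta", "darkgreen", "grey60"),
                   legend = c("fitted B*x^a + g", "ideal B*x^a",
                              "autofluorescence g"))
  invisible(NULL)
}
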