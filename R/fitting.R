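## Spot-level observations travel as a plain data.frame (one row per spot)
## with the columns of the intensity-table dialect; see readIntensityTable().

.obsColumns <- c("spot_id", "block", "column", "row", "series", "channel",
                 "pmt_gain", "x_nominal", "signal", "saturated")

.validateObservations <- function(obs) {
  if (!is.data.frame(obs))
    .scError("scancal_validation_error", "observations must be a data.frame")
  miss <- setdiff(.obsColumns, names(obs))
  if (length(miss))
    .scError("scancal_format_error",
             paste("observations are missing required column(s):",
                   paste(miss, collapse = ", ")))
  if (any(obs$signal < 0, na.rm = TRUE))
    .scError("scancal_validation_error", "negative signal intensities")
  if (any(obs$x_nominal < 0, na.rm = TRUE))
    .scError("scancal_validation_error", "negative nominal densities")
  invisible(obs)
}

## rows with a defined nominal density (buffer/marker spots have NA and
## never enter a fit), optionally minus saturated spots
.usableObs <- function(obs, excludeSaturated = TRUE, ceiling = 65535) {
  .validateObservations(obs)
  defined <- !is.na(obs$x_nominal)
  sat <- obs$saturated | obs$signal >= ceiling
  keep <- if (excludeSaturated) defined & !sat else defined
  list(obs = obs[keep, , drop = FALSE],
       nExcludedSaturated = if (excludeSaturated)
         sum(defined & sat) else 0L)
}

.relResiduals <- function(par, x, signal) {
  fit <- par[["B"]] * x^par[["a"]] + par[["g"]]
  r <- (signal - fit) / pmax(fit, .Machine$double.xmin)
  r[fit == 0 & signal == 0] <- 0
  r
}

#' Merit function: sum of squared relative residuals
#'
#' The objective minimized during fitting,
#' \deqn{E = \sum_i \left(\frac{SI_i - \widehat{SI}(x_i)}{\widehat{SI}(x_i)}\right)^2,}
#' i.e. least squares weighted by 1/fitted^2. Calibration data span many
#' orders of magnitude in both density and signal, so ordinary least
#' squares would be dominated entirely by the brightest spots; relative
#' residuals weight every decade equally. E is invariant under a common
#' rescaling of all signals together with B and g.
#'
#' @param model a [ScannerModel-class].
#' @param observations spot-level data.frame (see [readIntensityTable()]).
#' @param excludeSaturated drop saturated spots (default TRUE).
#' @param ceiling saturation ceiling used to (re)detect saturation.
#' @return Non-negative scalar E; 0 iff every used residual is 0.
#' @export
meritE <- function(model, observations, excludeSaturated = TRUE,
                   ceiling = 65535) {
  stopifnot(is(model, "ScannerModel"))
  u <- .usableObs(observations, excludeSaturated, ceiling)
  if (nrow(u$obs) == 0L)
    .scError("scancal_insufficient_data",
             "meritE: no usable (non-saturated, density-annotated) observations")
  sum(.relResiduals(modelParams(model), u$obs$x_nominal, u$obs$signal)^2)
}

#' Starting values for the response fit
#'
#' Heuristic initialization: g0 is the median signal of blank spots (x = 0),
#' falling back to the lowest-density spots when no blanks exist; a0 and B0
#' come from the least-squares line of log(SI - g0) against log x over
#' spots clearly above background (SI > 2 g0), exploiting that the response
#' linearizes in log-log coordinates once the offset is removed. Estimates
#' are clamped into the fitting bounds.
#'
#' @inheritParams meritE
#' @param observations spot-level data.frame.
#' @return Named numeric triple c(B, a, g).
#' @export
defaultInitialization <- function(observations, excludeSaturated = TRUE,
                                  ceiling = 65535) {
  u <- .usableObs(observations, excludeSaturated, ceiling)$obs
  if (nrow(u) < 4L)
    .scError("scancal_insufficient_data",
             "defaultInitialization: need at least 4 usable observations")
  blanks <- u$x_nominal == 0
  g0 <- if (any(blanks)) {
    stats::median(u$signal[blanks])
  } else {
    xmin <- min(u$x_nominal)
    stats::median(u$signal[u$x_nominal == xmin])
  }
  above <- u$x_nominal > 0 & u$signal > 2 * g0 & u$signal > 0
  if (!any(above))
    .scError("scancal_all_background", paste(
      "defaultInitialization: no spot rises above twice the background",
      "estimate; the data set lies entirely below the autofluorescence floor"))
  lx <- log(u$x_nominal[above])
  ly <- log(u$signal[above] - g0)
  if (length(unique(lx)) < 2L)
    .scError("scancal_insufficient_data",
             "defaultInitialization: need >= 2 distinct densities above background")
  co <- stats::coef(stats::lm(ly ~ lx))
  a0 <- min(max(unname(co[2]), 0.1), 2)
  B0 <- exp(unname(co[1]))
  if (!is.finite(B0) || B0 <= 0) B0 <- 1
  c(B = B0, a = a0, g = max(g0, 0))
}

.fitOnce <- function(start, x, signal, lower, upper) {
  out <- minpack.lm::nls.lm(
    par = as.list(start),
    lower = lower, upper = upper,
    fn = function(par) .relResiduals(par, x, signal),
    control = minpack.lm::nls.lm.control(
      ftol = 1e-10, ptol = 1e-8, maxfev = 10000, maxiter = 1000))
  par <- unlist(out$par)
  list(par = par, merit = sum(.relResiduals(par, x, signal)^2),
       converged = out$info %in% 1:4, message = out$message)
}

#' Fit the scanner response model to spot-level observations
#'
#' Estimates (B, a, g) by minimizing the relative least-squares merit
#' [meritE()] with the bounded Levenberg-Marquardt minimizer of
#' \pkg{minpack.lm}. Starting values come from [defaultInitialization()];
#' to guard against local minima a 5-point multi-start perturbs the initial
#' curvature by factors 0.8-1.2, the lowest final merit wins, and ties go
#' to the smallest a. Saturated spots (signal at or above `ceiling`) are
#' excluded by default; buffer and marker spots (undefined nominal density)
#' never enter the fit; blank spots enter with x = 0 and inform g.
#'
#' @param observations spot-level data.frame (see [readIntensityTable()]).
#' @param init optional named triple c(B, a, g) of starting values.
#' @param lower,upper named parameter bounds; defaults B > 0, a in
#'   [0.1, 2], g >= 0.
#' @param excludeSaturated drop saturated spots (default TRUE).
#' @param ceiling saturation ceiling in counts (default 65535).
#' @param seriesMeans fit per-series mean signals instead of spot-level
#'   data (default FALSE).
#' @param multiStart use the 5-point curvature multi-start (default TRUE).
#' @return A [FitResult-class].
#' @examples
#' layout <- makeSlideLayout(replicatesPerColumn = 4)
#' cfg <- SimulationConfig(ScannerModel(106, 0.95, 11.90, "Cy3", 100),
#'                         noiseCV = 0, seed = 1)
#' fit <- fitResponse(simulateScan(layout, cfg))
#' modelParams(fit)
#' @export
fitResponse <- function(observations, init = NULL,
                        lower = c(B = 1e-9, a = 0.1, g = 0),
                        upper = c(B = Inf, a = 2, g = Inf),
                        excludeSaturated = TRUE, ceiling = 65535,
                        seriesMeans = FALSE, multiStart = TRUE) {
  u <- .usableObs(observations, excludeSaturated, ceiling)
  dat <- u$obs
  if (seriesMeans && nrow(dat)) {
    agg <- stats::aggregate(signal ~ series + x_nominal, data = dat,
                            FUN = mean)
    dat <- data.frame(x_nominal = agg$x_nominal, signal = agg$signal)
  }
  # canonical row order: only (x, signal) enter the objective, so sorting
  # makes the optimizer's floating-point arithmetic independent of the
  # order observations arrived in
  dat <- dat[order(dat$x_nominal, dat$signal), , drop = FALSE]
  nz <- unique(dat$x_nominal[dat$x_nominal > 0])
  if (nrow(dat) < 4L || length(nz) < 2L)
    .scError("scancal_insufficient_data", paste(
      "fitResponse: need at least 4 usable observations spanning",
      ">= 2 distinct nonzero densities"))
  if (is.null(init))
    init <- defaultInitialization(observations, excludeSaturated, ceiling)
  init <- pmin(pmax(init[c("B", "a", "g")], lower), upper)
  scales <- if (multiStart) c(0.8, 0.9, 1.0, 1.1, 1.2) else 1.0
  best <- NULL
  for (s in scales) {
    start <- init
    start[["a"]] <- min(max(init[["a"]] * s, lower[["a"]]), upper[["a"]])
    cand <- .fitOnce(start, dat$x_nominal, dat$signal, lower, upper)
    if (is.null(best) || cand$merit < best$merit ||
        (cand$merit == best$merit && cand$par[["a"]] < best$par[["a"]]))
      best <- cand
  }
  ch <- unique(observations$channel); gn <- unique(observations$pmt_gain)
  model <- ScannerModel(best$par[["B"]], best$par[["a"]], best$par[["g"]],
                        channel = if (length(ch) == 1L) ch else NA_character_,
                        pmtGain = if (length(gn) == 1L) gn else NA_real_)
  new("FitResult", model = model, merit = best$merit,
      nUsed = nrow(dat), nExcludedSaturated = as.integer(u$nExcludedSaturated),
      residuals = .relResiduals(best$par, dat$x_nominal, dat$signal),
      converged = best$converged, message = best$message)
}

#' Bootstrap confidence intervals for the fitted parameters
#'
#' Resamples spots with replacement within each series (stratified, so the
#' dilution design is preserved), refits each resample starting from the
#' point estimate, and reports percentile intervals. Fully reproducible
#' under a fixed seed. When fewer than half the refits succeed the result
#' carries an unstable-fit flag.
#'
#' @inheritParams fitResponse
#' @param nBoot number of bootstrap resamples; 0 returns the plain
#'   [fitResponse()] result without intervals.
#' @param seed integer RNG seed (required when nBoot > 0).
#' @param level interval level (default 0.95).
#' @param ... passed on to [fitResponse()].
#' @return A [FitResult-class] with `bootstrapCI` filled in.
#' @export
bootstrapFit <- function(observations, nBoot = 200, seed, level = 0.95, ...) {
  point <- fitResponse(observations, ...)
  if (nBoot == 0L) return(point)
  if (missing(seed))
    .scError("scancal_validation_error",
             "bootstrapFit: 'seed' is mandatory when nBoot > 0")
  start <- modelParams(point)
  groups <- split(seq_len(nrow(observations)), observations$series)
  est <- withr::with_seed(as.integer(seed), {
    reps <- vector("list", nBoot)
    for (b in seq_len(nBoot)) {
      idx <- unlist(lapply(groups, function(ii)
        ii[sample.int(length(ii), replace = TRUE)]), use.names = FALSE)
      reps[[b]] <- tryCatch({
        fb <- fitResponse(observations[idx, , drop = FALSE], init = start,
                          multiStart = FALSE, ...)
        if (fb@converged) modelParams(fb) else NULL
      }, scancal_error = function(e) NULL)
    }
    reps
  })
  ok <- !vapply(est, is.null, logical(1))
  stable <- mean(ok) >= 0.5
  if (!stable)
    warning("bootstrapFit: unstable fit, under 50% of bootstrap refits succeeded")
  if (!any(ok))
    .scError("scancal_insufficient_data",
             "bootstrapFit: every bootstrap refit failed")
  mat <- do.call(rbind, est[ok])
  alpha <- (1 - level) / 2
  ci <- t(apply(mat, 2, stats::quantile, probs = c(alpha, 1 - alpha),
                names = FALSE, type = 7))
  dimnames(ci) <- list(c("B", "a", "g"), c("lower", "upper"))
  initialize(point, bootstrapCI = ci, bootstrapLevel = level,
             nBoot = as.integer(nBoot), bootstrapStable = stable)
}
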