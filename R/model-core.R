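#' Forward scanner response
#'
#' Evaluates the calibration model \eqn{SI = B x^a + g} at surface density
#' `x`. At `x = 0` the power term vanishes and the prediction equals the
#' autofluorescence offset `g`; the response is strictly increasing in `x`.
#'
#' @param x numeric vector of surface densities (fluorophores/um^2), >= 0.
#' @param model a [ScannerModel-class].
#' @return Numeric vector of predicted signal intensities (counts).
#' @examples
#' m <- ScannerModel(106, 0.95, 11.90)
#' predictSignal(c(0, 1), m)   # 11.90, 117.90
#' @seealso [idealSignal()], [invertSignal()]
#' @export
predictSignal <- function(x, model) {
  stopifnot(is(model, "ScannerModel"))
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0))
    .scError("scancal_domain_error",
             "predictSignal: surface density 'x' must be >= 0 and non-missing")
  model@B * x^model@a + model@g
}

#' Background-free scanner response
#'
#' The g-free response \eqn{B x^a}: what the detector would report without
#' the slide's buffer autofluorescence. Equals
#' `predictSignal(x, model) - autofluorescence(model)` for all x.
#'
#' @inheritParams predictSignal
#' @return Numeric vector of signal intensities (counts); 0 at x = 0.
#' @export
idealSignal <- function(x, model) {
  stopifnot(is(model, "ScannerModel"))
  x <- as.numeric(x)
  if (any(is.na(x)) || any(x < 0))
    .scError("scancal_domain_error",
             "idealSignal: surface density 'x' must be >= 0 and non-missing")
  model@B * x^model@a
}

#' Invert the response model: signal to surface density
#'
#' Converts measured intensities back to fluorophore surface densities,
#' \eqn{x = ((SI - g)/B)^{1/a}}. Only defined above the autofluorescence
#' floor: a signal at or below `g` carries no information about dye
#' quantity, so no extrapolation below background is attempted.
#'
#' @param SI numeric vector of signal intensities (counts); each must
#'   exceed `autofluorescence(model)`.
#' @param model a [ScannerModel-class].
#' @return Numeric vector of surface densities (fluorophores/um^2).
#' @examples
#' m <- ScannerModel(106, 0.95, 11.90)
#' invertSignal(predictSignal(2.5, m), m)   # 2.5
#' @export
invertSignal <- function(SI, model) {
  stopifnot(is(model, "ScannerModel"))
  SI <- as.numeric(SI)
  if (any(is.na(SI)) || any(SI <= model@g))
    .scError("scancal_below_background", paste0(
      "invertSignal: signal at or below the autofluorescence offset g = ",
      format(model@g), "; surface density is not identifiable"))
  ((SI - model@g) / model@B)^(1 / model@a)
}

#' Clip signals at the detector ceiling
#'
#' Applies hard saturation, `min(SI, ceiling)`; idempotent. 16-bit scanners
#' clip at 65535 counts.
#'
#' @param SI numeric vector of signal intensities (counts).
#' @param ceiling numeric(1) saturation ceiling, > 0 (default 65535).
#' @return `SI` with values above `ceiling` replaced by `ceiling`.
#' @export
applySaturation <- function(SI, ceiling = 65535) {
  if (length(ceiling) != 1L || !is.finite(ceiling) || ceiling <= 0)
    .scError("scancal_domain_error",
             "applySaturation: 'ceiling' must be a single value > 0")
  pmin(as.numeric(SI), ceiling)
}
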