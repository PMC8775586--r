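#' @import methods
NULL

#' SpectralCurve: a sampled relative spectral function
#'
#' Holds a relative sensitivity or transmittance curve sampled on a strictly
#' increasing wavelength grid. Values are unitless relative amplitudes; curves
#' produced by the spectral model are normalized to peak 1.
#'
#' @slot wavelengths numeric, strictly increasing wavelength grid (nm).
#' @slot values numeric, non-negative relative amplitudes, same length.
#' @export
setClass("SpectralCurve",
  representation(wavelengths = "numeric", values = "numeric"),
  validity = function(object) {
    msg <- NULL
    if (length(object@wavelengths) < 2L)
      msg <- c(msg, "need at least 2 wavelength samples")
    if (length(object@wavelengths) != length(object@values))
      msg <- c(msg, "wavelengths and values differ in length")
    if (any(diff(object@wavelengths) <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
    if (any(object@values < 0))
      msg <- c(msg, "values must be non-negative")
    if (is.null(msg)) TRUE else msg
  }
)

#' ChannelBand: peak wavelength and half-width of a sensitivity band
#'
#' @slot centerNm wavelength of the curve maximum (nm).
#' @slot hwhmNm half of the distance between the two half-maximum crossings
#'   (nm); one-sided when a crossing is missing on one flank.
#' @slot oneSided "none" for a regular two-sided band, else which flank had
#'   no half-maximum crossing ("left"/"right").
#' @export
setClass("ChannelBand",
  representation(centerNm = "numeric", hwhmNm = "numeric", oneSided = "character"),
  prototype(oneSided = "none"),
  validity = function(object) {
    msg <- NULL
    if (object@centerNm <= 0) msg <- c(msg, "centerNm must be positive")
    if (object@hwhmNm <= 0) msg <- c(msg, "hwhmNm must be positive")
    if (!object@oneSided %in% c("none", "left", "right"))
      msg <- c(msg, "oneSided must be none/left/right")
    if (is.null(msg)) TRUE else msg
  }
)

#' EyeGeometry: optical and cellular geometry of an eye
#'
#' Parameters for the photon-budget and angular-sampling estimates. Defaults
#' (see \code{\link{mouseEyeGeometry}}) describe the mouse eye under ample
#' daylight.
#'
#' @slot illuminanceFlux photon flux at the cornea (photons/um^2/s).
#' @slot pupilDiameterMm pupil diameter (mm).
#' @slot eyeDiameterMm eye diameter (mm).
#' @slot transmittance fractional transmittance of the eye optics (0-1).
#' @slot photoreceptorAreaUm2 light-collection area of one photoreceptor (um^2).
#' @slot coneDensityPerMm2 cone density (cells/mm^2).
#' @slot rodDensityPerMm2 rod density (cells/mm^2).
#' @export
setClass("EyeGeometry",
  representation(
    illuminanceFlux = "numeric", pupilDiameterMm = "numeric",
    eyeDiameterMm = "numeric", transmittance = "numeric",
    photoreceptorAreaUm2 = "numeric", coneDensityPerMm2 = "numeric",
    rodDensityPerMm2 = "numeric"
  ),
  validity = function(object) {
    v <- c(object@illuminanceFlux, object@pupilDiameterMm, object@eyeDiameterMm,
           object@photoreceptorAreaUm2, object@coneDensityPerMm2,
           object@rodDensityPerMm2)
    msg <- NULL
    if (any(v <= 0)) msg <- c(msg, "all geometry fields must be positive")
    if (object@transmittance < 0 || object@transmittance > 1)
      msg <- c(msg, "transmittance must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
  }
)

#' SceneMetadata: per-scene acquisition metadata
#'
#' @slot stem scene identifier (file stem).
#' @slot elevation camera elevation category: "up", "down" or "horizontal".
#' @slot exposureS exposure length (s).
#' @slot ndOd optical density of the green-channel neutral-density filter.
#' @slot weather,distance,objects free-text tags.
#' @export
setClass("SceneMetadata",
  representation(
    stem = "character", elevation = "character", exposureS = "numeric",
    ndOd = "numeric", weather = "character", distance = "character",
    objects = "character"
  ),
  prototype(weather = "", distance = "", objects = ""),
  validity = function(object) {
    msg <- NULL
    if (!object@elevation %in% c("up", "down", "horizontal"))
      msg <- c(msg, "elevation must be up/down/horizontal")
    if (object@exposureS <= 0) msg <- c(msg, "exposureS must be positive")
    if (object@ndOd < 0) msg <- c(msg, "ndOd must be non-negative")
    if (is.null(msg)) TRUE else msg
  }
)

#' ScenePair: a registered two-channel scene
#'
#' Same-shape UV and green images with a shared validity mask (pixels that
#' fell outside the registration warp are invalid), angular pixel pitch and
#' acquisition metadata. The unit that every image statistic consumes.
#'
#' @slot uv,green numeric matrices of equal shape.
#' @slot valid logical matrix marking pixels valid in both channels.
#' @slot pixelPitchDeg angular pixel pitch (degrees/pixel).
#' @slot metadata a \linkS4class{SceneMetadata}.
#' @slot normalized whether both channels have been min-max normalized to
#'   [0, 1].
#' @export
setClass("ScenePair",
  representation(
    uv = "matrix", green = "matrix", valid = "matrix",
    pixelPitchDeg = "numeric", metadata = "SceneMetadata",
    normalized = "logical"
  ),
  prototype(normalized = FALSE, pixelPitchDeg = 0.006),
  validity = function(object) {
    msg <- NULL
    if (!identical(dim(object@uv), dim(object@green)))
      msg <- c(msg, "uv and green must have the same shape")
    if (!identical(dim(object@uv), dim(object@valid)))
      msg <- c(msg, "validity mask shape mismatch")
    if (object@pixelPitchDeg <= 0) msg <- c(msg, "pixelPitchDeg must be positive")
    if (isTRUE(object@normalized)) {
      for (ch in c("uv", "green")) {
        v <- slot(object, ch)[object@valid]
        if (length(v) && (abs(min(v)) > 1e-9 || abs(max(v) - 1) > 1e-9))
          msg <- c(msg, sprintf("channel %s not normalized to [0,1]", ch))
      }
    }
    if (is.null(msg)) TRUE else msg
  }
)

#' WeibullFit: a fitted two-parameter Weibull contrast distribution
#'
#' The density is reported in two equivalent parameterizations. The canonical
#' scale-shape form has density
#' \deqn{f(x) = (\gamma/\beta)(x/\beta)^{\gamma-1} e^{-(x/\beta)^\gamma},}
#' where \code{betaScale} is the width (larger = wider distribution) and
#' \code{gammaShape} the peakedness (smaller = heavier tail). The rate form
#' \eqn{w(x) = \beta' \gamma x^{\gamma-1} e^{-\beta' x^\gamma}} is available
#' as \code{printedRateBeta} with \eqn{\beta' = \beta^{-\gamma}}.
#'
#' @slot betaScale canonical scale parameter (> 0).
#' @slot gammaShape shape parameter (> 0).
#' @slot nSamples number of samples used in the fit.
#' @slot nDropped number of non-positive samples excluded before fitting.
#' @slot logLik maximized log-likelihood.
#' @export
setClass("WeibullFit",
  representation(
    betaScale = "numeric", gammaShape = "numeric",
    nSamples = "integer", nDropped = "integer", logLik = "numeric"
  ),
  validity = function(object) {
    msg <- NULL
    if (object@betaScale <= 0) msg <- c(msg, "betaScale must be positive")
    if (object@gammaShape <= 0) msg <- c(msg, "gammaShape must be positive")
    if (is.null(msg)) TRUE else msg
  }
)

#' PowerLawFit: a b/omega^a fit to a power-spectrum slice
#'
#' Ordinary least squares of log10 power on log10 spatial frequency; the
#' slope is reported as the positive exponent \code{a} of \eqn{b/\omega^a}
#' and the intercept as the raw power \code{b} extrapolated to 1 cycle/pixel.
#'
#' @slot slopeA exponent a (positive for red spectra).
#' @slot interceptB power at 1 cycle/pixel (raw power units).
#' @slot fitRange frequency interval used (cycles/pixel).
#' @slot rSquared coefficient of determination of the log-log regression.
#' @slot nDropped zero-power bins excluded.
#' @export
setClass("PowerLawFit",
  representation(
    slopeA = "numeric", interceptB = "numeric", fitRange = "numeric",
    rSquared = "numeric", nDropped = "integer"
  ),
  validity = function(object) {
    msg <- NULL
    if (object@interceptB <= 0) msg <- c(msg, "interceptB must be positive")
    if (object@rSquared < 0 || object@rSquared > 1)
      msg <- c(msg, "rSquared must lie in [0,1]")
    if (any(object@fitRange <= 0)) msg <- c(msg, "fitRange must exclude DC")
    if (is.null(msg)) TRUE else msg
  }
)
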