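#' @include AllClasses.R
NULL

#' Accessors for spectral curves and fit objects
#'
#' @param object a package object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavelengths", function(object) standardGeneric("wavelengths"))
#' @rdname accessors
#' @export
setGeneric("curveValues", function(object) standardGeneric("curveValues"))
#' @rdname accessors
#' @export
setGeneric("centerNm", function(object) standardGeneric("centerNm"))
#' @rdname accessors
#' @export
setGeneric("hwhmNm", function(object) standardGeneric("hwhmNm"))
#' @rdname accessors
#' @export
setGeneric("betaScale", function(object) standardGeneric("betaScale"))
#' @rdname accessors
#' @export
setGeneric("gammaShape", function(object) standardGeneric("gammaShape"))
#' @rdname accessors
#' @export
setGeneric("printedRateBeta", function(object) standardGeneric("printedRateBeta"))
#' @rdname accessors
#' @export
setGeneric("slopeA", function(object) standardGeneric("slopeA"))
#' @rdname accessors
#' @export
setGeneric("interceptB", function(object) standardGeneric("interceptB"))
#' @rdname accessors
#' @export
setGeneric("uvChannel", function(object) standardGeneric("uvChannel"))
#' @rdname accessors
#' @export
setGeneric("greenChannel", function(object) standardGeneric("greenChannel"))
#' @rdname accessors
#' @export
setGeneric("validMask", function(object) standardGeneric("validMask"))
#' @rdname accessors
#' @export
setGeneric("pixelPitchDeg", function(object) standardGeneric("pixelPitchDeg"))
#' @rdname accessors
#' @export
setGeneric("sceneMetadata", function(object) standardGeneric("sceneMetadata"))
#' @rdname accessors
#' @export
setGeneric("isNormalized", function(object) standardGeneric("isNormalized"))

#' @rdname accessors
#' @export
setMethod("wavelengths", "SpectralCurve", function(object) object@wavelengths)
#' @rdname accessors
#' @export
setMethod("curveValues", "SpectralCurve", function(object) object@values)
#' @rdname accessors
#' @export
setMethod("centerNm", "ChannelBand", function(object) object@centerNm)
#' @rdname accessors
#' @export
setMethod("hwhmNm", "ChannelBand", function(object) object@hwhmNm)
#' @rdname accessors
#' @export
setMethod("betaScale", "WeibullFit", function(object) object@betaScale)
#' @rdname accessors
#' @export
setMethod("gammaShape", "WeibullFit", function(object) object@gammaShape)
#' @rdname accessors
#' @export
setMethod("printedRateBeta", "WeibullFit",
          function(object) object@betaScale^(-object@gammaShape))
#' @rdname accessors
#' @export
setMethod("slopeA", "PowerLawFit", function(object) object@slopeA)
#' @rdname accessors
#' @export
setMethod("interceptB", "PowerLawFit", function(object) object@interceptB)
#' @rdname accessors
#' @export
setMethod("uvChannel", "ScenePair", function(object) object@uv)
#' @rdname accessors
#' @export
setMethod("greenChannel", "ScenePair", function(object) object@green)
#' @rdname accessors
#' @export
setMethod("validMask", "ScenePair", function(object) object@valid)
#' @rdname accessors
#' @export
setMethod("pixelPitchDeg", "ScenePair", function(object) object@pixelPitchDeg)
#' @rdname accessors
#' @export
setMethod("sceneMetadata", "ScenePair", function(object) object@metadata)
#' @rdname accessors
#' @export
setMethod("isNormalized", "ScenePair", function(object) object@normalized)

setMethod("show", "SpectralCurve", function(object) {
  cat(sprintf("SpectralCurve: %d samples, %.0f-%.0f nm, peak %.3g at %.1f nm\n",
              length(object@wavelengths), min(object@wavelengths),
              max(object@wavelengths), max(object@values),
              object@wavelengths[which.max(object@values)]))
})

setMethod("show", "ChannelBand", function(object) {
  flag <- if (object@oneSided == "none") "" else
    sprintf(" (one-sided: %s flank)", object@oneSided)
  cat(sprintf("ChannelBand: %.1f +/- %.1f nm (center +/- HWHM)%s\n",
              object@centerNm, object@hwhmNm, flag))
})

setMethod("show", "WeibullFit", function(object) {
  cat(sprintf(
    "WeibullFit: beta (scale) = %.4g, gamma (shape) = %.4g, n = %d (%d dropped), logLik = %.2f\n",
    object@betaScale, object@gammaShape, object@nSamples, object@nDropped,
    object@logLik))
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: b/omega^a with a = %.3f, log10(b) = %.3f, R^2 = %.3f, range %.4g-%.4g cyc/px\n",
    object@slopeA, log10(object@interceptB), object@rSquared,
    object@fitRange[1], object@fitRange[2]))
})

setMethod("show", "ScenePair", function(object) {
  cat(sprintf(
    "ScenePair '%s' (%s): %d x %d px, %.3f deg/px, %.1f%% valid, %s\n",
    object@metadata@stem, object@metadata@elevation,
    nrow(object@uv), ncol(object@uv), object@pixelPitchDeg,
    100 * mean(object@valid),
    if (object@normalized) "normalized" else "raw"))
})

setMethod("show", "EyeGeometry", function(object) {
  cat(sprintf(
    "EyeGeometry: pupil %.2f mm, eye %.2f mm, T = %.2f, flux %.3g photons/um^2/s\n",
    object@pupilDiameterMm, object@eyeDiameterMm, object@transmittance,
    object@illuminanceFlux))
})
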