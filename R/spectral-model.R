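#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a spectral curve
#'
#' @param wavelengths strictly increasing wavelength grid (nm).
#' @param values non-negative relative amplitudes.
#' @param normalize rescale so the maximum value is 1.
#' @return a \linkS4class{SpectralCurve}.
#' @export
spectralCurve <- function(wavelengths, values, normalize = FALSE) {
  if (normalize) {
    if (max(values) <= 0) stop("cannot normalize an all-zero curve")
    values <- values / max(values)
  }
  new("SpectralCurve", wavelengths = as.numeric(wavelengths),
      values = as.numeric(values))
}

normalizeCurve <- function(curve) {
  spectralCurve(curve@wavelengths, curve@values, normalize = TRUE)
}

#' A1 visual pigment absorbance template
#'
#' Alpha-band absorbance nomogram for vitamin-A1 pigments, parameterized by
#' the wavelength of peak absorbance. In the normalized wavelength
#' \eqn{x = \lambda_{max}/\lambda} the template is
#' \deqn{S(x) = 1 / (e^{A(a-x)} + e^{B(b-x)} + e^{C(c-x)} + D)}
#' with A = 69.7, B = 28, C = -14.9, D = 0.674, b = 0.922, c = 1.104 and
#' \eqn{a = 0.8795 + 0.0459\, e^{-(\lambda_{max}-300)^2/11940}}. Mouse
#' S- and M-opsins are modelled with peaks at 360 and 508 nm.
#'
#' @param lambdaMaxNm wavelength of peak absorbance (nm); must lie inside
#'   the grid span.
#' @param grid strictly increasing evaluation wavelengths (nm).
#' @return a \linkS4class{SpectralCurve} normalized to peak 1.
#' @examples
#' sCone <- pigmentTemplate(360, 300:700)
#' mCone <- pigmentTemplate(508, 300:700)
#' @export
pigmentTemplate <- function(lambdaMaxNm, grid) {
  grid <- as.numeric(grid)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (lambdaMaxNm < min(grid) || lambdaMaxNm > max(grid))
    stop("lambdaMaxNm lies outside the wavelength grid")
  x <- lambdaMaxNm / grid
  A <- 69.7; B <- 28; C <- -14.9; D <- 0.674
  b <- 0.922; cc <- 1.104
  a <- 0.8795 + 0.0459 * exp(-(lambdaMaxNm - 300)^2 / 11940)
  v <- 1 / (exp(A * (a - x)) + exp(B * (b - x)) + exp(C * (cc - x)) + D)
  spectralCurve(grid, v, normalize = TRUE)
}

# Interpolate two curves onto the union grid restricted to the common
# wavelength support.
commonGrid <- function(c1, c2) {
  lo <- max(min(c1@wavelengths), min(c2@wavelengths))
  hi <- min(max(c1@wavelengths), max(c2@wavelengths))
  if (lo >= hi) stop("spectral curves have disjoint wavelength supports")
  g <- sort(unique(c(c1@wavelengths, c2@wavelengths)))
  g <- g[g >= lo & g <= hi]
  if (length(g) < 2L) stop("common wavelength support is degenerate")
  list(grid = g,
       v1 = stats::approx(c1@wavelengths, c1@values, g)$y,
       v2 = stats::approx(c2@wavelengths, c2@values, g)$y)
}

#' Correct a sensitivity curve with a transmittance spectrum
#'
#' Pointwise product of the two curves on the union grid restricted to their
#' common support (linear interpolation), renormalized to peak 1. Models the
#' spectral filtering of photoreceptor sensitivity by the ocular media, which
#' absorb short wavelengths more than long ones and so shift the effective
#' peak a few nanometres to the red.
#'
#' @param sensitivity,transmittance \linkS4class{SpectralCurve} objects with
#'   overlapping support.
#' @return a \linkS4class{SpectralCurve} normalized to peak 1.
#' @export
applyTransmittance <- function(sensitivity, transmittance) {
  cg <- commonGrid(sensitivity, transmittance)
  spectralCurve(cg$grid, cg$v1 * cg$v2, normalize = TRUE)
}

#' Effective sensitivity of a camera channel
#'
#' Composes the relative transmission of the channel optics with the quantum
#' efficiency of the sensor, as a pointwise spectral product (the physically
#' correct composition of transmission and quantum efficiency), normalized to
#' peak 1.
#'
#' @param opticsTransmission,sensorQe \linkS4class{SpectralCurve} objects.
#' @return a \linkS4class{SpectralCurve}.
#' @export
channelSensitivity <- function(opticsTransmission, sensorQe) {
  applyTransmittance(opticsTransmission, sensorQe)
}

#' Peak wavelength and half-width at half maximum of a curve
#'
#' The center is the wavelength of the maximum (lowest wavelength on a
#' plateau); the HWHM is half the distance between the two half-maximum
#' crossings, located by linear interpolation between samples. When one flank
#' never falls to half maximum, the available one-sided width is reported and
#' flagged.
#'
#' @param curve a \linkS4class{SpectralCurve}.
#' @return a \linkS4class{ChannelBand}.
#' @export
peakAndHwhm <- function(curve) {
  w <- curve@wavelengths
  v <- curve@values / max(curve@values)
  ip <- which.max(v)  # which.max takes the first index on plateaus
  center <- w[ip]
  half <- 0.5
  crossing <- function(idx) {
    # linear interpolation of the half-max crossing between samples idx, idx+1
    w[idx] + (half - v[idx]) * (w[idx + 1] - w[idx]) / (v[idx + 1] - v[idx])
  }
  left <- NA_real_
  if (ip > 1) {
    below <- which(v[seq_len(ip - 1)] < half)
    if (length(below)) left <- crossing(max(below))
  }
  right <- NA_real_
  if (ip < length(v)) {
    below <- which(v[(ip + 1):length(v)] < half)
    if (length(below)) {
      j <- ip + min(below)  # first sample below half on the right flank
      right <- crossing(j - 1)
    }
  }
  if (is.na(left) && is.na(right))
    stop("no half-maximum crossing on either side of the peak")
  if (is.na(left))
    return(new("ChannelBand", centerNm = center, hwhmNm = right - center,
               oneSided = "left"))
  if (is.na(right))
    return(new("ChannelBand", centerNm = center, hwhmNm = center - left,
               oneSided = "right"))
  new("ChannelBand", centerNm = center, hwhmNm = (right - left) / 2,
      oneSided = "none")
}

#' Eye geometry constructors
#'
#' \code{eyeGeometry} builds an \linkS4class{EyeGeometry} from explicit
#' values; \code{mouseEyeGeometry} returns the mouse defaults used for the
#' daylight photon-budget estimate: pupil diameter 0.5 mm, eye diameter 4 mm,
#' ocular transmittance 0.5, photoreceptor collection area 0.5 um^2, cone
#' density 12,400/mm^2, rod density 437,000/mm^2, and corneal photon flux
#' 1e7 photons/um^2/s (the dim end of ample daylight, ~1e3 lux; bright
#' daylight is ~1e9).
#'
#' @param illuminanceFlux photons/um^2/s at the cornea.
#' @param pupilDiameterMm,eyeDiameterMm diameters in mm.
#' @param transmittance fraction of light transmitted by the eye optics.
#' @param photoreceptorAreaUm2 collection area of one photoreceptor (um^2).
#' @param coneDensityPerMm2,rodDensityPerMm2 cell densities (cells/mm^2).
#' @return an \linkS4class{EyeGeometry}.
#' @export
eyeGeometry <- function(illuminanceFlux, pupilDiameterMm, eyeDiameterMm,
                        transmittance, photoreceptorAreaUm2,
                        coneDensityPerMm2, rodDensityPerMm2) {
  new("EyeGeometry", illuminanceFlux = illuminanceFlux,
      pupilDiameterMm = pupilDiameterMm, eyeDiameterMm = eyeDiameterMm,
      transmittance = transmittance,
      photoreceptorAreaUm2 = photoreceptorAreaUm2,
      coneDensityPerMm2 = coneDensityPerMm2,
      rodDensityPerMm2 = rodDensityPerMm2)
}

#' @rdname eyeGeometry
#' @export
mouseEyeGeometry <- function(illuminanceFlux = 1e7) {
  eyeGeometry(illuminanceFlux = illuminanceFlux, pupilDiameterMm = 0.5,
              eyeDiameterMm = 4, transmittance = 0.5,
              photoreceptorAreaUm2 = 0.5, coneDensityPerMm2 = 12400,
              rodDensityPerMm2 = 437000)
}

#' Photon flux on an individual photoreceptor
#'
#' Estimates the photon catch per photoreceptor as
#' \deqn{\Phi \cdot A_{pupil}/A_{retina} \cdot T \cdot A_{photoreceptor},}
#' with \eqn{A_{pupil} = \pi (d_{pupil}/2)^2} and
#' \eqn{A_{retina} = 4\pi (d_{eye}/2)^2 / 2} (the retina internally covers
#' half the eye ball). The area ratio is dimensionless so mm^2 cancel and the
#' result is in photons/photoreceptor/s. Under daylight fluxes of
#' 1e7--1e9 photons/um^2/s the mouse geometry gives on the order of
#' 1e4--1e6 photons/photoreceptor/s.
#'
#' @param geom an \linkS4class{EyeGeometry}.
#' @return photons per photoreceptor per second.
#' @export
photoreceptorPhotonFlux <- function(geom) {
  aPupil <- pi * (geom@pupilDiameterMm / 2)^2
  aRetina <- 4 * pi * (geom@eyeDiameterMm / 2)^2 / 2
  geom@illuminanceFlux * aPupil / aRetina * geom@transmittance *
    geom@photoreceptorAreaUm2
}

#' Angular sampling resolution of a photoreceptor lattice
#'
#' The visual angle subtended by one lattice spacing \eqn{1/\sqrt{\rho}} of a
#' photoreceptor mosaic of density \eqn{\rho}, viewed at the posterior nodal
#' distance \eqn{d_{eye}/2}:
#' \deqn{\theta = \frac{180}{\pi}\,\frac{1/\sqrt{\rho}}{d_{eye}/2}
#'   \;\mathrm{degrees}.}
#' For the mouse cone mosaic (12,400 cells/mm^2, 4 mm eye) this is about
#' 0.26 degrees, i.e. the "pixel size" of photopic mouse vision; for the rod
#' mosaic (437,000 cells/mm^2) about 0.04 degrees.
#'
#' @param densityPerMm2 cell density (cells/mm^2).
#' @param eyeDiameterMm eye diameter (mm).
#' @return sampling resolution in degrees.
#' @export
angularSamplingResolution <- function(densityPerMm2, eyeDiameterMm) {
  if (densityPerMm2 <= 0) stop("density must be positive")
  (180 / pi) * (1 / sqrt(densityPerMm2)) / (eyeDiameterMm / 2)
}

#' Read or write spectral curves as two-column CSV
#'
#' Format: header \code{wavelength_nm,value}, one sample per row; comment
#' lines starting with \code{#} are ignored.
#'
#' @param path CSV file path.
#' @param curve a \linkS4class{SpectralCurve} (for writing).
#' @return \code{readSpectralCurve}: a \linkS4class{SpectralCurve};
#'   \code{writeSpectralCurve}: invisibly, \code{path}.
#' @export
readSpectralCurve <- function(path) {
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("wavelength_nm", "value") %in% names(df)))
    stop("expected columns wavelength_nm,value in ", path)
  spectralCurve(df$wavelength_nm, df$value)
}

#' @rdname readSpectralCurve
#' @export
writeSpectralCurve <- function(curve, path) {
  df <- data.frame(wavelength_nm = curve@wavelengths, value = curve@values)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
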