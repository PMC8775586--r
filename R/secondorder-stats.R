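#' @include utils.R AllClasses.R
NULL

#' 2-D power spectral density
#'
#' \eqn{S(\omega_x,\omega_y) = F \cdot F^*} with F the unnormalized 2-D FFT
#' of the image; returned DC-centred with frequencies in cycles/pixel on
#' (-0.5, 0.5]. The default "as-printed" mode applies no window, detrending
#' or mean subtraction; \code{meanSubtract = TRUE} removes the image mean
#' first (the autocorrelation path). Total power obeys the
#' unnormalized-transform Parseval identity sum(S) = N*M*sum(I^2).
#'
#' @param channel image matrix, both sides >= 8.
#' @param meanSubtract subtract the image mean before transforming.
#' @return list of class "PowerSpectrum2D": \code{power} (matrix),
#'   \code{freqX} (cycles/pixel, columns), \code{freqY} (rows),
#'   \code{meanSubtracted}.
#' @export
powerSpectrum <- function(channel, meanSubtract = FALSE) {
  if (nrow(channel) < 8 || ncol(channel) < 8)
    stop("image sides must be >= 8")
  x <- channel
  if (meanSubtract) x <- x - mean(x)
  f <- stats::fft(x)
  s <- Re(f * Conj(f))
  structure(list(
    power = fftShift2(s),
    freqX = sort(fftFreq(ncol(channel))),
    freqY = sort(fftFreq(nrow(channel))),
    meanSubtracted = meanSubtract
  ), class = "PowerSpectrum2D")
}

#' Central axis slices of a 2-D power spectrum
#'
#' The positive-frequency halves of \eqn{S(\omega_x, 0)} (horizontal) and
#' \eqn{S(0, \omega_y)} (vertical), DC excluded.
#'
#' @param spec a \code{\link{powerSpectrum}}.
#' @return list with data.frames \code{horizontal} and \code{vertical},
#'   columns \code{freq} (cycles/pixel) and \code{power}.
#' @export
axisSlices <- function(spec) {
  iy0 <- which(spec$freqY == 0)
  ix0 <- which(spec$freqX == 0)
  ph <- spec$power[iy0, ]
  pv <- spec$power[, ix0]
  hsel <- spec$freqX > 0
  vsel <- spec$freqY > 0
  list(
    horizontal = data.frame(freq = spec$freqX[hsel], power = ph[hsel]),
    vertical = data.frame(freq = spec$freqY[vsel], power = pv[vsel])
  )
}

#' Log-log power-law fit b/omega^a to a spectrum slice
#'
#' Ordinary least squares of log10(power) on log10(frequency) over all
#' positive-frequency bins with positive power (zero-power bins dropped and
#' counted; each FFT bin has equal weight). The slope is reported as the
#' positive exponent a of \eqn{b/\omega^a} and the intercept as the raw
#' power b extrapolated to 1 cycle/pixel.
#'
#' @param slice data.frame with \code{freq} and \code{power} (one element of
#'   \code{\link{axisSlices}}).
#' @return a \linkS4class{PowerLawFit}.
#' @export
fitPowerLaw <- function(slice) {
  keep <- slice$freq > 0 & slice$power > 0
  dropped <- sum(!keep)
  f <- slice$freq[keep]; p <- slice$power[keep]
  if (length(f) < 8)
    stop("need at least 8 positive-power positive-frequency points")
  lf <- log10(f); lp <- log10(p)
  fit <- stats::lm.fit(cbind(1, lf), lp)
  res <- fit$residuals
  r2 <- 1 - sum(res^2) / sum((lp - mean(lp))^2)
  new("PowerLawFit", slopeA = -fit$coefficients[[2]],
      interceptB = 10^fit$coefficients[[1]],
      fitRange = range(f), rSquared = max(0, min(1, r2)),
      nDropped = as.integer(dropped))
}

#' Spatial autocorrelation map via the Wiener-Khinchin theorem
#'
#' Subtracts the image mean, computes the power spectrum, inverse-transforms
#' it and divides by the zero-lag value, giving circular (periodic)
#' autocorrelation coefficients with R(0, 0) = 1. Offsets are DC-centred
#' pixel displacements.
#'
#' @param channel image matrix, both sides >= 8; must not be constant.
#' @return list of class "AutocorrMap": \code{values} (matrix),
#'   \code{offsetsX} (columns), \code{offsetsY} (rows).
#' @export
autocorrelation <- function(channel) {
  if (nrow(channel) < 8 || ncol(channel) < 8)
    stop("image sides must be >= 8")
  x <- channel - mean(channel)
  if (max(abs(x)) < .Machine$double.eps)
    stop("constant image has no autocorrelation (zero variance)")
  f <- stats::fft(x)
  s <- Re(f * Conj(f))
  r <- Re(stats::fft(s, inverse = TRUE)) / length(s)
  r <- r / r[1, 1]
  nr <- nrow(channel); nc <- ncol(channel)
  intOffsets <- function(n) {
    k <- 0:(n - 1)
    k[k > n / 2] <- k[k > n / 2] - n  # integer analogue of the (-0.5, 0.5] grid
    k
  }
  offY <- intOffsets(nr)
  offX <- intOffsets(nc)
  structure(list(
    values = fftShift2(r),
    offsetsX = sort(offX),
    offsetsY = sort(offY)
  ), class = "AutocorrMap")
}

#' Correlation at a pixel displacement
#'
#' Looks up R(d_h, d_v), the correlation of pixel pairs separated
#' horizontally by \code{dH} columns and vertically by \code{dV} rows.
#' Representative displacements of 50 pixels along each axis summarize the
#' spatial extent of correlations per scene.
#'
#' @param acf an \code{\link{autocorrelation}} map.
#' @param dH,dV integer pixel displacements (horizontal, vertical).
#' @return correlation coefficient.
#' @export
correlationAt <- function(acf, dH, dV) {
  ix <- match(dH, acf$offsetsX)
  iy <- match(dV, acf$offsetsY)
  if (is.na(ix) || is.na(iy))
    stop("offset (", dH, ", ", dV, ") outside the autocorrelation map")
  acf$values[iy, ix]
}
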