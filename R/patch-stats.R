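#' @include utils.R AllClasses.R
NULL

# Binary disk kernel of integer points with dx^2 + dy^2 <= radius^2.
diskKernel <- function(radiusPx) {
  off <- (-radiusPx):radiusPx
  d2 <- outer(off^2, off^2, `+`)
  (d2 <= radiusPx^2) * 1
}

#' Circular-patch statistics map
#'
#' Slides a discrete circular patch (all integer offsets with
#' \eqn{dx^2+dy^2 \le r^2}) over every centre whose full patch lies inside
#' the image and computes one statistic per centre:
#' \describe{
#'   \item{mean, sd}{patch mean and population standard deviation,}
#'   \item{rms_contrast}{RMS contrast \eqn{\sigma/\mu} (sd over mean); a
#'     centre whose mean falls below 1e-6 is marked invalid (NA) and
#'     counted,}
#'   \item{skewness, kurtosis}{third and fourth standardized population
#'     moments (kurtosis is not excess: a Gaussian patch gives ~3),}
#'   \item{entropy}{Shannon entropy in bits of the patch intensity
#'     histogram (64 uniform bins on [0, 1]).}
#' }
#' Moment statistics are computed by FFT convolution of intensity powers
#' with the disk; entropy is evaluated per centre (use \code{stride} to
#' thin the grid when speed matters).
#'
#' @param channel normalized image matrix.
#' @param radiusPx patch radius in pixels (default 30, i.e. a 0.36 degree
#'   patch at 0.006 degrees/pixel).
#' @param statistic one of "mean", "sd", "rms_contrast", "skewness",
#'   "kurtosis", "entropy".
#' @param stride centre-grid step (default 1 = every valid centre).
#' @param entropyBins number of histogram bins for the entropy statistic.
#' @return list of class "PatchStatMap": \code{statistic}, \code{values}
#'   (matrix over the valid centre grid, NA = invalid centre),
#'   \code{radiusPx}, \code{stride}, \code{nInvalid}.
#' @export
circularPatchStats <- function(channel, radiusPx = 30,
                               statistic = c("mean", "sd", "rms_contrast",
                                             "skewness", "kurtosis", "entropy"),
                               stride = 1L, entropyBins = 64L) {
  statistic <- match.arg(statistic)
  r <- as.integer(radiusPx)
  if (nrow(channel) <= 2 * r + 1 || ncol(channel) <= 2 * r + 1)
    stop("image must be strictly larger than the patch diameter")
  disk <- diskKernel(r)
  m <- sum(disk)
  nInvalid <- 0L
  if (statistic == "entropy") {
    off <- which(disk == 1, arr.ind = TRUE) - (r + 1L)  # (dy, dx) offsets
    rows <- seq(r + 1L, nrow(channel) - r, by = stride)
    cols <- seq(r + 1L, ncol(channel) - r, by = stride)
    vals <- matrix(NA_real_, length(rows), length(cols))
    nrc <- nrow(channel)
    lin <- off[, 1] + nrc * off[, 2]  # column-major linear offsets
    for (j in seq_along(cols)) {
      base <- rows + nrc * (cols[j] - 1L)
      for (i in seq_along(rows)) {
        px <- channel[base[i] + lin]
        idx <- pmin(floor(px * entropyBins) + 1L, entropyBins)
        p <- tabulate(idx, nbins = entropyBins) / m
        p <- p[p > 0]
        vals[i, j] <- -sum(p * log2(p))
      }
    }
  } else {
    conv <- function(x) fftConvolve2(x, disk, shape = "valid") / m
    m1 <- conv(channel)
    vals <- switch(statistic,
      mean = m1,
      {
        m2 <- conv(channel^2)
        s2 <- pmax(m2 - m1^2, 0)
        sd <- sqrt(s2)
        switch(statistic,
          sd = sd,
          rms_contrast = {
            bad <- m1 < 1e-6
            nInvalid <- sum(bad)
            out <- sd / m1
            out[bad] <- NA_real_
            out
          },
          skewness = {
            m3 <- conv(channel^3)
            mu3 <- m3 - 3 * m1 * m2 + 2 * m1^3
            out <- mu3 / sd^3
            out[sd == 0] <- 0
            out
          },
          kurtosis = {
            m3 <- conv(channel^3)
            m4 <- conv(channel^4)
            mu4 <- m4 - 4 * m1 * m3 + 6 * m1^2 * m2 - 3 * m1^4
            out <- mu4 / sd^4
            out[sd == 0] <- NA_real_
            out
          })
      })
    if (stride > 1L) {
      vals <- vals[seq(1, nrow(vals), by = stride),
                   seq(1, ncol(vals), by = stride), drop = FALSE]
    }
  }
  structure(list(statistic = statistic, values = vals, radiusPx = r,
                 stride = as.integer(stride), nInvalid = as.integer(nInvalid)),
            class = "PatchStatMap")
}

#' Chromatic contrast map
#'
#' Pointwise difference of the UV and green RMS-contrast maps,
#' \eqn{C(x,y) = C^{UV}_{RMS}(x,y) - C^{Green}_{RMS}(x,y)}, on the
#' intersection of valid centres. Positive values mark locations with more
#' local contrast in UV than in green; swapping the channels negates the
#' map.
#'
#' @param uvMap,greenMap "PatchStatMap" objects with statistic
#'   "rms_contrast" on the same centre grid.
#' @return list of class "ChromaticContrastMap" with \code{values},
#'   \code{radiusPx}.
#' @export
chromaticContrast <- function(uvMap, greenMap) {
  if (uvMap$statistic != "rms_contrast" || greenMap$statistic != "rms_contrast")
    stop("both maps must be rms_contrast maps")
  if (!identical(dim(uvMap$values), dim(greenMap$values)) ||
      uvMap$radiusPx != greenMap$radiusPx || uvMap$stride != greenMap$stride)
    stop("patch-map grids do not match")
  structure(list(values = uvMap$values - greenMap$values,
                 radiusPx = uvMap$radiusPx),
            class = "ChromaticContrastMap")
}

#' Two-sided Weibull fit of a chromatic contrast distribution
#'
#' Fits the two-parameter Weibull distribution separately to the magnitudes
#' of the negative side (C < 0, locations greener in contrast) and the
#' positive side (C > 0, locations more UV-contrasted); exact zeros are
#' excluded. An asymmetry between the two side fits is the signature of one
#' channel dominating the local contrast.
#'
#' @param cmap a \code{\link{chromaticContrast}} map.
#' @param minSide minimum samples required per side (default 20).
#' @return list with \code{left} and \code{right} \linkS4class{WeibullFit}s
#'   (NULL with a flag when a side is too small), \code{nLeft},
#'   \code{nRight}, \code{nZero}, \code{flag} ("ok", "left_absent",
#'   "right_absent").
#' @export
fitChromaticWeibull <- function(cmap, minSide = 20L) {
  v <- as.vector(cmap$values)
  v <- v[!is.na(v)]
  neg <- -v[v < 0]
  pos <- v[v > 0]
  nZero <- sum(v == 0)
  left <- if (length(neg) >= minSide) fitWeibull(neg) else NULL
  right <- if (length(pos) >= minSide) fitWeibull(pos) else NULL
  flag <- if (is.null(left) && is.null(right)) "both_absent"
          else if (is.null(left)) "left_absent"
          else if (is.null(right)) "right_absent" else "ok"
  list(left = left, right = right, nLeft = length(neg),
       nRight = length(pos), nZero = nZero, flag = flag)
}
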