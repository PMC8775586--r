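#' @include utils.R AllClasses.R
NULL

#' Intensity histogram of a normalized channel
#'
#' 100 bins of width 0.01 on [0, 1]; bins are left-closed except the last,
#' which is closed on both sides so an intensity of exactly 1 is counted.
#' Probabilities are fractions of valid pixels and sum to 1.
#'
#' @param channel normalized image matrix (values in [0, 1], NAs allowed).
#' @param validityMask optional logical matrix; NA pixels are always
#'   excluded.
#' @return list with \code{binEdges} (length 101) and \code{probabilities}
#'   (length 100).
#' @export
intensityHistogram <- function(channel, validityMask = NULL) {
  v <- as.vector(channel)
  if (!is.null(validityMask)) v <- v[as.vector(validityMask)]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no valid pixels")
  if (min(v) < 0 || max(v) > 1)
    stop("channel is not normalized to [0, 1]")
  idx <- pmin(floor(v / 0.01) + 1L, 100L)
  counts <- tabulate(idx, nbins = 100L)
  list(binEdges = seq(0, 1, by = 0.01), probabilities = counts / length(v))
}

#' Laplacian-of-Gaussian kernel
#'
#' Centre-surround local-contrast operator
#' \deqn{LoG(x,y) = \frac{1}{\pi\sigma^4}\left(1 -
#'   \frac{x^2+y^2}{2\sigma^2}\right) e^{-(x^2+y^2)/2\sigma^2},}
#' sampled at integer offsets over [-3 sigma, 3 sigma] and mean-subtracted so
#' the discrete kernel sums exactly to zero (finite sampling of the
#' continuous kernel does not); a zero-sum kernel maps constant and affine
#' images exactly to zero contrast.
#'
#' @param sigmaPx standard deviation in pixels (>= 1).
#' @return list of class "LoGKernel" with \code{sigma}, \code{offsets},
#'   \code{weights} (zero-sum) and \code{rawWeights} (as sampled).
#' @export
logKernel <- function(sigmaPx) {
  if (sigmaPx < 1) stop("sigmaPx must be >= 1")
  r <- floor(3 * sigmaPx)
  off <- (-r):r
  d2 <- outer(off^2, off^2, `+`)
  raw <- (1 / (pi * sigmaPx^4)) * (1 - d2 / (2 * sigmaPx^2)) *
    exp(-d2 / (2 * sigmaPx^2))
  structure(list(sigma = sigmaPx, offsets = off,
                 weights = raw - mean(raw), rawWeights = raw),
            class = "LoGKernel")
}

#' Local contrast map
#'
#' Convolves a normalized channel with a Laplacian-of-Gaussian kernel using
#' valid-region convolution (no padding), so no synthetic edge contrast
#' enters the contrast distributions. The output shrinks by the kernel
#' support minus one per dimension.
#'
#' @param channel normalized image matrix (no NAs inside the used region).
#' @param kernel a \code{\link{logKernel}}.
#' @return contrast map matrix.
#' @export
localContrastMap <- function(channel, kernel) {
  k <- kernel$weights
  if (nrow(channel) <= nrow(k) || ncol(channel) <= ncol(k))
    stop("image must be larger than the kernel support")
  fftConvolve2(channel, k, shape = "valid")
}

#' Maximum-likelihood fit of the two-parameter Weibull distribution
#'
#' Profile likelihood over the shape: for fixed shape g the conditional MLE
#' of the canonical scale is \eqn{\hat\beta(g) = (\mathrm{mean}(x^g))^{1/g}}
#' in closed form, and the profile log-likelihood is maximized over log(g) by
#' golden-section search. Non-positive samples (structural zeros of a LoG map
#' on flat regions) are dropped and counted.
#'
#' @param samples numeric vector of contrast magnitudes; at least 20 strictly
#'   positive values after dropping zeros.
#' @return a \linkS4class{WeibullFit}.
#' @export
fitWeibull <- function(samples) {
  x <- samples[!is.na(samples)]
  dropped <- sum(x <= 0)
  x <- x[x > 0]
  n <- length(x)
  if (n < 20) stop("need at least 20 strictly positive samples")
  if (max(x) - min(x) < .Machine$double.eps * max(x))
    stop("degenerate likelihood: all samples equal")
  lx <- log(x)
  slx <- sum(lx)
  profileLL <- function(logg) {
    g <- exp(logg)
    # scale overflow guard: compute mean(x^g) on the log scale
    m <- exp(lx * g)
    mg <- mean(m)
    b <- mg^(1 / g)
    n * log(g) - n * g * log(b) + (g - 1) * slx - n  # sum((x/b)^g) == n at the MLE
  }
  opt <- stats::optimize(profileLL, interval = log(c(0.01, 100)),
                         maximum = TRUE, tol = 1e-10)
  g <- exp(opt$maximum)
  b <- mean(exp(lx * g))^(1 / g)
  new("WeibullFit", betaScale = b, gammaShape = g, nSamples = n,
      nDropped = as.integer(dropped), logLik = opt$objective)
}

#' Per-scene, per-scale Weibull contrast fits
#'
#' For each channel and each Laplacian-of-Gaussian scale, computes the local
#' contrast map, takes absolute contrast values, and fits the two-parameter
#' Weibull distribution. A smaller shape (gamma) means a heavier-tailed
#' contrast distribution, a larger scale (beta) a wider one -- both read as
#' "more contrast" in that channel.
#'
#' @param pair a normalized \linkS4class{ScenePair}.
#' @param sigmas LoG scales in pixels (default c(5, 10, 20, 40)).
#' @return data.frame with columns scene, channel, sigma, beta_scale,
#'   gamma_shape, printed_rate_beta, n, loglik.
#' @export
contrastWeibullPerScene <- function(pair, sigmas = c(5, 10, 20, 40)) {
  if (!pair@normalized) stop("pair must be normalized (see normalizeMinmax)")
  rows <- list()
  for (ch in c("UV", "Green")) {
    img <- if (ch == "UV") pair@uv else pair@green
    img[!pair@valid] <- 0  # cropped pairs should contain no invalid pixels
    for (s in sigmas) {
      k <- logKernel(s)
      fit <- tryCatch(
        fitWeibull(abs(as.vector(localContrastMap(img, k)))),
        error = function(e) stop("scene ", pair@metadata@stem, ", channel ",
                                 ch, ", sigma ", s, ": ", conditionMessage(e))
      )
      rows[[length(rows) + 1L]] <- data.frame(
        scene = pair@metadata@stem, channel = ch, sigma = s,
        beta_scale = fit@betaScale, gamma_shape = fit@gammaShape,
        printed_rate_beta = printedRateBeta(fit),
        n = fit@nSamples, loglik = fit@logLik, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
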