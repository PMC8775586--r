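#' @include utils.R AllClasses.R
NULL

#' Random field with a 1/omega^a power spectrum
#'
#' Shapes Gaussian white noise in the frequency domain with amplitude
#' proportional to \eqn{\omega^{-a/2}} (so expected power follows
#' \eqn{1/\omega^a}), zeroes the DC component, inverts the transform and
#' affinely maps the result to [0, 1]. \code{slopeA = 0} gives white noise;
#' \code{slopeA} near 2 emulates the spectral falloff of natural images.
#'
#' @param shape integer vector c(rows, cols).
#' @param slopeA target spectral exponent a (>= 0).
#' @param seed optional RNG seed (the caller's RNG state is restored).
#' @return numeric matrix in [0, 1].
#' @export
spectralField <- function(shape, slopeA, seed = NULL) {
  if (slopeA < 0) stop("slopeA must be non-negative")
  withSeed(seed, {
    nr <- shape[1]; nc <- shape[2]
    white <- matrix(stats::rnorm(nr * nc), nr, nc)
    fy <- fftFreq(nr); fx <- fftFreq(nc)
    omega <- sqrt(outer(fy^2, fx^2, `+`))
    amp <- omega^(-slopeA / 2)
    amp[1, 1] <- 0  # no DC power: 1/omega^a diverges at the origin
    shaped <- Re(stats::fft(stats::fft(white) * amp, inverse = TRUE)) / (nr * nc)
    rng <- range(shaped)
    if (rng[2] - rng[1] < .Machine$double.eps) return(matrix(0.5, nr, nc))
    (shaped - rng[1]) / (rng[2] - rng[1])
  })
}

#' Parameters of a synthetic two-channel scene
#'
#' Bundles every knob of the synthetic scene generator. Defaults emulate a
#' daylight natural scene captured by a registered UV/green camera pair:
#' 1/omega^2 spectral falloff in both channels, a smooth radial vignette, a
#' small projective misalignment between channels, light salt-and-pepper
#' sensor noise, ND attenuation of the green channel and 12-bit quantization.
#'
#' @param heightPx,widthPx image dimensions (>= 64).
#' @param slopeUv,slopeGreen target spectral exponents per channel.
#' @param intensityMode "bimodal_sky" (sky/object mixture typical of
#'   upper-field scenes) or "skewed_ground" (right-skewed unimodal, typical
#'   of lower-field scenes).
#' @param bimodalSeparation distance between the two intensity modes
#'   (normalized units); a length-2 vector gives per-channel (UV, green)
#'   separations, emulating scenes whose sky/object contrast differs between
#'   channels.
#' @param vignetteStrength fractional corner falloff in [0, 1).
#' @param spNoiseFraction fraction of salt-and-pepper pixels in [0, 0.05].
#' @param homography 3x3 projective matrix mapping UV coordinates to green
#'   coordinates.
#' @param exposureS exposure length (s); counts scale linearly with it.
#' @param ndOd optical density of the green-channel ND filter; green counts
#'   scale by 10^(-ndOd).
#' @param seed integer RNG seed.
#' @return a validated parameter list of class "SceneSimParams".
#' @export
sceneSimParams <- function(heightPx = 256, widthPx = 256,
                           slopeUv = 2, slopeGreen = 2,
                           intensityMode = c("bimodal_sky", "skewed_ground"),
                           bimodalSeparation = 0.5,
                           vignetteStrength = 0.2,
                           spNoiseFraction = 0.002,
                           homography = diag(3),
                           exposureS = 0.01, ndOd = 0,
                           seed = 1L) {
  intensityMode <- match.arg(intensityMode)
  if (heightPx < 64 || widthPx < 64) stop("image dimensions must be >= 64")
  if (slopeUv < 0 || slopeGreen < 0) stop("spectral slopes must be >= 0")
  if (spNoiseFraction < 0 || spNoiseFraction > 0.05)
    stop("spNoiseFraction must lie in [0, 0.05]")
  if (vignetteStrength < 0 || vignetteStrength >= 1)
    stop("vignetteStrength must lie in [0, 1)")
  if (abs(det(homography)) < 1e-12) stop("homography must be invertible")
  if (exposureS <= 0) stop("exposureS must be positive")
  if (ndOd < 0) stop("ndOd must be non-negative")
  bimodalSeparation <- rep_len(bimodalSeparation, 2L)
  if (any(bimodalSeparation < 0 | bimodalSeparation >= 1))
    stop("bimodalSeparation must lie in [0, 1)")
  structure(list(
    heightPx = as.integer(heightPx), widthPx = as.integer(widthPx),
    slopeUv = slopeUv, slopeGreen = slopeGreen,
    intensityMode = intensityMode, bimodalSeparation = bimodalSeparation,
    vignetteStrength = vignetteStrength, spNoiseFraction = spNoiseFraction,
    homography = homography, exposureS = exposureS, ndOd = ndOd,
    bitDepth = 12L, seed = as.integer(seed)
  ), class = "SceneSimParams")
}

# Reference exposure that maps a unit-intensity pixel to 98% of full scale.
.exposureRef <- 0.01
.fullScale <- 4095

# Intensity transform applied to a clean spectral field.
applyIntensityMode <- function(field, mode, separation, maskSeed, shape) {
  if (mode == "skewed_ground") {
    # monotone convex remap: compresses mid-tones, leaves a right tail
    return(list(image = field^3, skyMask = matrix(FALSE, shape[1], shape[2])))
  }
  # bimodal_sky: composite two levels through a smoothed random horizon mask
  horizonBase <- shape[1] / 2
  wobble <- spectralField(c(8L, shape[2]), 3, seed = maskSeed)[4, ]
  horizon <- horizonBase + (wobble - mean(wobble)) * shape[1] * 0.3
  rows <- matrix(seq_len(shape[1]), shape[1], shape[2])
  hmat <- matrix(horizon, shape[1], shape[2], byrow = TRUE)
  m <- stats::plogis((hmat - rows) / (shape[1] * 0.02))  # 1 above horizon (sky)
  amp <- min((1 - separation) / 2, 0.2)
  lo <- 0.5 - separation / 2
  hi <- 0.5 + separation / 2
  img <- lo * (1 - m) + hi * m + amp * (2 * field - 1)
  list(image = pmin(pmax(img, 0), 1), skyMask = m > 0.5)
}

# Smooth multiplicative vignetting field, 1 at the centre.
vignetteField <- function(shape, strength) {
  cy <- (shape[1] - 1) / 2; cx <- (shape[2] - 1) / 2
  ry <- (seq_len(shape[1]) - 1 - cy)
  rx <- (seq_len(shape[2]) - 1 - cx)
  r2 <- outer(ry^2, rx^2, `+`)
  1 - strength * r2 / max(r2)
}

#' Generate a synthetic raw scene pair with known ground truth
#'
#' Builds clean per-channel fields from \code{\link{spectralField}}, applies
#' the intensity mode, warps the green channel by the channel misalignment
#' homography, multiplies both channels by a shared vignette, scales counts
#' by exposure and (green only) ND attenuation, quantizes to 12 bits
#' (round-to-nearest after clipping) and finally salts a fraction of pixels
#' with impulse noise. The returned ground truth holds everything needed to
#' verify the preprocessing stages: clean channels, the vignette field, the
#' homography, the sky mask and the clipping fraction (over-exposure is a
#' data-quality criterion for real captures, so it is recorded here).
#'
#' @param params a \code{\link{sceneSimParams}} list.
#' @return list with integer matrices \code{rawUv}, \code{rawGreen}, the
#'   real-valued flat-field \code{reference} (vignette scaled to full range)
#'   and a \code{truth} list (cleanUv, cleanGreen, warpedCleanGreen,
#'   vignetteField, homography, skyMask, clippedFraction, clipWarning,
#'   params).
#' @export
makeScenePair <- function(params) {
  stopifnot(inherits(params, "SceneSimParams"))
  shape <- c(params$heightPx, params$widthPx)
  fUv <- spectralField(shape, params$slopeUv, seed = stageSeed(params$seed, "uv"))
  fGr <- spectralField(shape, params$slopeGreen, seed = stageSeed(params$seed, "green"))
  maskSeed <- stageSeed(params$seed, "mask")
  tUv <- applyIntensityMode(fUv, params$intensityMode,
                            params$bimodalSeparation[1], maskSeed, shape)
  tGr <- applyIntensityMode(fGr, params$intensityMode,
                            params$bimodalSeparation[2], maskSeed, shape)
  cleanUv <- tUv$image
  cleanGreen <- tGr$image
  # the green camera sees the scene through the channel misalignment
  wGr <- warpProjective(cleanGreen, params$homography, interp = "bilinear")
  warped <- wGr$image
  warped[!wGr$valid] <- mean(cleanGreen)  # fill out-of-view border samples
  vig <- vignetteField(shape, params$vignetteStrength)
  gain <- .fullScale * 0.98 * params$exposureS / .exposureRef
  quantize <- function(x) {
    counts <- x * gain
    clipped <- mean(counts > .fullScale | counts < 0)
    counts <- pmin(pmax(counts, 0), .fullScale)
    list(img = matrix(as.integer(floor(counts + 0.5)), nrow(x), ncol(x)),
         clipped = clipped)
  }
  qUv <- quantize(cleanUv * vig)
  qGr <- quantize(warped * vig * 10^(-params$ndOd))
  salt <- function(img, stage) {
    n <- round(params$spNoiseFraction * length(img))
    if (n == 0) return(img)
    withSeed(stageSeed(params$seed, stage), {
      idx <- sample(length(img), n)
      img[idx] <- ifelse(stats::runif(n) < 0.5, 0L, as.integer(.fullScale))
    })
    img
  }
  rawUv <- salt(qUv$img, "saltUv")
  rawGreen <- salt(qGr$img, "saltGreen")
  clippedFraction <- max(qUv$clipped, qGr$clipped)
  list(
    rawUv = rawUv, rawGreen = rawGreen,
    reference = vig * .fullScale,
    truth = list(
      cleanUv = cleanUv, cleanGreen = cleanGreen, warpedCleanGreen = warped,
      vignetteField = vig, homography = params$homography,
      skyMask = tUv$skyMask, clippedFraction = clippedFraction,
      clipWarning = clippedFraction > 0.001, params = params
    )
  )
}

#' Draw Weibull samples by inverse-CDF sampling
#'
#' Canonical scale-shape parameterization:
#' \eqn{x = \beta(-\ln(1-U))^{1/\gamma}} for uniform U.
#'
#' @param betaScale scale parameter (> 0).
#' @param gammaShape shape parameter (> 0).
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return numeric vector of n positive draws.
#' @export
sampleWeibull <- function(betaScale, gammaShape, n, seed = NULL) {
  if (betaScale <= 0 || gammaShape <= 0) stop("parameters must be positive")
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    u <- stats::runif(n)
    betaScale * (-log1p(-u))^(1 / gammaShape)
  })
}

#' Simulated control-point correspondences
#'
#' Draws points in the UV frame, maps them through the ground-truth
#' homography and perturbs the destination coordinates with Gaussian jitter,
#' emulating manually clicked registration landmarks. Near-collinear
#' configurations are redrawn.
#'
#' @param truth ground truth from \code{\link{makeScenePair}} (or any list
#'   with \code{homography} and \code{params} carrying the image dims).
#' @param nPoints number of correspondences (>= 4).
#' @param jitterPx standard deviation of the destination jitter (pixels).
#' @param seed optional RNG seed.
#' @return list with matrices \code{src} and \code{dst} (n x 2, (x, y)
#'   0-based pixel coordinates).
#' @export
makeControlPoints <- function(truth, nPoints, jitterPx = 0, seed = NULL) {
  if (nPoints < 4) stop("need at least 4 control points")
  h <- truth$homography
  w <- truth$params$widthPx; ht <- truth$params$heightPx
  withSeed(seed, {
    for (attempt in 1:100) {
      src <- cbind(stats::runif(nPoints, 0.1 * w, 0.9 * w),
                   stats::runif(nPoints, 0.1 * ht, 0.9 * ht))
      # degenerate if all points lie near one line: check smallest singular
      # value of the centred coordinates
      sv <- svd(scale(src, scale = FALSE))$d
      if (sv[2] > 1e-6 * sv[1]) break
    }
    dst <- applyHomography(h, src)
    if (jitterPx > 0)
      dst <- dst + matrix(stats::rnorm(2 * nPoints, 0, jitterPx), ncol = 2)
    list(src = src, dst = dst)
  })
}

#' Write a synthetic scene pair to disk
#'
#' Writes \code{<stem>_uv.png}, \code{<stem>_green.png} and
#' \code{<stem>_ref.png} as 16-bit grayscale PNGs, the ground truth as a JSON
#' sidecar \code{<stem>_truth.json} (without the full clean images), and
#' appends a metadata row to \code{scenes.csv} in \code{dir}.
#'
#' @param scene output of \code{\link{makeScenePair}}.
#' @param stem scene identifier.
#' @param dir output directory (created if missing).
#' @param elevation camera elevation category ("up"/"down"/"horizontal").
#' @param weather,distance,objects free-text metadata tags.
#' @return invisibly, the stem.
#' @export
writeScenePair <- function(scene, stem, dir, elevation = "up",
                           weather = "", distance = "", objects = "") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- scene$truth$params
  writePNG16(scene$rawUv, file.path(dir, paste0(stem, "_uv.png")))
  writePNG16(scene$rawGreen, file.path(dir, paste0(stem, "_green.png")))
  writePNG16(matrix(as.integer(round(scene$reference)),
                    nrow(scene$reference), ncol(scene$reference)),
             file.path(dir, paste0(stem, "_ref.png")))
  sidecar <- list(
    homography = scene$truth$homography,
    clippedFraction = scene$truth$clippedFraction,
    clipWarning = scene$truth$clipWarning,
    params = p[setdiff(names(p), "homography")]
  )
  jsonlite::write_json(sidecar, file.path(dir, paste0(stem, "_truth.json")),
                       auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  csv <- file.path(dir, "scenes.csv")
  row <- data.frame(stem = stem, elevation = elevation,
                    exposure_s = p$exposureS, nd_od = p$ndOd,
                    weather = weather, distance = distance, objects = objects,
                    stringsAsFactors = FALSE)
  utils::write.table(row, csv, sep = ",", row.names = FALSE,
                     col.names = !file.exists(csv), append = file.exists(csv),
                     quote = FALSE)
  invisible(stem)
}
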