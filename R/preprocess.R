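#' @include utils.R AllClasses.R
NULL

#' Flat-field vignetting correction
#'
#' Divides out the optical vignetting recorded in a flat-field reference
#' image:
#' \deqn{I_{corr}(x,y) = I_{raw}(x,y)\cdot\max[I_{ref}]/I_{ref}(x,y).}
#'
#' @param raw raw image matrix.
#' @param reference flat-field reference of the same shape, strictly
#'   positive everywhere.
#' @return corrected image (numeric matrix).
#' @export
correctVignetting <- function(raw, reference) {
  if (!identical(dim(raw), dim(reference)))
    stop("raw and reference images must have the same shape")
  nz <- sum(reference <= 0)
  if (nz > 0)
    stop("reference image contains ", nz, " non-positive pixels")
  raw * max(reference) / reference
}

#' 3x3 median filter
#'
#' Replaces each pixel by the median of its 3x3 neighbourhood to remove
#' salt-and-pepper sensor noise. Borders use reflect padding so the image
#' size is preserved. Implemented as an exact 9-element min/max exchange
#' network on shifted copies, so the result equals a sort-and-pick median at
#' every pixel.
#'
#' @param image 2D numeric matrix.
#' @return filtered matrix of the same shape and storage mode.
#' @export
medianFilter3x3 <- function(image) {
  nr <- nrow(image); nc <- ncol(image)
  # reflect padding (edge rows/cols mirrored without repetition of the edge
  # would be "reflect 101"; here we repeat the edge sample, i.e. replicate
  # its nearest neighbour, which is the usual 'symmetric' reflection)
  ri <- c(1L, seq_len(nr), nr)
  ci <- c(1L, seq_len(nc), nc)
  p <- image[ri, ci, drop = FALSE]
  shift <- function(dr, dc) p[(1 + dr):(nr + dr), (1 + dc):(nc + dc), drop = FALSE]
  a <- list(shift(0, 0), shift(0, 1), shift(0, 2),
            shift(1, 0), shift(1, 1), shift(1, 2),
            shift(2, 0), shift(2, 1), shift(2, 2))
  # Paeth's 19-exchange median-of-9 network; ex(i, j) leaves min in i, max in j
  ex <- function(i, j) {
    lo <- pmin(a[[i]], a[[j]]); hi <- pmax(a[[i]], a[[j]])
    a[[i]] <<- lo; a[[j]] <<- hi
  }
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 2); ex(4, 5); ex(7, 8)
  ex(2, 3); ex(5, 6); ex(8, 9)
  ex(1, 4); ex(6, 9); ex(5, 8)
  ex(4, 7); ex(2, 5); ex(3, 6)
  ex(5, 8); ex(5, 3); ex(7, 5)
  ex(5, 3)
  out <- a[[5]]
  if (is.integer(image)) storage.mode(out) <- "integer"
  out
}

#' Estimate a projective transform from control points
#'
#' Least-squares homography by the normalized direct linear transform:
#' points are translated/scaled to centroid 0 and RMS distance sqrt(2), the
#' 2n x 9 design is solved by SVD for the smallest singular vector, and the
#' result is denormalized and scaled so the bottom-right element is 1.
#'
#' @param pointsSrc,pointsDst n x 2 matrices of (x, y) correspondences
#'   (0-based pixel coordinates), n >= 4, non-degenerate.
#' @return 3x3 homography matrix mapping source to destination coordinates,
#'   with attribute \code{"reprojectionError"} holding per-point Euclidean
#'   errors.
#' @export
estimateProjective <- function(pointsSrc, pointsDst) {
  src <- matrix(as.numeric(pointsSrc), ncol = 2)
  dst <- matrix(as.numeric(pointsDst), ncol = 2)
  n <- nrow(src)
  if (n < 4 || nrow(dst) != n)
    stop("need >= 4 source/destination correspondences")
  normalizer <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums((p - rep(ctr, each = nrow(p)))^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    rbind(c(s, 0, -s * ctr[1]), c(0, s, -s * ctr[2]), c(0, 0, 1))
  }
  Ts <- normalizer(src); Td <- normalizer(dst)
  sn <- applyHomography(Ts, src)
  dn <- applyHomography(Td, dst)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- sn[i, 1]; y <- sn[i, 2]; u <- dn[i, 1]; v <- dn[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ] <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A, nu = 0, nv = 9)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("rank-deficient control-point configuration")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12) stop("degenerate homography (vanishing scale)")
  H <- H / H[3, 3]
  # geometric refinement: minimize the summed squared reprojection error
  # over the 8 free elements, starting from the algebraic solution
  obj <- function(par) {
    Hp <- matrix(c(par, 1), 3, 3, byrow = TRUE)
    sum((applyHomography(Hp, src) - dst)^2)
  }
  opt <- stats::optim(as.vector(t(H))[1:8], obj, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-14))
  if (opt$value <= obj(as.vector(t(H))[1:8]))
    H <- matrix(c(opt$par, 1), 3, 3, byrow = TRUE)
  proj <- applyHomography(H, src)
  attr(H, "reprojectionError") <- sqrt(rowSums((proj - dst)^2))
  H
}

#' Register the UV image onto the green image grid
#'
#' Resamples the UV image onto the green pixel grid by inverse-mapped
#' interpolation through the homography \code{h} (which maps UV coordinates
#' to green coordinates). Pixels whose source location falls outside the UV
#' frame are marked invalid and should be removed by cropping, never filled.
#'
#' @param uv,green image matrices.
#' @param h 3x3 homography mapping UV to green coordinates.
#' @param interp "bilinear" (default) or "nearest".
#' @return list with \code{uv} (registered UV image, invalid pixels NA),
#'   \code{green}, and logical \code{valid}.
#' @export
registerPair <- function(uv, green, h, interp = c("bilinear", "nearest")) {
  interp <- match.arg(interp)
  w <- warpProjective(uv, h, dims = dim(green), interp = interp,
                      fill = NA_real_)
  if (mean(w$valid) < 0.5)
    stop("registration leaves less than 50% valid overlap")
  list(uv = w$image, green = green, valid = w$valid)
}

#' Construct a ScenePair
#'
#' @param uv,green equal-shape image matrices.
#' @param metadata a \linkS4class{SceneMetadata}.
#' @param pixelPitchDeg angular pixel pitch (degrees/pixel; default 0.006).
#' @param valid optional logical validity mask (default all valid, NA pixels
#'   invalid).
#' @param normalized whether the channels are min-max normalized.
#' @return a \linkS4class{ScenePair}.
#' @export
scenePair <- function(uv, green, metadata, pixelPitchDeg = 0.006,
                      valid = NULL, normalized = FALSE) {
  uv <- as.matrix(uv); green <- as.matrix(green)
  if (is.null(valid)) valid <- !is.na(uv) & !is.na(green)
  new("ScenePair", uv = uv, green = green, valid = valid,
      pixelPitchDeg = pixelPitchDeg, metadata = metadata,
      normalized = normalized)
}

#' Crop a scene pair
#'
#' Crops both channels (and the validity mask) identically. The rectangle is
#' half-open in 0-based (x, y) coordinates; the angular pixel pitch is never
#' changed by cropping.
#'
#' @param pair a \linkS4class{ScenePair}.
#' @param rect list or vector with \code{x}, \code{y}, \code{width},
#'   \code{height} (0-based, half-open).
#' @return the cropped \linkS4class{ScenePair}.
#' @export
cropPair <- function(pair, rect) {
  rect <- as.list(rect)
  x0 <- rect$x; y0 <- rect$y; w <- rect$width; h <- rect$height
  if (w <= 0 || h <= 0) stop("empty crop rectangle")
  if (x0 < 0 || y0 < 0 || x0 + w > ncol(pair@uv) || y0 + h > nrow(pair@uv))
    stop("crop rectangle out of bounds")
  rows <- (y0 + 1):(y0 + h); cols <- (x0 + 1):(x0 + w)
  new("ScenePair", uv = pair@uv[rows, cols, drop = FALSE],
      green = pair@green[rows, cols, drop = FALSE],
      valid = pair@valid[rows, cols, drop = FALSE],
      pixelPitchDeg = pair@pixelPitchDeg, metadata = pair@metadata,
      normalized = pair@normalized)
}

#' Min-max intensity normalization
#'
#' Each channel is independently mapped to [0, 1] by subtracting its minimum
#' and dividing by the resulting maximum (over valid pixels), modelling the
#' adaptation of visual sensitivity to the intensity range of each scene.
#'
#' @param pair a \linkS4class{ScenePair}.
#' @return the normalized \linkS4class{ScenePair} (normalized flag set).
#' @export
normalizeMinmax <- function(pair) {
  norm1 <- function(ch) {
    v <- ch[pair@valid]
    rng <- range(v)
    if (rng[2] - rng[1] < .Machine$double.eps)
      stop("cannot normalize a constant channel")
    out <- (ch - rng[1]) / (rng[2] - rng[1])
    out[!pair@valid] <- NA_real_
    out
  }
  new("ScenePair", uv = norm1(pair@uv), green = norm1(pair@green),
      valid = pair@valid, pixelPitchDeg = pair@pixelPitchDeg,
      metadata = pair@metadata, normalized = TRUE)
}

#' Full raw-to-registered preprocessing chain
#'
#' Vignetting correction, 3x3 median filtering, projective registration of
#' the UV channel onto the green grid, and cropping, in that order.
#' Normalization is left to analysis time.
#'
#' @param rawUv,rawGreen raw integer image matrices.
#' @param reference flat-field reference image (shared by both channels
#'   unless \code{referenceGreen} is given).
#' @param h homography mapping UV to green coordinates (identity for
#'   pre-registered captures).
#' @param rect crop rectangle (see \code{\link{cropPair}}); \code{NULL}
#'   keeps the full frame.
#' @param metadata a \linkS4class{SceneMetadata}.
#' @param pixelPitchDeg degrees per pixel.
#' @param referenceGreen optional channel-specific reference for the green
#'   camera.
#' @return an unnormalized \linkS4class{ScenePair}.
#' @export
preprocessScene <- function(rawUv, rawGreen, reference, h = diag(3),
                            rect = NULL, metadata,
                            pixelPitchDeg = 0.006, referenceGreen = NULL) {
  if (is.null(referenceGreen)) referenceGreen <- reference
  cUv <- medianFilter3x3(correctVignetting(rawUv, reference))
  cGr <- medianFilter3x3(correctVignetting(rawGreen, referenceGreen))
  reg <- registerPair(cUv, cGr, h)
  pair <- scenePair(reg$uv, reg$green, metadata, pixelPitchDeg,
                    valid = reg$valid)
  if (!is.null(rect)) pair <- cropPair(pair, rect)
  pair
}

#' Relative intensity profiles across a set of raw captures
#'
#' Undoes the acquisition scaling of each capture (divide by exposure
#' length, multiply by the ND attenuation 10^OD), normalizes by the grand
#' mean pixel intensity over all captures, averages along the off axis, and
#' summarizes per elevation category by the median and interquartile range
#' at each aligned position. Alignment: horizontal profiles are centred;
#' vertical profiles are aligned to the top edge for lower-field captures,
#' the bottom edge for upper-field captures and the centre for horizontal
#' ones, so that the image edge closest to the horizon sits at position 0.
#'
#' @param captures list of captures, each a list with \code{image} (matrix)
#'   and \code{metadata} (a \linkS4class{SceneMetadata}).
#' @param axis "horizontal" (profile along columns) or "vertical" (along
#'   rows).
#' @return named list per category, each a data.frame with \code{position},
#'   \code{median}, \code{q25}, \code{q75}, \code{n}.
#' @export
relativeIntensityProfiles <- function(captures,
                                      axis = c("horizontal", "vertical")) {
  axis <- match.arg(axis)
  corrected <- lapply(captures, function(cp) {
    cp$image / cp$metadata@exposureS * 10^cp$metadata@ndOd
  })
  grand <- mean(vapply(corrected, mean, numeric(1)))
  profiles <- lapply(seq_along(captures), function(i) {
    img <- corrected[[i]] / grand
    if (axis == "horizontal") colMeans(img) else rowMeans(img)
  })
  cats <- vapply(captures, function(cp) cp$metadata@elevation, character(1))
  out <- list()
  for (cat in intersect(c("up", "down", "horizontal"), unique(cats))) {
    idx <- which(cats == cat)
    lens <- lengths(profiles[idx])
    L <- max(lens)
    aligned <- vapply(idx, function(i) {
      p <- profiles[[i]]
      v <- rep(NA_real_, L)
      off <- if (axis == "horizontal" || cat == "horizontal") {
        floor((L - length(p)) / 2)          # centre alignment
      } else if (cat == "down") {
        0L                                   # top edge (row 1 = position 0)
      } else {
        L - length(p)                        # bottom edge at the last slot
      }
      v[(off + 1):(off + length(p))] <- p
      v
    }, numeric(L))
    aligned <- matrix(aligned, nrow = L)
    pos <- if (axis == "vertical" && cat == "up") rev(seq_len(L) - 1) else seq_len(L) - 1
    out[[cat]] <- data.frame(
      position = pos,
      median = apply(aligned, 1, stats::median, na.rm = TRUE),
      q25 = apply(aligned, 1, stats::quantile, probs = 0.25, na.rm = TRUE),
      q75 = apply(aligned, 1, stats::quantile, probs = 0.75, na.rm = TRUE),
      n = apply(aligned, 1, function(r) sum(!is.na(r)))
    )
  }
  missing <- setdiff(c("up", "down", "horizontal"), names(out))
  if (length(missing))
    warning("no captures in category: ", paste(missing, collapse = ", "))
  out
}
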