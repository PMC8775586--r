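# Internal numerical helpers shared across modules.

# Frequency grid of an N-point DFT in cycles/sample, mapped into (-0.5, 0.5]
# (the Nyquist bin of an even-length transform is reported as +0.5).
fftFreq <- function(n) {
  f <- (seq_len(n) - 1) / n
  f[f > 0.5] <- f[f > 0.5] - 1
  f
}

# Reorder a 2-D DFT output so that DC sits at the centre, rows/cols sorted by
# ascending frequency as given by fftFreq().
fftShift2 <- function(x) {
  fr <- order(fftFreq(nrow(x)))
  fc <- order(fftFreq(ncol(x)))
  x[fr, fc, drop = FALSE]
}

# 2-D convolution via zero-padded FFTs.  shape = "valid" returns only the
# region where the kernel lies fully inside the image (no padding enters).
fftConvolve2 <- function(x, k, shape = c("valid", "full")) {
  shape <- match.arg(shape)
  nr <- nrow(x) + nrow(k) - 1L
  nc <- ncol(x) + ncol(k) - 1L
  px <- matrix(0, nr, nc)
  pk <- matrix(0, nr, nc)
  px[seq_len(nrow(x)), seq_len(ncol(x))] <- x
  pk[seq_len(nrow(k)), seq_len(ncol(k))] <- k
  full <- Re(stats::fft(stats::fft(px) * stats::fft(pk), inverse = TRUE)) / (nr * nc)
  if (shape == "full") return(full)
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x))
    stop("kernel larger than image: no valid convolution region")
  full[nrow(k):nrow(x), ncol(k):ncol(x), drop = FALSE]
}

# Apply a 3x3 homography (0-based (x, y) pixel coordinates) to an n x 2 matrix
# of points; returns n x 2 matrix.
applyHomography <- function(h, xy) {
  xy <- matrix(as.numeric(xy), ncol = 2)
  p <- cbind(xy, 1) %*% t(h)
  p[, 1:2, drop = FALSE] / p[, 3]
}

# Sample an image (matrix, rows = y, cols = x, 0-based coords) at fractional
# (x, y) locations by bilinear interpolation.  Out-of-bounds samples give NA.
bilinearSample <- function(img, x, y) {
  nr <- nrow(img); nc <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  inb <- x0 >= 0 & y0 >= 0 & x0 <= nc - 1 & y0 <= nr - 1
  # clamp the upper neighbour so exact border samples stay in bounds
  x1 <- pmin(x0 + 1, nc - 1); y1 <- pmin(y0 + 1, nr - 1)
  out <- rep(NA_real_, length(x))
  i <- which(inb)
  if (length(i)) {
    idx <- function(yy, xx) yy[i] + 1L + nrow(img) * xx[i]  # column-major linear index
    v00 <- img[idx(y0, x0)]; v01 <- img[idx(y0, x1)]
    v10 <- img[idx(y1, x0)]; v11 <- img[idx(y1, x1)]
    out[i] <- (1 - fy[i]) * ((1 - fx[i]) * v00 + fx[i] * v01) +
      fy[i] * ((1 - fx[i]) * v10 + fx[i] * v11)
  }
  out
}

# Warp an image onto an output grid through homography h mapping source
# coordinates to destination coordinates: out(p) = img(h^{-1} p).
# interp = "nearest" rounds source coordinates (exact for integer shifts).
warpProjective <- function(img, h, dims = dim(img),
                           interp = c("bilinear", "nearest"),
                           fill = NA_real_) {
  interp <- match.arg(interp)
  hinv <- solve(h)
  xs <- rep(seq_len(dims[2]) - 1, each = dims[1])
  ys <- rep(seq_len(dims[1]) - 1, times = dims[2])
  src <- applyHomography(hinv, cbind(xs, ys))
  if (interp == "nearest") {
    sx <- round(src[, 1]); sy <- round(src[, 2])
    inb <- sx >= 0 & sy >= 0 & sx <= ncol(img) - 1 & sy <= nrow(img) - 1
    v <- rep(NA_real_, length(sx))
    v[inb] <- img[cbind(sy[inb] + 1, sx[inb] + 1)]
  } else {
    v <- bilinearSample(img, src[, 1], src[, 2])
  }
  valid <- matrix(!is.na(v), dims[1], dims[2])
  v[is.na(v)] <- fill
  list(image = matrix(v, dims[1], dims[2]), valid = valid)
}

# Run an expression with a locally-set RNG seed, restoring the caller's
# generator state afterwards; NULL seed leaves the RNG untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage substream seed derived from one global seed, so each
# pipeline stage is individually reproducible.
stageSeed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  (as.integer(seed) %% 1000003L) * 2011L + sum(utf8ToInt(stage)) %% 65521L
}
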