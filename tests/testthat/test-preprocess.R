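test_that("vignetting correction implements flat-field division exactly", {
  raw <- matrix(runif(400, 100, 4000), 20, 20)
  refU <- matrix(500, 20, 20)
  expect_equal(correctVignetting(raw, refU), raw)  # uniform reference: no-op

  ref <- matrix(runif(400, 200, 4000), 20, 20)
  expect_equal(correctVignetting(ref, ref), matrix(max(ref), 20, 20))

  # correction followed by re-multiplication with ref/max(ref) is the identity
  corr <- correctVignetting(raw, ref)
  expect_equal(corr * ref / max(ref), raw, tolerance = 1e-12)

  refBad <- ref; refBad[3, 7] <- 0
  expect_error(correctVignetting(raw, refBad), "1 non-positive")
})

test_that("vignetting round trip on a synthetic scene is within one count", {
  p <- sceneSimParams(heightPx = 128, widthPx = 128, vignetteStrength = 0.2,
                      spNoiseFraction = 0, seed = 6)
  sp <- makeScenePair(p)
  corrected <- correctVignetting(sp$rawUv, sp$reference)
  cleanCounts <- sp$truth$cleanUv * 4095 * 0.98
  expect_lte(max(abs(corrected - cleanCounts)), 1)
})

test_that("3x3 median filter equals the sort-and-pick oracle", {
  const <- matrix(7L, 10, 10)
  expect_identical(medianFilter3x3(const), const)

  impulse <- matrix(0L, 12, 12); impulse[6, 6] <- 4095L
  expect_identical(medianFilter3x3(impulse), matrix(0L, 12, 12))

  set.seed(42)
  img <- matrix(sample(0:4095, 256, TRUE), 16, 16)
  expect_identical(medianFilter3x3(img), oracleMedian3x3(img))
  # fractional values too (the filter is used after flat-field division)
  imgF <- matrix(runif(256), 16, 16)
  expect_equal(medianFilter3x3(imgF), oracleMedian3x3(imgF), tolerance = 0)
})

test_that("median filtering is near-idempotent on impulse noise", {
  set.seed(7)
  img <- matrix(2000L, 64, 64)
  img[sample(4096, 40)] <- 4095L  # ~1% salt
  once <- medianFilter3x3(img)
  twice <- medianFilter3x3(once)
  expect_lt(mean(once != twice), 0.001)
})

test_that("projective estimation is exact on exact correspondences", {
  src <- rbind(c(0, 0), c(100, 0), c(0, 100), c(100, 100))
  hId <- estimateProjective(src, src)
  expect_equal(unclass(hId)[1:3, 1:3], diag(3), tolerance = 1e-9,
               ignore_attr = TRUE)

  h <- rbind(c(0.98, 0.05, 4), c(-0.03, 1.02, -7), c(2e-5, -1e-5, 1))
  dst <- uvscene:::applyHomography(h, src)
  hHat <- estimateProjective(src, dst)
  expect_equal(unclass(hHat)[1:3, 1:3], h, tolerance = 1e-7, ignore_attr = TRUE)
  expect_lt(max(attr(hHat, "reprojectionError")), 1e-6)

  expect_error(estimateProjective(src[1:3, ], src[1:3, ]), ">= 4")
  colinear <- cbind(1:6, 2 * (1:6))
  expect_error(estimateProjective(colinear, colinear), "rank-deficient")
})

test_that("registration warps UV onto the green grid correctly", {
  img <- matrix(runif(64 * 64), 64, 64)
  idn <- registerPair(img, img, diag(3))
  expect_equal(idn$uv, img)
  expect_true(all(idn$valid))

  # pure integer translation is exact on the overlap
  hT <- diag(3); hT[1, 3] <- 3; hT[2, 3] <- 2  # UV shifted by (+3, +2)
  reg <- registerPair(img, img, hT, interp = "nearest")
  expect_equal(reg$uv[10:60, 10:60], img[(10:60) - 2, (10:60) - 3])
  expect_false(all(reg$valid))

  # warp then inverse-warp returns the original on a smooth image
  xy <- 0:95
  smooth <- 2000 + 1000 * outer(sin(2 * pi * xy / 96), cos(2 * pi * xy / 96))
  h <- rbind(c(1.002, 0.004, 0.7), c(-0.003, 0.998, -0.4), c(1e-6, -1e-6, 1))
  fwd <- uvscene:::warpProjective(smooth, h, interp = "bilinear")
  back <- uvscene:::warpProjective(fwd$image, solve(h), interp = "bilinear")
  core <- 10:86
  expect_lt(max(abs(back$image[core, core] - smooth[core, core])), 2)

  hFar <- diag(3); hFar[1, 3] <- 60
  expect_error(registerPair(img, img, hFar), "50%")
})

test_that("cropping preserves pitch and composes", {
  img <- matrix(runif(200 * 200, 0, 4095), 200, 200)
  pair <- makeTestPair(img, img)

  full <- cropPair(pair, list(x = 0, y = 0, width = 200, height = 200))
  expect_equal(uvChannel(full), uvChannel(pair))

  c1 <- cropPair(pair, list(x = 10, y = 20, width = 100, height = 120))
  c2 <- cropPair(c1, list(x = 5, y = 5, width = 50, height = 60))
  direct <- cropPair(pair, list(x = 15, y = 25, width = 50, height = 60))
  expect_equal(uvChannel(c2), uvChannel(direct))
  expect_equal(pixelPitchDeg(c2), pixelPitchDeg(pair))

  # a 341-px crop spans ~2.0 degrees at 0.006 deg/px; 1766 px spans ~10.6
  expect_equal(341 * pixelPitchDeg(pair), 2.046, tolerance = 1e-12)
  expect_equal(round(1766 * pixelPitchDeg(pair), 1), 10.6)

  expect_error(cropPair(pair, list(x = 0, y = 0, width = 0, height = 10)),
               "empty")
  expect_error(cropPair(pair, list(x = 150, y = 0, width = 100, height = 10)),
               "out of bounds")
})

test_that("min-max normalization is affine-invariant per channel", {
  set.seed(3)
  img <- matrix(runif(400, 100, 3000), 20, 20)
  pair <- makeTestPair(img, 2.5 * img + 300)
  norm <- normalizeMinmax(pair)
  expect_true(isNormalized(norm))
  expect_equal(range(uvChannel(norm)), c(0, 1))
  # affine transforms normalize to the same image
  expect_equal(uvChannel(norm), greenChannel(norm), tolerance = 1e-12)

  two <- makeTestPair(matrix(c(100, 4000), 8, 8), matrix(c(100, 4000), 8, 8))
  expect_equal(sort(unique(as.vector(uvChannel(normalizeMinmax(two))))), c(0, 1))

  constPair <- makeTestPair(matrix(5, 10, 10), img[1:10, 1:10])
  expect_error(normalizeMinmax(constPair), "constant")
})

test_that("full preprocessing recovers the clean synthetic structure", {
  h <- rbind(c(1.004, 0.006, 1.2), c(-0.005, 0.997, -0.8), c(2e-6, -1e-6, 1))
  p <- sceneSimParams(heightPx = 160, widthPx = 160, homography = h,
                      vignetteStrength = 0.25, spNoiseFraction = 0.005,
                      seed = 13)
  sp <- makeScenePair(p)
  cp <- makeControlPoints(sp$truth, 12, jitterPx = 0, seed = 14)
  hHat <- estimateProjective(cp$src, cp$dst)
  pair <- preprocessScene(sp$rawUv, sp$rawGreen, sp$reference, hHat,
                          rect = list(x = 12, y = 12, width = 136, height = 136),
                          metadata = makeTestMetadata())
  norm <- normalizeMinmax(pair)
  clean <- sp$truth$warpedCleanGreen[13:148, 13:148]
  cleanN <- (clean - min(clean)) / (max(clean) - min(clean))
  expect_gt(stats::cor(as.vector(greenChannel(norm)), as.vector(cleanN)), 0.99)
  expect_equal(pixelPitchDeg(pair), 0.006)
})

test_that("relative intensity profiles undo acquisition scaling", {
  mkCap <- function(img, elev, expo = 0.01, nd = 0, stem = "c") {
    list(image = img, metadata = makeTestMetadata(stem, elev, expo, nd))
  }
  # single uniform image: flat profile at 1 after grand-mean normalization
  prof <- suppressWarnings(
    relativeIntensityProfiles(list(mkCap(matrix(1234, 30, 40), "up")),
                              axis = "horizontal"))
  expect_equal(prof$up$median, rep(1, 40), tolerance = 1e-12)

  # exposure and ND corrections cancel acquisition differences
  set.seed(5)
  base <- matrix(runif(1200, 500, 3000), 30, 40)
  caps <- list(mkCap(base, "up", expo = 0.01),
               mkCap(base * 2, "up", expo = 0.02))
  prof2 <- suppressWarnings(relativeIntensityProfiles(caps, axis = "vertical"))
  expect_equal(prof2$up$q25, prof2$up$q75, tolerance = 1e-12)

  capsNd <- list(mkCap(base, "down", nd = 0),
                 mkCap(base / 10, "down", nd = 1))
  prof3 <- suppressWarnings(relativeIntensityProfiles(capsNd, axis = "horizontal"))
  expect_equal(prof3$down$q25, prof3$down$q75, tolerance = 1e-10)

  # upper-field images twice as bright show a profile twice as high
  capsUD <- list(mkCap(base * 2, "up"), mkCap(base, "down"))
  prof4 <- suppressWarnings(relativeIntensityProfiles(capsUD, axis = "horizontal"))
  expect_equal(mean(prof4$up$median) / mean(prof4$down$median), 2,
               tolerance = 1e-10)
  expect_warning(
    relativeIntensityProfiles(list(mkCap(base, "up")), axis = "horizontal"),
    "horizontal")
})
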