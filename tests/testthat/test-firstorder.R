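test_that("intensity histograms conserve mass on the 0.01 grid", {
  h <- intensityHistogram(matrix(0.5, 10, 10))
  expect_length(h$probabilities, 100)
  expect_equal(sum(h$probabilities), 1, tolerance = 1e-12)
  expect_equal(h$probabilities[51], 1)  # all mass in [0.50, 0.51)

  two <- intensityHistogram(matrix(c(0, 1), 10, 10))
  expect_equal(two$probabilities[1], 0.5)
  expect_equal(two$probabilities[100], 0.5)  # 1.0 counted in the final bin

  set.seed(2)
  r <- intensityHistogram(matrix(runif(500), 25, 20))
  expect_equal(sum(r$probabilities), 1, tolerance = 1e-12)
  expect_true(all(r$probabilities >= 0))

  expect_error(intensityHistogram(matrix(c(-0.1, 0.5), 5, 4)), "normalized")
})

test_that("LoG kernels follow the analytic centre-surround form", {
  for (s in c(5, 10)) {
    k <- logKernel(s)
    r <- floor(3 * s)
    expect_equal(dim(k$weights), c(2 * r + 1, 2 * r + 1))
    # raw origin value is 1/(pi sigma^4)
    expect_equal(k$rawWeights[r + 1, r + 1], 1 / (pi * s^4), tolerance = 1e-12)
    # sign change on the circle x^2 + y^2 = 2 sigma^2
    d2 <- outer(k$offsets^2, k$offsets^2, `+`)
    onCircle <- abs(d2 - 2 * s^2) < 1e-9
    if (any(onCircle)) expect_true(all(abs(k$rawWeights[onCircle]) < 1e-15))
    expect_true(all(k$rawWeights[d2 < 2 * s^2 - 1e-9] > 0))
    expect_true(all(k$rawWeights[d2 > 2 * s^2 + 1e-9] < 0))
    # zero-sum after adjustment; 4-fold rotational symmetry
    expect_lt(abs(sum(k$weights)), 1e-3 * max(abs(k$weights)))
    expect_equal(k$weights, t(k$weights))
    expect_equal(k$weights, k$weights[rev(seq_len(nrow(k$weights))), ])
  }
  expect_error(logKernel(0.5), ">= 1")
})

test_that("local contrast maps annihilate affine images and pass impulses", {
  k <- logKernel(2)
  const <- matrix(0.7, 40, 40)
  expect_lt(max(abs(localContrastMap(const, k))), 1e-10)

  ramp <- outer(seq(0, 1, length.out = 40), seq(0, 0.5, length.out = 40), `+`) / 1.5
  expect_lt(max(abs(localContrastMap(ramp, k))), 1e-10)

  # impulse response equals the (symmetric) kernel
  sz <- nrow(k$weights)
  imp <- matrix(0, 3 * sz, 3 * sz)
  imp[sz + (sz + 1) %/% 2 + 3, sz + (sz + 1) %/% 2 + 3] <- 1
  resp <- localContrastMap(imp, k)
  expect_equal(max(resp), max(k$weights), tolerance = 1e-9)
  expect_lt(max(abs(range(resp) - range(k$weights))), 1e-9)

  expect_error(localContrastMap(matrix(0, 5, 5), k), "larger")
})

test_that("Weibull MLE recovers known parameters", {
  xExp <- sampleWeibull(1, 1, 1e5, seed = 31)
  fExp <- fitWeibull(xExp)
  expect_equal(betaScale(fExp), 1, tolerance = 0.02)
  expect_equal(gammaShape(fExp), 1, tolerance = 0.02)

  xHeavy <- sampleWeibull(0.05, 0.8, 1e5, seed = 32)
  fHeavy <- fitWeibull(xHeavy)
  expect_equal(betaScale(fHeavy), 0.05, tolerance = 0.02 * 0.05)
  expect_equal(gammaShape(fHeavy), 0.8, tolerance = 0.02 * 0.8)
  # the printed-rate parameterization is beta^(-gamma)
  expect_equal(printedRateBeta(fHeavy),
               betaScale(fHeavy)^(-gammaShape(fHeavy)))

  # scale equivariance: scaling samples scales beta, leaves gamma
  xs <- sampleWeibull(0.3, 1.4, 2e4, seed = 33)
  f1 <- fitWeibull(xs); f2 <- fitWeibull(7 * xs)
  expect_equal(betaScale(f2), 7 * betaScale(f1), tolerance = 1e-4)
  expect_equal(gammaShape(f2), gammaShape(f1), tolerance = 1e-5)

  expect_error(fitWeibull(rep(2, 50)), "degenerate")
  expect_error(fitWeibull(runif(10)), "at least 20")
})

test_that("Weibull MLE agrees with a grid-search likelihood maximizer", {
  set.seed(40)
  cases <- list(c(0.5, 0.7), c(1, 1), c(2, 1.5), c(0.05, 0.9), c(3, 2.5))
  for (cs in cases) {
    x <- sampleWeibull(cs[1], cs[2], 2000, seed = round(100 * cs[1] + cs[2]))
    fit <- fitWeibull(x)
    grid <- oracleWeibullGrid(x, betaScale(fit) * c(0.8, 1.25),
                              gammaShape(fit) * c(0.8, 1.25))
    # grid resolution: 200 log-spaced points over a 1.56x span
    relStep <- (1.25 / 0.8)^(1 / 199) - 1
    expect_equal(betaScale(fit), grid$beta, tolerance = 3 * relStep)
    expect_equal(gammaShape(fit), grid$gamma, tolerance = 3 * relStep)
    expect_gte(fit@logLik, grid$logLik - 1e-6)
  }
})

test_that("per-scene contrast fits reflect channel construction", {
  # identical channels: identical fits
  img <- spectralField(c(128, 128), 2, seed = 50)
  pair <- normalizeMinmax(makeTestPair(img, img))
  wb <- contrastWeibullPerScene(pair, sigmas = c(5, 10))
  uvRows <- wb[wb$channel == "UV", ]
  grRows <- wb[wb$channel == "Green", ]
  expect_equal(uvRows$beta_scale, grRows$beta_scale, tolerance = 1e-10)
  expect_equal(uvRows$gamma_shape, grRows$gamma_shape, tolerance = 1e-10)

  # brightness scaling before normalization changes nothing
  pair2 <- normalizeMinmax(makeTestPair(img * 2.7 + 0.1, img))
  wb2 <- contrastWeibullPerScene(pair2, sigmas = c(5, 10))
  expect_equal(wb2$beta_scale, wb$beta_scale, tolerance = 1e-8)

  # heavier-tailed UV construction gives smaller UV gamma
  direction <- sapply(1:5, function(i) {
    p <- sceneSimParams(heightPx = 160, widthPx = 160, seed = 60 + i,
                        bimodalSeparation = c(0.7, 0.25),
                        vignetteStrength = 0, spNoiseFraction = 0)
    sp <- makeScenePair(p)
    pr <- normalizeMinmax(makeTestPair(sp$rawUv, sp$rawGreen))
    w <- contrastWeibullPerScene(pr, sigmas = 10)
    w$gamma_shape[w$channel == "UV"] < w$gamma_shape[w$channel == "Green"]
  })
  expect_gte(sum(direction), 4)
})

test_that("LoG responses are approximately scale covariant", {
  img <- spectralField(c(256, 256), 2.5, seed = 70)
  small <- img[seq(1, 256, 2), seq(1, 256, 2)]  # 2x downsample
  mapSmall <- localContrastMap(small, logKernel(5))
  mapBig <- localContrastMap(img, logKernel(10))
  # compare the sigma map on the downsampled image with the 2-sigma map on
  # the original, sampled on the matching grid
  big2 <- mapBig[seq(1, nrow(mapBig), 2), seq(1, ncol(mapBig), 2)]
  n <- min(nrow(mapSmall), nrow(big2)); m <- min(ncol(mapSmall), ncol(big2))
  cc <- stats::cor(as.vector(mapSmall[1:n, 1:m]), as.vector(big2[1:n, 1:m]))
  expect_gt(cc, 0.9)
})

test_that("Weibull MLE agrees with an independent library fit", {
  x <- sampleWeibull(0.4, 1.3, 5000, seed = 41)
  fit <- fitWeibull(x)
  ref <- fitdistrplus::fitdist(x, "weibull")
  expect_equal(gammaShape(fit), unname(ref$estimate["shape"]), tolerance = 1e-3)
  expect_equal(betaScale(fit), unname(ref$estimate["scale"]), tolerance = 1e-3)
})
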