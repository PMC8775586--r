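test_that("pigment template peaks at its nominal wavelength and is normalized", {
  grid <- 300:700
  for (lmax in c(360, 508)) {
    tmpl <- pigmentTemplate(lmax, grid)
    expect_equal(max(curveValues(tmpl)), 1)
    expect_true(all(curveValues(tmpl) >= 0))
    expect_equal(wavelengths(tmpl)[which.max(curveValues(tmpl))], lmax)
  }
  tmpl508 <- pigmentTemplate(508, grid)
  expect_equal(curveValues(tmpl508)[grid == 508], 1)
  expect_error(pigmentTemplate(250, grid), "outside")
})

test_that("pigment template matches an independent scalar transcription", {
  grid <- seq(300, 700, by = 1)
  tmpl <- pigmentTemplate(500, grid)
  v550 <- curveValues(tmpl)[grid == 550]
  oracle <- oraclePigmentAlpha(550, 500) /
    max(oraclePigmentAlpha(grid, 500))
  expect_equal(v550, oracle, tolerance = 1e-12)
  # a handful of other wavelengths on both flanks
  for (wl in c(420, 470, 520, 600)) {
    expect_equal(curveValues(tmpl)[grid == wl],
                 oraclePigmentAlpha(wl, 500) / max(oraclePigmentAlpha(grid, 500)),
                 tolerance = 1e-12)
  }
})

test_that("transmittance correction is a renormalized pointwise product", {
  grid <- 300:700
  s <- pigmentTemplate(360, grid)
  flat <- spectralCurve(grid, rep(1, length(grid)))
  out <- applyTransmittance(s, flat)
  expect_equal(curveValues(out), curveValues(s), tolerance = 1e-12)

  # a monotonically increasing transmittance can only shift the peak redward
  ramp <- spectralCurve(grid, seq(0.1, 1, length.out = length(grid)))
  shifted <- applyTransmittance(s, ramp)
  peak0 <- wavelengths(s)[which.max(curveValues(s))]
  peak1 <- wavelengths(shifted)[which.max(curveValues(shifted))]
  expect_gte(peak1, peak0)

  # short-pass-absorbing ocular media shift the S-pigment peak a few nm longer
  media <- spectralCurve(grid, stats::plogis((grid - 340) / 25))
  sShift <- applyTransmittance(s, media)
  newPeak <- wavelengths(sShift)[which.max(curveValues(sShift))]
  expect_gt(newPeak, 360)
  expect_lt(newPeak, 380)

  disjoint <- spectralCurve(800:900, rep(1, 101))
  expect_error(applyTransmittance(s, disjoint), "disjoint")
})

test_that("products of curves commute and associate up to renormalization", {
  grid <- seq(300, 700, by = 2)
  a <- pigmentTemplate(400, grid)
  b <- spectralCurve(grid, stats::plogis((grid - 380) / 30))
  c3 <- spectralCurve(grid, exp(-((grid - 450) / 80)^2))
  ab <- applyTransmittance(a, b)
  ba <- applyTransmittance(b, a)
  expect_equal(curveValues(ab), curveValues(ba), tolerance = 1e-12)
  abc1 <- applyTransmittance(applyTransmittance(a, b), c3)
  abc2 <- applyTransmittance(a, applyTransmittance(b, c3))
  expect_equal(curveValues(abc1), curveValues(abc2), tolerance = 1e-10)
})

test_that("channel sensitivity composes optics with sensor QE", {
  grid <- seq(300, 700, by = 1)
  optics <- spectralCurve(grid, exp(-((grid - 368) / 8)^2 / 2))
  flatQe <- spectralCurve(grid, rep(0.5, length(grid)))
  chan <- channelSensitivity(optics, flatQe)
  expect_equal(curveValues(chan),
               curveValues(spectralCurve(grid, curveValues(optics), normalize = TRUE)),
               tolerance = 1e-12)
  band <- peakAndHwhm(chan)
  expect_equal(centerNm(band), 368)

  # box transmission times an increasing ramp peaks at the box's red edge
  box <- spectralCurve(grid, as.numeric(grid >= 350 & grid <= 390))
  rampQe <- spectralCurve(grid, seq(0.01, 1, length.out = length(grid)))
  prod <- channelSensitivity(box, rampQe)
  expect_equal(wavelengths(prod)[which.max(curveValues(prod))], 390)
})

test_that("peak and HWHM match closed forms and converge with grid refinement", {
  sigma <- 25.48
  closedHwhm <- sigma * sqrt(2 * log(2))
  for (step in c(1, 0.1)) {
    grid <- seq(350, 650, by = step)
    g <- spectralCurve(grid, exp(-((grid - 500)^2) / (2 * sigma^2)))
    band <- peakAndHwhm(g)
    expect_equal(centerNm(band), 500, tolerance = step)
    expect_equal(hwhmNm(band), closedHwhm, tolerance = 0.01 * closedHwhm)
  }
  # refinement shrinks the error
  coarse <- peakAndHwhm(spectralCurve(seq(350, 650, 1),
    exp(-((seq(350, 650, 1) - 500)^2) / (2 * sigma^2))))
  fine <- peakAndHwhm(spectralCurve(seq(350, 650, 0.1),
    exp(-((seq(350, 650, 0.1) - 500)^2) / (2 * sigma^2))))
  expect_lte(abs(hwhmNm(fine) - closedHwhm), abs(hwhmNm(coarse) - closedHwhm) + 1e-9)

  # symmetric triangle: center at the apex
  tri <- spectralCurve(400:500, c(seq(0, 1, length.out = 51),
                                  seq(1, 0, length.out = 51)[-1]))
  expect_equal(centerNm(peakAndHwhm(tri)), 450)

  # box plateau: lowest-wavelength tie-break, HWHM half the box width
  grid <- 400:600
  box <- peakAndHwhm(spectralCurve(grid, as.numeric(grid >= 480 & grid <= 520)))
  expect_equal(centerNm(box), 480)
  expect_equal(hwhmNm(box), 20, tolerance = 0.06)

  # monotone curve: one-sided band is flagged
  mono <- peakAndHwhm(spectralCurve(400:500, seq(0.1, 1, length.out = 101)))
  expect_equal(mono@oneSided, "right")
})

test_that("photoreceptor photon flux follows the pupil/retina geometry", {
  geom <- mouseEyeGeometry(1e7)
  flux <- photoreceptorPhotonFlux(geom)
  # Phi * Apupil/Aretina * T * Aphotoreceptor by hand:
  # Apupil = pi*0.25^2, Aretina = 4*pi*4/2 -> ratio = 1/128
  expect_equal(flux, 1e7 / 128 * 0.5 * 0.5, tolerance = 1e-12)
  expect_equal(floor(log10(flux)), 4)  # dim daylight: order 1e4 photons/s
  expect_equal(floor(log10(photoreceptorPhotonFlux(mouseEyeGeometry(1e9)))), 6)

  dark <- eyeGeometry(1e7, 0.5, 4, 0, 0.5, 12400, 437000)
  expect_equal(photoreceptorPhotonFlux(dark), 0)

  # linearity and pupil-area scaling
  expect_equal(photoreceptorPhotonFlux(mouseEyeGeometry(2e7)), 2 * flux)
  wide <- eyeGeometry(1e7, 1.0, 4, 0.5, 0.5, 12400, 437000)
  expect_equal(photoreceptorPhotonFlux(wide), 4 * flux)
  bigA <- eyeGeometry(1e7, 0.5, 4, 0.5, 1.0, 12400, 437000)
  expect_equal(photoreceptorPhotonFlux(bigA), 2 * flux)
})

test_that("angular sampling resolution reproduces the printed mosaic estimates", {
  cone <- angularSamplingResolution(12400, 4)
  expect_equal(cone, 0.257, tolerance = 0.005)
  expect_lt(abs(cone - 0.25) / 0.25, 0.05)
  rod <- angularSamplingResolution(437000, 4)
  expect_equal(rod, 0.0433, tolerance = 0.001)
  # four-fold denser mosaic halves the sampling angle
  expect_equal(angularSamplingResolution(4 * 12400, 4), cone / 2, tolerance = 1e-12)
  expect_error(angularSamplingResolution(0, 4), "positive")
})

test_that("spectral curves round-trip through two-column CSV", {
  grid <- seq(300, 700, by = 5)
  crv <- pigmentTemplate(508, grid)
  path <- tempfile(fileext = ".csv")
  writeSpectralCurve(crv, path)
  back <- readSpectralCurve(path)
  expect_equal(wavelengths(back), wavelengths(crv))
  expect_equal(curveValues(back), curveValues(crv), tolerance = 1e-12)
  # comment lines are ignored
  lines <- readLines(path)
  writeLines(c("# reference curve", lines), path)
  expect_equal(curveValues(readSpectralCurve(path)), curveValues(crv),
               tolerance = 1e-12)
})

test_that("bundled reference curves load and describe the mouse channels", {
  ext <- system.file("extdata", package = "uvscene")
  sens <- readSpectralCurve(file.path(ext, "camera_uv_optics_synthetic.csv"))
  qe <- readSpectralCurve(file.path(ext, "sensor_qe_synthetic.csv"))
  band <- peakAndHwhm(channelSensitivity(sens, qe))
  expect_equal(centerNm(band), 368, tolerance = 2)
  grn <- readSpectralCurve(file.path(ext, "camera_green_optics_synthetic.csv"))
  bandG <- peakAndHwhm(channelSensitivity(grn, qe))
  expect_equal(centerNm(bandG), 500, tolerance = 5)
})
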