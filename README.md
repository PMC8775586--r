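# uvscene

Natural image statistics for dichromatic UV/green visual scenes.

Mice (and many other rodents) are dichromats whose retina expresses a
UV-sensitive S-opsin (peak ~360 nm) and a green-sensitive M-opsin
(peak ~508 nm), with a pronounced dorsoventral gradient: the ventral retina,
which views the **upper** visual field, is dominated by UV-sensitive cones,
while the dorsal retina, viewing the **lower** field, is green-dominated.
Whether this arrangement is an efficient match to the statistics of natural
scenes is an empirical question about those statistics, asked separately in
the UV and green bands and separately above and below the horizon.

`uvscene` provides the full analysis pipeline for paired UV/green images of
natural scenes, for researchers in visual neuroscience and natural scene
statistics:

- **Spectral model** — A1 visual pigment nomogram, ocular transmittance
  correction, effective camera channel sensitivity with peak/HWHM
  extraction, photoreceptor photon-budget and angular-sampling estimates.
- **Preprocessing** — flat-field vignetting correction
  `I_corr = I_raw · max(I_ref)/I_ref`, 3×3 median filtering, projective
  registration from control points (normalized DLT + geometric refinement),
  cropping and per-scene min–max intensity normalization.
- **First-order statistics** — intensity histograms (bin 0.01);
  Laplacian-of-Gaussian local contrast,
  `LoG(x,y) = (1/πσ⁴)(1 − (x²+y²)/2σ²) exp(−(x²+y²)/2σ²)` at
  σ = 5, 10, 20, 40 px; maximum-likelihood fits of the two-parameter Weibull
  distribution to contrast magnitudes (scale β = width, shape γ =
  peakedness; smaller γ means a heavier tail, i.e. more strong edges).
- **Patch statistics** — circular-patch (radius 30 px) RMS contrast
  `C_RMS = σ/μ`, local skewness/kurtosis/entropy maps, chromatic contrast
  `C = C_RMS^UV − C_RMS^Green` with separate Weibull fits to its two sides.
- **Second-order statistics** — 2-D power spectra `S = F·F*`, log-log
  power-law fits `b/ω^a` to the axis slices `S(ω_x, 0)` and `S(0, ω_y)`,
  and spatial autocorrelation via the Wiener–Khinchin theorem
  (`R = IFFT[S]`, normalized so R(0,0) = 1) with representative values at
  50-px displacements.
- **Comparisons** — per-scene paired sign tests between channels and
  rank-sum tests between the two sides of the chromatic contrast
  distribution, grouped by upper/lower visual field, with star annotation
  at p < 0.05 / 0.01 / 0.001.
- **Synthetic scenes** — a generator of registered two-channel scene pairs
  with tunable 1/ω^a spectra, sky/ground intensity structure, vignetting,
  channel misalignment, ND/exposure scaling, sensor noise and 12-bit
  quantization, with full ground truth for validation.

## Worked example

```r
library(uvscene)

# How many photons does a mouse cone catch in daylight, and how finely
# does the cone mosaic sample the world?
geom <- mouseEyeGeometry(1e7)          # dim end of daylight, photons/um^2/s
photoreceptorPhotonFlux(geom)          # 19531.25 photons/photoreceptor/s
angularSamplingResolution(12400, 4)    # 0.257 degrees per cone spacing

# A synthetic upper-field scene: strong sky/object contrast in UV,
# washed-out contrast in green.
p  <- sceneSimParams(heightPx = 256, widthPx = 256, seed = 42,
                     bimodalSeparation = c(0.7, 0.25),
                     vignetteStrength = 0.2, spNoiseFraction = 0.002)
sp <- makeScenePair(p)
md <- new("SceneMetadata", stem = "demo", elevation = "up",
          exposureS = 0.01, ndOd = 1)
pair <- preprocessScene(sp$rawUv, sp$rawGreen, sp$reference, metadata = md)
pair
#> ScenePair 'demo' (up): 256 x 256 px, 0.006 deg/px, 100.0% valid, raw

st <- computeSceneStats(pair, pipelineConfig(patchStride = 2L))
subset(st, parameter %in% c("weibull_gamma_s10", "acf_50_0"))[, 1:5]
#>  scene category channel         parameter     value
#>   demo       up      UV weibull_gamma_s10 0.8298817
#>   demo       up   Green weibull_gamma_s10 1.1413684
#>   demo       up      UV          acf_50_0 0.8806752
#>   demo       up   Green          acf_50_0 0.8219121
```

The Weibull shape γ is smaller in UV (0.83 vs 1.14): the UV contrast
distribution is heavier-tailed, i.e. the UV channel of this sky scene
carries more strong local edges. The autocorrelation at a 50-px horizontal
displacement is higher in UV (0.88 vs 0.82): UV structure is also more
spatially extended. Run `runPipeline()` over a batch of scenes to get these
parameters per scene plus the sign-test summary table (`comparisons.csv`
and a markdown report).

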