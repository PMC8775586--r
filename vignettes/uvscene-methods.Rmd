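---
title: "Methods: image statistics for dichromatic UV/green scenes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image statistics for dichromatic UV/green scenes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvscene)
```

# The scientific setting

A dichromatic retina samples the world through two spectral channels. In
the mouse, UV-sensitive cones dominate the ventral retina (viewing the
upper visual field) and green-sensitive cones the dorsal retina (lower
field). Testing whether this layout is matched to the environment requires
the statistics of natural scenes measured separately per spectral band and
per visual field: intensity distributions, local contrast, and the
second-order structure (power spectra and spatial correlations) that
efficient-coding arguments are built on.

`uvscene` implements that measurement pipeline for registered pairs of UV
and green images, plus a spectral model of the photoreceptors and camera,
and a synthetic scene generator that provides ground truth for every stage.

# Spectral model

Photoreceptor absorbance is modelled with the A1 visual pigment nomogram
(alpha band), parameterized only by the peak wavelength; mouse S- and
M-opsins use peaks of 360 and 508 nm. Ocular media absorb short
wavelengths preferentially, so effective sensitivity is the pointwise
product of the absorbance curve and a transmittance spectrum, renormalized
to peak 1. The same composition describes a camera channel: optics
transmission times sensor quantum efficiency. Although such compositions
are sometimes loosely described as "convolving" the curves, the physically
meaningful operation for transmission chains is the pointwise spectral
product, and that is what `applyTransmittance()` and
`channelSensitivity()` compute. Curves on different grids are linearly
interpolated onto the union grid restricted to the common support; disjoint
supports are an error.

`peakAndHwhm()` summarizes a band by the wavelength of its maximum and its
half-width at half maximum, interpolating the half-maximum crossings
linearly between samples. On a plateau the lowest wavelength attaining the
maximum is reported (a deterministic tie-break); if one flank never falls
to half maximum the one-sided width is returned with a flag rather than
failing.

Two closed-form physiological estimates are included. The photon flux on a
photoreceptor is
$\Phi \cdot A_{pupil}/A_{retina} \cdot T \cdot A_{photoreceptor}$ with
$A_{pupil} = \pi (d_{pupil}/2)^2$ and
$A_{retina} = 4\pi(d_{eye}/2)^2/2$ (the retina lines half the eye ball);
with the mouse defaults (pupil 0.5 mm, eye 4 mm, transmittance 0.5,
collection area 0.5 µm², daylight flux $10^7$–$10^9$ photons/µm²/s) this
gives order $10^4$–$10^6$ photons/photoreceptor/s. The angular sampling
resolution of a mosaic of density $\rho$ is the angle subtended by one
lattice spacing $1/\sqrt{\rho}$ at the posterior nodal distance
$d_{eye}/2$,
$\theta = (180/\pi)\,(1/\sqrt{\rho})/(d_{eye}/2)$. We use this
dimensionally consistent form — the spacing of a planar mosaic of density
$\rho$ is $1/\sqrt{\rho}$, not $1/\rho$ — which reproduces the standard
~0.25° figure for the mouse cone mosaic (12,400 cells/mm²) and ~0.04° for
rods (437,000 cells/mm²).

# Preprocessing

Raw captures are 12-bit data in 16-bit grayscale PNG. The chain is fixed
as: flat-field vignetting correction, 3×3 median filter, projective
registration of UV onto the green grid, crop. Normalization happens at
analysis time.

Choices the data do not dictate, and what we chose:

* **Median-filter borders.** Reflect (edge-replicating) padding, so the
  image size is preserved; the filter itself is an exact min/max exchange
  network equal to a sort-and-pick median at every pixel.
* **Warp interpolation.** Bilinear by default (nearest-neighbour available
  for exactness tests). Pixels that map outside the source frame are
  tracked in a validity mask and excluded by cropping — never filled —
  so no synthetic values enter the statistics.
* **Registration.** Least-squares homography from control points by the
  normalized direct linear transform, followed by a geometric refinement
  that minimizes summed squared reprojection error. With 12 control points
  jittered by 0.5 px the mean reprojection error over the frame is well
  under 1 px.
* **Reference images.** A per-channel flat-field reference is used when
  supplied, otherwise one shared reference.
* **Acquisition corrections.** The relative-intensity profiles divide by
  exposure time (the sensor is linear) and undo the absorptive
  neutral-density attenuation as $10^{OD}$.
* **Coordinates.** 0-based (x, y) pixel coordinates for points and
  homographies; half-open crop rectangles; (row, col) = (y, x) for
  matrices.

Min–max normalization maps each channel independently to [0, 1],
modelling adaptation of visual sensitivity to each scene's range; a
constant channel is an error rather than a silent zero-divide.

# First-order statistics

Local contrast is the response to a Laplacian-of-Gaussian filter
$$\mathrm{LoG}(x,y) = \frac{1}{\pi\sigma^4}\Bigl(1 -
\frac{x^2+y^2}{2\sigma^2}\Bigr)\,e^{-(x^2+y^2)/2\sigma^2}$$
sampled at integer offsets on $[-3\sigma, 3\sigma]$, at
$\sigma = 5, 10, 20, 40$ px (0.18°–1.44° at the default 0.006°/px pitch).
The sampled kernel does not sum exactly to zero, so it is mean-subtracted;
this makes constant and affine images map exactly to zero contrast, which
the tests rely on. Convolution uses the valid region only (no padding), so
image borders contribute no spurious contrast. Scale invariance of natural
scenes appears operationally: the $\sigma$ response on a 2× downsampled
image correlates > 0.9 with the $2\sigma$ response on the original.

Contrast magnitudes are fitted with the two-parameter Weibull distribution.
We report the canonical scale–shape parameterization
$f(x) = (\gamma/\beta)(x/\beta)^{\gamma-1}e^{-(x/\beta)^\gamma}$, in which
a larger $\beta$ is a wider distribution and a smaller $\gamma$ a heavier
tail — the reading under which "higher contrast" has its intuitive sign.
The equivalent rate form $w(x) = \beta'\gamma x^{\gamma-1}e^{-\beta' x^\gamma}$
is reported alongside via $\beta' = \beta^{-\gamma}$, because the rate
convention also appears in the literature and the conversion is easy to
get wrong silently. Fitting is maximum likelihood with a profile over the
shape: for fixed $\gamma$ the conditional scale MLE is
$\hat\beta = (\mathrm{mean}(x^\gamma))^{1/\gamma}$ in closed form, and the
profile likelihood is maximized over $\log\gamma \in [\log 0.01, \log 100]$
by golden-section search. We fit absolute contrast values by MLE (rather
than histogram regression, and rather than signed values); structural
zeros — LoG responses on perfectly flat regions — are excluded and
counted. All-equal samples are a degenerate likelihood and an error.

# Patch and chromatic statistics

RMS contrast is $\sigma/\mu$ over a discrete circular patch (all integer
offsets with $dx^2+dy^2 \le r^2$, radius 30 px ≈ 0.36° diameter),
evaluated at every centre whose full patch is inside the image. Moments are
population moments — a patch is an exhaustive pixel set, not a sample —
and kurtosis is not excess (a Gaussian patch gives ≈ 3). Patch entropy
uses 64 uniform bins on [0, 1] and log base 2; both are conventions the
source data do not pin down, so they are configurable and documented.
A patch whose mean falls below $10^{-6}$ after normalization would make
$\sigma/\mu$ meaningless; such centres are marked invalid and counted.

Chromatic contrast is the pointwise difference of the two channels' RMS
maps, $C = C^{UV}_{RMS} - C^{Green}_{RMS}$; it is antisymmetric under
channel swap by construction. Its distribution is summarized by separate
Weibull fits to the magnitudes of the $C<0$ and $C>0$ sides (zeros
excluded, side counts reported); an asymmetry between side fits is the
signature of one channel dominating local contrast.

# Second-order statistics

The power spectrum is $S = F F^*$ with $F$ the unnormalized 2-D FFT,
DC-centred, frequencies in cycles/pixel on $(-0.5, 0.5]$. The default
"as-printed" mode applies no window, detrending or mean subtraction.
Power-law structure is measured on the positive-frequency halves of the two
central slices $S(\omega_x, 0)$ and $S(0, \omega_y)$ by ordinary least
squares of $\log_{10} S$ on $\log_{10}\omega$ over all positive-frequency
bins up to Nyquist with equal weight per FFT bin; $R^2$ is reported so a
user can restrict the range. The slope is reported as the positive
exponent $a$ of $b/\omega^a$ and the intercept as the *raw* power $b$ at
1 cycle/pixel (reports print $\log_{10} b$); zero-power bins are dropped
and counted. Non-square images keep their own frequency grids.

The spatial autocorrelation follows the Wiener–Khinchin theorem:
mean-subtract, transform, square, inverse-transform. This is the circular
(periodic) autocorrelation — the pure-FFT route implies it — and we
normalize by the zero-lag value so the map holds correlation coefficients
with $R(0,0)=1$, dimensionless and comparable across scenes of different
sizes and variances. Mean subtraction and normalization are flagged in the
object so the convention is auditable. Per scene, the values at
displacements (50, 0) and (0, 50) pixels summarize correlation width for
the comparison stage.

# Channel comparisons

Within each visual-field category (upper/lower; horizontal scenes are
excluded from hypothesis tests but retained for intensity profiles), each
parameter is compared between channels with a paired, two-sided exact sign
test (exact zeros dropped, classical convention; fewer than 5 informative
pairs is flagged underpowered). The left/right chromatic side fits are
compared with a two-sided Wilcoxon rank-sum test: exact enumeration when
both groups have ≤ 10 untied values, otherwise the normal approximation
with tie and continuity corrections. Stars mark p < 0.05/0.01/0.001 with
strict inequalities. No multiple-testing correction is applied by default,
mirroring per-panel reporting conventions; per-scene correlation values
enter the sign test untransformed (a Fisher transform would not change the
signs of paired differences and hence not the test).

# The synthetic scene generator

`makeScenePair()` inverts the preprocessing model: clean per-channel
fields with known spectral exponent (white noise shaped to
$1/\omega^a$ amplitude in the frequency domain, DC removed since
$1/\omega^a$ diverges there, then mapped affinely to [0, 1]); an intensity
transform — either a two-mode sky/object composite through a smoothed
random horizon mask, or a convex remap ($u^3$) producing the right-skewed
unimodal distributions typical of ground vegetation; a projective
misalignment applied to the green channel; a shared smooth radial
vignette; exposure scaling and green-channel ND attenuation
$10^{-OD}$; 12-bit quantization (round-to-nearest after clipping, with the
clipped fraction recorded because over-exposure is a data-quality
criterion for real captures); and salt-and-pepper impulse pixels. One
global seed fans out to fixed per-stage substreams, so each stage is
individually reproducible.

The generator emulates the *statistical* structure the analysis assumes —
spectral falloff, bimodal/skewed intensities, channel misalignment, sensor
degradations — and deliberately not the appearance of real vegetation or
sky: no chromatic correlation structure beyond a shared horizon mask, no
depth-of-field or atmospheric effects, no real opsin-weighted radiometry.
Passing tests on synthetic batches therefore validate the estimators and
the pipeline plumbing, not any biological claim about real scenes; claims
about real scenes require real registered image pairs, which the package
reads but does not ship.

A per-channel `bimodalSeparation` reproduces, on demand, the canonical
upper-field pattern: a channel with stronger sky/object separation shows a
heavier-tailed contrast distribution (smaller $\gamma$), a larger
power-spectrum intercept, wider spatial correlation, and a right-heavy
chromatic contrast distribution. With equal parameters in both channels
the generator provides an exact null for calibrating the test battery.

# Numerical choices and problem sizes

* FFT convolutions are exact to ~$10^{-13}$ relative; equality tests
  against brute-force oracles (median network, circular autocorrelation,
  disk membership) use $10^{-10}$ absolute tolerances.
* The Weibull profile search uses a $10^{-10}$ tolerance on
  $\log\gamma$; the grid-search cross-check uses a 200×200 log-spaced
  grid and agreement is required within grid resolution.
* Quantization in the generator is round-to-nearest after clipping, which
  keeps the flat-field round trip within one digital number for corner
  falloff up to ~50% — floor-style truncation would double that error.
* Validation sizes are chosen to make sampling error small relative to the
  tolerances while keeping the default test run fast: spectral-slope
  recovery uses ten 512² fields per exponent (±0.1), Weibull recovery
  $10^5$ draws (±2%), the directional batch twelve 256² scenes with the
  full σ set, and the null calibration fifty replicates of twelve 160²
  scenes with σ ∈ {5, 10} (at that image size the σ = 40 kernel would
  leave almost no valid convolution region, and two scales suffice for a
  type-I-error check across the parameter battery).

# Known limitations

* The bundled spectral curves are labelled synthetic stand-ins (Gaussian
  channel bands, smooth QE ramp); real measured optics and transmittance
  tables must be supplied by the user, and the few-nm red shift of the
  S-cone peak under ocular media is therefore checked directionally, not
  to a reference value.
* The autocorrelation is circular; a zero-padded linear variant is not
  currently exposed.
* Registration assumes user-supplied (or simulated) control points; there
  is no automatic feature matching, lens-distortion model, or focus-based
  auto-cropping.
* Entropy bin width, log base, and the power-law fit range are
  conventions, not measurements; all are configurable and recorded in
  outputs.
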