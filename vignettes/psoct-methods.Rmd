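---
title: "Reconstruction and stromal texture analysis in conically scanned PS-OCT: models, parameters, numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstruction and stromal texture analysis in conically scanned PS-OCT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psoct)
```

This vignette is the package's account of the science it implements:
the forward model behind the phantom simulator, the processing chain
and its assumptions, the parameters that matter, the numerical choices,
and what the desk-scale validation does and does not demonstrate about
instrument data.

## The problem

Spectrometer-based (spectral-domain) OCT measures, per lateral
position, a spectral interferogram $I(k)$; its Fourier transform along
the wavenumber $k = 2\pi/\lambda$ yields a depth profile (A-scan). A
conical scan keeps the beam nearly perpendicular to the curved cornea,
so the entire cornea fits in the depth range — at the price of sending
the beam through a different glass path of the aspheric condenser lens
at every scan angle. The resulting *scan-position-dependent* dispersion
mismatch broadens the axial point spread function (PSF) away from the
scan center and cannot be fixed by a single global correction. The
polarization-sensitive (PS) detection adds a second spectrometer: the
co-polarized channel sees polarization-preserving backscatter (surfaces,
most interfaces), the cross-polarized channel the polarization-altering
share (stromal collagen lamellae), and the two spectrometers are never
pixel-to-pixel identical, so each needs its own wavelength calibration.

## Forward model of the phantom

The simulator produces raw fringes with the standard weak-scatterer
Fourier-domain forward model, per channel and per A-scan:

$$
I(p) \;=\; S(k_p)\Big[\,\mathrm{DC} + \textstyle\sum_j 2 a_j
\cos\!\big(2 k_p z_j + a_2 (k_p - k_0)^2 + a_3 (k_p-k_0)^3\big)\Big]
\;+\; F(p) \;+\; \varepsilon(p),
$$

with $S$ a Gaussian source envelope (840 nm center, 100 nm FWHM by
default), $k_p$ the channel's nonlinear pixel-to-wavenumber mapping
(a smooth polynomial in pixel index; the two channels differ in their
nonlinear term), $z_j$ the optical-path depths of the reflectors,
$F$ a per-B-scan static spectral pattern (fixed-pattern noise) and
$\varepsilon$ white Gaussian noise. Sample–sample interference
(autocorrelation terms) is omitted: corneal reflectivities are weak and
the processing chain never addresses such terms. The units convention:
$k$ in rad/µm, depths in µm of optical path, and $a_2$ in
rad/(rad/µm)², i.e. phase per squared wavenumber deviation from the
center wavenumber $k_0$.

The conical geometry is simulated through its *consequences* only: a
near-constant surface depth with a slow lateral ripple, a per-B-scan
axial motion term, and a smooth polynomial $a_2(x)$ across the scan
(default $a_2(t) = 2 + 16t^2 + 3t^3$ on $t \in [-1,1]$, i.e. mild
dispersion at the center rising to ~15–21 rad/(rad/µm)² at the scan
edges — enough to broaden the peripheral PSF well over twofold when
only a single central correction is applied). Ray tracing of the scan
optics is out of scope.

Two non-obvious ingredients deserve a note:

* **Surface micro-roughness.** The phantom surface carries a 0.3 µm rms
  per-A-scan jitter — far below a depth pixel. Without it, a perfectly
  smooth constant-depth surface produces *identical* fringes across a
  B-scan and the mean-spectrum subtraction would annihilate the surface
  signal itself, which never happens with real tissue because speckle
  and micro-roughness decorrelate the fringe phase. With desk-scale
  B-scans (tens to a few hundred A-scans) the subtracted sample mean
  still contains a random $\sim 1/\sqrt{N}$ fraction of the correlated
  fringe, which modulates per-A-scan peak heights by several percent —
  a finite-$N$ effect that vanishes at the instrument's 1024 A-scans
  per B-scan. Width-based quantities (PSF FWHM) are insensitive to it.
* **Spectral truncation.** The default spectrometer span is 114 nm for
  a 100 nm-FWHM source, so the Gaussian tails are clipped. This is the
  realistic regime — and it matters: the clipped spectrum's effective
  width is smaller, so a given $a_2$ broadens the PSF less than the
  Gaussian closed form predicts, and the PSF acquires sidelobes (no
  spectral shaping is applied anywhere in the chain). The sampled
  (numerical) relation is used wherever the broadening matters, e.g.
  for the default search range (`a2_for_broadening_sampled()`). With
  this geometry the dispersion-free magnitude-PSF FWHM evaluates to
  ~4.2 µm in air, consistent with the class of instrument emulated,
  against ~3.1 µm for the untruncated Gaussian closed form (the
  resolution quoted for a Gaussian source of this bandwidth).

### Stromal texture

The cross-polarized stroma is modeled as *sparse bright structures on a
dark background*: a Gaussian-correlated random field (white noise
convolved with a Gaussian kernel on the torus — exactly stationary) of
which only the upper tail scatters. Three depth laws, all in fractional
stromal depth $u \in [0,1]$, encode what is seen in cross-polarized
en-face imagery of healthy corneas: structure size (lateral correlation
length) grows from 15 to 120 µm as $u^2$; structure density falls (the
zeroed quantile rises linearly from 0.80 to 0.92); and the amplitude
decays 2.5-fold. A dense speckle field was deliberately *not* used:
for a dense positive image the raw (non-mean-subtracted) normalized
autocorrelation is dominated by a near-constant plateau
$\approx (\mathbb{E}I)^2/\mathbb{E}I^2$ across the whole integration
window, and the IACF becomes insensitive to correlation length. The
sparse-structure model reproduces both reported behaviors: the IACF
*decrease* with depth (density loss) and the subsequent *increase*
(structure growth), with the integrated intensity falling
monotonically as a control.

## The processing chain

**Calibration.** Auxiliary-interferometer fringes
$S(k)\cos(2kz_\mathrm{delay})$ are recorded per channel on the native
pixel grid. The analytic-signal phase is unwrapped, fitted with a
3rd-order polynomial over the well-modulated region (envelope above 5%
of its maximum; the fit extrapolates to the edges), converted via
$k(p) = \phi(p)/(2z_\mathrm{delay})$, and anchored absolutely by
placing the envelope peak (sub-pixel, log-parabolic) at the nominal
center wavenumber. On simulated fringes the recovered mappings agree
with ground truth to a few times $10^{-5}$ relative over the central
90% of pixels. All spectra are then cubic-spline interpolated onto one
uniform grid contained in the intersection of both channels' supports
(grid length = pixel count, no zero padding at this stage; linear
interpolation available as a config switch).

**Preprocessing.** Per B-scan and channel, the mean spectrum over
A-scans is subtracted — removing the DC term and any static spectral
pattern exactly, by linearity.

**Dispersion compensation.** Per A-scan of the co-polarized channel:
Hilbert transform to the analytic spectrum, multiply by
$\exp\!\big(i\,a_2 (k-k_0)^2\big)$, FFT the real part (zero-padded to
the next power of two at least twice the grid length), and score the
candidate $a_2$ by the A-scan's peak intensity, excluding the 10
depth pixels nearest zero delay (a residual-DC guard; the paper-stage
default of 200 equally spaced candidates is kept). The per-A-scan
argmaxima are fitted with a 5th-order polynomial in A-scan index, and
the *fitted* values generate the final images of both channels — the
cross channel is never searched, per the transfer rule (the raw optima
are retained for diagnostics). A third-order term can be searched
behind a flag but is off by default; its optimum is approximately zero
for this system class. Ties in the metric break toward the smallest
$|a_2|$ (minimal-correction prior); if half the A-scans saturate the
search boundary a warning reports a misconfigured range. The stored
coefficient is the *applied compensation* value, so recovering the
profile means matching the negative of the simulator's forward
coefficient.

**Flattening.** The surface is the shallowest local maximum (3-pixel
neighborhood) above 0.3 of the A-scan maximum, searched below a
20-pixel DC-exclusion zone, with a contrast gate (maximum must exceed
20 times the A-scan median) that flags signal-free A-scans invalid
rather than returning a noise peak. Alignment is integer-pixel (no
sub-pixel interpolation: intensity fidelity is preferred over
smoothness); invalid A-scans inherit the nearest valid surface along
the fast axis, and more than 10% invalid aborts. Repeated B-scans at
one location (B-M-mode) flow through the same path and are averaged
arithmetically after alignment. Lateral motion is not corrected.

**IACF.** Per en-face plane of the flattened cross-polarized volume:
threshold (below → 0), zero outside the centered circular ROI (default
4.2 mm at 11 µm/pixel), raw 2D autocorrelation over zero-padded
(non-circular) lags via FFT, normalize by the zero-lag value, zero the
central point, and sum over the square window $|\Delta x|, |\Delta y|
\le 30$ px. No mean subtraction is applied before autocorrelation:
thresholding already zeroes the background, and circular wrap-around
would couple opposite ROI edges. The default threshold is the 99.5th
percentile of a signal-free deep plane, chosen so that only a few
isolated noise pixels survive where no signal is expected; a fixed
multiple of the noise median was rejected because under speckle
statistics (exponential intensity) three times the median still passes
about a quarter of pure-noise pixels. The integrated ROI intensity is
reported alongside as the control curve. Known artifact behavior is
documented, not suppressed: a strong specular-reflex plane yields a
large connected bright region and hence an inflated IACF.

## Numerical choices

* **Peak metric refinement.** The search metric reads the peak on the
  2× padded depth grid with *log-parabolic interpolation* across the
  maximum bin. Without it, scalloping of the discrete peak height
  biases the argmax by up to ~2 of the 200 search steps, depending on
  the sub-pixel depth of the reflector; with it the search reaches the
  grid-quantization limit (±half a step).
* **Sidelobe symmetry**, the classic visual indicator of successful
  compensation, is only meaningful on a densely sampled PSF: at 2×
  padding the sidelobe *maxima* themselves scallop by 5–25%. The
  validation measures them on a 16×-padded magnitude A-scan, where
  post-compensation asymmetry is ~1–2%.
* **Phase-correction round trip.** Applying $+a_2$ then $-a_2$ through
  the real-part path is exact only in the continuum; the discrete
  analytic-signal reconstruction leaks a small fraction (~0.5% per
  coefficient at moderate $a_2$) of the windowed chirp kernel's tails.
  The pipeline applies the phase once, so this is a property of the
  validation suite, not of the images.
* **FWHM convention.** Axial resolution is measured as the FWHM of the
  *magnitude* A-scan (square root of intensity), interpolated linearly
  at the half-maximum crossings. Ratios (restoration within 5%,
  degradation > 2×) are insensitive to the convention.
* **Depth axes.** With spectra on a uniform grid of spacing
  $\delta k$ and FFT length $L$, depth bin $m$ sits at
  $\pi m /(L\,\delta k)$ µm of optical path; tissue depth divides by
  the group index 1.385. The same conversion (2.96 µm from 4.1 µm
  in air) applies to the resolution.
* **Degenerate inputs.** Single-A-scan B-scans warn (mean subtraction
  is degenerate); all-zero ROIs make the normalized autocorrelation
  undefined and raise an error, while the profile wrapper reports
  IACF = 0 for planes where nothing survives the threshold — the
  natural limit for signal-free depths.

## Validation scale and what it shows

The test suite and the acceptance script run everything at desk scale,
chosen to keep the full suite within minutes on one core: 1024-pixel
spectrometers (2048 is the instrument default), B-scans of 32–256
A-scans, volumes up to 12 × 32 A-scans for motion/flattening checks,
texture stacks of 384 × 384 pixels × 16–23 planes at the real 11 µm
pitch and 4.2 mm ROI, and Monte-Carlo loops of 5–20 seeds. The 2000-step
brute-force search oracle runs on one 256-A-scan B-scan.

Passing these checks demonstrates that the *chain* is correct on data
whose generative model is known exactly: mappings are recovered,
dispersion profiles are recovered and transferred, motion is removed,
and the IACF tracks the texture statistics built into the phantom. It
does not demonstrate robustness to everything real corneas add —
speckle statistics beyond the sparse-structure model, depth-dependent
signal decay and shadowing, lateral motion, specular reflexes (whose
IACF inflation is expected and documented), or pathology. The phantom
also omits confocal gating and sensitivity roll-off beyond a simple
attenuation option, and the simulator's correlation-length and density
laws are plausible choices, not measurements.

## Persistence

Volumes and results persist as RDS; images export as multi-page TIFF
(float linear and 8-bit log-scaled views), the IACF profile and
per-B-scan dispersion profiles as CSV, and a JSON provenance record
(seed, geometry, search configuration, threshold, package version)
accompanies every bundle written by `run_pipeline()`.
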