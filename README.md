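# psoct

Post-processing for ultrahigh-resolution **polarization-sensitive
spectral-domain OCT** of the cornea, with a synthetic phantom that makes
the whole chain testable without instrument data.

Conically scanned corneal OCT keeps the beam nearly perpendicular to the
curved surface, so the whole cornea stays in the depth range — but the
aspheric scan optics introduce a *scan-angle-dependent* dispersion
mismatch that blurs the axial point spread function away from the scan
center. This package implements the numerical chain that deals with
that, stage by stage:

1. **k-space calibration** — each of the two polarization spectrometers
   gets its own pixel-to-wavenumber rescaling function, derived from
   auxiliary Michelson fringes (`derive_mapping()`), and all spectra are
   resampled onto one common uniform grid in k = 2π/λ
   (`resample_to_k()`), so a common reflector lands on the same depth
   pixel in both channels.
2. **DC / fixed-pattern removal** — the mean spectrum of all A-scans of
   a B-scan is subtracted from each spectrum
   (`subtract_mean_spectrum()`).
3. **Variable dispersion compensation** — per A-scan, a quadratic
   (in wavenumber) phase `a2 (k − k0)²` is added to the analytic
   spectrum; `a2` is searched over 200 values, keeping the value that
   maximizes the A-scan peak intensity; the per-A-scan optima are
   smoothed by a 5th-order polynomial in A-scan index, and the fitted
   coefficients are applied to both channels (searched on the
   co-polarized channel only; `compensate_bscan()`).
4. **Surface flattening** — the corneal surface is found per A-scan by
   peak detection and all A-scans are aligned to it, which also removes
   axial eye motion (`detect_surface_map()`, `flatten_volume()`).
5. **IACF texture analysis** — en-face images of the cross-polarized
   channel are thresholded, restricted to a central circular region
   (default 4.2 mm), autocorrelated in 2D, normalized by the zero-lag
   value, center-eliminated, and integrated over a central lag window
   (±30 px at 11 µm/px): the *integrated autocorrelation factor*, a
   depth-resolved proxy for stromal texture feature size
   (`iacf_depth_profile()`).

A layered corneal phantom simulator (`simulate_volume()`,
`texture_volume()`) provides ground truth for every stage: known
pixel-to-wavelength mappings, a smooth polynomial `a2(x)` profile,
per-B-scan axial motion, and a stromal texture whose structure size
grows and density falls with depth.

## Worked example

Calibrate, simulate a 256-A-scan phantom B-scan with scan-dependent
dispersion, and recover the compensation profile:

```r
library(psoct)
src  <- source_spectrum()                       # 840 nm, 100 nm FWHM
sps  <- list(co    = spectrometer_model(1024, "co"),
             cross = spectrometer_model(1024, "cross"))

# 1. calibrate: pixel-to-wavenumber mappings from Michelson fringes
fr  <- simulate_calibration_fringes(sps, mirror_delay_um = 450, src)
cal <- calibration_map(list(co    = derive_mapping(fr$co, 450),
                            cross = derive_mapping(fr$cross, 450)))

# 2. one phantom B-scan with dispersion varying across the scan
raw <- simulate_volume(phantom_spec(), dispersion_truth(),
                       geometry = list(n_bscans = 1, n_ascans = 256),
                       source = src, spectrometers = sps, seed = 1)

# 3. preprocess + variable dispersion compensation
co    <- subtract_mean_spectrum(resample_to_k(raw$co[1, , ],    cal, "co"))
cross <- subtract_mean_spectrum(resample_to_k(raw$cross[1, , ], cal, "cross"))
cfg <- dispersion_search_config(source = src, k = cal$k_grid)
res <- compensate_bscan(co, cross, cal$k_grid, cfg)

step <- diff(cfg$a2_range) / (cfg$n_steps - 1)
cat(sprintf("search grid: %d steps of %.3f rad/(rad/um)^2 over [%.1f, %.1f]\n",
            cfg$n_steps, step, cfg$a2_range[1], cfg$a2_range[2]))
cat(sprintf("max |fitted - (-truth)|: %.3f  (%.2f grid steps)\n",
            max(abs(res$profile$fitted + raw$truth$a2)),
            max(abs(res$profile$fitted + raw$truth$a2)) / step))
cat(sprintf("axial resolution: %.2f um in air -> %.2f um in tissue (n = 1.385)\n",
            4.1, resolution_in_tissue(4.1)))
```

Printed output:

```
search grid: 200 steps of 0.265 rad/(rad/um)^2 over [-26.4, 26.4]
max |fitted - (-truth)|: 0.381  (1.44 grid steps)
axial resolution: 4.10 um in air -> 2.96 um in tissue (n = 1.385)
```

The recovered per-A-scan compensation coefficients (sign-flipped
relative to the simulated sample dispersion) match the ground-truth
profile to within ~1.4 steps of the 200-value search grid; the
measured 4.1 µm in-air axial resolution corresponds to 2.96 µm inside
the cornea (refractive index 1.385).

`run_pipeline(pipeline_config(...))` chains all stages — simulate,
calibrate, reconstruct, flatten, analyze — and optionally writes
TIFF tomograms, the IACF profile as CSV, per-B-scan dispersion profiles
and a JSON provenance record. A thin command-line wrapper is installed
at `inst/scripts/psoct` (`simulate`, `run-all`, `iacf` subcommands).

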