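# optomap

Multiparametric analysis of cardiac optical-mapping recordings in R.

Optical mapping (optocardiography) images heart tissue stained with a
voltage-sensitive dye and a calcium indicator; a dual-camera tandem-lens
system records two synchronized fluorescence movies — typically 100 × 100
pixels at 1 kHz — of a paced, propagating excitation wave. `optomap` turns
those movies into the quantities cardiac electrophysiologists report:

* per-pixel **activation maps** (max-slope or 50%-crossing detectors, both
  with sub-frame interpolation) and Hilbert-transform **phase movies**;
* **APD80 / CaTD80** — action potential or calcium-transient duration from
  activation to 80% repolarization;
* **rise time** — 20% → 90% upstroke interval;
* **Tau** — calcium decay rate constant (s⁻¹) from a log-linear fit,
  exact on single exponentials;
* **conduction velocity** by the Bayly method — local polynomial surfaces
  `T(x, y)` fitted to the activation map, velocity `v = ∇T / |∇T|²`, reduced
  to longitudinal/transverse sector medians CV_L, CV_T and the anisotropy
  ratio AR = CV_L / CV_T;
* signal conditioning (spatial/zero-phase temporal smoothing, polynomial
  drift removal, amplitude normalization, SNR masking), dual-camera
  co-registration with an alignment score, and a two-group Student's t
  comparison for treatment studies.

A seeded synthetic generator (`simulate_recording()`) produces dual-channel
recordings of anisotropically propagating waves from piecewise
linear/exponential templates whose metrics have closed forms, with exact
per-pixel ground truth — so every estimator in the package is validated
end-to-end against known truth. Movies interchange as multipage 16-bit TIFF
or raw u16 binary plus a JSON calibration sidecar.

See `vignettes/optomap-methods.Rmd` for the full methods description.

## Worked example

Simulate a noiseless paced wave on a 50 × 50 grid (1 kHz, 0.2 mm pixels,
basic cycle length 150 ms, control-condition templates), then recover its
parameters:

```r
library(optomap)

cfg <- simulation_config(grid = c(50, 50), n_beats = 2,
                         stimulus_site = c(25, 25),
                         noise_sd_voltage = 0, noise_sd_calcium = 0, seed = 1)
rec <- simulate_recording(cfg)
rec$voltage
#> <movie_stack> 310 frames of 50 x 50 (voltage channel, negative polarity)
#>   1 ms/frame (0.31 s, 1000 Hz), 0.2 mm/pixel

# noiseless input: conditioning = polarity correction + normalization
cc <- conditioning_config(spatial_kernel = NULL, temporal_filter = NULL,
                          drift_poly_order = NULL)
v    <- condition_movie(rec$voltage, cc)
mask <- build_mask(v, cc)

parameter_map(v, mask, "duration", params = list(level = 0.8))
#> <parameter_map> duration [ms], 50 x 50 (2500 valid)
#>   range 68.23 .. 68.23, mean 68.23

ca <- condition_movie(rec$calcium, cc)
parameter_map(ca, build_mask(ca, cc), "decay_rate")
#> <parameter_map> decay_rate [s^-1], 50 x 50 (2500 valid)
#>   range 32.78 .. 32.78, mean 32.78

act <- parameter_map(v, mask, "activation_time",
                     params = list(act_method = "level_crossing"))
fld <- velocity_field(act, spacing_mm = cfg$pixel_spacing_mm)
cv_summary(fld, fiber_angle = cfg$fiber_angle_rad,
           stimulus_site = cfg$stimulus_site)
#> <cv_summary> CV_L 0.678 m/s (n=45), CV_T 0.310 m/s (n=1134), AR 2.19, axis 0.0 deg
```

The APD80 and Tau maps reproduce the configured template values exactly
(68.23 ms, 32.78 s⁻¹); the Bayly sector medians recover the configured
speeds (0.67 and 0.30 mm/ms) to within a few percent on this small grid —
the residual spread comes from fitting quadratic surfaces to an elliptical
wavefront, and shrinks with distance from the pacing site.

Two-group comparison from published-style summaries (mean ± SE, n):

```r
group_compare(list(mean = 68.23, se = 1.67, n = 4),
              list(mean = 44.04, se = 5.54, n = 4))
#> <group_stats> 68.23 +/- 1.67 (n=4) vs 44.04 +/- 5.54 (n=4)
#>   t = 4.181, df = 6, p = 0.00581 (significant at 0.05)
```

A thin command-line driver wraps the same functions:

```sh
Rscript inst/cli/optomap.R simulate --config sim.yaml --out data/
Rscript inst/cli/optomap.R run --config pipeline.yaml
Rscript inst/cli/optomap.R compare --a 68.23,1.67,4 --b 44.04,5.54,4
```

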