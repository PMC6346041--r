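---
title: "Multiparametric optical-mapping analysis with optomap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiparametric optical-mapping analysis with optomap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

Cardiac optical mapping images the electrical activity of heart tissue with
fluorescent indicators: a voltage-sensitive dye (e.g. RH237) reports the
transmembrane potential and a calcium indicator (e.g. Rhod-2) reports the
intracellular calcium transient. A dual-camera tandem-lens system splits the
emitted light (~690 nm voltage, ~590 nm calcium) onto two fast sensors —
typically 100 x 100 pixels at 1 kHz — producing two synchronized movies of a
paced, propagating excitation wave. From those movies electrophysiologists
quantify, per pixel:

* **activation time** — wavefront arrival, mapped over the tissue;
* **rise time (RT)** — upstroke duration from 20% to 90% of amplitude;
* **APD80 / CaTD80** — action potential (calcium transient) duration from
  activation to 80% repolarization (recovery);
* **Tau** — the calcium transient decay rate constant, in s^-1;
* **conduction velocity (CV)** — speed and direction of propagation, and its
  longitudinal/transverse anisotropy.

`optomap` implements this analysis chain as a tested R library plus a thin
command-line driver, together with a synthetic wave generator that carries
exact per-pixel ground truth so every estimator can be validated end to end.

## Data model and conventions

A recording is a `movie_stack`: a `T x H x W` array with `frame_interval_ms`,
`pixel_spacing_mm` (square pixels; anisotropic spacing is rejected at load),
a channel label (`voltage`, `calcium`, `other`) and a polarity. Polarity
`negative` means fluorescence *falls* on the physiological upstroke, as with
RH237 voltage emission; normalization flips it so that downstream code always
sees positive-going signals. Pixels are 0-based with the origin at the top
left and the row index increasing downward; time is measured in ms from the
first frame (frame *k* is at *k*·dt). Interchange formats are open:
multipage 16-bit TIFF or raw little-endian u16 binary, each with a JSON
sidecar holding the calibration (`frame_interval_ms`, `pixel_spacing_mm`,
`shape`, `channel`, `polarity`, `scale`). Readers reject inconsistent
metadata rather than repairing it. Native proprietary camera formats are out
of scope; converting them to the sidecar pair is the user's responsibility.

## Signal conditioning

The default chain, each stage individually configurable or skippable
(`conditioning_config()`):

1. **Spatial smoothing** — 3 x 3 uniform (or Gaussian) kernel per frame,
   mirror padding. Trades spatial resolution for SNR.
2. **Temporal smoothing** — Savitzky-Golay, 7 ms window, cubic (default), or
   a Butterworth low-pass applied forward-backward. Both are zero-phase:
   causal filters would shift every activation time and bias velocity maps.
   The low-pass operates on the mean-subtracted trace so constants pass
   untouched.
3. **Drift removal** — per pixel, a least-squares polynomial (default order
   1, at most 4) over the full trace is subtracted, leaving residuals with
   zero projection onto the trend basis. This targets photobleaching and
   slow baseline wander.
4. **Normalization** — per pixel min -> 0, max -> 1 after polarity
   correction. Zero-range pixels cannot be normalized; they are flagged in
   `meta$invalid_pixels` rather than divided by zero. The operation is
   idempotent on valid pixels.

For noiseless synthetic data the smoothing stages are unnecessary and are
skipped in the package's own validation runs (normalization alone is applied)
so that estimator accuracy is measured, not filter distortion.

The analysis mask (`build_mask()`) admits a pixel when peak-to-peak
amplitude divided by a robust noise estimate reaches a threshold (default
5). Noise is `1.4826 * MAD(diff(trace)) / sqrt(2)`: the first difference
suppresses the (slow) physiological component, the MAD resists outliers, and
the `sqrt(2)` undoes the variance doubling of differencing. Note that the
peak-to-peak amplitude of *pure* Gaussian noise grows like
`2 * sigma * sqrt(2 log T)` (about 6.6 sigma at T = 300), so thresholds must
sit well above that to reject empty background — the mask tests use 20.

Dual-camera co-registration (`register_translation()`) searches integer
translations within a radius for the maximum normalized cross-correlation,
and reports an alignment score: the percentage of overlap pixels whose
Otsu-binarized values agree after shifting. The score is a simple stand-in
for a camera-alignment quality figure; rotation, scaling and sub-pixel shifts
are out of scope because dual-camera rigs are aligned mechanically.

## Beat segmentation and waveform kinetics

`segment_beats()` detects upward mid-level crossings separated by at least
`min_cycle_ms` (default 100 ms; pacing at a 150 ms basic cycle length gives
comfortably separated beats), requires the excursion to exceed a prominence
fraction of the trace amplitude, and places window boundaries at the
diastolic minima between consecutive upstrokes.

Within a beat window, the **baseline** is the mean of the first 20% of the
pre-upstroke segment — a deterministic, testable definition — and the
**amplitude** is peak minus baseline. All level-based metrics interpolate
crossings linearly, which makes them exact on piecewise-linear waveforms
sampled on-grid and invariant under affine rescaling of the trace.

### Activation detectors

Two detectors are provided because they trade robustness against resolution:

* **`max_slope`** (default for duration metrics): the time of the largest
  first difference. At a *strict* derivative maximum — the generic case for
  smooth, sigmoidal upstrokes — the forward difference `v[k+1] - v[k]`
  estimates the derivative at the interval midpoint, so the time `k + 1/2`
  is refined by the parabola through the three neighboring differences
  (vertex offset clipped to half a frame). When the discrete derivative has
  a *plateau* (ties within 1e-6 relative), as any linear upstroke produces,
  a parabola vertex is ill-defined; instead the onset is recovered from the
  partial difference leading into the plateau: the first full-slope frame
  `k0` minus `d[k0-1]/d[k0]` frames. For a noiseless linear upstroke this
  recovers the continuous onset exactly. Ties break to the earliest frame.
* **`level_crossing`**: the linearly interpolated time the upstroke first
  reaches 50% of beat amplitude. Sub-frame resolution and noise-stable, so
  the conduction-velocity chain defaults to it: at 1 kHz and 0.1-0.2 mm
  pixels, frame-quantized activation times cannot resolve inter-pixel
  delays. Note that max-slope on a *linear* upstroke under noise is
  degenerate — every ramp frame is nearly tied, so the argmax wanders over
  the upstroke; the crossing detector is the right choice for noisy data
  with fast linear-looking upstrokes.

**APD/CaTD** (`duration_at_level()`) is measured from the activation time to
the interpolated downstroke crossing of `(1 - level)` of amplitude above
baseline — the conventional optical-mapping definition, stated explicitly
here because measuring from a fixed upstroke fraction is an equally common
alternative. **RT** (`rise_time()`) is the interpolated 20%-to-90% upstroke
interval. **Tau** (`decay_rate()`) fits a least-squares line to
`log(value - baseline)` over the decay segment between 0.9 and 0.3 of
amplitude (at least 4 samples) and reports `-slope` in s^-1 — a rate
constant, not a time constant. The log-linear fit is exact on noiseless
single exponentials; its R-squared is reported, and fits below 0.95 are
flagged as evidence of non-exponential decay. The 0.9-0.3 window avoids both
the plateau shoulder and the noisy late tail; it is configurable since
published Tau values rarely state their fitting window.

`parameter_map()` vectorizes any of these metrics over the masked pixels of
one beat; failed or unmasked pixels carry an explicit `NA`, never a silent
zero. `phase_movie()` returns each pixel's instantaneous phase from the
analytic-signal (Hilbert) embedding of the zero-mean trace, computed by the
standard FFT half-spectrum doubling; each beat contributes one full 2-pi
wrap, which makes the phase movie the raw material for rotor and
wavebreak analysis (not itself in scope).

## Conduction velocity (Bayly method)

A local polynomial surface `T(x, y)` (order 2 by default, 5 x 5-pixel
windows) is least-squares fitted to the activation map around every interior
pixel, in mm coordinates centered on the window, so the fitted linear
coefficients are the gradient at the center. The velocity estimate is

    v = grad T / |grad T|^2        (mm/ms = m/s)

— direction of steepest activation increase, magnitude `1 / |grad T|`.
Windows are excluded when they hold fewer than `max(10, p + 2)` valid
pixels, when fit R-squared falls below 0.9, or when the speed leaves
[0.05, 2.0] m/s; exclusion counts are kept. On an exactly linear surface the
estimate equals the closed form to machine precision.

`cv_summary()` reduces the vector field to the two numbers practitioners
report: vectors whose (undirected) direction lies within 15 degrees of the
fiber axis form the longitudinal sector, within 15 degrees of its
perpendicular the transverse sector, and the **median** sector speeds give
CV_L and CV_T with anisotropy ratio AR = CV_L / CV_T. The median resists the
residual outliers that survive gating. If no fiber angle is supplied, the
axis is estimated as the 5-degree direction bin with the highest median
speed. Axes are labeled so CV_L >= CV_T, hence AR >= 1 by construction.
Windows within two window-widths of a known pacing site are excluded from
the summary because wavefront curvature near a point source biases speeds
low. With an elliptical wave the sector medians sit slightly off the true
axis speeds (vectors up to 15 degrees off-axis are slower/faster than the
axis extremes); at AR ~ 2.2 this bias is about 1% longitudinally and 3%
transversally, well inside the 5% validation band used here.

## The synthetic wave generator

`simulate_recording()` emulates the dual-camera recording of a paced,
anisotropically conducting tissue sheet — not its ionic electrophysiology.
Design choices:

* **Geometry.** Beat *b* arrives at a pixel at
  `stim_delay + (b-1)*BCL + sqrt((xi/CV_L)^2 + (eta/CV_T)^2)`, with
  `(xi, eta)` the pixel's mm offsets from the stimulus site in the fiber
  frame: elliptical wavefronts with exactly known arrival times, speeds and
  directions. Placing the stimulus far outside the grid yields the planar
  limit used for duration validation; `grid_aligned_activation` optionally
  rounds arrivals to the frame grid (the rounded values become the truth).
* **Templates.** Waveforms are piecewise linear/exponential *specifically*
  so that every reported metric has a closed-form location: the AP is a
  linear upstroke of `RT/0.7` (so the 20-90% interval is exactly the
  configured RT), a plateau of `plateau_fraction * APD80`, and a linear
  repolarization whose 0.2-crossing falls exactly APD80 after onset. The
  calcium transient shares the upstroke, holds a plateau of duration
  `CaTD80 - RT/0.7 - ln(5)/k`, then decays as `exp(-k t)`; the plateau
  duration is solved from that identity (`ln(5)/k` is where the exponential
  passes 0.2), and an infeasible triple (negative plateau) is a
  configuration error naming the three parameters. Acceptance checks are
  therefore exact recoveries, not tolerance tuning.
* **Degradations.** Multiplicative photobleaching `exp(-beta t)`, additive
  linear drift, and iid Gaussian noise per channel from a seeded generator;
  identical config and seed reproduce the stacks bit-exactly. The voltage
  channel is emitted inverted (negative polarity) and defaults to more noise
  (5% vs 2% of amplitude) because RH237 yields dimmer emission than Rhod-2.
  Intensities are scaled into a camera-like count range but kept continuous
  in memory; quantization to u16 happens only on `write_movie()`.
* **Defaults are the study conditions.** 100 x 100 pixels, 1 kHz, 0.2 mm
  pixels, BCL 150 ms, 5 beats, and control-condition waveform parameters
  (APD80 68.23 ms, RT 5.05 ms, CaTD80 70.82 ms, calcium RT 13.98 ms, Tau
  32.78 s^-1, CV_L 0.67, CV_T 0.30 mm/ms). `stim_delay_ms` (10 ms) gives
  the first beat a diastolic baseline segment. The plateau fraction (0.4)
  is a shape choice typical of murine optical action potentials; none of
  the validated metrics depend on it.

What the generator does **not** emulate: ionic-model dynamics (restitution,
alternans, curvature-dependent velocity), reentry, motion artifact, optical
point-spread blur, and stimulus artifacts. Passing the validation suite
therefore demonstrates estimator correctness on clean geometry and
realistic noise, not robustness to every pathology of in-situ recordings.

## Pipeline, statistics and reproducibility

`run_pipeline()` drives load/simulate -> condition -> mask -> metric maps ->
conduction velocity -> export from a schema-validated JSON/YAML config
(unknown keys are rejected before any computation). Artifacts are CSV maps
(`NA` marks invalid pixels), PNG renderings (viridis, 2nd-98th percentile
color range, invalid pixels transparent), trace CSVs, a CV summary JSON and
a manifest echoing the config, package version, seed, mask and exclusion
counts. Fixed inputs and seed reproduce byte-identical numeric artifacts;
any stage failure aborts with the stage name and removes partial outputs.

`group_compare()` implements the two-group demonstration statistic: a
pooled-variance two-tailed Student's t-test (`df = n_a + n_b - 2`), taking
either raw per-heart values (delegated to `stats::t.test`) or published
`mean ± se, n` summaries (group variance reconstructed as `n * se^2`); both
entry points agree exactly on matching data, and Welch's correction is
available behind a flag for raw input. Applied to the control-vs-pinacidil
APD80 summaries (68.23 ± 1.67 vs 44.04 ± 5.54, n = 4 each) it gives
p = 0.006, significant at 0.05 and consistent with the headline p = 0.01.

The command-line driver (`inst/cli/optomap.R`) exposes `simulate`, `run`
and `compare`; the conditioning, analysis, velocity and export stages are
addressed through the `run` config blocks rather than separate verbs, since
each block can be enabled or disabled independently.

### Validation problem sizes

The test suite validates estimators on small grids (4-60 pixels square)
where oracles are cheap, and the acceptance layer re-runs the full chain at
the native 100 x 100, 1 kHz scale: a noiseless quasi-planar two-beat
recording for APD80/CaTD80/RT recovery, the noiseless transient for Tau, and
a one-beat elliptical wave for CV_L/CV_T. These sizes are the package's
validation conditions; all are configurable.

## Known limitations

* Max-slope activation on linear (or extremely fast) upstrokes under noise
  is ill-posed; use the 50%-crossing detector there.
* The alignment score is a binarized-overlap agreement figure; it is not
  claimed to equal any particular published camera-alignment metric.
* Integer-translation registration only; no rotation, scale, or sub-pixel.
* CV sector medians carry a small geometry bias (~3% transverse at AR ~ 2.2)
  inherent to +/-15-degree sectoring of an elliptical wave.
* No ratiometric correction, motion tracking, restitution/alternans or
  dominant-frequency analysis; phase output is raw material for such work.

```{r example}
library(optomap)

cfg <- simulation_config(grid = c(50, 50), n_beats = 3,
                         stimulus_site = c(25, 25), seed = 1)
rec <- simulate_recording(cfg)

cc <- conditioning_config()          # 3x3 uniform, SG 7 ms, drift order 1
v <- condition_movie(rec$voltage, cc)
mask <- build_mask(v, cc)

apd <- parameter_map(v, mask, "duration", params = list(level = 0.8))
act <- parameter_map(v, mask, "activation_time",
                     params = list(act_method = "level_crossing"))
fld <- velocity_field(act, spacing_mm = cfg$pixel_spacing_mm)
cv_summary(fld, fiber_angle = cfg$fiber_angle_rad,
           stimulus_site = cfg$stimulus_site)
```
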