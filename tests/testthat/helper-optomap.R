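# Shared fixtures, all built in code.

# Piecewise-linear AP sampled at `dt`: zero until t_on, linear upstroke of
# `up` ms, plateau at 1 until plateau_end, linear repolarization reaching 0
# at t_zero. With up >= 2 frames the max-slope detector recovers t_on
# exactly, so analytic crossing times are exact oracles.
pw_ap_trace <- function(t_on = 10, up = 2, plateau_end = 50, t_zero = 100,
                        t_total = 150, dt = 1) {
  t <- seq(0, t_total, by = dt)
  v <- ifelse(t < t_on, 0,
       ifelse(t < t_on + up, (t - t_on) / up,
       ifelse(t <= plateau_end, 1,
       ifelse(t < t_zero, 1 - (t - plateau_end) / (t_zero - plateau_end),
              0))))
  as_trace(v, dt)
}

one_window <- function(trace) {
  w <- suppressWarnings(segment_beats(trace))
  expect_length(w, 1L)
  w[[1L]]
}

noiseless_config <- function(...) {
  simulation_config(noise_sd_voltage = 0, noise_sd_calcium = 0, ...)
}

# small noiseless quasi-planar recording shared across test files
small_planar_rec <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_recording(noiseless_config(
        grid = c(12, 12), n_beats = 2, stimulus_site = c(6, -60),
        cv_long_mm_per_ms = 0.5, cv_trans_mm_per_ms = 0.5))
    cache
  }
})

raw_conditioning <- function(...) {
  conditioning_config(spatial_kernel = NULL, temporal_filter = NULL,
                      drift_poly_order = NULL, ...)
}
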