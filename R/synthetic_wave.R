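#' Configuration for the synthetic dual-channel wave simulator
#'
#' Describes a paced, anisotropically propagating excitation wave imaged on a
#' square pixel grid, emulating a dual-camera voltage/calcium optical-mapping
#' recording of paced cardiac tissue. Defaults follow the demonstration
#' conditions the package validates against: a 100 x 100 sensor, 1 kHz
#' sampling, 150 ms basic cycle length, and physiological mouse-heart
#' waveform parameters (APD80 68.23 ms, AP rise time 5.05 ms, CaTD80
#' 70.82 ms, calcium rise time 13.98 ms, decay rate 32.78 1/s, CV_L
#' 0.67 mm/ms, CV_T 0.30 mm/ms).
#'
#' @param grid `c(H, W)` pixels.
#' @param pixel_spacing_mm mm per pixel.
#' @param frame_interval_ms ms per frame.
#' @param n_beats number of paced beats.
#' @param bcl_ms basic cycle length (pacing period), ms.
#' @param stimulus_site `c(row, col)` of the pacing site, 1-based; may lie
#'   outside the grid to approximate a planar wave.
#' @param stim_delay_ms time of the first stimulus after recording onset.
#' @param cv_long_mm_per_ms,cv_trans_mm_per_ms conduction speeds along and
#'   across the fiber axis (mm/ms = m/s); `cv_long >= cv_trans > 0`.
#' @param fiber_angle_rad fiber axis, radians from the +x (column) axis.
#' @param ap list `rt2090_ms`, `apd80_ms`, `plateau_fraction` for the action
#'   potential template.
#' @param ca list `rt2090_ms`, `catd80_ms`, `decay_rate_per_s` for the
#'   calcium transient template.
#' @param noise_sd_voltage,noise_sd_calcium iid Gaussian noise SD as a
#'   fraction of amplitude per channel (voltage defaults higher: RH237
#'   emission is dimmer than Rhod-2).
#' @param drift_slope additive linear drift, fraction of amplitude per second.
#' @param bleach_rate_per_s multiplicative photobleaching rate.
#' @param grid_aligned_activation round true activation times to the frame
#'   grid (the rounded values are also stored as truth).
#' @param seed integer RNG seed; identical config and seed give bit-identical
#'   output.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(grid = c(100L, 100L), pixel_spacing_mm = 0.2,
                              frame_interval_ms = 1, n_beats = 5L,
                              bcl_ms = 150, stimulus_site = c(50, 50),
                              stim_delay_ms = 10,
                              cv_long_mm_per_ms = 0.67,
                              cv_trans_mm_per_ms = 0.30,
                              fiber_angle_rad = 0,
                              ap = list(rt2090_ms = 5.05, apd80_ms = 68.23,
                                        plateau_fraction = 0.4),
                              ca = list(rt2090_ms = 13.98, catd80_ms = 70.82,
                                        decay_rate_per_s = 32.78),
                              noise_sd_voltage = 0.05,
                              noise_sd_calcium = 0.02,
                              drift_slope = 0, bleach_rate_per_s = 0,
                              grid_aligned_activation = FALSE,
                              seed = 1L) {
  stopifnot(length(grid) == 2L, all(grid >= 1), pixel_spacing_mm > 0,
            frame_interval_ms > 0, n_beats >= 1, bcl_ms > 0,
            length(stimulus_site) == 2L, all(is.finite(stimulus_site)))
  if (!(cv_long_mm_per_ms >= cv_trans_mm_per_ms && cv_trans_mm_per_ms > 0))
    stop("need cv_long >= cv_trans > 0", call. = FALSE)
  if (bcl_ms <= ap$apd80_ms)
    stop("bcl_ms must exceed apd80_ms", call. = FALSE)
  if (ap$rt2090_ms <= 0 || ap$apd80_ms <= 0 || ca$rt2090_ms <= 0 ||
      ca$catd80_ms <= 0 || ca$decay_rate_per_s <= 0)
    stop("all template durations and rates must be positive", call. = FALSE)
  # both template parameterizations must be feasible; errors name the
  # conflicting parameters
  ap_piecewise_params(ap)
  ca_piecewise_params(ca)
  structure(list(grid = as.integer(grid), pixel_spacing_mm = pixel_spacing_mm,
                 frame_interval_ms = frame_interval_ms,
                 n_beats = as.integer(n_beats), bcl_ms = bcl_ms,
                 stimulus_site = stimulus_site, stim_delay_ms = stim_delay_ms,
                 cv_long_mm_per_ms = cv_long_mm_per_ms,
                 cv_trans_mm_per_ms = cv_trans_mm_per_ms,
                 fiber_angle_rad = fiber_angle_rad, ap = ap, ca = ca,
                 noise_sd_voltage = noise_sd_voltage,
                 noise_sd_calcium = noise_sd_calcium,
                 drift_slope = drift_slope,
                 bleach_rate_per_s = bleach_rate_per_s,
                 grid_aligned_activation = isTRUE(grid_aligned_activation),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

ap_piecewise_params <- function(ap) {
  up <- ap$rt2090_ms / 0.7           # linear upstroke: 20-90% takes 0.7 of it
  pl <- ap$plateau_fraction * ap$apd80_ms
  if (up + pl >= ap$apd80_ms)
    stop(sprintf(
      "infeasible AP template: upstroke %.3g ms + plateau %.3g ms must be < apd80 %.3g ms",
      up, pl, ap$apd80_ms), call. = FALSE)
  # linear repolarization crosses 0.2 exactly apd80 after upstroke onset
  repol_slope <- 0.8 / (ap$apd80_ms - up - pl)   # per ms, from 1 downward
  list(up = up, plateau = pl, repol_slope = repol_slope,
       total = up + pl + 1 / repol_slope)
}

ca_piecewise_params <- function(ca) {
  up <- ca$rt2090_ms / 0.7
  k <- ca$decay_rate_per_s / 1000            # per ms
  tail20 <- log(5) / k                       # exp(-k t) = 0.2
  plateau <- ca$catd80_ms - up - tail20
  if (plateau < 0)
    stop(sprintf(paste0(
      "infeasible calcium template: catd80 (%.4g ms) must be at least ",
      "upstroke rt2090/0.7 (%.4g ms) plus exponential 20%%-tail ln(5)/k ",
      "(%.4g ms); raise catd80, shorten rt2090, or raise decay rate"),
      ca$catd80_ms, up, tail20), call. = FALSE)
  list(up = up, plateau = plateau, k = k)
}

ap_value <- function(t, p) {
  v <- numeric(length(t))
  i <- t >= 0 & t < p$up
  v[i] <- t[i] / p$up
  i <- t >= p$up & t < p$up + p$plateau
  v[i] <- 1
  i <- t >= p$up + p$plateau & t < p$total
  v[i] <- 1 - p$repol_slope * (t[i] - p$up - p$plateau)
  v
}

ca_value <- function(t, p) {
  v <- numeric(length(t))
  i <- t >= 0 & t < p$up
  v[i] <- t[i] / p$up
  i <- t >= p$up & t < p$up + p$plateau
  v[i] <- 1
  i <- t >= p$up + p$plateau
  v[i] <- exp(-p$k * (t[i] - p$up - p$plateau))
  v
}

#' Sampled waveform templates with exact closed-form metrics
#'
#' `ap_template`: piecewise-linear action potential - linear upstroke of
#' duration `rt2090_ms / 0.7` (so the 20-90% rise time is exactly as
#' configured), plateau at 1 for `plateau_fraction * apd80_ms`, then a linear
#' repolarization timed so the 0.2-crossing falls exactly `apd80_ms` after
#' upstroke onset. `ca_template`: same upstroke, a plateau whose duration is
#' solved from `catd80 = upstroke + plateau + ln(5)/k`, then exponential
#' decay `exp(-k t)`. Every duration/rise-time/decay metric of the templates
#' therefore has an exact analytic value.
#'
#' @param ap,ca parameter lists as in [simulation_config()].
#' @param dt_ms sampling interval in ms.
#' @return numeric vector of samples in `[0, 1]` starting at upstroke onset.
#' @export
ap_template <- function(ap, dt_ms = 1) {
  p <- ap_piecewise_params(ap)
  ap_value(seq(0, p$total + dt_ms, by = dt_ms), p)
}

#' @rdname ap_template
#' @export
ca_template <- function(ca, dt_ms = 1) {
  p <- ca_piecewise_params(ca)
  # sample until the exponential tail falls below 1e-4
  total <- p$up + p$plateau + log(1e4) / p$k
  ca_value(seq(0, total, by = dt_ms), p)
}

#' Continuous ground-truth activation surface
#'
#' Arrival time of beat `beat` at every pixel:
#' `stim_delay + (beat - 1) * bcl + sqrt((xi/cv_L)^2 + (eta/cv_T)^2)` where
#' `(xi, eta)` are the pixel's mm offsets from the stimulus site rotated into
#' the fiber frame. With `grid_aligned_activation` the times are rounded to
#' the frame grid (and the rounded values are the truth).
#'
#' @param config a [simulation_config()].
#' @param beat beat number, 1-based.
#' @return `H x W` matrix of activation times in ms.
#' @export
activation_surface <- function(config, beat = 1L) {
  H <- config$grid[1]; W <- config$grid[2]
  sp <- config$pixel_spacing_mm
  dy <- (matrix(seq_len(H), H, W) - config$stimulus_site[1]) * sp
  dx <- (matrix(seq_len(W), H, W, byrow = TRUE) - config$stimulus_site[2]) * sp
  th <- config$fiber_angle_rad
  xi <- dx * cos(th) + dy * sin(th)
  eta <- -dx * sin(th) + dy * cos(th)
  tt <- config$stim_delay_ms + (beat - 1) * config$bcl_ms +
    sqrt((xi / config$cv_long_mm_per_ms)^2 +
         (eta / config$cv_trans_mm_per_ms)^2)
  if (config$grid_aligned_activation)
    tt <- round(tt / config$frame_interval_ms) * config$frame_interval_ms
  tt
}

# analytic velocity truth (speed and direction of propagation) per pixel
true_velocity <- function(config) {
  H <- config$grid[1]; W <- config$grid[2]
  sp <- config$pixel_spacing_mm
  dy <- (matrix(seq_len(H), H, W) - config$stimulus_site[1]) * sp
  dx <- (matrix(seq_len(W), H, W, byrow = TRUE) - config$stimulus_site[2]) * sp
  th <- config$fiber_angle_rad
  a <- config$cv_long_mm_per_ms; b <- config$cv_trans_mm_per_ms
  xi <- dx * cos(th) + dy * sin(th)
  eta <- -dx * sin(th) + dy * cos(th)
  tt <- sqrt((xi / a)^2 + (eta / b)^2)
  tt[tt == 0] <- NA_real_
  gxi <- (xi / a^2) / tt
  geta <- (eta / b^2) / tt
  gx <- gxi * cos(th) - geta * sin(th)
  gy <- gxi * sin(th) + geta * cos(th)
  gmag2 <- gxi^2 + geta^2
  list(speed = 1 / sqrt(gmag2),
       direction = atan2(gy / gmag2, gx / gmag2))
}

#' Simulate a dual-channel optical-mapping recording with ground truth
#'
#' Builds voltage and calcium movie stacks of a paced anisotropic wave: each
#' pixel's trace is the channel template shifted by the pixel's activation
#' time, summed over beats, then degraded by multiplicative photobleaching
#' `exp(-bleach_rate * t)`, additive linear drift, and iid Gaussian noise
#' (all per channel, from the seeded generator). The voltage channel is
#' emitted inverted (polarity `"negative"`, as with RH237 emission); calcium
#' is positive. Intensities are scaled to a 16-bit-representable count range.
#' Identical config and seed reproduce the stacks bit-exactly.
#'
#' @param config a [simulation_config()].
#' @return list with `voltage` and `calcium` ([movie_stack()]s) and `truth`:
#'   per-pixel `activation_ms` (beat 1), `speed_m_per_s`, `direction_rad`,
#'   the exact template metrics (`apd80_ms`, `rt_v_ms`, `catd80_ms`,
#'   `rt_ca_ms`, `tau_per_s`), and the config echo.
#' @export
simulate_recording <- function(config) {
  H <- config$grid[1]; W <- config$grid[2]
  dt <- config$frame_interval_ms
  n_frames <- ceiling((config$stim_delay_ms +
                       config$n_beats * config$bcl_ms) / dt)
  times <- (seq_len(n_frames) - 1) * dt
  act1 <- activation_surface(config, 1L)
  onset <- as.vector(act1)                 # H*W, column-major
  n_pix <- H * W
  ap_p <- ap_piecewise_params(config$ap)
  ca_p <- ca_piecewise_params(config$ca)
  build <- function(value_fun, p) {
    m <- matrix(0, n_frames, n_pix)
    for (b in seq_len(config$n_beats)) {
      off <- (b - 1) * config$bcl_ms
      rel <- outer(times, onset + off, "-")
      m <- m + value_fun(rel, p)
    }
    m
  }
  volt <- build(ap_value, ap_p)
  cal <- build(ca_value, ca_p)
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()), add = TRUE)
  }
  set.seed(config$seed)
  degrade <- function(m, noise_sd) {
    t_s <- times / 1000
    if (config$bleach_rate_per_s > 0)
      m <- m * exp(-config$bleach_rate_per_s * t_s)
    if (config$drift_slope != 0)
      m <- m + config$drift_slope * t_s
    if (noise_sd > 0)
      m <- m + matrix(stats::rnorm(length(m), sd = noise_sd),
                      nrow = nrow(m))
    m
  }
  volt <- degrade(volt, config$noise_sd_voltage)
  cal <- degrade(cal, config$noise_sd_calcium)
  # scale to a camera-like count range; voltage inverted (neg. polarity)
  counts <- function(m, invert) {
    m <- if (invert) 3000 - 2000 * m else 1000 + 2000 * m
    array(m, dim = c(n_frames, H, W))
  }
  mk <- function(m, channel, polarity) {
    movie_stack(counts(m, polarity == "negative"), dt,
                config$pixel_spacing_mm, channel = channel,
                polarity = polarity, meta = list(synthetic = TRUE))
  }
  tv <- true_velocity(config)
  truth <- list(activation_ms = act1, bcl_ms = config$bcl_ms,
                n_beats = config$n_beats,
                apd80_ms = config$ap$apd80_ms,
                rt_v_ms = config$ap$rt2090_ms,
                catd80_ms = config$ca$catd80_ms,
                rt_ca_ms = config$ca$rt2090_ms,
                tau_per_s = config$ca$decay_rate_per_s,
                speed_m_per_s = tv$speed, direction_rad = tv$direction,
                config = config)
  list(voltage = mk(volt, "voltage", "negative"),
       calcium = mk(cal, "calcium", "positive"),
       truth = truth)
}
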