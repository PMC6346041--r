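test_that("paced trains segment into the expected beat windows", {
  rec <- small_planar_rec()
  v <- normalize_pixels(rec$voltage)
  tr <- pixel_trace(v, 6, 6)
  wins <- segment_beats(tr)
  expect_length(wins, 2L)   # n_beats = 2 in the fixture
  # 5-beat train at BCL 150 ms: 5 windows with upstrokes ~150 ms apart
  five <- simulate_recording(noiseless_config(
    grid = c(4, 4), n_beats = 5, stimulus_site = c(2, -20)))
  tr5 <- pixel_trace(normalize_pixels(five$voltage), 2, 2)
  w5 <- segment_beats(tr5)
  expect_length(w5, 5L)
  ups <- vapply(w5, function(w) w$upstroke, integer(1))
  expect_true(all(abs(diff(ups) - 150) <= 2))
  # single AP -> one window; flat trace -> none, with a warning
  expect_length(one_window(pw_ap_trace()), 3L)  # a beat_window has 3 fields
  expect_warning(w0 <- segment_beats(as_trace(rep(1, 50), 1)), "flat")
  expect_length(w0, 0L)
})

test_that("activation detectors locate step edges and wavefront arrivals", {
  # ideal step 0->1 between frames 49 and 50 at 1 kHz
  step <- as_trace(c(rep(0, 50), rep(1, 40), rep(0, 30)), 1)
  w <- beat_window(1, 110, 50)
  expect_equal(activation_time(step, w), 49.5)
  # monotonically decreasing window -> invalid
  dec <- as_trace(seq(1, 0, length.out = 50), 1)
  expect_true(is.na(activation_time(dec, beat_window(1, 50, 25))))
  # planar wave at 0.5 mm/ms: pixel 6 mm from the source arrives 12 ms
  # after the stimulus (plus the configured stimulus delay)
  cfg <- noiseless_config(grid = c(3, 40), pixel_spacing_mm = 0.2,
                          n_beats = 1, stimulus_site = c(2, 1),
                          cv_long_mm_per_ms = 0.5, cv_trans_mm_per_ms = 0.5)
  rec <- simulate_recording(cfg)
  tr <- pixel_trace(normalize_pixels(rec$voltage), 2, 31)  # 30 px = 6 mm
  w <- one_window(tr)
  expect_equal(activation_time(tr, w), cfg$stim_delay_ms + 12,
               tolerance = 1e-6)
  expect_equal(activation_time(tr, w, "level_crossing"),
               cfg$stim_delay_ms + 12 + 0.5 * cfg$ap$rt2090_ms / 0.7,
               tolerance = 1e-6)
})

test_that("rise time interpolates 20-90% crossings and is affine invariant", {
  # linear 0->1 ramp lasting 10 ms: RT = (0.9 - 0.2) * 10
  ramp <- pw_ap_trace(t_on = 20, up = 10, plateau_end = 60, t_zero = 110)
  w <- one_window(ramp)
  expect_equal(rise_time(ramp, w), 7.0)
  scaled <- as_trace(5 * ramp$values + 2, 1)
  expect_equal(rise_time(scaled, w), 7.0)
  # template-configured rise time recovered exactly from samples
  tmpl <- as_trace(c(rep(0, 20), ap_template(list(rt2090_ms = 5.05,
                                                  apd80_ms = 68.23,
                                                  plateau_fraction = 0.4))), 1)
  expect_equal(rise_time(tmpl, one_window(tmpl)), 5.05, tolerance = 1e-9)
})

test_that("duration at level matches analytic crossings and is monotone", {
  # upstroke onset 10 ms, plateau to 50 ms, linear to 0 at 100 ms:
  # level 0.8 crosses 0.2 at t=90 -> APD80 = 80; level 0.5 -> 65
  tr <- pw_ap_trace()
  w <- one_window(tr)
  expect_equal(duration_at_level(tr, w, 0.8), 80)
  expect_equal(duration_at_level(tr, w, 0.5), 65)
  expect_equal(duration_at_level(tr, w, 0.9), 85)
  lv <- seq(0.1, 0.9, by = 0.1)
  durs <- vapply(lv, function(l) duration_at_level(tr, w, l), numeric(1))
  expect_true(all(diff(durs) >= 0))
  # affine invariance
  aff <- as_trace(3 * tr$values - 7, 1)
  expect_equal(duration_at_level(aff, w, 0.8), 80)
  # template APD80 recovered exactly on noiseless samples
  tmpl <- as_trace(c(rep(0, 20), ap_template(list(rt2090_ms = 5.05,
                                                  apd80_ms = 68.23,
                                                  plateau_fraction = 0.4))), 1)
  expect_equal(duration_at_level(tmpl, one_window(tmpl)), 68.23,
               tolerance = 1e-9)
})

test_that("decay-rate fit is exact on exponentials and scales linearly", {
  k <- 32.78
  tr <- as_trace(c(rep(0, 20), ca_template(list(rt2090_ms = 13.98,
                                                catd80_ms = 70.82,
                                                decay_rate_per_s = k))), 1)
  w <- one_window(tr)
  fit <- decay_rate(tr, w)
  expect_equal(fit$rate_per_s, k, tolerance = 1e-9)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  expect_false(fit$flagged)
  # doubled rate doubles the estimate
  tr2 <- as_trace(c(rep(0, 20), ca_template(list(rt2090_ms = 13.98,
                                                 catd80_ms = 70.82,
                                                 decay_rate_per_s = 2 * k))), 1)
  expect_equal(decay_rate(tr2, one_window(tr2))$rate_per_s, 2 * k,
               tolerance = 1e-9)
  # non-exponential (linear) decay: finite rate but imperfect log-linear fit
  lin <- pw_ap_trace(t_on = 10, up = 2, plateau_end = 20, t_zero = 140,
                     t_total = 160)
  fl <- decay_rate(lin, one_window(lin))
  expect_true(is.finite(fl$rate_per_s))
  expect_lt(fl$r2, 0.999)
  expect_identical(fl$flagged, fl$r2 < 0.95)
  # too-short decay segment -> invalid
  steep <- as_trace(c(rep(0, 10), 1, 0.95, 0.1, rep(0.05, 20)), 1)
  expect_true(is.na(decay_rate(steep, beat_window(1, 30, 11))$rate_per_s))
})

test_that("log-linear decay fit agrees with a nonlinear exponential oracle", {
  skip_if_not_installed("minpack.lm")
  for (k in c(25, 32.78, 60)) {
    tr <- as_trace(c(rep(0, 15), ca_template(list(rt2090_ms = 10,
                                                  catd80_ms = 90,
                                                  decay_rate_per_s = k))), 1)
    w <- one_window(tr)
    est <- decay_rate(tr, w)$rate_per_s
    # independent oracle: nonlinear least squares on the same samples
    v <- tr$values
    pk <- which.max(v)
    seg <- pk:length(v)
    seg <- seg[v[seg] > 0.05 & v[seg] < 0.9]
    df <- data.frame(t = (seg - 1) / 1000, y = v[seg])
    nl <- minpack.lm::nlsLM(y ~ a * exp(-r * t), data = df,
                            start = list(a = 5, r = 20))
    expect_equal(est, unname(coef(nl)["r"]), tolerance = 1e-6)
  }
})

test_that("parameter maps follow the ground truth and mark invalid pixels", {
  rec <- small_planar_rec()
  cc <- raw_conditioning()
  v <- condition_movie(rec$voltage, cc)
  mask <- build_mask(v, cc)
  expect_true(all(mask$include))
  act <- parameter_map(v, mask, "activation_time")
  expect_equal(act$values, rec$truth$activation_ms, tolerance = 1e-6)
  # activation increases linearly along the propagation axis
  mid <- act$values[6, ]
  expect_true(all(diff(mid) > 0))
  expect_equal(stats::sd(diff(mid)), 0, tolerance = 1e-6)
  # uniform template: APD80 map constant (spread below one frame)
  apd <- parameter_map(v, mask, "duration", params = list(level = 0.8))
  rng <- range(apd$values, na.rm = TRUE)
  expect_lt(diff(rng), 1)
  # empty mask -> all invalid with a warning
  expect_warning(
    pm0 <- parameter_map(v, pixel_mask(matrix(FALSE, 12, 12)), "duration"),
    "empty mask")
  expect_true(all(is.na(pm0$values)))
  expect_error(parameter_map(v, mask, "frobnicate"), "unknown metric")
})

test_that("phase movies wrap once per beat and flag degenerate pixels", {
  # pure sinusoid of period 100 ms: phase advances 2*pi per period
  t <- 0:499
  s <- sin(2 * pi * t / 100)
  f <- array(s, dim = c(500, 1, 2))
  f[, 1, 2] <- 1  # constant pixel
  ph <- phase_movie(movie_stack(f + 2, 1, 0.1))
  p1 <- ph[, 1, 1]
  expect_true(all(p1 >= -pi & p1 <= pi))
  expect_true(count_phase_wraps(p1) %in% 4:5)  # ~5 periods
  core <- 100:400
  expect_equal(diff(p1[core]) %% (2 * pi), rep(2 * pi / 100, length(core) - 1),
               tolerance = 0.05)
  expect_true(all(is.na(ph[, 1, 2])))
  # 5-beat paced train: one wrap per beat at every pixel
  five <- simulate_recording(noiseless_config(
    grid = c(4, 4), n_beats = 5, stimulus_site = c(2, -20)))
  vph <- phase_movie(normalize_pixels(five$voltage))
  wraps <- apply(vph, c(2, 3), count_phase_wraps)
  expect_true(all(wraps >= 4 & wraps <= 5))
})
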