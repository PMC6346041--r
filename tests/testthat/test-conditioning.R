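const_stack <- function(value = 5, d = c(10, 6, 6), dt = 1) {
  movie_stack(array(value, dim = d), dt, 0.1)
}

test_that("spatial smoothing normalizes its kernel and spreads point sources", {
  st <- const_stack()
  for (k in c("uniform", "gaussian")) {
    cc <- conditioning_config(spatial_kernel = k)
    expect_equal(spatial_smooth(st, cc)$frames, st$frames)
  }
  # single bright pixel, 3x3 uniform -> 9 pixels each at 1/9
  f <- array(0, dim = c(2, 7, 7)); f[, 4, 4] <- 9
  sm <- spatial_smooth(movie_stack(f, 1, 0.1), conditioning_config())
  expect_equal(sm$frames[1, 3:5, 3:5], matrix(1, 3, 3))
  expect_equal(sum(sm$frames[1, , ]), 9)
  expect_error(spatial_smooth(movie_stack(array(0, c(2, 2, 2)), 1, 0.1),
                              conditioning_config(spatial_size = 5)),
               "larger than frame")
})

test_that("3x3 uniform smoothing cuts white-noise variance about 9-fold", {
  set.seed(11)
  f <- array(rnorm(300 * 12 * 12), dim = c(300, 12, 12))
  st <- movie_stack(f + 10, 1, 0.1)
  sm <- spatial_smooth(st, conditioning_config())
  v_in <- apply(st$frames[, 4:9, 4:9], c(2, 3), var)
  v_out <- apply(sm$frames[, 4:9, 4:9], c(2, 3), var)
  expect_gt(mean(v_in) / mean(v_out), 7.5)
  expect_lt(mean(v_in) / mean(v_out), 10.5)
})

test_that("smoothing operators commute with constant offsets", {
  set.seed(12)
  f <- array(rnorm(40 * 6 * 6) + 5, dim = c(40, 6, 6))
  st <- movie_stack(f, 1, 0.1)
  st_off <- movie_stack(f + 3, 1, 0.1)
  cc <- conditioning_config()
  expect_equal(spatial_smooth(st_off, cc)$frames,
               spatial_smooth(st, cc)$frames + 3)
  expect_equal(temporal_smooth(st_off, cc)$frames,
               temporal_smooth(st, cc)$frames + 3, tolerance = 1e-10)
})

test_that("temporal filters are zero-phase on upstrokes and gentle in-band", {
  dt <- 1
  t <- seq(0, 200, by = dt)
  sig <- 1 / (1 + exp(-(t - 50)))  # max slope exactly at t = 50
  mk <- function(v) movie_stack(array(rep(v, each = 1), c(length(v), 1, 1)),
                                dt, 0.1)
  for (cc in list(conditioning_config(),  # Savitzky-Golay 7 ms
                  conditioning_config(temporal_filter = "lowpass",
                                      lowpass_cutoff_hz = 100))) {
    out <- temporal_smooth(mk(sig), cc)$frames[, 1, 1]
    t_max <- t[which.max(diff(out))]
    expect_lt(abs(t_max - 50), 1)
    # constant trace unchanged
    expect_equal(temporal_smooth(const_stack(), cc)$frames,
                 const_stack()$frames, tolerance = 1e-10)
  }
  # in-band sinusoid attenuated < 5%
  s10 <- sin(2 * pi * 10 * t / 1000)
  out <- temporal_smooth(mk(s10), conditioning_config())$frames[, 1, 1]
  core <- 20:180
  expect_gt(max(out[core]) / max(s10[core]), 0.95)
  expect_error(
    temporal_smooth(mk(sig[1:5]), conditioning_config(sg_window_ms = 50)),
    "longer than recording")
  expect_error(
    temporal_smooth(mk(sig), conditioning_config(temporal_filter = "lowpass",
                                                 lowpass_cutoff_hz = 600)),
    "Nyquist")
})

test_that("drift removal leaves residuals orthogonal to the trend basis", {
  tt <- 0:199
  line <- 2 + 0.03 * tt
  mk <- function(v) movie_stack(array(v, c(length(v), 1, 1)), 1, 0.1)
  # pure line, order 1 -> zero
  out <- remove_drift(mk(line), conditioning_config(drift_poly_order = 1))
  expect_equal(max(abs(out$frames)), 0, tolerance = 1e-10)
  # AP train plus line: residual uncorrelated with time
  ap <- rep(pw_ap_trace(t_total = 99)$values, 2)
  out <- remove_drift(mk(ap + line), conditioning_config(drift_poly_order = 1))
  expect_lt(abs(cor(out$frames[, 1, 1], tt)), 1e-10)
  # order 0 subtracts the mean
  out <- remove_drift(mk(ap), conditioning_config(drift_poly_order = 0))
  expect_equal(out$frames[, 1, 1], ap - mean(ap))
  expect_error(remove_drift(movie_stack(array(1:8, c(2, 2, 2)), 1, 0.1),
                            conditioning_config(drift_poly_order = 3)),
               "below the number of frames")
})

test_that("normalization maps to [0,1], handles polarity, and is idempotent", {
  set.seed(13)
  f <- array(rnorm(50 * 3 * 3, 100, 20), dim = c(50, 3, 3))
  st <- movie_stack(f, 1, 0.1)
  nm <- normalize_pixels(st)
  expect_equal(apply(nm$frames, c(2, 3), min), matrix(0, 3, 3))
  expect_equal(apply(nm$frames, c(2, 3), max), matrix(1, 3, 3))
  expect_identical(nm$polarity, "positive")
  # negated copy with negative polarity normalizes identically
  neg <- movie_stack(max(f) - f, 1, 0.1, polarity = "negative")
  expect_equal(normalize_pixels(neg)$frames, nm$frames)
  # idempotence
  expect_equal(normalize_pixels(nm)$frames, nm$frames)
  # constant pixel flagged invalid, not divided by zero
  f[, 2, 2] <- 42
  expect_warning(nm2 <- normalize_pixels(movie_stack(f, 1, 0.1)),
                 "zero-range")
  expect_true(nm2$meta$invalid_pixels[2, 2])
  expect_false(any(nm2$meta$invalid_pixels[-2, -2]))
  expect_true(all(is.finite(nm2$frames)))
})

test_that("SNR mask separates active pixels from flat noise", {
  set.seed(14)
  ap <- rep(pw_ap_trace(t_total = 149)$values, 2)
  n_t <- length(ap)
  f <- array(rnorm(n_t * 5 * 5, sd = 0.01), dim = c(n_t, 5, 5))
  active <- matrix(FALSE, 5, 5); active[2:4, 2:4] <- TRUE
  for (i in 1:5) for (j in 1:5) if (active[i, j]) f[, i, j] <- f[, i, j] + ap
  st <- movie_stack(f + 1, 1, 0.1)
  # pure-noise pixels reach peak-to-peak ~6.6 sigma over ~300 samples
  # (extreme-value statistics), so the separating threshold sits well above
  # that and far below the active pixels' SNR of ~100
  mask <- build_mask(st, conditioning_config(snr_threshold = 20))
  expect_identical(mask$include, active)
  # all-constant movie -> empty mask with a warning
  expect_warning(m0 <- build_mask(const_stack(), conditioning_config()),
                 "empty")
  expect_false(any(m0$include))
  # threshold 0 includes every non-constant pixel
  m_all <- build_mask(st, conditioning_config(snr_threshold = 0))
  expect_true(all(m_all$include))
})

test_that("translation registration recovers integer shifts exactly", {
  set.seed(15)
  base <- matrix(rnorm(40 * 40), 40, 40)
  ref <- spatial_smooth(movie_stack(array(rep(base, each = 2), c(2, 40, 40)),
                                    1, 0.1), conditioning_config())$frames[1, , ]
  idt <- register_translation(ref, ref, 4)
  expect_identical(idt$offset, c(0L, 0L))
  expect_equal(idt$score, 100)
  for (sh in list(c(3L, 0L), c(1L, 2L), c(0L, 4L), c(2L, 3L))) {
    moving <- matrix(mean(ref), 40, 40)
    moving[(1 + sh[1]):40, (1 + sh[2]):40] <-
      ref[1:(40 - sh[1]), 1:(40 - sh[2])]
    res <- register_translation(ref, moving, 5)
    expect_identical(res$offset, sh)
    expect_equal(res$score, 100)
  }
  expect_error(register_translation(ref, ref[1:20, 1:20], 2), "shape")
  expect_error(register_translation(ref, ref, 40), "smaller than the frame")
})

test_that("independent random binary frames score near 50% agreement", {
  set.seed(16)
  a <- matrix(rbinom(100 * 100, 1, 0.5), 100, 100)
  b <- matrix(rbinom(100 * 100, 1, 0.5), 100, 100)
  res <- register_translation(a, b, 0)
  expect_gt(res$score, 45)
  expect_lt(res$score, 55)
})
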