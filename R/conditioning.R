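#' Signal-conditioning configuration
#'
#' Bundles the parameters of the per-pixel conditioning chain. The default
#' chain, applied by [condition_movie()] in this order, is: 3x3 uniform
#' spatial smoothing, zero-phase Savitzky-Golay temporal smoothing (7 ms
#' window, cubic), linear drift removal, then per-pixel amplitude
#' normalization. Any stage can be disabled by setting its field to `NULL`
#' (or `drift_poly_order = NULL`).
#'
#' @param spatial_kernel `"uniform"`, `"gaussian"`, or `NULL` to skip.
#' @param spatial_size odd kernel size in pixels.
#' @param spatial_sigma Gaussian sigma in pixels (gaussian kernel only).
#' @param temporal_filter `"savitzky_golay"`, `"lowpass"`, or `NULL` to skip.
#' @param sg_window_ms Savitzky-Golay window length in ms (rounded to an odd
#'   number of frames).
#' @param sg_order Savitzky-Golay polynomial order.
#' @param lowpass_cutoff_hz Butterworth cutoff in Hz (must be below Nyquist);
#'   applied forward-backward so the filter is zero-phase.
#' @param lowpass_order Butterworth order.
#' @param drift_poly_order polynomial order (0-4) for baseline drift removal,
#'   or `NULL` to skip.
#' @param snr_threshold minimum peak-to-peak amplitude over robust noise for a
#'   pixel to enter the analysis mask.
#' @return a `conditioning_config` list.
#' @export
conditioning_config <- function(spatial_kernel = "uniform",
                                spatial_size = 3L, spatial_sigma = 1,
                                temporal_filter = "savitzky_golay",
                                sg_window_ms = 7, sg_order = 3L,
                                lowpass_cutoff_hz = 100, lowpass_order = 3L,
                                drift_poly_order = 1L,
                                snr_threshold = 5) {
  if (!is.null(spatial_kernel)) {
    spatial_kernel <- match.arg(spatial_kernel, c("uniform", "gaussian"))
    spatial_size <- as.integer(spatial_size)
    if (spatial_size < 1L || spatial_size %% 2L == 0L)
      stop("`spatial_size` must be odd and positive", call. = FALSE)
  }
  if (!is.null(temporal_filter))
    temporal_filter <- match.arg(temporal_filter,
                                 c("savitzky_golay", "lowpass"))
  if (!is.null(drift_poly_order)) {
    drift_poly_order <- as.integer(drift_poly_order)
    if (drift_poly_order < 0L || drift_poly_order > 4L)
      stop("`drift_poly_order` must be between 0 and 4", call. = FALSE)
  }
  if (snr_threshold < 0) stop("`snr_threshold` must be >= 0", call. = FALSE)
  structure(list(spatial_kernel = spatial_kernel,
                 spatial_size = spatial_size, spatial_sigma = spatial_sigma,
                 temporal_filter = temporal_filter,
                 sg_window_ms = sg_window_ms, sg_order = as.integer(sg_order),
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 lowpass_order = as.integer(lowpass_order),
                 drift_poly_order = drift_poly_order,
                 snr_threshold = snr_threshold),
            class = "conditioning_config")
}

# mirror-padded index vector for a shift of k over n positions
mirror_index <- function(n, k) {
  idx <- seq_len(n) + k
  idx[idx < 1L] <- 2L - idx[idx < 1L]
  idx[idx > n] <- 2L * n - idx[idx > n]
  idx
}

spatial_kernel_weights <- function(config) {
  s <- config$spatial_size
  half <- (s - 1L) %/% 2L
  if (config$spatial_kernel == "uniform") {
    k <- matrix(1, s, s)
  } else {
    g <- exp(-((-half):half)^2 / (2 * config$spatial_sigma^2))
    k <- outer(g, g)
  }
  k / sum(k)
}

#' Spatial smoothing of every frame
#'
#' Convolves each frame with a normalized uniform or Gaussian kernel, using
#' mirror padding at the edges. Constant frames are unchanged; calibration is
#' preserved.
#'
#' @param stack a [movie_stack()].
#' @param config a [conditioning_config()].
#' @return the smoothed [movie_stack()].
#' @export
spatial_smooth <- function(stack, config = conditioning_config()) {
  if (is.null(config$spatial_kernel)) return(stack)
  d <- dim(stack$frames)
  s <- config$spatial_size
  if (s > d[2] || s > d[3])
    stop("spatial kernel larger than frame", call. = FALSE)
  k <- spatial_kernel_weights(config)
  half <- (s - 1L) %/% 2L
  out <- array(0, dim = d)
  # shift-and-add over kernel taps, vectorized across frames and pixels
  for (i in seq_len(s)) {
    ri <- mirror_index(d[2], i - 1L - half)
    for (j in seq_len(s)) {
      cj <- mirror_index(d[3], j - 1L - half)
      out <- out + k[i, j] * stack$frames[, ri, cj, drop = FALSE]
    }
  }
  replace_frames(stack, out)
}

#' Zero-phase temporal smoothing of every pixel trace
#'
#' Savitzky-Golay (symmetric window, inherently zero-phase) or Butterworth
#' low-pass applied forward and backward (`signal::filtfilt`). Neither
#' introduces a systematic time shift, so activation times are unbiased.
#'
#' @inheritParams spatial_smooth
#' @return the filtered [movie_stack()].
#' @export
temporal_smooth <- function(stack, config = conditioning_config()) {
  if (is.null(config$temporal_filter)) return(stack)
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1])
  if (config$temporal_filter == "savitzky_golay") {
    n <- max(3L, round(config$sg_window_ms / stack$frame_interval_ms))
    if (n %% 2L == 0L) n <- n + 1L
    if (n > d[1])
      stop("Savitzky-Golay window longer than recording", call. = FALSE)
    p <- min(config$sg_order, n - 1L)
    for (jj in seq_len(ncol(m)))
      m[, jj] <- signal::sgolayfilt(m[, jj], p = p, n = n)
  } else {
    nyquist <- 1000 / (2 * stack$frame_interval_ms)
    if (config$lowpass_cutoff_hz >= nyquist)
      stop(sprintf("lowpass cutoff %.3g Hz must be below Nyquist %.3g Hz",
                   config$lowpass_cutoff_hz, nyquist), call. = FALSE)
    bf <- signal::butter(config$lowpass_order,
                         config$lowpass_cutoff_hz / nyquist)
    # filter the mean-subtracted trace so DC (and constants) pass untouched
    for (jj in seq_len(ncol(m))) {
      mu <- mean(m[, jj])
      m[, jj] <- signal::filtfilt(bf, m[, jj] - mu) + mu
    }
  }
  replace_frames(stack, array(m, dim = d))
}

#' Remove slow baseline drift per pixel
#'
#' Fits a least-squares polynomial of order `drift_poly_order` to each full
#' pixel trace and subtracts it; the residual has zero projection onto the
#' polynomial basis. Order 0 subtracts the mean; order 1 removes linear
#' photobleaching-like trends.
#'
#' @inheritParams spatial_smooth
#' @return the detrended [movie_stack()].
#' @export
remove_drift <- function(stack, config = conditioning_config()) {
  ord <- config$drift_poly_order
  if (is.null(ord)) return(stack)
  d <- dim(stack$frames)
  if (ord >= d[1])
    stop("drift polynomial order must be below the number of frames",
         call. = FALSE)
  tt <- seq_len(d[1])
  basis <- cbind(rep(1 / sqrt(d[1]), d[1]),
                 if (ord > 0) stats::poly(tt, degree = ord))
  m <- matrix(stack$frames, nrow = d[1])
  m <- m - basis %*% crossprod(basis, m)  # orthonormal basis projection
  replace_frames(stack, array(m, dim = d))
}

#' Normalize each pixel trace to [0, 1]
#'
#' Negative-polarity channels (fluorescence falls on the upstroke, e.g. RH237
#' voltage emission) are negated first, so the output always has positive
#' polarity. Each pixel is then mapped min -> 0, max -> 1. Zero-range pixels
#' cannot be normalized: their traces are set to zero and recorded in
#' `meta$invalid_pixels` (an `H x W` logical matrix), with a warning.
#' Applying the function twice equals applying it once on valid pixels.
#'
#' @param stack a [movie_stack()].
#' @return the normalized [movie_stack()], polarity `"positive"`.
#' @export
normalize_pixels <- function(stack) {
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1])
  if (stack$polarity == "negative") m <- -m
  lo <- apply(m, 2, min)
  hi <- apply(m, 2, max)
  rng <- hi - lo
  bad <- rng <= 0
  rng[bad] <- 1
  m <- (m - rep(lo, each = d[1])) / rep(rng, each = d[1])
  m[, bad] <- 0
  if (any(bad))
    warning(sum(bad), " zero-range pixel(s) flagged invalid", call. = FALSE)
  stack <- replace_frames(stack, array(m, dim = d))
  stack$polarity <- "positive"
  prev <- stack$meta$invalid_pixels
  inv <- matrix(bad, d[2], d[3])
  stack$meta$invalid_pixels <- if (is.null(prev)) inv else (inv | prev)
  stack
}

#' Build an analysis mask from per-pixel signal-to-noise ratio
#'
#' A pixel is included when its peak-to-peak amplitude divided by a robust
#' noise estimate reaches `snr_threshold`. Noise is estimated from the first
#' difference of the trace as `1.4826 * MAD(diff) / sqrt(2)`, so slow
#' physiological components do not inflate it. Noiseless active pixels get
#' infinite SNR; flat pixels get zero.
#'
#' @inheritParams spatial_smooth
#' @return a [pixel_mask()].
#' @export
build_mask <- function(stack, config = conditioning_config()) {
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1])
  amp <- apply(m, 2, max) - apply(m, 2, min)
  dm <- m[-1, , drop = FALSE] - m[-d[1], , drop = FALSE]
  noise <- apply(dm, 2, stats::mad) / sqrt(2)
  snr <- ifelse(noise > 0, amp / noise, ifelse(amp > 0, Inf, 0))
  inc <- matrix(snr >= config$snr_threshold & amp > 0, d[2], d[3])
  if (!is.null(stack$meta$invalid_pixels))
    inc <- inc & !stack$meta$invalid_pixels
  if (!any(inc)) warning("SNR mask is empty", call. = FALSE)
  pixel_mask(inc)
}

#' Apply the full conditioning chain
#'
#' Spatial smoothing, temporal smoothing, drift removal, then normalization,
#' each controlled (and individually skippable) by the configuration.
#'
#' @inheritParams spatial_smooth
#' @param normalize run [normalize_pixels()] at the end.
#' @return the conditioned [movie_stack()].
#' @export
condition_movie <- function(stack, config = conditioning_config(),
                            normalize = TRUE) {
  stack <- spatial_smooth(stack, config)
  stack <- temporal_smooth(stack, config)
  stack <- remove_drift(stack, config)
  if (normalize) stack <- normalize_pixels(stack)
  stack
}

#' Co-register two camera frames by integer translation
#'
#' Finds the integer pixel shift of `moving` relative to `ref` that maximizes
#' the normalized cross-correlation over the overlapping region, searching
#' `(-search_radius..search_radius)^2`. The alignment score is the percentage
#' of overlap pixels whose Otsu-binarized values agree after shifting - a
#' simple spatial-alignment quality figure for dual-camera setups.
#'
#' @param ref,moving numeric matrices of identical shape (single frames).
#' @param search_radius maximum absolute shift in pixels.
#' @return a list with `offset` (`c(dy, dx)`: `moving[r + dy, c + dx]`
#'   corresponds to `ref[r, c]`), `score` in `[0, 100]`, and `ncc` at the
#'   optimum.
#' @export
register_translation <- function(ref, moving, search_radius = 5L) {
  if (!identical(dim(ref), dim(moving)))
    stop("frames must have identical shape", call. = FALSE)
  r <- as.integer(search_radius)
  if (r < 0L) stop("`search_radius` must be >= 0", call. = FALSE)
  if (r >= min(dim(ref)))
    stop("search radius must be smaller than the frame", call. = FALSE)
  best <- list(ncc = -Inf, offset = c(0L, 0L))
  for (dy in -r:r) for (dx in -r:r) {
    rr <- max(1L, 1L - dy):min(nrow(ref), nrow(ref) - dy)
    cc <- max(1L, 1L - dx):min(ncol(ref), ncol(ref) - dx)
    a <- ref[rr, cc]; b <- moving[rr + dy, cc + dx]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      ncc <- ifelse(all(a == a[1]) && all(b == b[1]) && a[1] == b[1], 1, 0)
    } else {
      ncc <- stats::cor(as.vector(a), as.vector(b))
    }
    if (ncc > best$ncc) best <- list(ncc = ncc, offset = c(dy, dx))
  }
  dy <- best$offset[1]; dx <- best$offset[2]
  rr <- max(1L, 1L - dy):min(nrow(ref), nrow(ref) - dy)
  cc <- max(1L, 1L - dx):min(ncol(ref), ncol(ref) - dx)
  a <- ref[rr, cc]; b <- moving[rr + dy, cc + dx]
  bin01 <- function(x) {
    rngx <- range(x)
    if (diff(rngx) == 0) return(matrix(FALSE, nrow(x), ncol(x)))
    xn <- (x - rngx[1]) / diff(rngx)
    xn > EBImage::otsu(xn, range = c(0, 1))
  }
  score <- 100 * mean(bin01(a) == bin01(b))
  list(offset = best$offset, score = score, ncc = best$ncc)
}
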