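#' Single-pixel (or ROI) time series
#'
#' @param values numeric vector of at least 8 finite samples (normalized
#'   fluorescence, dimensionless).
#' @param frame_interval_ms positive scalar, ms per sample.
#' @return a `trace` object.
#' @export
as_trace <- function(values, frame_interval_ms) {
  values <- as.numeric(values)
  if (length(values) < 8L) stop("trace needs >= 8 samples", call. = FALSE)
  if (!all(is.finite(values))) stop("trace values must be finite", call. = FALSE)
  if (frame_interval_ms <= 0) stop("frame interval must be > 0", call. = FALSE)
  structure(list(values = values, frame_interval_ms = frame_interval_ms),
            class = "trace")
}

#' One beat's index window within a trace
#'
#' Indices are 1-based and inclusive; the upstroke index lies strictly inside
#' the window.
#'
#' @param start,end first and last frame of the window.
#' @param upstroke frame index of the detected upstroke.
#' @return a `beat_window` object.
#' @export
beat_window <- function(start, end, upstroke) {
  if (!(start < upstroke && upstroke < end))
    stop("need start < upstroke < end", call. = FALSE)
  structure(list(start = as.integer(start), end = as.integer(end),
                 upstroke = as.integer(upstroke)), class = "beat_window")
}

# first linearly interpolated crossing of `level`; direction +1 up, -1 down.
# returns fractional 1-based index or NA.
first_crossing <- function(v, level, from, to, direction = 1L) {
  if (to <= from) return(NA_real_)
  idx <- from:(to - 1L)
  if (direction > 0) {
    hit <- which(v[idx] < level & v[idx + 1L] >= level)
  } else {
    hit <- which(v[idx] > level & v[idx + 1L] <= level)
  }
  if (!length(hit)) {
    # exact start on the level counts as an immediate crossing
    if ((direction > 0 && v[from] >= level) ||
        (direction < 0 && v[from] <= level)) return(as.numeric(from))
    return(NA_real_)
  }
  k <- idx[hit[1L]]
  k + (level - v[k]) / (v[k + 1L] - v[k])
}

# baseline = mean of the first 20% of the pre-upstroke segment of the window
beat_baseline <- function(v, w) {
  pre <- w$upstroke - w$start
  n <- max(1L, floor(0.2 * pre))
  mean(v[w$start:(w$start + n - 1L)])
}

beat_peak_idx <- function(v, w) {
  w$start - 1L + which.max(v[w$start:w$end])
}

#' Segment a paced trace into beat windows
#'
#' Detects upstrokes as upward mid-level crossings separated by at least
#' `min_cycle_ms`, requiring the trace excursion to exceed `prominence` of
#' the full amplitude. Window boundaries are placed at the diastolic minima
#' between consecutive upstrokes; each window contains exactly one upstroke
#' (its maximum-slope frame).
#'
#' @param trace a [as_trace()] object, expected roughly normalized to [0, 1].
#' @param min_cycle_ms shortest allowed cycle length (default 100 ms; pacing
#'   in the bundled simulator uses a 150 ms basic cycle length).
#' @param prominence minimum beat excursion as a fraction of the trace
#'   amplitude.
#' @return list of [beat_window()] (empty, with a warning, if no beats).
#' @export
segment_beats <- function(trace, min_cycle_ms = 100, prominence = 0.5) {
  v <- trace$values
  dt <- trace$frame_interval_ms
  n <- length(v)
  rng <- range(v)
  amp <- rng[2] - rng[1]
  if (amp <= 0) {
    warning("flat trace: no beats detected", call. = FALSE)
    return(list())
  }
  mid <- rng[1] + pmax(prominence, 0.5) * amp
  up <- which(v[-n] < mid & v[-1L] >= mid)
  if (!length(up)) {
    warning("no beats detected", call. = FALSE)
    return(list())
  }
  min_gap <- max(2L, round(min_cycle_ms / dt))
  keep <- up[1L]
  for (k in up[-1L]) if (k - keep[length(keep)] >= min_gap) keep <- c(keep, k)
  up <- keep
  nb <- length(up)
  # boundaries at diastolic minima midway between upstrokes
  bounds <- integer(nb + 1L)
  bounds[1L] <- 1L
  bounds[nb + 1L] <- n
  if (nb > 1L) for (i in seq_len(nb - 1L)) {
    seg <- up[i]:up[i + 1L]
    bounds[i + 1L] <- seg[which.min(v[seg])]
  }
  out <- vector("list", nb)
  for (i in seq_len(nb)) {
    s <- bounds[i]; e <- bounds[i + 1L]
    dseg <- diff(v[s:e])
    us <- s - 1L + which.max(dseg)  # earliest tie by which.max
    if (us <= s) us <- s + 1L
    if (us >= e) us <- e - 1L
    out[[i]] <- beat_window(s, e, us)
  }
  out
}

#' Activation time of one beat
#'
#' `max_slope` (default): the time of the largest first difference within
#' the window (earliest on ties). At a strict derivative maximum (smooth
#' upstroke) the forward difference is placed at its interval midpoint and
#' refined by parabolic interpolation of the three-point derivative
#' neighborhood. On a derivative plateau (linear upstroke) the vertex is
#' ill-defined; there the onset is recovered sub-frame from the partial
#' first difference leading into the plateau, which is exact for noiseless
#' piecewise-linear upstrokes. `level_crossing`: the linearly interpolated
#' time at which the upstroke first reaches 50% of the beat amplitude -
#' sub-frame resolution, preferred for conduction-velocity work.
#'
#' @param trace a [as_trace()] object (normalized).
#' @param window a [beat_window()].
#' @param method `"max_slope"` or `"level_crossing"`.
#' @param level crossing level as fraction of beat amplitude.
#' @return activation time in ms from the start of the recording, or `NA` if
#'   the window has no positive slope.
#' @export
activation_time <- function(trace, window,
                            method = c("max_slope", "level_crossing"),
                            level = 0.5) {
  method <- match.arg(method)
  v <- trace$values
  dt <- trace$frame_interval_ms
  w <- window
  d <- diff(v[w$start:w$end])
  if (max(d) <= 0) return(NA_real_)
  if (method == "max_slope") {
    dmax <- max(d)
    tol <- 1e-6 * dmax  # near-ties are derivative plateaus, not strict maxima
    k <- which(d >= dmax - tol)[1L]  # earliest tie
    left <- w$start - 1L + k - 1L    # 0-based time of d[k]'s left sample
    if (k < length(d) && d[k + 1L] >= dmax - tol) {
      # derivative plateau (linear upstroke): the partial first difference
      # just before the plateau locates the onset within the frame exactly
      r <- if (k > 1L) max(0, min(1, d[k - 1L] / d[k])) else 0
      return((left - r) * dt)
    }
    # strict maximum: forward difference belongs at the interval midpoint;
    # parabolic vertex refinement when the 3-point neighborhood allows it
    refine <- 0
    if (k > 1L && k < length(d)) {
      denom <- d[k - 1L] - 2 * d[k] + d[k + 1L]
      if (denom < 0)
        refine <- max(-0.5, min(0.5, 0.5 * (d[k - 1L] - d[k + 1L]) / denom))
    }
    return((left + 0.5 + refine) * dt)
  }
  base <- beat_baseline(v, w)
  pk <- beat_peak_idx(v, w)
  amp <- v[pk] - base
  if (amp <= 0) return(NA_real_)
  x <- first_crossing(v, base + level * amp, w$start, pk, +1L)
  if (is.na(x)) return(NA_real_)
  (x - 1) * dt
}

#' Upstroke rise time between two amplitude fractions
#'
#' Time for the upstroke to go from `lo` to `hi` of the beat amplitude
#' (defaults 20% to 90%), by linear interpolation of the first crossings.
#' Invariant under affine rescaling of the trace.
#'
#' @inheritParams activation_time
#' @param lo,hi amplitude fractions, `0 < lo < hi < 1`.
#' @return rise time in ms, or `NA` if a level is never reached.
#' @export
rise_time <- function(trace, window, lo = 0.2, hi = 0.9) {
  v <- trace$values
  dt <- trace$frame_interval_ms
  w <- window
  base <- beat_baseline(v, w)
  pk <- beat_peak_idx(v, w)
  amp <- v[pk] - base
  if (amp <= 0) return(NA_real_)
  x_lo <- first_crossing(v, base + lo * amp, w$start, pk, +1L)
  x_hi <- first_crossing(v, base + hi * amp, w$start, pk, +1L)
  if (is.na(x_lo) || is.na(x_hi)) return(NA_real_)
  (x_hi - x_lo) * dt
}

#' Duration at a repolarization level (APD / CaTD)
#'
#' Time from the activation time (max-slope detector by default) to the
#' linearly interpolated downstroke crossing of `(1 - level)` of the beat
#' amplitude above the diastolic baseline. `level = 0.8` gives APD80 on
#' voltage and CaTD80 on calcium traces.
#'
#' @inheritParams activation_time
#' @param level repolarization fraction in (0, 1).
#' @param act_method activation detector passed to [activation_time()].
#' @return duration in ms, or `NA` when the crossing is not reached inside
#'   the window.
#' @export
duration_at_level <- function(trace, window, level = 0.8,
                              act_method = "max_slope") {
  stopifnot(level > 0, level < 1)
  v <- trace$values
  dt <- trace$frame_interval_ms
  w <- window
  act <- activation_time(trace, window, method = act_method)
  if (is.na(act)) return(NA_real_)
  base <- beat_baseline(v, w)
  pk <- beat_peak_idx(v, w)
  amp <- v[pk] - base
  if (amp <= 0) return(NA_real_)
  x <- first_crossing(v, base + (1 - level) * amp, pk, w$end, -1L)
  if (is.na(x)) return(NA_real_)
  (x - 1) * dt - act
}

#' Calcium transient decay rate by log-linear fit
#'
#' Fits a least-squares line to `log(value - baseline)` over the decay
#' segment between `fit_hi` and `fit_lo` of the beat amplitude and returns
#' the rate constant `-slope` in 1/s. Exact on noiseless single exponentials.
#' A fit with R-squared below `r2_min` is flagged (`flagged = TRUE`) as
#' evidence the decay is not exponential.
#'
#' @inheritParams activation_time
#' @param fit_hi,fit_lo amplitude fractions bounding the fitted segment.
#' @param r2_min flag threshold on the log-linear R-squared.
#' @return list with `rate_per_s`, `r2`, `flagged`; `rate_per_s` is `NA` when
#'   fewer than 4 usable samples exist or the segment is non-positive after
#'   baseline subtraction.
#' @export
decay_rate <- function(trace, window, fit_hi = 0.9, fit_lo = 0.3,
                       r2_min = 0.95) {
  v <- trace$values
  dt <- trace$frame_interval_ms
  w <- window
  base <- beat_baseline(v, w)
  pk <- beat_peak_idx(v, w)
  amp <- v[pk] - base
  bad <- list(rate_per_s = NA_real_, r2 = NA_real_, flagged = TRUE)
  if (amp <= 0) return(bad)
  rel <- (v - base) / amp
  idx <- pk:w$end
  inseg <- idx[rel[idx] <= fit_hi]
  if (!length(inseg)) return(bad)
  from <- inseg[1L]
  below <- idx[idx >= from & rel[idx] < fit_lo]
  to <- if (length(below)) below[1L] - 1L else w$end
  seg <- from:to
  seg <- seg[v[seg] - base > 0]
  if (length(seg) < 4L) return(bad)
  y <- log(v[seg] - base)
  tt <- (seg - 1) * dt / 1000  # seconds
  fit <- stats::lm.fit(cbind(1, tt), y)
  slope <- fit$coefficients[2L]
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  list(rate_per_s = -unname(slope), r2 = r2, flagged = r2 < r2_min)
}

metric_units <- function(metric) {
  switch(metric, decay_rate = "s^-1", amplitude = "a.u.", "ms")
}

#' Per-pixel metric map over one beat
#'
#' Applies one of the per-trace metrics to every masked pixel's `beat_index`-th
#' beat. Pixels that are unmasked, have too few beats, or whose metric fails
#' are marked invalid (`NA`).
#'
#' @param stack a conditioned, normalized [movie_stack()].
#' @param mask a [pixel_mask()].
#' @param metric one of `"activation_time"`, `"rise_time"`, `"duration"`
#'   (APD/CaTD at `params$level`), `"decay_rate"`, `"amplitude"`.
#' @param beat_index which beat (1-based).
#' @param params metric parameters: `level`, `lo`, `hi`, `act_method`,
#'   `fit_hi`, `fit_lo`, `min_cycle_ms`, `prominence` as applicable.
#' @return a [new_parameter_map()].
#' @export
parameter_map <- function(stack, mask, metric, beat_index = 1L,
                          params = list()) {
  known <- c("activation_time", "rise_time", "duration", "decay_rate",
             "amplitude")
  if (!metric %in% known)
    stop("unknown metric `", metric, "`; expected one of: ",
         paste(known, collapse = ", "), call. = FALSE)
  stopifnot_mask_matches(mask, stack)
  d <- dim(stack$frames)
  dt <- stack$frame_interval_ms
  vals <- matrix(NA_real_, d[2], d[3])
  inc <- which(mask$include)
  if (!length(inc)) {
    warning("empty mask: all-invalid map", call. = FALSE)
    return(new_parameter_map(vals, metric, metric_units(metric)))
  }
  m <- matrix(stack$frames, nrow = d[1])
  p <- function(name, default) if (is.null(params[[name]])) default else params[[name]]
  min_cycle <- p("min_cycle_ms", 100)
  prom <- p("prominence", 0.5)
  for (ii in inc) {
    tr <- structure(list(values = m[, ii], frame_interval_ms = dt),
                    class = "trace")
    wins <- withCallingHandlers(
      segment_beats(tr, min_cycle_ms = min_cycle, prominence = prom),
      warning = function(w) invokeRestart("muffleWarning"))
    if (length(wins) < beat_index) next
    w <- wins[[beat_index]]
    vals[ii] <- switch(metric,
      activation_time = activation_time(tr, w,
        method = p("act_method", "max_slope"), level = p("level", 0.5)),
      rise_time = rise_time(tr, w, lo = p("lo", 0.2), hi = p("hi", 0.9)),
      duration = duration_at_level(tr, w, level = p("level", 0.8),
        act_method = p("act_method", "max_slope")),
      decay_rate = decay_rate(tr, w, fit_hi = p("fit_hi", 0.9),
        fit_lo = p("fit_lo", 0.3))$rate_per_s,
      amplitude = {
        base <- beat_baseline(tr$values, w)
        tr$values[beat_peak_idx(tr$values, w)] - base
      })
  }
  new_parameter_map(vals, metric, metric_units(metric))
}

# analytic signal of each column via FFT (positive-frequency doubling)
analytic_signal <- function(m) {
  n <- nrow(m)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2L:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2L:((n + 1L) / 2L)] <- 2
  }
  stats::mvfft(stats::mvfft(m) * h, inverse = TRUE) / n
}

#' Instantaneous phase movie
#'
#' Per-pixel instantaneous phase of the zero-mean trace from its
#' analytic-signal (Hilbert) embedding, in `(-pi, pi]`. Each beat contributes
#' one full 2*pi wrap. Constant or unmasked pixels are `NA`.
#'
#' @param stack a conditioned [movie_stack()].
#' @param mask optional [pixel_mask()].
#' @return `T x H x W` array of phases.
#' @export
phase_movie <- function(stack, mask = NULL) {
  d <- dim(stack$frames)
  m <- matrix(stack$frames, nrow = d[1])
  mu <- colMeans(m)
  m <- m - rep(mu, each = d[1])
  rng <- apply(m, 2, function(x) max(x) - min(x))
  z <- analytic_signal(m)
  ph <- atan2(Im(z), Re(z))
  ph[, rng <= 0] <- NA_real_
  if (!is.null(mask)) {
    stopifnot_mask_matches(mask, stack)
    ph[, !as.vector(mask$include)] <- NA_real_
  }
  array(ph, dim = d)
}

#' Count 2*pi phase wraps in a phase trace
#' @param phase numeric vector of phases in `(-pi, pi]`.
#' @return integer number of downward wraps (complete cycles).
#' @export
count_phase_wraps <- function(phase) {
  sum(diff(phase) < -pi, na.rm = TRUE)
}

#' Export a trace as CSV (time_ms, value)
#' @param trace a [as_trace()] object.
#' @param path CSV output path.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(
    time_ms = (seq_along(trace$values) - 1) * trace$frame_interval_ms,
    value = trace$values)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
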