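#' Movie stack: a calibrated fluorescence recording
#'
#' The universal container for an optical-mapping recording: a `T x H x W`
#' array of intensities plus temporal/spatial calibration and channel
#' semantics. Time is measured in ms from the first frame (frame `k`, 0-based,
#' is at `k * frame_interval_ms`); pixels are square, 0-based, origin at the
#' top-left with the row index increasing downward.
#'
#' @param frames numeric array with `dim = c(T, H, W)`, `T >= 2`, all values
#'   finite and non-negative (arbitrary fluorescence units).
#' @param frame_interval_ms positive scalar, ms per frame.
#' @param pixel_spacing_mm positive scalar, mm per pixel (square pixels).
#' @param channel one of `"voltage"`, `"calcium"`, `"other"`.
#' @param polarity `"positive"` or `"negative"`. Negative means fluorescence
#'   decreases on the physiological upstroke (e.g. RH237 voltage emission).
#' @param meta free-form named list of provenance.
#' @return an object of class `movie_stack`.
#' @export
movie_stack <- function(frames, frame_interval_ms, pixel_spacing_mm,
                        channel = c("other", "voltage", "calcium"),
                        polarity = c("positive", "negative"),
                        meta = list()) {
  channel <- match.arg(channel)
  polarity <- match.arg(polarity)
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("`frames` must be a T x H x W array", call. = FALSE)
  d <- dim(frames)
  if (d[1] < 2L || d[2] < 1L || d[3] < 1L)
    stop("need T >= 2 frames and H, W >= 1", call. = FALSE)
  if (!all(is.finite(frames)))
    stop("all intensities must be finite", call. = FALSE)
  if (!is.numeric(frame_interval_ms) || length(frame_interval_ms) != 1L ||
      !is.finite(frame_interval_ms) || frame_interval_ms <= 0)
    stop("`frame_interval_ms` must be a positive scalar", call. = FALSE)
  if (!is.numeric(pixel_spacing_mm) || length(pixel_spacing_mm) != 1L ||
      !is.finite(pixel_spacing_mm) || pixel_spacing_mm <= 0)
    stop("`pixel_spacing_mm` must be a positive scalar", call. = FALSE)
  structure(
    list(frames = frames,
         frame_interval_ms = as.numeric(frame_interval_ms),
         pixel_spacing_mm = as.numeric(pixel_spacing_mm),
         channel = channel, polarity = polarity, meta = meta),
    class = "movie_stack")
}

#' @export
print.movie_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf(
    "<movie_stack> %d frames of %d x %d (%s channel, %s polarity)\n",
    d[1], d[2], d[3], x$channel, x$polarity))
  cat(sprintf("  %.4g ms/frame (%.4g s, %.4g Hz), %.4g mm/pixel\n",
              x$frame_interval_ms, d[1] * x$frame_interval_ms / 1000,
              1000 / x$frame_interval_ms, x$pixel_spacing_mm))
  invisible(x)
}

#' @export
dim.movie_stack <- function(x) dim(x$frames)

#' Frame times in ms
#' @param stack a `movie_stack`.
#' @return numeric vector of length `T`: 0, dt, 2 dt, ...
#' @export
frame_times <- function(stack) {
  (seq_len(dim(stack$frames)[1]) - 1) * stack$frame_interval_ms
}

#' Extract one pixel's time series as a trace
#'
#' @param stack a `movie_stack`.
#' @param row,col 1-based pixel indices.
#' @return a `trace` object (see [as_trace()]).
#' @export
pixel_trace <- function(stack, row, col) {
  as_trace(stack$frames[, row, col], stack$frame_interval_ms)
}

replace_frames <- function(stack, frames) {
  stack$frames <- frames
  stack
}

#' Pixel inclusion mask
#'
#' @param include logical `H x W` matrix; `TRUE` marks analyzable pixels.
#' @return a `pixel_mask` object.
#' @export
pixel_mask <- function(include) {
  if (!is.matrix(include)) stop("`include` must be a matrix", call. = FALSE)
  storage.mode(include) <- "logical"
  if (anyNA(include)) stop("mask must not contain NA", call. = FALSE)
  structure(list(include = include), class = "pixel_mask")
}

#' @export
print.pixel_mask <- function(x, ...) {
  cat(sprintf("<pixel_mask> %d x %d, %d of %d pixels included\n",
              nrow(x$include), ncol(x$include),
              sum(x$include), length(x$include)))
  invisible(x)
}

stopifnot_mask_matches <- function(mask, stack) {
  if (!identical(dim(mask$include), dim(stack$frames)[2:3]))
    stop("mask shape does not match movie", call. = FALSE)
}

#' Scalar metric map over the imaging grid
#'
#' Holds an `H x W` matrix of per-pixel metric values. Excluded or failed
#' pixels are `NA` (the explicit invalid marker), never silent zeros. Values
#' outside the declared plausibility bounds are rejected at creation.
#'
#' @param values numeric `H x W` matrix; `NA` marks invalid pixels.
#' @param metric name tag, e.g. `"apd80"`, `"activation_time"`.
#' @param units unit string (`"ms"`, `"s^-1"`, ...).
#' @param bounds length-2 numeric; every finite value must lie within.
#' @return a `parameter_map` object.
#' @export
new_parameter_map <- function(values, metric, units = "ms",
                              bounds = c(-Inf, Inf)) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  storage.mode(values) <- "double"
  fin <- values[is.finite(values)]
  if (length(fin) && (any(fin < bounds[1]) || any(fin > bounds[2])))
    stop(sprintf("values outside plausibility bounds [%g, %g] for %s",
                 bounds[1], bounds[2], metric), call. = FALSE)
  values[!is.finite(values)] <- NA_real_
  structure(list(values = values, metric = metric, units = units,
                 bounds = bounds),
            class = "parameter_map")
}

#' @export
print.parameter_map <- function(x, ...) {
  ok <- is.finite(x$values)
  cat(sprintf("<parameter_map> %s [%s], %d x %d (%d valid)\n",
              x$metric, x$units, nrow(x$values), ncol(x$values), sum(ok)))
  if (any(ok))
    cat(sprintf("  range %.4g .. %.4g, mean %.4g\n",
                min(x$values[ok]), max(x$values[ok]), mean(x$values[ok])))
  invisible(x)
}

#' Mean of a parameter map over its valid pixels
#' @param map a `parameter_map`.
#' @param mask optional `pixel_mask` restricting the average further.
#' @return scalar mean over valid (and masked) pixels.
#' @export
map_mean <- function(map, mask = NULL) {
  v <- map$values
  if (!is.null(mask)) v[!mask$include] <- NA_real_
  mean(v, na.rm = TRUE)
}
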