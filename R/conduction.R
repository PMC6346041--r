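#' Local polynomial fit of the activation surface and its gradient
#'
#' Fits a least-squares polynomial surface `T(x, y)` of order 1 or 2 to the
#' valid activation times in an odd window around `center`, in mm coordinates
#' relative to the center (x along columns, y along rows, row index
#' increasing downward). Returns the analytic gradient at the center and the
#' coefficient of determination of the fit.
#'
#' @param act_values numeric `H x W` matrix of activation times in ms (`NA`
#'   marks invalid pixels), e.g. `parameter_map$values`.
#' @param center `c(row, col)`, 1-based.
#' @param window odd window size in pixels.
#' @param order polynomial order, 1 or 2.
#' @param spacing_mm pixel spacing in mm.
#' @return list with `gradient` (`c(gx, gy)` in ms/mm), `r2`, and `n` valid
#'   pixels used; `NULL` when the window has too few valid pixels
#'   (`< max(10, n_coef + 2)`).
#' @export
local_polynomial_gradient <- function(act_values, center, window = 5L,
                                      order = 2L, spacing_mm = 0.1) {
  window <- as.integer(window)
  if (window %% 2L == 0L) stop("`window` must be odd", call. = FALSE)
  if (!order %in% 1:2) stop("`order` must be 1 or 2", call. = FALSE)
  half <- (window - 1L) %/% 2L
  rows <- (center[1] - half):(center[1] + half)
  cols <- (center[2] - half):(center[2] + half)
  if (min(rows) < 1L || min(cols) < 1L ||
      max(rows) > nrow(act_values) || max(cols) > ncol(act_values))
    stop("window extends outside the map", call. = FALSE)
  z <- act_values[rows, cols]
  xy <- expand.grid(y = (rows - center[1]) * spacing_mm,
                    x = (cols - center[2]) * spacing_mm)
  ok <- is.finite(z)
  n_coef <- if (order == 1L) 3L else 6L
  if (sum(ok) < max(10L, n_coef + 2L)) return(NULL)
  x <- xy$x[ok]; y <- xy$y[ok]; zz <- as.vector(z)[ok]
  X <- if (order == 1L) cbind(1, x, y) else cbind(1, x, y, x^2, x * y, y^2)
  fit <- stats::lm.fit(X, zz)
  ss_res <- sum(fit$residuals^2)
  ss_tot <- sum((zz - mean(zz))^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else as.numeric(ss_res < 1e-18)
  # with coordinates centered on the window, dT/dx and dT/dy at the center
  # are the linear coefficients
  list(gradient = unname(fit$coefficients[2:3]), r2 = r2, n = sum(ok))
}

#' Conduction-velocity vector field (Bayly method)
#'
#' Slides an odd window over the activation map, fits a local polynomial
#' surface at every interior pixel, and converts each gradient to a velocity
#' vector `v = grad(T) / |grad(T)|^2` (direction of propagation, speed
#' `1 / |grad T|`), in m/s (mm/ms). Windows failing the fit-quality or speed
#' gates are excluded and counted.
#'
#' @param act_map a `parameter_map` of activation times (ms) or a plain
#'   numeric matrix.
#' @param spacing_mm pixel spacing in mm.
#' @param window odd window size in pixels.
#' @param order polynomial order (1 or 2).
#' @param r2_min minimum fit R-squared to retain a window.
#' @param speed_bounds `c(min, max)` plausible speeds in m/s.
#' @param step stride between window centers in pixels.
#' @return a `velocity_field`: data frame with `row`, `col`, `vx`, `vy`,
#'   `speed`, `r2`; attributes `spacing_mm`, `window`, `exclusions` (named
#'   counts).
#' @export
velocity_field <- function(act_map, spacing_mm = NULL, window = 5L,
                           order = 2L, r2_min = 0.9,
                           speed_bounds = c(0.05, 2.0), step = 1L) {
  if (inherits(act_map, "parameter_map")) act_map <- act_map$values
  if (is.null(spacing_mm))
    stop("`spacing_mm` is required", call. = FALSE)
  half <- (as.integer(window) - 1L) %/% 2L
  H <- nrow(act_map); W <- ncol(act_map)
  centers_r <- seq(1L + half, H - half, by = step)
  centers_c <- seq(1L + half, W - half, by = step)
  if (!length(centers_r) || !length(centers_c))
    stop("activation map smaller than one window", call. = FALSE)
  excl <- c(few_pixels = 0L, low_r2 = 0L, speed_gate = 0L)
  rows <- cols <- vxs <- vys <- spd <- r2s <- numeric(0)
  # fast path: precomputed pseudo-inverse for fully valid windows
  off <- ((-half):half) * spacing_mm
  xy <- expand.grid(y = off, x = off)
  Xfull <- if (order == 1L) cbind(1, xy$x, xy$y) else
    cbind(1, xy$x, xy$y, xy$x^2, xy$x * xy$y, xy$y^2)
  Pfull <- solve(crossprod(Xfull), t(Xfull))
  for (r in centers_r) for (cc in centers_c) {
    z <- act_map[(r - half):(r + half), (cc - half):(cc + half)]
    if (!anyNA(z)) {
      zz <- as.vector(z)
      beta <- Pfull %*% zz
      res <- zz - Xfull %*% beta
      ss_tot <- sum((zz - mean(zz))^2)
      r2 <- if (ss_tot > 0) 1 - sum(res^2) / ss_tot else
        as.numeric(sum(res^2) < 1e-18)
      g <- beta[2:3]
    } else {
      fit <- local_polynomial_gradient(act_map, c(r, cc), window = window,
                                       order = order, spacing_mm = spacing_mm)
      if (is.null(fit)) { excl["few_pixels"] <- excl["few_pixels"] + 1L; next }
      g <- fit$gradient; r2 <- fit$r2
    }
    g2 <- sum(g^2)
    if (g2 <= 0) { excl["speed_gate"] <- excl["speed_gate"] + 1L; next }
    if (r2 < r2_min) { excl["low_r2"] <- excl["low_r2"] + 1L; next }
    v <- g / g2  # mm/ms = m/s
    s <- sqrt(sum(v^2))
    if (s < speed_bounds[1] || s > speed_bounds[2]) {
      excl["speed_gate"] <- excl["speed_gate"] + 1L; next
    }
    rows <- c(rows, r); cols <- c(cols, cc)
    vxs <- c(vxs, v[1]); vys <- c(vys, v[2]); spd <- c(spd, s)
    r2s <- c(r2s, r2)
  }
  if (!length(rows)) warning("no windows retained", call. = FALSE)
  out <- data.frame(row = rows, col = cols, vx = vxs, vy = vys,
                    speed = spd, r2 = r2s)
  attr(out, "spacing_mm") <- spacing_mm
  attr(out, "window") <- as.integer(window)
  attr(out, "exclusions") <- excl
  class(out) <- c("velocity_field", class(out))
  out
}

# smallest angular distance between two undirected axes, in radians [0, pi/2]
axis_distance <- function(a, b) {
  d <- (a - b) %% pi
  pmin(d, pi - d)
}

#' Longitudinal/transverse conduction-velocity summary
#'
#' Splits the velocity field into a longitudinal sector (vector directions
#' within `sector_halfwidth_deg` of the fiber axis, directions treated as
#' undirected axes) and a transverse sector (within the same half-width of
#' the perpendicular), and reports the median speed of each, their ratio
#' (anisotropy ratio), and the axis used. If `fiber_angle` is not given the
#' axis is estimated as the direction maximizing median speed over 5-degree
#' bins. Axes are labeled so the longitudinal speed is the faster one
#' (`anisotropy_ratio >= 1`). Windows closer to `stimulus_site` than
#' `exclude_radius_mm` (default two window widths) are excluded, since
#' wavefront curvature near the source biases speeds.
#'
#' @param field a [velocity_field()].
#' @param fiber_angle known fiber axis in radians (angle from the +x/column
#'   axis toward +y/down), or `NULL` to estimate.
#' @param sector_halfwidth_deg angular half-width of each sector.
#' @param min_vectors minimum retained vectors to attempt a summary.
#' @param stimulus_site optional `c(row, col)` of the pacing site, 1-based.
#' @param exclude_radius_mm exclusion radius around the stimulus.
#' @return a `cv_summary` list: `cv_long_m_per_s`, `cv_trans_m_per_s`,
#'   `anisotropy_ratio`, `fiber_angle_rad` in `[0, pi)`, sector counts,
#'   `valid` flag and `diagnostic` message.
#' @export
cv_summary <- function(field, fiber_angle = NULL, sector_halfwidth_deg = 15,
                       min_vectors = 20L, stimulus_site = NULL,
                       exclude_radius_mm = NULL) {
  spacing <- attr(field, "spacing_mm")
  win <- attr(field, "window")
  df <- as.data.frame(field)
  if (!is.null(stimulus_site)) {
    if (is.null(exclude_radius_mm))
      exclude_radius_mm <- 2 * win * spacing
    dist_mm <- spacing * sqrt((df$row - stimulus_site[1])^2 +
                              (df$col - stimulus_site[2])^2)
    df <- df[dist_mm >= exclude_radius_mm, , drop = FALSE]
  }
  invalid <- function(msg) {
    structure(list(cv_long_m_per_s = NA_real_, cv_trans_m_per_s = NA_real_,
                   anisotropy_ratio = NA_real_, fiber_angle_rad = NA_real_,
                   n_long = 0L, n_trans = 0L, valid = FALSE,
                   diagnostic = msg), class = "cv_summary")
  }
  if (nrow(df) < min_vectors)
    return(invalid(sprintf("only %d retained vectors (need >= %d)",
                           nrow(df), min_vectors)))
  ang <- atan2(df$vy, df$vx) %% pi  # undirected propagation axis
  if (is.null(fiber_angle)) {
    bins <- seq(0, pi, by = 5 * pi / 180)
    centers <- bins[-length(bins)] + 2.5 * pi / 180
    med <- vapply(centers, function(a) {
      in_bin <- axis_distance(ang, a) <= 2.5 * pi / 180
      if (sum(in_bin) >= 3L) stats::median(df$speed[in_bin]) else NA_real_
    }, numeric(1))
    if (all(is.na(med))) return(invalid("no populated angular bins"))
    fiber_angle <- centers[which.max(med)]
  }
  hw <- sector_halfwidth_deg * pi / 180
  in_long <- axis_distance(ang, fiber_angle) <= hw
  in_trans <- axis_distance(ang, fiber_angle + pi / 2) <= hw
  if (!any(in_long)) return(invalid("empty longitudinal sector"))
  if (!any(in_trans)) return(invalid("empty transverse sector"))
  cv_l <- stats::median(df$speed[in_long])
  cv_t <- stats::median(df$speed[in_trans])
  axis <- fiber_angle %% pi
  if (cv_t > cv_l) {  # relabel so the longitudinal axis is the faster one
    tmp <- cv_l; cv_l <- cv_t; cv_t <- tmp
    tmp <- in_long; in_long <- in_trans; in_trans <- tmp
    axis <- (axis + pi / 2) %% pi
  }
  structure(list(cv_long_m_per_s = cv_l, cv_trans_m_per_s = cv_t,
                 anisotropy_ratio = cv_l / cv_t, fiber_angle_rad = axis,
                 n_long = sum(in_long), n_trans = sum(in_trans),
                 valid = TRUE, diagnostic = ""), class = "cv_summary")
}

#' @export
print.cv_summary <- function(x, ...) {
  if (!x$valid) {
    cat("<cv_summary> invalid:", x$diagnostic, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<cv_summary> CV_L %.3f m/s (n=%d), CV_T %.3f m/s (n=%d), AR %.2f, axis %.1f deg\n",
    x$cv_long_m_per_s, x$n_long, x$cv_trans_m_per_s, x$n_trans,
    x$anisotropy_ratio, x$fiber_angle_rad * 180 / pi))
  invisible(x)
}

#' Export a velocity field as CSV
#' @param field a [velocity_field()].
#' @param path CSV output path.
#' @export
write_velocity_csv <- function(field, path) {
  utils::write.table(as.data.frame(field), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}
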