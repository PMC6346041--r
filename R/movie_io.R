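#' @importFrom jsonlite read_json write_json
#' @importFrom utils write.table read.table
NULL

sidecar_path_for <- function(path) paste0(path, ".json")

is_tiff_path <- function(path) grepl("\\.tiff?$", path, ignore.case = TRUE)

read_sidecar <- function(sidecar_path) {
  if (!file.exists(sidecar_path))
    stop("calibration sidecar not found: ", sidecar_path, call. = FALSE)
  sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  for (k in c("frame_interval_ms", "pixel_spacing_mm", "channel", "polarity"))
    if (is.null(sc[[k]]))
      stop("sidecar missing required field `", k, "`", call. = FALSE)
  if (length(sc$pixel_spacing_mm) != 1L)
    stop("anisotropic pixel spacing is not supported (square pixels only)",
         call. = FALSE)
  if (is.null(sc$scale)) sc$scale <- 1
  sc
}

#' Read a movie stack from TIFF or raw binary plus JSON sidecar
#'
#' Open interchange formats: multipage 16-bit grayscale TIFF (one page per
#' frame) or raw little-endian unsigned-16-bit frame-major binary. A JSON
#' sidecar supplies the calibration (`frame_interval_ms`, `pixel_spacing_mm`,
#' `channel`, `polarity`, optional intensity `scale`, and for raw binary the
#' `shape` as `[T, H, W]`). Stored integers are multiplied by `scale` on read.
#' Inconsistent metadata is rejected, never repaired.
#'
#' @param path movie file (`.tif`/`.tiff` treated as TIFF, anything else as
#'   raw binary).
#' @param sidecar_path JSON sidecar; defaults to `<path>.json`.
#' @return a [movie_stack()].
#' @export
read_movie <- function(path, sidecar_path = sidecar_path_for(path)) {
  if (!file.exists(path)) stop("movie file not found: ", path, call. = FALSE)
  sc <- read_sidecar(sidecar_path)
  if (is_tiff_path(path)) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE, info = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    bits <- attr(pages[[1]], "bits.per.sample")
    if (!is.null(bits) && bits != 16L)
      stop("unsupported TIFF: expected 16 bits per sample, got ", bits,
           call. = FALSE)
    if (length(dim(pages[[1]])) != 2L)
      stop("unsupported TIFF: expected single-channel grayscale pages",
           call. = FALSE)
    d <- c(length(pages), dim(pages[[1]]))
    if (!is.null(sc$shape) && !identical(as.integer(sc$shape), as.integer(d)))
      stop(sprintf("sidecar shape [%s] does not match TIFF content [%s]",
                   paste(sc$shape, collapse = ","),
                   paste(d, collapse = ",")), call. = FALSE)
    frames <- array(0, dim = d)
    for (t in seq_len(d[1])) frames[t, , ] <- pages[[t]]
  } else {
    if (is.null(sc$shape) || length(sc$shape) != 3L)
      stop("raw binary requires sidecar `shape` = [T, H, W]", call. = FALSE)
    d <- as.integer(sc$shape)
    n_expect <- prod(d)
    n_bytes <- file.size(path)
    if (n_bytes != 2 * n_expect)
      stop(sprintf(
        "raw file holds %d bytes but sidecar shape [%s] needs %d",
        n_bytes, paste(d, collapse = ","), 2 * n_expect), call. = FALSE)
    con <- file(path, "rb"); on.exit(close(con))
    v <- readBin(con, what = "integer", n = n_expect, size = 2L,
                 signed = FALSE, endian = "little")
    # file is frame-major, each frame row-major; R arrays are column-major
    frames <- aperm(array(v, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  }
  frames <- frames * sc$scale
  movie_stack(frames, sc$frame_interval_ms, sc$pixel_spacing_mm,
              channel = sc$channel, polarity = sc$polarity,
              meta = as.list(sc$meta))
}

#' Write a movie stack as TIFF or raw binary plus JSON sidecar
#'
#' Intensities are stored as unsigned 16-bit integers. Values above 65535
#' either abort (default) or, with `rescale = TRUE`, are divided by a scale
#' factor recorded in the sidecar so the round trip is exact to one
#' quantization step. [read_movie()] after `write_movie()` is the identity on
#' integer-valued frames within range, and on all calibration fields.
#'
#' @param stack a [movie_stack()].
#' @param path output movie path (`.tif`/`.tiff` for TIFF, else raw binary).
#' @param sidecar_path JSON sidecar path; defaults to `<path>.json`.
#' @param rescale allow automatic intensity rescaling into the u16 range.
#' @return invisibly, the sidecar list.
#' @export
write_movie <- function(stack, path, sidecar_path = sidecar_path_for(path),
                        rescale = FALSE) {
  v <- stack$frames
  if (min(v) < 0) stop("negative intensities cannot be stored", call. = FALSE)
  scale <- 1
  if (max(v) > 65535) {
    if (!rescale)
      stop("max intensity ", max(v), " exceeds 16-bit range; ",
           "pass rescale = TRUE to store a scaled copy", call. = FALSE)
    scale <- max(v) / 65535
  }
  stored <- round(v / scale)
  d <- dim(stored)
  sc <- list(frame_interval_ms = stack$frame_interval_ms,
             pixel_spacing_mm = stack$pixel_spacing_mm,
             shape = as.integer(d), channel = stack$channel,
             polarity = stack$polarity, scale = scale, meta = stack$meta)
  if (is_tiff_path(path)) {
    pages <- lapply(seq_len(d[1]), function(t) stored[t, , ] / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    # frame-major, row-major within frame, little-endian u16
    flat <- as.integer(aperm(stored, c(3, 2, 1)))
    bytes <- as.raw(rbind(flat %% 256L, flat %/% 256L))
    con <- file(path, "wb")
    writeBin(bytes, con)
    close(con)
  }
  jsonlite::write_json(sc, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(sc)
}

#' Crop to a region of interest and spatially bin
#'
#' Each output pixel is the mean of its `bin_factor x bin_factor` block;
#' `pixel_spacing_mm` is multiplied by `bin_factor`. The mean intensity over
#' the ROI is conserved.
#'
#' @param stack a [movie_stack()].
#' @param roi `c(row, col, height, width)` in 0-based pixel coordinates
#'   (origin top-left); defaults to the full frame.
#' @param bin_factor positive integer; ROI height and width must be divisible
#'   by it.
#' @return a [movie_stack()] with spatial dims `roi / bin_factor`.
#' @export
crop_and_bin <- function(stack, roi = NULL, bin_factor = 1L) {
  d <- dim(stack$frames)
  if (is.null(roi)) roi <- c(0L, 0L, d[2], d[3])
  roi <- as.integer(roi)
  if (length(roi) != 4L || any(roi[3:4] < 1L))
    stop("`roi` must be c(row, col, height, width)", call. = FALSE)
  if (roi[1] < 0L || roi[2] < 0L ||
      roi[1] + roi[3] > d[2] || roi[2] + roi[4] > d[3])
    stop("roi extends outside the frame", call. = FALSE)
  bin_factor <- as.integer(bin_factor)
  if (bin_factor < 1L) stop("`bin_factor` must be >= 1", call. = FALSE)
  if (roi[3] %% bin_factor != 0L || roi[4] %% bin_factor != 0L)
    stop("roi dimensions must be divisible by bin_factor", call. = FALSE)
  sub <- stack$frames[, roi[1] + seq_len(roi[3]), roi[2] + seq_len(roi[4]),
                      drop = FALSE]
  if (bin_factor > 1L) {
    h2 <- roi[3] %/% bin_factor; w2 <- roi[4] %/% bin_factor
    out <- array(0, dim = c(d[1], h2, w2))
    for (i in seq_len(bin_factor)) for (j in seq_len(bin_factor)) {
      out <- out + sub[, seq(i, roi[3], by = bin_factor),
                       seq(j, roi[4], by = bin_factor), drop = FALSE]
    }
    sub <- out / bin_factor^2
  }
  stack$frames <- sub
  stack$pixel_spacing_mm <- stack$pixel_spacing_mm * bin_factor
  stack
}

#' Read and write pixel masks (PNG or CSV)
#'
#' PNG masks are binary images (any nonzero value includes the pixel); CSV
#' masks are 0/1 grids without headers.
#'
#' @param mask a [pixel_mask()].
#' @param path `.png` or `.csv` file.
#' @return `read_mask` returns a [pixel_mask()]; `write_mask` returns the path
#'   invisibly.
#' @export
write_mask <- function(mask, path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    png::writePNG(mask$include * 1.0, path)
  } else {
    utils::write.table(mask$include * 1L, path, sep = ",",
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(path) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
    if (length(dim(img)) == 3L) img <- img[, , 1]
    pixel_mask(img > 0.5)
  } else {
    m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE))
    dimnames(m) <- NULL
    pixel_mask(m != 0)
  }
}

#' Read and write parameter maps as CSV grids
#'
#' `H` rows by `W` columns, no headers; invalid pixels written as `NA`.
#'
#' @param map a [new_parameter_map()] object.
#' @param path CSV file.
#' @param metric,units tags for the re-read map.
#' @return `read_map_csv` returns a `parameter_map`.
#' @export
write_map_csv <- function(map, path) {
  utils::write.table(map$values, path, sep = ",", na = "NA",
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path, metric = "unknown", units = "ms") {
  m <- as.matrix(utils::read.table(path, sep = ",", header = FALSE,
                                   na.strings = "NA"))
  dimnames(m) <- NULL
  new_parameter_map(m, metric = metric, units = units)
}
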