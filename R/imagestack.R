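#' Calibrated image stack
#'
#' Container for a time-ordered stack of single-channel frames with physical
#' calibration. Frames are stored as a numeric array with dimensions
#' `(rows, cols, frames)`; pixel `(x, y)` (0-based, x = column, y = row,
#' origin at the top-left) of frame `k` is `frames[y + 1, x + 1, k]`.
#'
#' @param frames numeric array `(rows, cols, frames)`, or a matrix for a
#'   single frame.
#' @param pixel_size pixel pitch, micrometres per pixel (> 0).
#' @param frame_interval time between frames, seconds (> 0).
#' @return An object of class `image_stack` with elements `frames`,
#'   `pixel_size` (um/px) and `frame_interval` (s).
#' @examples
#' st <- image_stack(array(runif(64 * 64 * 3), c(64, 64, 3)), 0.1625, 0.02)
#' dim(st)
#' @export
image_stack <- function(frames, pixel_size, frame_interval) {
  if (is.matrix(frames)) frames <- array(frames, c(dim(frames), 1L))
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop_mbk("`frames` must be a (rows, cols, frames) array")
  if (dim(frames)[3] < 1L) stop_mbk("stack must contain at least one frame")
  check_scalar_pos(pixel_size, "pixel_size")
  check_scalar_pos(frame_interval, "frame_interval")
  structure(list(frames = frames, pixel_size = pixel_size,
                 frame_interval = frame_interval),
            class = "image_stack")
}

#' @export
dim.image_stack <- function(x) dim(x$frames)

#' Number of frames in a stack
#' @param stack an [image_stack()].
#' @return Integer frame count.
#' @export
n_frames <- function(stack) dim(stack$frames)[3]

#' Acquisition times of a stack
#' @param stack an [image_stack()].
#' @return Numeric vector of frame times in seconds, starting at 0.
#' @export
frame_times <- function(stack)
  (seq_len(n_frames(stack)) - 1L) * stack$frame_interval

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<image_stack> %d frame(s) of %d x %d px\n", d[3], d[1], d[2]))
  cat(sprintf("  pixel size     %.4f um/px (field %.1f x %.1f um)\n",
              x$pixel_size, d[2] * x$pixel_size, d[1] * x$pixel_size))
  cat(sprintf("  frame interval %.4f s (%.1f fps, %.2f s total)\n",
              x$frame_interval, 1 / x$frame_interval,
              d[3] * x$frame_interval))
  invisible(x)
}

#' Read a multi-page TIFF as a calibrated image stack
#'
#' Pages are loaded in file order and kept on their native intensity scale
#' (integer sample values are not rescaled to `[0, 1]`). Calibration is not
#' read from TIFF tags; it must be supplied. When `pixel_size` is omitted
#' the default for a 40x objective with a 6.5 um sensor pitch
#' (0.1625 um/px) is used with a warning, since tracking results are only
#' physically meaningful with the true calibration.
#'
#' @param path path to a multi-page TIFF (8/16-bit integer or float).
#' @param pixel_size micrometres per pixel; see Details for the default.
#' @param frame_interval seconds per frame (e.g. 0.02 for 50 fps).
#' @return An [image_stack()].
#' @seealso [write_stack()]
#' @export
read_stack <- function(path, pixel_size = NULL, frame_interval) {
  if (!file.exists(path)) stop_mbk("file not found: %s", path)
  if (is.null(pixel_size)) {
    pixel_size <- 0.1625
    warning("pixel_size not supplied; assuming 0.1625 um/px (40x objective, ",
            "6.5 um sensor pitch). Supply the true calibration for analysis.",
            call. = FALSE)
  }
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shp <- dim(pages[[1]])
  if (length(shp) > 2L)
    stop_mbk("multi-channel TIFF pages are not supported (got %s samples)",
             shp[3])
  ok <- vapply(pages, function(p) identical(dim(p)[1:2], shp[1:2]), logical(1))
  if (!all(ok))
    stop_mbk("TIFF pages differ in shape (page %d is %s, expected %d x %d)",
             which(!ok)[1], paste(dim(pages[[which(!ok)[1]]]), collapse = " x "),
             shp[1], shp[2])
  frames <- array(0, c(shp[1], shp[2], length(pages)))
  for (k in seq_along(pages)) frames[, , k] <- pages[[k]]
  image_stack(frames, pixel_size, frame_interval)
}

#' Write an image stack to a multi-page TIFF
#'
#' Intensities are quantized to unsigned 16-bit. With the default
#' `scale = NULL` the stack range is mapped to `[0, 65535]`; pass an explicit
#' `scale = c(lo, hi)` for a fixed mapping, or `scale = FALSE` when the data
#' are already integers in `[0, 65535]` (written bit-exactly).
#'
#' @param stack an [image_stack()].
#' @param path output path.
#' @param scale `NULL`, `FALSE`, or `c(lo, hi)`; see Details.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, scale = NULL) {
  fr <- stack$frames
  if (isFALSE(scale)) {
    if (min(fr) < 0 || max(fr) > 65535)
      stop_mbk("scale = FALSE requires intensities already in [0, 65535]")
    q <- round(fr)
  } else {
    rng <- if (is.null(scale)) range(fr) else scale
    if (diff(rng) <= 0) rng <- rng + c(0, 1)
    q <- round(pmax(0, pmin(1, (fr - rng[1]) / diff(rng))) * 65535)
  }
  pages <- lapply(seq_len(dim(q)[3]), function(k) q[, , k] / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
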