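#' Rectangular tissue geometry
#'
#' Describes one rectangular muscle bundle within the field of view. The
#' standard bundle is a 308 x 45 um rectangle (7:1 aspect ratio); the long
#' axis makes `long_axis_angle` degrees with the +x (column) direction,
#' measured toward +y (downward, image convention).
#'
#' @param center `c(x, y)` centre in micrometres, in the frame coordinate
#'   system (origin at the top-left pixel centre).
#' @param long_axis_angle degrees in `(-90, 90]`.
#' @param length,width bundle dimensions in micrometres (`length > width`).
#' @return An object of class `tissue_geometry`.
#' @examples
#' tissue_geometry(center = c(165, 50))
#' @export
tissue_geometry <- function(center, long_axis_angle = 0,
                            length = 308, width = 45) {
  if (!is.numeric(center) || base::length(center) != 2L)
    stop_mbk("`center` must be c(x, y) in micrometres")
  check_scalar_pos(length, "length")
  check_scalar_pos(width, "width")
  if (length <= width) stop_mbk("`length` must exceed `width`")
  if (long_axis_angle <= -90 || long_axis_angle > 90)
    stop_mbk("`long_axis_angle` must lie in (-90, 90]")
  structure(list(center = as.numeric(center),
                 long_axis_angle = long_axis_angle,
                 length = length, width = width),
            class = "tissue_geometry")
}

#' @export
print.tissue_geometry <- function(x, ...) {
  cat(sprintf(
    "<tissue_geometry> %.0f x %.0f um at (%.1f, %.1f) um, axis %.1f deg\n",
    x$length, x$width, x$center[1], x$center[2], x$long_axis_angle))
  invisible(x)
}

# unit vector along the long axis (image convention, y down)
axis_unit <- function(angle_deg) {
  a <- angle_deg * pi / 180
  c(cos(a), sin(a))
}

#' Tracking region of interest
#'
#' @param center `c(x, y)` integer pixel centre (0-based).
#' @param half_size `c(hx, hy)` half extent in pixels (template spans
#'   `2 * h + 1` pixels per axis); at least 4 px each.
#' @param label `"proximal"` or `"distal"`.
#' @param tissue_id identifier for the parent tissue.
#' @return An object of class `roi_spec`.
#' @export
roi_spec <- function(center, half_size = c(10, 10), label = "proximal",
                     tissue_id = "tissue") {
  half_size <- rep_len(as.integer(half_size), 2L)
  if (any(half_size < 4L)) stop_mbk("ROI half_size must be at least 4 px")
  structure(list(center = as.integer(round(center)), half_size = half_size,
                 label = match.arg(label, c("proximal", "distal")),
                 tissue_id = tissue_id),
            class = "roi_spec")
}

#' @export
print.roi_spec <- function(x, ...) {
  cat(sprintf("<roi_spec> %s [%s]: centre (%d, %d) px, half size (%d, %d) px\n",
              x$label, x$tissue_id, x$center[1], x$center[2],
              x$half_size[1], x$half_size[2]))
  invisible(x)
}

roi_in_frame <- function(roi, frame_dim, pad = 0L) {
  lo <- roi$center - roi$half_size - pad
  hi <- roi$center + roi$half_size + pad
  lo[1] >= 0L && lo[2] >= 0L && hi[1] <= frame_dim[2] - 1L &&
    hi[2] <= frame_dim[1] - 1L
}

#' Place the standard ROI pair on the inner 50% of a bundle
#'
#' Positions two template ROIs on the bundle long axis at `+/- length/4`
#' from the centre, so that their separation spans the inner 50% of the
#' bundle length -- the placement found to be most robust to small
#' positioning errors (see the ROI-placement analysis in
#' [roi_placement_sensitivity()]).
#'
#' @param geometry a [tissue_geometry()].
#' @param pixel_size micrometres per pixel.
#' @param roi_half_size half extent in pixels (scalar or `c(hx, hy)`).
#' @param frame_dim optional `c(rows, cols)`; when given, each ROI is
#'   checked to lie fully inside the frame.
#' @param tissue_id identifier stored in both ROIs.
#' @return A list with elements `proximal` and `distal` ([roi_spec()]s).
#'   Each ROI also carries `center_um`, its exact (unrounded) centre in um.
#' @examples
#' g <- tissue_geometry(center = c(165, 50))
#' place_rois_inner50(g, pixel_size = 0.1625,
#'                    frame_dim = c(615, 2031))
#' @export
place_rois_inner50 <- function(geometry, pixel_size, roi_half_size = 10,
                               frame_dim = NULL, tissue_id = "tissue") {
  check_scalar_pos(pixel_size, "pixel_size")
  u <- axis_unit(geometry$long_axis_angle)
  offsets <- list(proximal = -geometry$length / 4,
                  distal   = +geometry$length / 4)
  half <- rep_len(as.integer(roi_half_size), 2L)
  sep_px <- (geometry$length / 2) / pixel_size
  if (2 * max(half) >= sep_px)
    stop_mbk("ROI half_size (%d px) too large: templates would overlap at a separation of %.1f px",
             max(half), sep_px)
  rois <- lapply(names(offsets), function(lab) {
    c_um <- geometry$center + offsets[[lab]] * u
    r <- roi_spec(round(c_um / pixel_size), half, lab, tissue_id)
    r$center_um <- c_um
    if (!is.null(frame_dim) && !roi_in_frame(r, frame_dim))
      stop_mbk("%s ROI at (%d, %d) px falls outside the %d x %d frame",
               lab, r$center[1], r$center[2], frame_dim[2], frame_dim[1])
    r
  })
  names(rois) <- names(offsets)
  rois
}
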