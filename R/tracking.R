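#' Tracking parameters
#'
#' @param search_radius maximum displacement searched, pixels. Must be at
#'   least the expected peak displacement of the ROI.
#' @param subpixel refine the integer correlation peak to subpixel
#'   precision with a local quadratic (paraboloid) fit of the correlation
#'   surface (vertex clamped to +/- 0.5 px)?
#' @param reference `"first_frame"`, `"quiescent_auto"` (frame minimizing
#'   ROI motion over a rolling window), or an explicit 1-based frame index.
#' @param min_correlation QC threshold on the per-frame peak correlation.
#' @param method `"fft"` (FFT-accelerated, default) or `"direct"`
#'   (exhaustive spatial-domain evaluation; identical result, used as the
#'   independent oracle in tests).
#' @return A list of class `tracking_params`.
#' @export
tracking_params <- function(search_radius = 15L, subpixel = TRUE,
                            reference = "first_frame",
                            min_correlation = 0.5,
                            method = c("fft", "direct")) {
  if (search_radius < 1L) stop_mbk("search_radius must be >= 1 px")
  if (min_correlation <= 0 || min_correlation >= 1)
    stop_mbk("min_correlation must lie in (0, 1)")
  structure(list(search_radius = as.integer(search_radius),
                 subpixel = isTRUE(subpixel), reference = reference,
                 min_correlation = min_correlation,
                 method = match.arg(method)),
            class = "tracking_params")
}

# ---- zero-normalized cross-correlation -------------------------------------

# Exhaustive ZNCC between template T and all (2r+1)^2 placements inside the
# search window S (dimensions template + 2r).  Reference implementation.
zncc_direct <- function(template, window, radius) {
  th <- template - mean(template)
  tn <- sqrt(sum(th^2))
  nr <- nrow(template); nc <- ncol(template)
  out <- matrix(NA_real_, 2L * radius + 1L, 2L * radius + 1L)
  for (v in -radius:radius) {
    for (u in -radius:radius) {
      patch <- window[(radius + v + 1L):(radius + v + nr),
                      (radius + u + 1L):(radius + u + nc)]
      ph <- patch - mean(patch)
      pn <- sqrt(sum(ph^2))
      out[v + radius + 1L, u + radius + 1L] <-
        if (tn < 1e-12 || pn < 1e-12) 0 else sum(th * ph) / (tn * pn)
    }
  }
  out
}

# FFT-accelerated ZNCC: numerator by padded FFT correlation of the
# zero-mean template with the window; denominator from box sums of the
# window (integral images).
zncc_fft <- function(template, window, radius) {
  th <- template - mean(template)
  tn <- sqrt(sum(th^2))
  nr <- nrow(template); nc <- ncol(template)
  wr <- nrow(window); wc <- ncol(window)
  pr <- wr + nr - 1L; pc <- wc + nc - 1L  # linear (non-circular) correlation
  A <- matrix(0, pr, pc); A[1:wr, 1:wc] <- window
  B <- matrix(0, pr, pc); B[1:nr, 1:nc] <- th
  num_full <- Re(fft(fft(A) * Conj(fft(B)), inverse = TRUE)) / (pr * pc)
  # num_full[v+1, u+1] = sum_{y,x} window[y+v, x+u] * th[y, x], 0-based lags
  num <- num_full[1:(2L * radius + 1L), 1:(2L * radius + 1L)]
  # box sums of window and window^2 over template-size boxes
  s1 <- box_sums(window, nr, nc)
  s2 <- box_sums(window^2, nr, nc)
  npix <- nr * nc
  varw <- s2 - s1^2 / npix
  varw[varw < 0] <- 0
  den <- tn * sqrt(varw[1:(2L * radius + 1L), 1:(2L * radius + 1L)])
  out <- num / den
  out[!is.finite(out) | den < 1e-12] <- 0
  pmax(pmin(out, 1), -1)
}

# sums of all nr x nc boxes of M via cumulative sums; result[(v+1),(u+1)]
# is the sum of M[v+1:(v+nr), u+1:(u+nc)] (0-based offsets)
box_sums <- function(M, nr, nc) {
  R <- nrow(M); C <- ncol(M)
  Z <- matrix(0, R + 1L, C + 1L)
  Z[2:(R + 1L), 2:(C + 1L)] <- t(apply(apply(M, 2L, cumsum), 1L, cumsum))
  nv <- R - nr + 1L; nu <- C - nc + 1L
  rv0 <- 1:nv; rv1 <- (nr + 1L):(R + 1L)
  cu0 <- 1:nu; cu1 <- (nc + 1L):(C + 1L)
  Z[rv1, cu1, drop = FALSE] - Z[rv0, cu1, drop = FALSE] -
    Z[rv1, cu0, drop = FALSE] + Z[rv0, cu0, drop = FALSE]
}

# Subpixel refinement: least-squares paraboloid over the 3x3 correlation
# neighbourhood around the integer peak, vertex clamped to +/- 0.5 px.
# More noise-robust than the separable 3-point fit (9 samples constrain
# the vertex) at identical cost.
quad_refine_2d <- local({
  xs <- rep(-1:1, each = 3)      # column offset (x) in column-major order
  ys <- rep(-1:1, 3)             # row offset (y)
  X <- cbind(1, xs, ys, xs^2, ys^2, xs * ys)
  XtXinvXt <- solve(crossprod(X), t(X))
  function(N) {
    b <- XtXinvXt %*% as.vector(N)
    H <- matrix(c(2 * b[4], b[6], b[6], 2 * b[5]), 2L)
    v <- tryCatch(-solve(H, b[2:3]), error = function(e) c(0, 0))
    # only trust a concave vertex
    if (b[4] >= 0 || b[5] >= 0) v <- c(0, 0)
    pmax(-0.5, pmin(0.5, as.numeric(v)))
  }
})

# ---- ROI tracking ----------------------------------------------------------

#' Track a region of interest through an image stack
#'
#' For every frame, finds the displacement of the reference-frame template
#' that maximizes the zero-normalized cross-correlation within
#' `+/- search_radius` px, refined to subpixel precision by a quadratic
#' (paraboloid) fit of the correlation surface around the integer peak.
#' Zero-normalization (mean subtraction and variance scaling of both
#' template and candidate patch) makes the match robust to the slow
#' illumination drift typical of brightfield time series.
#'
#' @param stack an [image_stack()].
#' @param roi an [roi_spec()]; template and search window must fit inside
#'   the frame for all candidate displacements.
#' @param params a [tracking_params()].
#' @return A `displacement_trace`: data frame with columns `frame` (1-based),
#'   `t` (s), `dx_um`, `dy_um` (displacement relative to the reference
#'   frame, um) and `score` (peak correlation, in `[-1, 1]`), plus
#'   attributes `roi`, `reference`, `pixel_size`, `frame_interval`,
#'   `params` and `border_peak` (frames whose integer peak lay on the
#'   search-window border, indicating a too-small radius).
#' @examples
#' mov <- gen_contraction_movie(contraction_truth(fs_max = 0.03), seed = 1,
#'                              duration = 3)
#' rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
#'                            frame_dim = dim(mov$stack)[1:2])
#' tr <- track_roi(mov$stack, rois$proximal, tracking_params(search_radius = 8))
#' head(as.data.frame(tr))
#' @export
track_roi <- function(stack, roi, params = tracking_params()) {
  r <- params$search_radius
  fd <- dim(stack$frames)
  if (!roi_in_frame(roi, fd[1:2], pad = r))
    stop_mbk("search window (ROI + %d px) is clipped by the frame edge", r)
  ref_idx <- resolve_reference(stack, list(roi), params$reference)
  cx <- roi$center[1]; cy <- roi$center[2]; hx <- roi$half_size[1]
  hy <- roi$half_size[2]
  rows_t <- (cy - hy):(cy + hy) + 1L
  cols_t <- (cx - hx):(cx + hx) + 1L
  rows_w <- (cy - hy - r):(cy + hy + r) + 1L
  cols_w <- (cx - hx - r):(cx + hx + r) + 1L
  template <- stack$frames[rows_t, cols_t, ref_idx]
  nt <- n_frames(stack)
  dx <- dy <- score <- numeric(nt)
  border <- logical(nt)
  corr_fun <- if (params$method == "fft") zncc_fft else zncc_direct
  for (k in seq_len(nt)) {
    if (k == ref_idx) { score[k] <- 1; next }
    cc <- corr_fun(template, stack$frames[rows_w, cols_w, k], r)
    pk <- arrayInd(which.max(cc), dim(cc))
    v <- pk[1] - r - 1L; u <- pk[2] - r - 1L
    border[k] <- abs(v) == r || abs(u) == r
    du <- dv <- 0
    # an exact match (correlation 1) needs no refinement; the quadratic
    # vertex of the texture autocorrelation is not at the peak sample
    if (params$subpixel && !border[k] && cc[pk[1], pk[2]] < 1 - 1e-9) {
      uv <- quad_refine_2d(cc[pk[1] + (-1:1), pk[2] + (-1:1)])
      du <- uv[1]; dv <- uv[2]
    }
    # the template content moved by -(u, v) relative to the frame search:
    # a peak at lag (u, v) means frame content at roi + (u, v) matches the
    # reference template, i.e. the tissue moved by (u, v).
    dx[k] <- (u + du) * stack$pixel_size
    dy[k] <- (v + dv) * stack$pixel_size
    score[k] <- max(cc)
  }
  out <- data.frame(frame = seq_len(nt), t = frame_times(stack),
                    dx_um = dx, dy_um = dy, score = score)
  structure(out, class = c("displacement_trace", "data.frame"),
            roi = roi, reference = ref_idx, pixel_size = stack$pixel_size,
            frame_interval = stack$frame_interval, params = params,
            border_peak = which(border))
}

resolve_reference <- function(stack, rois, reference) {
  if (is.numeric(reference)) {
    k <- as.integer(reference)
    if (k < 1L || k > n_frames(stack)) stop_mbk("reference frame out of range")
    return(k)
  }
  if (identical(reference, "first_frame")) return(1L)
  if (identical(reference, "quiescent_auto"))
    return(find_quiescent_frame(stack, rois))
  stop_mbk("unknown reference specification")
}

#' Pick a quiescent reference frame
#'
#' Spontaneously beating tissues may start a recording mid-beat; the first
#' frame is then a poor reference. This helper scores each frame by the
#' total absolute temporal intensity change inside the given ROIs over a
#' rolling window and returns the frame with the least motion.
#'
#' @param stack an [image_stack()].
#' @param rois list of [roi_spec()]s.
#' @param window rolling window length, frames.
#' @return 1-based frame index.
#' @export
find_quiescent_frame <- function(stack, rois, window = 5L) {
  nt <- n_frames(stack)
  if (nt < 3L) return(1L)
  motion <- numeric(nt - 1L)
  for (roi in rois) {
    rows <- (roi$center[2] - roi$half_size[2]):(roi$center[2] + roi$half_size[2]) + 1L
    cols <- (roi$center[1] - roi$half_size[1]):(roi$center[1] + roi$half_size[1]) + 1L
    patch <- stack$frames[rows, cols, , drop = FALSE]
    motion <- motion + vapply(seq_len(nt - 1L), function(k)
      sum(abs(patch[, , k + 1L] - patch[, , k])), numeric(1))
  }
  roll <- vapply(seq_len(nt), function(k) {
    i <- max(1L, k - window %/% 2L):min(nt - 1L, k + window %/% 2L)
    mean(motion[i])
  }, numeric(1))
  which.min(roll)
}

#' @export
print.displacement_trace <- function(x, ...) {
  roi <- attr(x, "roi")
  cat(sprintf("<displacement_trace> %s, %d frames (reference frame %d)\n",
              roi$label, nrow(x), attr(x, "reference")))
  cat(sprintf("  |displacement| max %.3f um, min score %.3f\n",
              max(sqrt(x$dx_um^2 + x$dy_um^2)), min(x$score)))
  bp <- attr(x, "border_peak")
  if (length(bp))
    cat(sprintf("  WARNING: peak on search border at %d frame(s) (radius too small?)\n",
                length(bp)))
  invisible(x)
}

#' @export
plot.displacement_trace <- function(x, ...) {
  graphics::plot(x$t, x$dx_um, type = "l", xlab = "time (s)",
                 ylab = "displacement (um)", ...)
  graphics::lines(x$t, x$dy_um, lty = 2)
  graphics::legend("topright", c("dx", "dy"), lty = 1:2, bty = "n")
  invisible(x)
}

#' Write a displacement trace to CSV
#' @param trace a `displacement_trace`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  df <- as.data.frame(trace)
  names(df) <- c("frame", "t_s", "dx_um", "dy_um", "score")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# ---- pairwise QC -----------------------------------------------------------

#' Symmetrical motion index of an ROI pair
#'
#' With `a_p`, `a_d` the long-axis displacement components of the proximal
#' and distal ROI, the index at each frame is
#' `|a_p + a_d| / (|a_p| + |a_d|)`: 0 for perfectly symmetric opposing
#' motion (pure contraction about the midpoint), 1 for common-mode rigid
#' translation. Frames whose denominator is below `noise_floor` are
#' returned as `NA` (no resolvable motion).
#'
#' @param prox,dist `displacement_trace`s of equal length sharing a
#'   reference frame.
#' @param axis_angle long-axis angle, degrees.
#' @param noise_floor minimum total axial motion (um) for the index to be
#'   defined.
#' @return Numeric vector, one value per frame (`NA` below the floor).
#' @export
symmetry_index <- function(prox, dist, axis_angle = 0, noise_floor = 0.05) {
  if (nrow(prox) != nrow(dist))
    stop_mbk("traces differ in length (%d vs %d)", nrow(prox), nrow(dist))
  u <- axis_unit(axis_angle)
  ap <- prox$dx_um * u[1] + prox$dy_um * u[2]
  ad <- dist$dx_um * u[1] + dist$dy_um * u[2]
  den <- abs(ap) + abs(ad)
  idx <- abs(ap + ad) / den
  idx[den <= noise_floor] <- NA_real_
  idx
}

#' QC verdict for a tracked ROI pair
#'
#' Rejects a tracked pair when (i) any frame's peak correlation falls below
#' `min_correlation`, (ii) the median symmetrical motion index over frames
#' with resolvable motion exceeds `symmetry_cutoff` (the pair translates
#' rather than contracts), or (iii) peak transverse displacement exceeds
#' `transverse_fraction` of peak axial displacement. Always returns a
#' verdict; reasons are enumerated.
#'
#' @param prox,dist `displacement_trace`s.
#' @param axis_angle long-axis angle, degrees.
#' @param min_correlation,symmetry_cutoff,transverse_fraction thresholds.
#' @param noise_floor passed to [symmetry_index()].
#' @return List with `accept` (logical) and `reasons` (character).
#' @export
qc_trace <- function(prox, dist, axis_angle = 0, min_correlation = 0.5,
                     symmetry_cutoff = 0.5, transverse_fraction = 0.5,
                     noise_floor = 0.05) {
  reasons <- character()
  for (tr in list(prox, dist)) {
    bad <- which(tr$score < min_correlation & tr$frame != attr(tr, "reference"))
    if (length(bad))
      reasons <- c(reasons, sprintf(
        "low correlation at frame %d (%s ROI, score %.2f)",
        bad[1], attr(tr, "roi")$label, tr$score[bad[1]]))
  }
  # judge symmetry on contraction frames only: the total axial motion must
  # clear both the absolute noise floor and a fraction of its own maximum,
  # so quiescent frames (where template-noise bias dominates) don't vote
  u0 <- axis_unit(axis_angle)
  den <- abs(prox$dx_um * u0[1] + prox$dy_um * u0[2]) +
    abs(dist$dx_um * u0[1] + dist$dy_um * u0[2])
  floor_eff <- max(noise_floor, 0.25 * max(den))
  si <- symmetry_index(prox, dist, axis_angle, floor_eff)
  if (any(!is.na(si)) && median(si, na.rm = TRUE) > symmetry_cutoff)
    reasons <- c(reasons, sprintf(
      "asymmetric/common-mode motion (median symmetry index %.2f > %.2f)",
      median(si, na.rm = TRUE), symmetry_cutoff))
  u <- axis_unit(axis_angle)
  ax <- max(abs(c(prox$dx_um * u[1] + prox$dy_um * u[2],
                  dist$dx_um * u[1] + dist$dy_um * u[2])))
  tv <- max(abs(c(-prox$dx_um * u[2] + prox$dy_um * u[1],
                  -dist$dx_um * u[2] + dist$dy_um * u[1])))
  if (ax > noise_floor && tv > transverse_fraction * ax)
    reasons <- c(reasons, sprintf(
      "transverse displacement %.2f um exceeds %.0f%% of axial %.2f um",
      tv, 100 * transverse_fraction, ax))
  list(accept = length(reasons) == 0L, reasons = reasons)
}
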