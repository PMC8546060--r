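#' Ground truth for a synthetic contraction movie
#'
#' Parameters of the simulated beat and imaging noise. Defaults emulate a
#' healthy bundle: 5% peak fractional shortening, spontaneous beating at
#' 0.4 Hz with a 0.5 s contraction and 0.7 s relaxation limb, and additive
#' sensor noise at 5% of the texture contrast.
#'
#' @param fs_max peak fractional shortening (0 to 0.2).
#' @param frequency beat frequency, Hz.
#' @param t_con,t_rel contraction / relaxation durations, s.
#' @param waveform `"raised_cosine"` or `"two_sigmoid"`.
#' @param noise_sd additive Gaussian noise SD, as a fraction of texture
#'   contrast.
#' @param drift_um_s rigid drift velocity along x, um/s.
#' @param common_mode_um peak rigid (common-mode) translation along x, um,
#'   applied with the beat time course.
#' @param texture_corr_um correlation length of the band-limited texture, um.
#' @return List of class `contraction_truth`.
#' @export
contraction_truth <- function(fs_max = 0.05, frequency = 0.4,
                              t_con = 0.5, t_rel = 0.7,
                              waveform = c("raised_cosine", "two_sigmoid"),
                              noise_sd = 0.05, drift_um_s = 0,
                              common_mode_um = 0, texture_corr_um = 2) {
  if (fs_max < 0 || fs_max > 0.2) stop_mbk("fs_max must lie in [0, 0.2]")
  if (t_con <= 0 || t_rel <= 0) stop_mbk("durations must be positive")
  if (noise_sd < 0) stop_mbk("noise_sd must be >= 0")
  if (frequency > 0 && t_con + t_rel > 1 / frequency)
    stop_mbk("beat (t_con + t_rel = %.2f s) longer than period %.2f s",
             t_con + t_rel, 1 / frequency)
  structure(list(fs_max = fs_max, frequency = frequency, t_con = t_con,
                 t_rel = t_rel, waveform = match.arg(waveform),
                 noise_sd = noise_sd, drift_um_s = drift_um_s,
                 common_mode_um = common_mode_um,
                 texture_corr_um = texture_corr_um),
            class = "contraction_truth")
}

# normalized beat shape eta(t) in [0, 1] for a full recording
beat_shape <- function(t, truth) {
  if (truth$frequency <= 0) {
    tau <- t                     # single beat starting at t = 0
  } else {
    tau <- t %% (1 / truth$frequency)
  }
  eta <- numeric(length(t))
  up <- tau >= 0 & tau < truth$t_con
  dn <- tau >= truth$t_con & tau < truth$t_con + truth$t_rel
  if (truth$waveform == "raised_cosine") {
    eta[up] <- (1 - cos(pi * tau[up] / truth$t_con)) / 2
    eta[dn] <- (1 + cos(pi * (tau[dn] - truth$t_con) / truth$t_rel)) / 2
  } else {
    s <- function(x) 1 / (1 + exp(-x))
    k_up <- 10 / truth$t_con; k_dn <- 10 / truth$t_rel
    raw <- s(k_up * (tau - truth$t_con / 2)) *
      (1 - s(k_dn * (tau - truth$t_con - truth$t_rel / 2)))
    on <- up | dn
    eta[on] <- raw[on] / max(raw[on])
  }
  eta
}

# Lanczos-3 interpolation weights for query positions xq (0-based, on a grid
# 0..n-1); returns a sparse (n x length(xq)) operator W with columns summing
# to ~1, so that  signal_out = signal_ref %*% W  resamples every row.
lanczos_operator <- function(xq, n, a = 3L) {
  if (any(xq < a - 1 | xq >= n - a)) stop_mbk("resampling query outside grid")
  i0 <- floor(xq)
  taps <- (-a + 1L):a
  ii <- outer(taps, i0, `+`)                 # 2a x m integer sample indices
  dx <- sweep(-outer(taps, i0, `+`), 2L, xq, `+`)  # xq - index
  lz <- function(x) {
    w <- numeric(length(x))
    z <- abs(x) < 1e-9
    w[z] <- 1
    s <- !z & abs(x) < a
    w[s] <- a * sin(pi * x[s]) * sin(pi * x[s] / a) / (pi^2 * x[s]^2)
    w
  }
  W <- matrix(lz(dx), nrow(dx), ncol(dx))
  W <- sweep(W, 2L, colSums(W), `/`)         # renormalize (partition of unity)
  Matrix::sparseMatrix(i = as.vector(ii) + 1L,
                       j = rep(seq_along(xq), each = 2L * a),
                       x = as.vector(W), dims = c(n, length(xq)))
}

# band-limited texture: white noise smoothed with a Gaussian kernel,
# rescaled to zero mean / unit SD
bandlimited_texture <- function(nr, nc, sigma_px) {
  raw <- matrix(rnorm(nr * nc), nr, nc)
  sm <- EBImage::gblur(raw, sigma = sigma_px)
  (sm - mean(sm)) / sd(sm)
}

#' Generate a synthetic contraction movie with exact ground truth
#'
#' Renders a band-limited random texture confined to the tissue rectangle
#' and warps it frame by frame with the uniform-axial-strain displacement
#' field `u_x(x, t) = -eps(t) (x - x_c)` (plus optional drift and
#' common-mode translation), using Lanczos-3 resampling. Because the strain
#' field is spatially uniform along the axis, the imposed separation change
#' of any two material points is exactly `eps(t)` -- the stored truth is
#' analytic, not itself tracked.
#'
#' The default field of view covers the tissue plus the margins needed for
#' tracking windows; the default pixel size (0.4875 um/px, a 3x binning of
#' the 40x-objective pitch) keeps full-length movies affordable while
#' leaving ~4.5 px per sarcomere-scale feature.
#'
#' @param truth a [contraction_truth()].
#' @param geometry a [tissue_geometry()] with `long_axis_angle = 0`
#'   (uniaxial generator); default centred 308 x 45 um bundle.
#' @param pixel_size um/px.
#' @param fps frames per second.
#' @param duration recording length, s.
#' @param margin_um extra field beyond the tissue on each side, um.
#' @param background baseline intensity (texture contrast is 1).
#' @param seed integer seed; identical `(truth, seed)` give bit-identical
#'   movies.
#' @return List of class `synthetic_movie`: `stack` ([image_stack()]),
#'   `truth`, `geometry`, `epsilon` (imposed strain per frame), `t`
#'   (frame times) and `seed`.
#' @export
gen_contraction_movie <- function(truth = contraction_truth(),
                                  geometry = NULL,
                                  pixel_size = 0.4875, fps = 50,
                                  duration = 20, margin_um = 12,
                                  background = 2, seed = 1L) {
  if (is.null(geometry)) {
    fov_x <- 308 + 2 * margin_um
    fov_y <- 45 + 2 * margin_um
    geometry <- tissue_geometry(center = c(fov_x / 2, fov_y / 2))
  }
  if (geometry$long_axis_angle != 0)
    stop_mbk("gen_contraction_movie renders axis-aligned bundles; use gen_monolayer_movie for rotated domains")
  nc <- ceiling((geometry$length + 2 * margin_um) / pixel_size)
  nr <- ceiling((geometry$width + 2 * margin_um) / pixel_size)
  tt <- (seq_len(round(duration * fps)) - 1L) / fps
  eps <- truth$fs_max * beat_shape(tt, truth)
  shift <- truth$drift_um_s * tt +
    truth$common_mode_um * beat_shape(tt, truth)
  xc_px <- geometry$center[1] / pixel_size
  yc_px <- geometry$center[2] / pixel_size
  # reference texture on a grid wide enough for the largest stretch-back
  max_eps <- max(eps); max_shift <- max(abs(shift)) / pixel_size
  pad <- ceiling((max_eps * nc / 2 + max_shift) / (1 - max_eps)) + 4L
  ref_nc <- nc + 2L * pad
  x_px <- 0:(nc - 1L)
  local_seed(seed, {
    tex <- bandlimited_texture(nr, ref_nc, truth$texture_corr_um / pixel_size)
    # confine to the tissue rectangle with a ~1 um smooth roll-off
    xr_um <- ((0:(ref_nc - 1L)) - pad) * pixel_size
    yr_um <- (0:(nr - 1L)) * pixel_size
    wx <- smooth_window(xr_um, geometry$center[1], geometry$length / 2, 1)
    wy <- smooth_window(yr_um, geometry$center[2], geometry$width / 2, 1)
    tex <- tex * tcrossprod(wy, wx)
    frames <- array(0, c(nr, nc, length(tt)))
    for (k in seq_along(tt)) {
      xq <- xc_px + (x_px - xc_px - shift[k] / pixel_size) / (1 - eps[k])
      W <- lanczos_operator(xq + pad, ref_nc)
      fr <- background + as.matrix(tex %*% W)
      if (truth$noise_sd > 0)
        fr <- fr + rnorm(nr * nc, sd = truth$noise_sd)
      frames[, , k] <- fr
    }
    structure(list(stack = image_stack(frames, pixel_size, 1 / fps),
                   truth = truth, geometry = geometry, epsilon = eps,
                   t = tt, seed = seed),
              class = "synthetic_movie")
  })
}

# raised-cosine edge window: 1 inside |x - c| < half - roll, 0 outside half
smooth_window <- function(x, center, half, roll) {
  d <- abs(x - center)
  w <- numeric(length(x))
  w[d <= half - roll] <- 1
  tr <- d > half - roll & d < half
  w[tr] <- 0.5 * (1 + cos(pi * (d[tr] - half + roll) / roll))
  w
}

#' @export
print.synthetic_movie <- function(x, ...) {
  cat(sprintf("<synthetic_movie> FS %.1f%%, %.2f Hz, %d frames (seed %d)\n",
              100 * x$truth$fs_max, x$truth$frequency, n_frames(x$stack),
              x$seed))
  print(x$stack)
  invisible(x)
}

#' Generate a disorganized multi-domain monolayer movie
#'
#' Tiles the field with independent texture domains, each contracting
#' uniaxially along its own random direction with its own amplitude and
#' phase -- a surrogate for the heterogeneous motion of nonpatterned
#' cardiomyocyte monolayers, against which the organized single-bundle
#' generator is contrasted.
#'
#' @param n_domains number of domains (tiled on a near-square grid).
#' @param fs_range domain peak fractional shortening range (uniform draw).
#' @param frequency beat frequency, Hz (shared; phases differ per domain).
#' @param fov_um field of view `c(x, y)`, um.
#' @param pixel_size,fps,duration,background,noise_sd as in
#'   [gen_contraction_movie()].
#' @param seed integer seed.
#' @return List of class `synthetic_movie` with `domains` (per-domain truth:
#'   centre, angle, fs_max, phase) in place of `geometry`.
#' @export
gen_monolayer_movie <- function(n_domains = 8, fs_range = c(0.01, 0.08),
                                frequency = 0.4, fov_um = c(330, 100),
                                pixel_size = 0.65, fps = 25, duration = 10,
                                background = 2, noise_sd = 0.05, seed = 1L) {
  ncx <- ceiling(sqrt(n_domains * fov_um[1] / fov_um[2]))
  ncy <- ceiling(n_domains / ncx)
  nc <- ceiling(fov_um[1] / pixel_size)
  nr <- ceiling(fov_um[2] / pixel_size)
  tt <- (seq_len(round(duration * fps)) - 1L) / fps
  dx_um <- fov_um[1] / ncx; dy_um <- fov_um[2] / ncy
  local_seed(seed, {
    doms <- list()
    d <- 0L
    for (iy in seq_len(ncy)) for (ix in seq_len(ncx)) {
      if (d >= n_domains) next
      d <- d + 1L
      doms[[d]] <- list(
        x0 = (ix - 1) * dx_um, y0 = (iy - 1) * dy_um,
        x1 = ix * dx_um, y1 = iy * dy_um,
        angle = runif(1, -90, 90),
        fs_max = runif(1, fs_range[1], fs_range[2]),
        phase = runif(1, 0, 1 / frequency))
    }
    frames <- array(background, c(nr, nc, length(tt)))
    base_truth <- contraction_truth(fs_max = 0.05, frequency = frequency,
                                    noise_sd = 0)
    for (dm in doms) {
      # pixel block of this domain
      cx0 <- max(0L, floor(dm$x0 / pixel_size))
      cx1 <- min(nc - 1L, ceiling(dm$x1 / pixel_size) - 1L)
      cy0 <- max(0L, floor(dm$y0 / pixel_size))
      cy1 <- min(nr - 1L, ceiling(dm$y1 / pixel_size) - 1L)
      bx <- (cx0:cx1) + 1L; by <- (cy0:cy1) + 1L
      # texture on a padded grid around the block
      padp <- ceiling(max(fs_range) * max(dx_um, dy_um) / pixel_size) + 6L
      tnr <- length(by) + 2L * padp; tnc <- length(bx) + 2L * padp
      tex <- bandlimited_texture(tnr, tnc, 2 / pixel_size)
      cxp <- (cx0 + cx1) / 2; cyp <- (cy0 + cy1) / 2
      u <- axis_unit(dm$angle)
      xg <- outer(rep(1, length(by)), cx0:cx1)
      yg <- outer(cy0:cy1, rep(1, length(bx)))
      eps_d <- dm$fs_max * beat_shape(tt + dm$phase, base_truth)
      for (k in seq_along(tt)) {
        # invert the uniaxial warp along the domain axis
        sx <- xg - cxp; sy <- yg - cyp
        ax <- sx * u[1] + sy * u[2]          # axial coordinate
        tv <- -sx * u[2] + sy * u[1]         # transverse coordinate
        ax0 <- ax / (1 - eps_d[k])
        qx <- cxp + ax0 * u[1] - tv * u[2]
        qy <- cyp + ax0 * u[2] + tv * u[1]
        blk <- bilinear_lookup(tex, qx - cx0 + padp, qy - cy0 + padp)
        frames[by, bx, k] <- background + blk
      }
    }
    if (noise_sd > 0)
      frames <- frames + array(rnorm(length(frames), sd = noise_sd),
                               dim(frames))
    structure(list(stack = image_stack(frames, pixel_size, 1 / fps),
                   truth = list(n_domains = n_domains, fs_range = fs_range,
                                frequency = frequency, noise_sd = noise_sd),
                   domains = doms, t = tt, seed = seed),
              class = "synthetic_movie")
  })
}

# bilinear sample of matrix M at 0-based (x, y) positions (matrices)
bilinear_lookup <- function(M, x, y) {
  nr <- nrow(M); nc <- ncol(M)
  dims <- dim(x)
  x <- pmax(0, pmin(nc - 1.001, x))
  y <- pmax(0, pmin(nr - 1.001, y))
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  i00 <- (x0) * nr + y0 + 1
  v00 <- M[i00]; v10 <- M[i00 + nr]
  v01 <- M[i00 + 1]; v11 <- M[i00 + nr + 1]
  out <- v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
    v01 * (1 - fx) * fy + v11 * fx * fy
  matrix(out, dims[1], dims[2])
}

#' Ground truth for a synthetic structure image
#'
#' @param spacing sarcomere spacing, um (1.2--3.5).
#' @param mu_theta,sigma_theta mean and SD of myofibril orientation, degrees.
#' @param stripe_width,stripe_gap myofibrillar bundle stripe width and gap,
#'   um (F-actin kind).
#' @param background baseline intensity; striation/stripe amplitude is 1.
#' @param noise_sd additive Gaussian noise SD.
#' @return List of class `structure_truth`.
#' @export
structure_truth <- function(spacing = 2.2, mu_theta = 0, sigma_theta = 5,
                            stripe_width = 4, stripe_gap = 5,
                            background = 1, noise_sd = 0.05) {
  if (spacing < 1.2 || spacing > 3.5)
    stop_mbk("spacing must lie in the detection band [1.2, 3.5] um")
  if (sigma_theta < 0) stop_mbk("sigma_theta must be >= 0")
  structure(list(spacing = spacing, mu_theta = mu_theta,
                 sigma_theta = sigma_theta, stripe_width = stripe_width,
                 stripe_gap = stripe_gap, background = background,
                 noise_sd = noise_sd),
            class = "structure_truth")
}

#' Generate a synthetic structure image (striations or F-actin bundles)
#'
#' `kind = "striation"` renders parallel myofibril strips spanning the
#' tissue; strip `i` carries intensity
#' `B + cos(2 pi s_i / spacing)` with `s_i` the coordinate along the
#' strip's own axis, whose angle is drawn from `N(mu_theta, sigma_theta)`.
#' `kind = "factin_bundles"` renders axial stripes of the stated width and
#' gap with smooth (0.3 um) edges.
#'
#' @param truth a [structure_truth()].
#' @param geometry a [tissue_geometry()]; default centred 308 x 45 um.
#' @param pixel_size um/px; must resolve the spacing with >= 4 px/period.
#' @param kind `"striation"` or `"factin_bundles"`.
#' @param strip_width_um width of each constant-angle myofibril strip
#'   (striation kind), um.
#' @param margin_um field margin, um.
#' @param seed integer seed.
#' @return List of class `structure_image`: `image` (matrix), `pixel_size`,
#'   `truth`, `geometry`, `angles` (per-strip true angles, striation kind)
#'   or `stripes` (per-stripe transverse centres/widths, bundle kind), and
#'   `coverage` (true stripe area fraction, bundle kind).
#' @export
gen_structure_image <- function(truth = structure_truth(),
                                geometry = NULL, pixel_size = 0.1625,
                                kind = c("striation", "factin_bundles"),
                                strip_width_um = 4, margin_um = 8,
                                seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "striation" && truth$spacing / pixel_size < 4)
    stop_mbk("pixel size %.3f um cannot resolve %.2f um spacing (need >= 4 px/period)",
             pixel_size, truth$spacing)
  if (is.null(geometry))
    geometry <- tissue_geometry(center = c(308 / 2 + margin_um,
                                           45 / 2 + margin_um))
  nc <- ceiling((geometry$length + 2 * margin_um) / pixel_size)
  nr <- ceiling((geometry$width + 2 * margin_um) / pixel_size)
  x_um <- (0:(nc - 1L)) * pixel_size
  y_um <- (0:(nr - 1L)) * pixel_size
  X <- outer(rep(1, nr), x_um)
  Y <- outer(y_um, rep(1, nc))
  inx <- abs(x_um - geometry$center[1]) <= geometry$length / 2
  local_seed(seed, {
    img <- matrix(truth$background, nr, nc)
    extra <- list()
    if (kind == "striation") {
      # Myofibrils are rendered as a grid of short segments (strip_width_um
      # across, segment_len_um along the tissue axis), each with its own
      # orientation drawn from N(mu_theta, sigma_theta) and its own phase.
      # Axial gaps of 3.6 um exceed the 3.5 um detection band so striation
      # bands are never paired across segment boundaries.
      seg_len <- 8; gap_x <- 3.6; gap_y <- 1
      y0 <- geometry$center[2] - geometry$width / 2
      x0 <- geometry$center[1] - geometry$length / 2
      pitch_y <- strip_width_um + gap_y; pitch_x <- seg_len + gap_x
      n_rows <- max(1L, floor((geometry$width + gap_y) / pitch_y))
      n_cols <- max(1L, floor((geometry$length + gap_x) / pitch_x))
      angles <- matrix(rnorm(n_rows * n_cols, truth$mu_theta,
                             truth$sigma_theta), n_rows, n_cols)
      phases <- matrix(runif(n_rows * n_cols, 0, truth$spacing),
                       n_rows, n_cols)
      for (i in seq_len(n_rows)) {
        iny <- y_um >= y0 + (i - 1) * pitch_y &
          y_um < y0 + (i - 1) * pitch_y + strip_width_um
        if (!any(iny)) next
        for (j in seq_len(n_cols)) {
          injx <- x_um >= x0 + (j - 1) * pitch_x &
            x_um < x0 + (j - 1) * pitch_x + seg_len
          if (!any(injx)) next
          a <- angles[i, j] * pi / 180
          S <- (X[iny, injx, drop = FALSE] - geometry$center[1]) * cos(a) +
            (Y[iny, injx, drop = FALSE] - geometry$center[2]) * sin(a)
          img[iny, injx] <- truth$background +
            cos(2 * pi * (S + phases[i, j]) / truth$spacing)
        }
      }
      extra <- list(angles = wrap_half(as.vector(angles)))
    } else {
      period <- truth$stripe_width + truth$stripe_gap
      w_half <- geometry$width / 2
      centers <- seq(-w_half + period / 2, w_half - period / 2 + 1e-9,
                     by = period)
      edge <- 0.3
      prof <- numeric(nr)
      for (cc in centers) {
        d <- abs(y_um - geometry$center[2] - cc)
        prof <- prof + smooth_window(y_um, geometry$center[2] + cc,
                                     truth$stripe_width / 2 + edge / 2, edge)
      }
      iny <- abs(y_um - geometry$center[2]) <= w_half
      img[iny, inx] <- truth$background + pmin(prof[iny], 1)
      extra <- list(stripes = data.frame(center_um = centers,
                                         width_um = truth$stripe_width),
                    coverage = length(centers) * truth$stripe_width /
                      geometry$width)
    }
    if (truth$noise_sd > 0)
      img <- img + matrix(rnorm(nr * nc, sd = truth$noise_sd), nr, nc)
    structure(c(list(image = img, pixel_size = pixel_size, truth = truth,
                     geometry = geometry, kind = kind, seed = seed), extra),
              class = "structure_image")
  })
}

#' @export
print.structure_image <- function(x, ...) {
  cat(sprintf("<structure_image> %s, %d x %d px at %.4f um/px (seed %d)\n",
              x$kind, nrow(x$image), ncol(x$image), x$pixel_size, x$seed))
  invisible(x)
}
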