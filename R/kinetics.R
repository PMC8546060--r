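#' Fractional-shortening waveform from a tracked ROI pair
#'
#' The instantaneous inter-ROI axial length is
#' `L(t) = L_sep + a_d(t) - a_p(t)`, with `L_sep` the axial separation of
#' the ROI centres and `a_p`, `a_d` the long-axis displacement components.
#' The resting length `L0` is a quiescent-baseline estimate (upper quantile
#' of `L(t)`, since contraction only shortens), and
#' `fs(t) = (L0 - L(t)) / L0`.
#'
#' @param prox,dist `displacement_trace`s from [track_roi()] (QC-accepted).
#' @param axis_angle long-axis angle, degrees.
#' @param baseline_quantile quantile of `L(t)` used as `L0`.
#' @return A `shortening_waveform`: data frame with columns `t` (s) and
#'   `fs`, plus attributes `L0` (um), `L` (um per frame) and
#'   `frame_interval`.
#' @export
build_waveform <- function(prox, dist, axis_angle = 0,
                           baseline_quantile = 0.9) {
  if (nrow(prox) != nrow(dist)) stop_mbk("traces differ in length")
  u <- axis_unit(axis_angle)
  rp <- attr(prox, "roi"); rd <- attr(dist, "roi")
  px <- attr(prox, "pixel_size")
  sep_vec <- (rd$center - rp$center) * px
  sep0 <- sum(sep_vec * u)
  sgn <- if (sep0 < 0) -1 else 1
  sep0 <- abs(sep0)
  if (sep0 <= 0) stop_mbk("ROI centres have no axial separation")
  ap <- (prox$dx_um * u[1] + prox$dy_um * u[2]) * sgn
  ad <- (dist$dx_um * u[1] + dist$dy_um * u[2]) * sgn
  L <- sep0 + ad - ap
  if (any(L <= 0)) stop_mbk("non-positive inter-ROI length (tracking failure)")
  L0 <- as.numeric(quantile(L, baseline_quantile))
  out <- data.frame(t = prox$t, fs = (L0 - L) / L0)
  structure(out, class = c("shortening_waveform", "data.frame"),
            L0 = L0, L = L, frame_interval = attr(prox, "frame_interval"))
}

#' Construct a shortening waveform directly
#'
#' For analytic fixtures and model output (no tracking involved).
#'
#' @param t time, s.
#' @param fs fractional shortening, dimensionless.
#' @param L0 resting length, um.
#' @return A `shortening_waveform`.
#' @export
shortening_waveform <- function(t, fs, L0 = 154) {
  if (length(t) != length(fs)) stop_mbk("t and fs differ in length")
  structure(data.frame(t = t, fs = fs),
            class = c("shortening_waveform", "data.frame"),
            L0 = L0, L = L0 * (1 - fs),
            frame_interval = if (length(t) > 1) t[2] - t[1] else NA_real_)
}

#' @export
print.shortening_waveform <- function(x, ...) {
  cat(sprintf("<shortening_waveform> %d samples, %.2f s, L0 = %.1f um, max fs = %.2f%%\n",
              nrow(x), max(x$t) - min(x$t), attr(x, "L0"), 100 * max(x$fs)))
  invisible(x)
}

#' @export
plot.shortening_waveform <- function(x, ...) {
  graphics::plot(x$t, 100 * x$fs, type = "l", xlab = "time (s)",
                 ylab = "fractional shortening (%)", ...)
  invisible(x)
}

#' Segment beats and merge them into a mean beat
#'
#' Beats are detected as `fs` peaks with topographic prominence of at least
#' `prominence_frac` of the global maximum, separated by at least
#' `min_spacing_s`. Each beat is windowed from the preceding to the
#' following inter-beat valley, aligned on the interpolated upstroke
#' crossing of its half-maximum, and interpolated onto a common time grid
#' spanning the intersection of all windows. The merged beat is the
#' pointwise mean with a 95% confidence band (`mean +/- 1.96 SEM`). Beat
#' frequency is `(n_beats - 1)` divided by the span of peak times.
#'
#' @param waveform a `shortening_waveform`.
#' @param prominence_frac fraction of the global `fs` maximum.
#' @param min_spacing_s minimum peak spacing, s.
#' @return A `beat_set`: list with `n_beats`, `frequency` (Hz), `peaks`
#'   (indices), `windows` (per-beat index ranges), `beats` (per-beat
#'   matrices interpolated onto the grid), `rel_t`, `mean`, `ci_lo`,
#'   `ci_hi`, `frame_interval`, and `reason` when empty.
#' @export
segment_and_merge <- function(waveform, prominence_frac = 0.5,
                              min_spacing_s = 0.3) {
  fs <- waveform$fs; t <- waveform$t
  dt <- attr(waveform, "frame_interval")
  gmax <- max(fs)
  empty <- function(reason)
    structure(list(n_beats = 0L, frequency = NA_real_, peaks = integer(),
                   windows = list(), beats = NULL, rel_t = numeric(),
                   mean = numeric(), ci_lo = numeric(), ci_hi = numeric(),
                   frame_interval = dt, reason = reason),
              class = "beat_set")
  if (gmax <= 0) return(empty("no positive shortening in the record"))
  pk <- find_peaks(fs, min_prominence = prominence_frac * gmax,
                   min_distance = max(1L, round(min_spacing_s / dt)))
  if (nrow(pk) == 0L) return(empty("no beats detected"))
  peaks <- pk$index
  # windows: valley-to-valley around each peak
  bounds <- c(1L, vapply(seq_len(length(peaks) - 1L), function(i) {
    seg <- peaks[i]:peaks[i + 1L]
    seg[which.min(fs[seg])]
  }, integer(1)), length(fs))
  windows <- lapply(seq_along(peaks), function(i) bounds[i]:bounds[i + 1L])
  # alignment: upstroke half-maximum crossing, linearly interpolated
  t_align <- vapply(seq_along(peaks), function(i) {
    w <- windows[[i]]
    half <- fs[peaks[i]] / 2
    limb <- w[w <= peaks[i]]
    below <- limb[fs[limb] < half]
    if (!length(below)) return(t[limb[1]])
    j <- max(below)
    if (j == peaks[i]) return(t[j])
    t[j] + dt * (half - fs[j]) / (fs[j + 1L] - fs[j])
  }, numeric(1))
  pre <- min(t_align - t[vapply(windows, min, integer(1))])
  post <- min(t[vapply(windows, max, integer(1))] - t_align)
  rel_t <- seq(-floor(pre / dt) * dt, floor(post / dt) * dt, by = dt)
  beats <- vapply(seq_along(peaks), function(i) {
    w <- windows[[i]]
    approx(t[w] - t_align[i], fs[w], xout = rel_t, rule = 2)$y
  }, numeric(length(rel_t)))
  beats <- matrix(beats, nrow = length(rel_t))
  m <- rowMeans(beats)
  sem <- if (ncol(beats) > 1L) apply(beats, 1L, sd) / sqrt(ncol(beats)) else
    rep(0, length(rel_t))
  freq <- if (length(peaks) > 1L)
    (length(peaks) - 1L) / (t[peaks[length(peaks)]] - t[peaks[1L]]) else
      NA_real_
  structure(list(n_beats = length(peaks), frequency = freq, peaks = peaks,
                 windows = windows, beats = beats, rel_t = rel_t,
                 mean = m, ci_lo = m - 1.96 * sem, ci_hi = m + 1.96 * sem,
                 frame_interval = dt, reason = NULL),
            class = "beat_set")
}

#' @export
print.beat_set <- function(x, ...) {
  if (x$n_beats == 0L) {
    cat(sprintf("<beat_set> empty (%s)\n", x$reason))
  } else {
    cat(sprintf("<beat_set> %d beat(s), frequency %.3f Hz, merged max fs %.2f%%\n",
                x$n_beats, x$frequency, 100 * max(x$mean)))
  }
  invisible(x)
}

#' @export
plot.beat_set <- function(x, ...) {
  if (x$n_beats == 0L) stop_mbk("empty beat set")
  graphics::plot(x$rel_t, 100 * x$mean, type = "n",
                 ylim = range(100 * c(x$ci_lo, x$ci_hi)),
                 xlab = "time from upstroke half-max (s)",
                 ylab = "fractional shortening (%)", ...)
  graphics::polygon(c(x$rel_t, rev(x$rel_t)),
                    100 * c(x$ci_lo, rev(x$ci_hi)),
                    col = "grey85", border = NA)
  graphics::lines(x$rel_t, 100 * x$mean)
  invisible(x)
}

# derivative chain used for both the merged beat and each individual beat
kinetics_from_beat <- function(rel_t, fs, dt, sg_window, sg_order,
                               decel_tol, relax_recovery) {
  n <- length(fs)
  if (n < sg_window + 2L) stop_mbk("beat too short for smoothing window")
  fs_s <- signal::sgolayfilt(fs, p = sg_order, n = sg_window)
  v <- c(NA, (fs_s[3:n] - fs_s[1:(n - 2L)]) / (2 * dt), NA)
  # compact 3-point stencil: the wider nested-difference stencil smears the
  # acceleration discontinuity at contraction onset
  a <- c(NA, (fs_s[3:n] - 2 * fs_s[2:(n - 1L)] + fs_s[1:(n - 2L)]) / dt^2, NA)
  ipk <- which.max(fs_s)
  max_fs <- fs_s[ipk]
  if (max_fs <= 0) stop_mbk("no positive shortening in beat")
  con <- seq_len(ipk)
  rel <- ipk:n
  # |velocity| at the interpolated time fs crosses X * max on each limb
  v_at <- function(frac, limb, first) {
    level <- frac * max_fs
    if (first) {
      cross <- which(fs_s[limb[-length(limb)]] < level &
                       fs_s[limb[-1L]] >= level)
      if (!length(cross)) return(NA_real_)
      j <- limb[cross[1L]]
    } else {
      cross <- which(fs_s[limb[-length(limb)]] >= level &
                       fs_s[limb[-1L]] < level)
      if (!length(cross)) return(NA_real_)
      j <- limb[cross[length(cross)]]
    }
    w <- (level - fs_s[j]) / (fs_s[j + 1L] - fs_s[j])
    tx <- rel_t[j] + w * dt
    vv <- v[!is.na(v)]
    abs(approx(rel_t[!is.na(v)], vv, xout = tx, rule = 2)$y)
  }
  v_con <- vapply(c(0.2, 0.5, 0.8), v_at, numeric(1), limb = con,
                  first = TRUE)
  v_rel <- vapply(c(0.8, 0.5, 0.2), v_at, numeric(1), limb = rel,
                  first = FALSE)
  peak_acc <- max(a[con], na.rm = TRUE)
  # deceleration time: linear contractile slope from the mid-contraction
  # phase (fs in [30, 70]% of max); onset where velocity drops below
  # (1 - decel_tol) of that slope after the velocity peak
  mid <- con[fs_s[con] >= 0.3 * max_fs & fs_s[con] <= 0.7 * max_fs]
  decel_time <- NA_real_
  if (length(mid) >= 2L) {
    slope <- unname(coef(lm(fs_s[mid] ~ rel_t[mid]))[2L])
    iv <- con[!is.na(v[con])]
    ivmax <- iv[which.max(v[iv])]
    after <- iv[iv >= ivmax]
    onset <- after[v[after] < (1 - decel_tol) * slope]
    if (length(onset)) decel_time <- rel_t[ipk] - rel_t[onset[1L]]
  }
  # relaxation time: fs peak to `relax_recovery` recovery toward baseline
  # (crossing time linearly interpolated between samples)
  base <- min(fs_s[rel])
  level <- max_fs - relax_recovery * (max_fs - base)
  below <- rel[fs_s[rel] <= level]
  relax_time <- NA_real_
  if (length(below)) {
    j <- below[1L]
    t_cross <- if (j > ipk && fs_s[j - 1L] > level)
      rel_t[j - 1L] + dt * (fs_s[j - 1L] - level) / (fs_s[j - 1L] - fs_s[j])
    else rel_t[j]
    relax_time <- t_cross - rel_t[ipk]
  }
  list(max_fs = max_fs, v_con_20 = v_con[1], v_con_50 = v_con[2],
       v_con_80 = v_con[3], v_rel_80 = v_rel[1], v_rel_50 = v_rel[2],
       v_rel_20 = v_rel[3], peak_acceleration = peak_acc,
       deceleration_time = decel_time, relaxation_time = relax_time,
       velocity = v, acceleration = a, fs_smooth = fs_s)
}

#' Extract contractile kinetic parameters from a beat set
#'
#' On the merged beat, computes the exported parameter set: maximal
#' fractional shortening; normalized contraction velocities at 20/50/80%
#' of peak shortening (`s^-1`, magnitudes of `d(fs)/dt` interpolated at the
#' first crossing of each level on the contraction limb); relaxation
#' velocities at 80/50/20% (last crossings on the relaxation limb); peak
#' contraction acceleration (`s^-2`); contraction deceleration time (from
#' deviation from the linear contractile slope to the fs peak); relaxation
#' time (fs peak to 90% recovery); and beat frequency. Velocities are
#' derivatives of Savitzky-Golay-smoothed `fs` by centred differences.
#' Per-parameter SDs across beats come from applying the identical
#' extraction to each aligned beat.
#'
#' @param beats a `beat_set` with at least one beat.
#' @param sg_window,sg_order Savitzky-Golay window (odd, frames) and
#'   polynomial order.
#' @param decel_tol fractional drop below the linear contractile slope that
#'   marks deceleration onset.
#' @param relax_recovery recovery fraction defining the relaxation-time
#'   endpoint.
#' @return A `kinetics_summary`: list of scalar parameters, `sd` (named
#'   per-beat SDs), `n_beats`, and the smoothed merged traces.
#' @examples
#' t <- seq(0, 1, by = 0.02)
#' fs <- 0.05 * (1 - cos(pi * pmin(t, 0.5) / 0.5)) / 2
#' fs[t > 0.5] <- 0.05 * (1 + cos(pi * (t[t > 0.5] - 0.5) / 0.5)) / 2
#' wf <- shortening_waveform(t, fs)
#' ks <- extract_kinetics(segment_and_merge(wf))
#' ks$v_con_50  # ~ 0.05 * pi / (2 * 0.5)
#' @export
extract_kinetics <- function(beats, sg_window = 7L, sg_order = 3L,
                             decel_tol = 0.1, relax_recovery = 0.9) {
  if (!inherits(beats, "beat_set")) stop_mbk("`beats` must be a beat_set")
  if (beats$n_beats == 0L) stop_mbk("empty beat set (%s)", beats$reason)
  dt <- beats$frame_interval
  merged <- kinetics_from_beat(beats$rel_t, beats$mean, dt, sg_window,
                               sg_order, decel_tol, relax_recovery)
  par_names <- c("max_fs", "v_con_20", "v_con_50", "v_con_80", "v_rel_80",
                 "v_rel_50", "v_rel_20", "peak_acceleration",
                 "deceleration_time", "relaxation_time")
  per_beat <- matrix(NA_real_, beats$n_beats, length(par_names),
                     dimnames = list(NULL, par_names))
  for (b in seq_len(beats$n_beats)) {
    kb <- try(kinetics_from_beat(beats$rel_t, beats$beats[, b], dt,
                                 sg_window, sg_order, decel_tol,
                                 relax_recovery), silent = TRUE)
    if (!inherits(kb, "try-error"))
      per_beat[b, ] <- unlist(kb[par_names])
  }
  sds <- apply(per_beat, 2L, sd)
  out <- merged[par_names]
  out$frequency <- beats$frequency
  out$sd <- sds
  out$n_beats <- beats$n_beats
  out$per_beat <- as.data.frame(per_beat)
  out$rel_t <- beats$rel_t
  out$fs_smooth <- merged$fs_smooth
  out$velocity <- merged$velocity
  out$acceleration <- merged$acceleration
  structure(out, class = "kinetics_summary")
}

#' @export
print.kinetics_summary <- function(x, ...) {
  cat("<kinetics_summary>\n")
  cat(sprintf("  max fractional shortening  %.2f%% (SD %.2f%%)\n",
              100 * x$max_fs, 100 * x$sd[["max_fs"]]))
  cat(sprintf("  v_con 20/50/80%%            %.4f / %.4f / %.4f s^-1\n",
              x$v_con_20, x$v_con_50, x$v_con_80))
  cat(sprintf("  v_rel 80/50/20%%            %.4f / %.4f / %.4f s^-1\n",
              x$v_rel_80, x$v_rel_50, x$v_rel_20))
  cat(sprintf("  peak acceleration          %.3f s^-2\n",
              x$peak_acceleration))
  cat(sprintf("  deceleration time          %.3f s\n", x$deceleration_time))
  cat(sprintf("  relaxation time            %.3f s\n", x$relaxation_time))
  cat(sprintf("  frequency                  %.3f Hz over %d beat(s)\n",
              x$frequency, x$n_beats))
  invisible(x)
}

#' @describeIn extract_kinetics plot the merged beat with its smoothed
#'   shortening, velocity and acceleration traces.
#' @param x a `kinetics_summary`.
#' @param ... ignored.
#' @export
plot.kinetics_summary <- function(x, ...) {
  old <- graphics::par(mfrow = c(3, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(old))
  graphics::plot(x$rel_t, 100 * x$fs_smooth, type = "l",
                 ylab = "shortening (%)", xlab = "")
  graphics::plot(x$rel_t, abs(x$velocity), type = "l",
                 ylab = "|velocity| (1/s)", xlab = "")
  graphics::plot(x$rel_t, abs(x$acceleration), type = "l",
                 ylab = "|acceleration| (1/s^2)",
                 xlab = "time from upstroke half-max (s)")
  invisible(x)
}

#' Per-parameter fold change after an intervention
#'
#' Paired comparison for one tissue: `fold = after / before` for each
#' kinetic parameter. Parameters with zero (or undefined) baseline are
#' flagged as undefined rather than propagating `Inf`.
#'
#' @param before,after `kinetics_summary` objects for the same tissue.
#' @return Data frame with columns `parameter`, `before`, `after`, `fold`
#'   and `defined`.
#' @export
drug_response <- function(before, after) {
  par_names <- c("max_fs", "v_con_20", "v_con_50", "v_con_80", "v_rel_80",
                 "v_rel_50", "v_rel_20", "peak_acceleration",
                 "deceleration_time", "relaxation_time", "frequency")
  b <- vapply(par_names, function(p) before[[p]] %||% NA_real_, numeric(1))
  a <- vapply(par_names, function(p) after[[p]] %||% NA_real_, numeric(1))
  defined <- is.finite(b) & is.finite(a) & b != 0
  fold <- ifelse(defined, a / b, NA_real_)
  data.frame(parameter = par_names, before = b, after = a, fold = fold,
             defined = defined, row.names = NULL)
}

#' Summarize fold changes across tissues
#'
#' @param folds list of data frames from [drug_response()], one per tissue.
#' @return Data frame with per-parameter mean and SD of the fold change and
#'   the number of tissues contributing, plus the paired input table as the
#'   `"pairs"` attribute.
#' @export
drug_response_summary <- function(folds) {
  all <- do.call(rbind, Map(function(d, i) transform(d, tissue = i),
                            folds, seq_along(folds)))
  sp <- split(all, all$parameter)
  out <- do.call(rbind, lapply(sp, function(d) {
    f <- d$fold[d$defined]
    data.frame(parameter = d$parameter[1], mean_fold = mean(f),
               sd_fold = sd(f), n = length(f))
  }))
  rownames(out) <- NULL
  attr(out, "pairs") <- all
  out
}
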