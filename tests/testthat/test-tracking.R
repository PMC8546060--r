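test_that("identical frames give zero displacement and perfect scores", {
  st <- shifted_stack(0, 0, seed = 3)
  tr <- track_roi(st, roi_spec(c(40, 40), c(10, 10)),
                  tracking_params(search_radius = 5))
  expect_equal(tr$dx_um, c(0, 0))
  expect_equal(tr$dy_um, c(0, 0))
  expect_equal(tr$score, c(1, 1))
})

test_that("integer pixel shifts are recovered exactly", {
  for (sh in list(c(3, -2), c(-4, 1), c(0, 5))) {
    st <- shifted_stack(sh[1], sh[2], seed = 7)
    tr <- track_roi(st, roi_spec(c(40, 40), c(10, 10)),
                    tracking_params(search_radius = 6, subpixel = FALSE))
    expect_equal(tr$dx_um[2], sh[1] * st$pixel_size)
    expect_equal(tr$dy_um[2], sh[2] * st$pixel_size)
    expect_gt(tr$score[2], 0.99)
  }
})

test_that("FFT correlation equals the exhaustive spatial-domain oracle", {
  # full correlation surfaces agree to numerical precision, and the argmax
  # (hence the tracked displacement) is identical, over seeded stacks
  for (seed in 1:12) {
    st <- shifted_stack(sample(-4:4, 1), sample(-4:4, 1), n = 60,
                        seed = seed, noise_sd = 0.2)
    roi <- roi_spec(c(30, 30), c(8, 8))
    cx <- roi$center[1]; cy <- roi$center[2]
    hx <- roi$half_size[1]; hy <- roi$half_size[2]; r <- 6L
    template <- st$frames[(cy - hy):(cy + hy) + 1, (cx - hx):(cx + hx) + 1, 1]
    window <- st$frames[(cy - hy - r):(cy + hy + r) + 1,
                        (cx - hx - r):(cx + hx + r) + 1, 2]
    cc_f <- mbkit:::zncc_fft(template, window, r)
    cc_d <- mbkit:::zncc_direct(template, window, r)
    expect_lt(max(abs(cc_f - cc_d)), 1e-8)
    expect_identical(which.max(cc_f), which.max(cc_d))
    tf <- track_roi(st, roi, tracking_params(search_radius = r,
                                             method = "fft"))
    td <- track_roi(st, roi, tracking_params(search_radius = r,
                                             method = "direct"))
    expect_equal(tf$dx_um, td$dx_um)
    expect_equal(tf$dy_um, td$dy_um)
  }
})

test_that("subpixel shifts in [-0.5, 0.5] px are recovered within 0.1 px at SNR 10", {
  shifts <- seq(-0.5, 0.5, by = 0.125)
  for (i in seq_along(shifts)) {
    st <- subpixel_stack(shifts[i], seed = 20 + i, noise_sd = 0.1)
    tr <- track_roi(st, roi_spec(c(52, 52), c(10, 10)),
                    tracking_params(search_radius = 4))
    expect_lt(abs(tr$dx_um[2] - shifts[i]), 0.1)
    expect_lt(abs(tr$dy_um[2]), 0.1)
  }
})

test_that("mirror-flipping the stack negates dx and preserves dy", {
  st <- shifted_stack(3, -2, seed = 11)
  n <- dim(st)[2]
  fl <- st
  fl$frames <- st$frames[, n:1, , drop = FALSE]
  tr <- track_roi(st, roi_spec(c(40, 40), c(10, 10)),
                  tracking_params(search_radius = 6))
  trf <- track_roi(fl, roi_spec(c(n - 1 - 40, 40), c(10, 10)),
                   tracking_params(search_radius = 6))
  expect_equal(trf$dx_um[2], -tr$dx_um[2], tolerance = 1e-10)
  expect_equal(trf$dy_um[2], tr$dy_um[2], tolerance = 1e-10)
})

test_that("clipped search windows error and border peaks are flagged", {
  st <- shifted_stack(0, 0, seed = 5)
  expect_error(track_roi(st, roi_spec(c(12, 40), c(10, 10)),
                         tracking_params(search_radius = 5)),
               "clipped")
  # shift larger than the radius pushes the peak to the search border
  st2 <- shifted_stack(6, 0, seed = 6)
  tr <- track_roi(st2, roi_spec(c(40, 40), c(10, 10)),
                  tracking_params(search_radius = 3))
  expect_true(2L %in% attr(tr, "border_peak"))
})

test_that("symmetry index separates contraction from common-mode motion", {
  tp <- fake_trace_pair(ap = c(0, -1), ad = c(0, 1))
  expect_equal(symmetry_index(tp$prox, tp$dist)[2], 0)
  tp2 <- fake_trace_pair(ap = c(0, 1), ad = c(0, 1))
  expect_equal(symmetry_index(tp2$prox, tp2$dist)[2], 1)
  tp3 <- fake_trace_pair(ap = c(0, 1), ad = c(0, 0))
  expect_equal(symmetry_index(tp3$prox, tp3$dist)[2], 1)
  # below the noise floor the index is undefined
  tp4 <- fake_trace_pair(ap = c(0, 0.01), ad = c(0, -0.01))
  expect_true(is.na(symmetry_index(tp4$prox, tp4$dist)[2]))
  expect_error(symmetry_index(tp$prox, tp2$dist[1, ]), "length")
})

test_that("QC accepts clean movies and rejects constructed defects", {
  mov <- gen_contraction_movie(contraction_truth(fs_max = 0.04),
                               duration = 5, seed = 31)
  rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                             frame_dim = dim(mov$stack)[1:2])
  par <- tracking_params(search_radius = 10)
  p <- track_roi(mov$stack, rois$proximal, par)
  d <- track_roi(mov$stack, rois$distal, par)
  expect_true(qc_trace(p, d)$accept)

  # one frame replaced by noise -> low-correlation rejection naming the frame
  bad <- mov$stack
  k <- 120L
  bad$frames[, , k] <- matrix(rnorm(prod(dim(bad)[1:2])), dim(bad)[1])
  pb <- track_roi(bad, rois$proximal, par)
  db <- track_roi(bad, rois$distal, par)
  qb <- qc_trace(pb, db)
  expect_false(qb$accept)
  expect_true(any(grepl(sprintf("low correlation at frame %d", k),
                        qb$reasons)))

  # rigid translation (no shortening) -> common-mode rejection
  rig <- gen_contraction_movie(contraction_truth(fs_max = 0,
                                                 common_mode_um = 2),
                               duration = 5, seed = 32)
  rr <- place_rois_inner50(rig$geometry, rig$stack$pixel_size,
                           frame_dim = dim(rig$stack)[1:2])
  pr <- track_roi(rig$stack, rr$proximal, par)
  dr <- track_roi(rig$stack, rr$distal, par)
  qr <- qc_trace(pr, dr)
  expect_false(qr$accept)
  expect_true(any(grepl("common-mode", qr$reasons)))
})

test_that("quiescent_auto picks a low-motion reference frame", {
  mov <- gen_contraction_movie(contraction_truth(fs_max = 0.05,
                                                 frequency = 0.8,
                                                 t_con = 0.3, t_rel = 0.4),
                               duration = 2.5, seed = 33)
  rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                             frame_dim = dim(mov$stack)[1:2])
  k <- find_quiescent_frame(mov$stack, rois)
  # quiescent phase of the 1.25 s cycle: after relaxation, before next beat
  phase <- mov$t[k] %% 1.25
  expect_true(phase > 0.7 || phase < 0.05)
})
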