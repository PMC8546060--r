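test_that("generators are pure functions of truth and seed", {
  a <- gen_contraction_movie(contraction_truth(), duration = 1.2, seed = 9)
  b <- gen_contraction_movie(contraction_truth(), duration = 1.2, seed = 9)
  expect_identical(a$stack$frames, b$stack$frames)
  c_ <- gen_contraction_movie(contraction_truth(), duration = 1.2, seed = 10)
  expect_false(identical(a$stack$frames, c_$stack$frames))

  s1 <- gen_structure_image(structure_truth(), seed = 4)
  s2 <- gen_structure_image(structure_truth(), seed = 4)
  expect_identical(s1$image, s2$image)

  m1 <- gen_monolayer_movie(n_domains = 4, duration = 1, fps = 10, seed = 2)
  m2 <- gen_monolayer_movie(n_domains = 4, duration = 1, fps = 10, seed = 2)
  expect_identical(m1$stack$frames, m2$stack$frames)

  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(gen_structure_image(structure_truth(), seed = 5))
  expect_identical(rnorm(1), before)
})

test_that("the imposed warp is strain-exact at tracked material points", {
  # material point X0 appears at xc + (X0 - xc)(1 - eps): the tracked ROI
  # displacement must equal -(X0 - xc) eps(t) to subpixel accuracy
  mov <- gen_contraction_movie(contraction_truth(fs_max = 0.05,
                                                 noise_sd = 0),
                               duration = 2.4, seed = 21)
  rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                             frame_dim = dim(mov$stack)[1:2])
  for (lab in c("proximal", "distal")) {
    roi <- rois[[lab]]
    tr <- track_roi(mov$stack, roi, tracking_params(search_radius = 10))
    X0 <- roi$center[1] * mov$stack$pixel_size
    want <- -(X0 - mov$geometry$center[1]) * mov$epsilon
    expect_lt(max(abs(tr$dx_um - want)), 0.1 * mov$stack$pixel_size)
  }
})

test_that("a zero-amplitude movie is static and reads as fs = 0", {
  mov <- gen_contraction_movie(contraction_truth(fs_max = 0, noise_sd = 0),
                               duration = 1, seed = 22)
  expect_equal(max(abs(sweep(mov$stack$frames, c(1, 2),
                             mov$stack$frames[, , 1]))), 0)
  rois <- place_rois_inner50(mov$geometry, mov$stack$pixel_size,
                             frame_dim = dim(mov$stack)[1:2])
  p <- track_roi(mov$stack, rois$proximal, tracking_params(search_radius = 5))
  d <- track_roi(mov$stack, rois$distal, tracking_params(search_radius = 5))
  wf <- build_waveform(p, d)
  expect_equal(wf$fs, rep(0, nrow(wf)))
})

test_that("movies that would push texture out of range are rejected", {
  expect_error(contraction_truth(fs_max = 0.5), "0.2")
  expect_error(contraction_truth(fs_max = 0.1, frequency = 2,
                                 t_con = 0.4, t_rel = 0.4), "period")
})

test_that("structure generator honours its resolution precondition", {
  expect_error(gen_structure_image(structure_truth(spacing = 1.3),
                                   pixel_size = 0.45), "resolve")
  expect_error(structure_truth(spacing = 5), "detection band")
  # sigma 0 grating: recovered angles all agree within a degree
  si <- gen_structure_image(structure_truth(sigma_theta = 0, mu_theta = 7),
                            seed = 6)
  seg <- segment_sarcomere_units(si$image, si$pixel_size)
  expect_lt(diff(range(seg$units$angle_deg)), 1)
  expect_equal(mean(seg$units$angle_deg), 7, tolerance = 0.5)
})

test_that("the two-sigmoid beat family is a valid normalized waveform", {
  tr <- contraction_truth(waveform = "two_sigmoid", frequency = 0.4,
                          t_con = 0.5, t_rel = 0.7)
  t <- seq(0, 2.5, by = 0.02)
  eta <- mbkit:::beat_shape(t, tr)
  expect_equal(max(eta), 1, tolerance = 1e-9)
  expect_gte(min(eta), 0)
  expect_equal(eta[t > 1.3 & t < 2.4], rep(0, sum(t > 1.3 & t < 2.4)))
  # rises during contraction, falls during relaxation
  at <- function(x) eta[which.min(abs(t - x))]
  expect_gt(at(0.4), at(0.1))
  expect_gt(at(0.7), at(1.1))
})

test_that("monolayer domains tile without overlap and beat independently", {
  mono <- gen_monolayer_movie(n_domains = 8, duration = 1, fps = 10,
                              seed = 3)
  expect_equal(length(mono$domains), 8)
  for (i in 1:7) for (j in (i + 1):8) {
    a <- mono$domains[[i]]; b <- mono$domains[[j]]
    overlap <- max(0, min(a$x1, b$x1) - max(a$x0, b$x0)) *
      max(0, min(a$y1, b$y1) - max(a$y0, b$y0))
    expect_equal(overlap, 0)
  }
  angles <- vapply(mono$domains, `[[`, numeric(1), "angle")
  expect_gt(diff(range(angles)), 10)  # directions genuinely differ
})
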