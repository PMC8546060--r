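test_that("stripe fixtures yield the right peaks, widths and area fraction", {
  # 5 axial stripes of 4 um on a 45 um width -> 5 peaks per window,
  # widths 4 +/- 0.5 um, fraction 20/45
  si <- gen_structure_image(structure_truth(stripe_width = 4, stripe_gap = 5),
                            kind = "factin_bundles", seed = 1)
  prof <- extract_bundle_peaks(si$image, si$geometry, si$pixel_size)
  for (p in prof) {
    expect_equal(nrow(p$peaks), 5)
    expect_true(all(abs(p$peaks$width_um - 4) < 0.5))
  }
  dens <- compute_density(prof)
  expect_equal(dens$myofibril_area_fraction, 20 / 45, tolerance = 0.02)
  expect_equal(dens$n_bundles, 5)
  expect_lt(dens$heterogeneity, 0.02)
})

test_that("blank images and DC offsets are handled", {
  si <- gen_structure_image(structure_truth(stripe_width = 4, stripe_gap = 5),
                            kind = "factin_bundles", seed = 1)
  blank <- matrix(1, nrow(si$image), ncol(si$image))
  pb <- extract_bundle_peaks(blank, si$geometry, si$pixel_size)
  expect_true(all(vapply(pb, function(p) nrow(p$peaks), integer(1)) == 0))
  expect_equal(compute_density(pb)$myofibril_area_fraction, 0)

  # adding 50% DC offset leaves peaks unchanged (background subtraction)
  poff <- extract_bundle_peaks(si$image + 0.5 * max(si$image), si$geometry,
                               si$pixel_size)
  d0 <- compute_density(extract_bundle_peaks(si$image, si$geometry,
                                             si$pixel_size))
  doff <- compute_density(poff)
  expect_equal(doff$myofibril_area_fraction, d0$myofibril_area_fraction,
               tolerance = 0.005)
  # and so does a pure gain
  dgain <- compute_density(extract_bundle_peaks(3 * si$image, si$geometry,
                                                si$pixel_size))
  expect_equal(dgain$myofibril_area_fraction, d0$myofibril_area_fraction,
               tolerance = 1e-9)
})

test_that("area fraction tracks generator coverage within 0.05", {
  layouts <- list(c(1.8, 7.2), c(3.6, 5.4), c(5.4, 3.6), c(7.2, 1.8))
  for (wg in layouts) {
    si <- gen_structure_image(structure_truth(stripe_width = wg[1],
                                              stripe_gap = wg[2]),
                              kind = "factin_bundles", seed = 2)
    d <- compute_density(extract_bundle_peaks(si$image, si$geometry,
                                              si$pixel_size))
    expect_lt(abs(d$myofibril_area_fraction - si$coverage), 0.05)
  }
})

test_that("fraction measures area, not bundle count", {
  # double-width stripes at matched coverage: fraction unchanged within 0.05
  thin <- gen_structure_image(structure_truth(stripe_width = 3,
                                              stripe_gap = 4.5),
                              kind = "factin_bundles", seed = 3)
  wide <- gen_structure_image(structure_truth(stripe_width = 6,
                                              stripe_gap = 9),
                              kind = "factin_bundles", seed = 3)
  dt_ <- compute_density(extract_bundle_peaks(thin$image, thin$geometry,
                                              thin$pixel_size))
  dw <- compute_density(extract_bundle_peaks(wide$image, wide$geometry,
                                             wide$pixel_size))
  expect_lt(abs(dt_$myofibril_area_fraction - thin$coverage), 0.05)
  expect_lt(abs(dw$myofibril_area_fraction - wide$coverage), 0.05)
  expect_gt(dt_$n_bundles, dw$n_bundles)
})

test_that("window and geometry preconditions are enforced", {
  si <- gen_structure_image(structure_truth(), kind = "factin_bundles",
                            seed = 1)
  expect_error(extract_bundle_peaks(si$image, NULL, si$pixel_size),
               "geometry")
  expect_error(extract_bundle_peaks(si$image, si$geometry, si$pixel_size,
                                    window_um = 1000), "exceeds")
  expect_error(mean_intensity_in_mask(si$image, matrix(TRUE, 2, 2)),
               "mismatch")
  m <- mean_intensity_in_mask(si$image, si$image > mean(si$image))
  expect_gt(m, mean(si$image))
})
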