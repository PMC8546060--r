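test_that("waveform arithmetic: inward ROI motion gives fs = dL/L0", {
  # ROIs 154 um apart, each moving 3.85 um inward -> max fs = 7.7/154 = 5%
  n <- 100
  beat <- numeric(n)
  beat[40:60] <- sin(seq(0, pi, length.out = 21))^2
  tp <- fake_trace_pair(ap = 3.85 * beat, ad = -3.85 * beat)
  wf <- build_waveform(tp$prox, tp$dist)
  expect_equal(max(wf$fs), 7.7 / 154, tolerance = 1e-6)
  # zero displacement -> fs identically 0
  tp0 <- fake_trace_pair(ap = numeric(n), ad = numeric(n))
  expect_equal(build_waveform(tp0$prox, tp0$dist)$fs, rep(0, n))
  # pure common-mode translation -> separation unchanged -> fs = 0
  tpc <- fake_trace_pair(ap = 2 * beat, ad = 2 * beat)
  expect_equal(max(abs(build_waveform(tpc$prox, tpc$dist)$fs)), 0,
               tolerance = 1e-12)
})

test_that("closed-form raised-cosine kinetics match analytic values", {
  # fs(t) = FS (1 - cos(pi t / Tc))/2, FS = 0.05, Tc = 0.5 s, 50 fps:
  # |v| at 20/80% = 0.8 FS pi/(2 Tc), at 50% = FS pi/(2 Tc);
  # peak acceleration = FS pi^2 / (2 Tc^2)
  wf <- cosine_waveform(fs_max = 0.05, t_con = 0.5, t_rel = 0.5)
  ks <- extract_kinetics(segment_and_merge(wf))
  expect_equal(ks$v_con_20, 0.8 * 0.05 * pi / 1, tolerance = 0.02)
  expect_equal(ks$v_con_50, 0.05 * pi / 1, tolerance = 0.02)
  expect_equal(ks$v_con_80, 0.8 * 0.05 * pi / 1, tolerance = 0.02)
  expect_equal(ks$peak_acceleration, 0.05 * pi^2 / (2 * 0.25),
               tolerance = 0.05)
  expect_equal(ks$max_fs, 0.05, tolerance = 0.005)
  # time-symmetric beat: contraction and relaxation speeds agree
  expect_equal(ks$v_rel_50, ks$v_con_50, tolerance = 0.02)
  expect_equal(ks$v_rel_20, ks$v_con_20, tolerance = 0.03)
  # relaxation time: fs falls to 10% of peak at
  # t = Tc/pi * acos(1 - 2*0.9) after the peak
  expect_equal(ks$relaxation_time, 0.5 / pi * acos(1 - 1.8),
               tolerance = 0.05)
  expect_true(ks$deceleration_time > 0 && ks$deceleration_time < 0.5)
})

test_that("identical beats merge with zero-width confidence band", {
  wf <- cosine_waveform(frequency = 0.4, duration = 25)
  bs <- segment_and_merge(wf)
  expect_equal(bs$n_beats, 10)
  expect_equal(bs$frequency, 0.4, tolerance = 1e-9)
  expect_lt(max(bs$ci_hi - bs$ci_lo), 1e-12)
  # merged mean equals the per-beat mean at every aligned time point
  expect_equal(bs$mean, rowMeans(bs$beats))
})

test_that("amplitude jitter is reflected in the confidence band", {
  # beats with seeded 5% CV amplitude: merged max within 2 SEM of the mean
  dt <- 0.02
  t <- seq(0, 25 - dt, by = dt)
  tr <- contraction_truth(fs_max = 0.1, frequency = 0.4, t_con = 0.5,
                          t_rel = 0.5, noise_sd = 0)
  shape <- mbkit:::beat_shape(t, tr)
  amps <- mbkit:::local_seed(42, rnorm(10, 0.05, 0.05 * 0.05))
  fs <- shape * amps[pmin(10, floor(t * 0.4) + 1)]
  bs <- segment_and_merge(shortening_waveform(t, fs))
  expect_equal(bs$n_beats, 10)
  sem <- sd(amps) / sqrt(10)
  expect_lt(abs(max(bs$mean) - mean(amps)), 2 * sem + 1e-6)
})

test_that("flat and empty records degrade explicitly", {
  flat <- shortening_waveform(seq(0, 5, 0.02), rep(0, 251))
  bs <- segment_and_merge(flat)
  expect_equal(bs$n_beats, 0L)
  expect_match(bs$reason, "no")
  expect_error(extract_kinetics(bs), bs$reason, fixed = TRUE)
})

test_that("drug response reports per-parameter folds and flags zero baselines", {
  wf <- cosine_waveform(frequency = 0.4, duration = 10)
  ks <- extract_kinetics(segment_and_merge(wf))
  same <- drug_response(ks, ks)
  expect_true(all(same$fold[same$defined] == 1))
  # halved-amplitude intervention: fs and velocity folds of 0.5
  wf2 <- cosine_waveform(fs_max = 0.025, frequency = 0.4, duration = 10)
  ks2 <- extract_kinetics(segment_and_merge(wf2))
  dr <- drug_response(ks, ks2)
  expect_equal(dr$fold[dr$parameter == "max_fs"], 0.5, tolerance = 0.02)
  expect_equal(dr$fold[dr$parameter == "v_con_50"], 0.5, tolerance = 0.02)
  expect_equal(dr$fold[dr$parameter == "frequency"], 1, tolerance = 1e-6)
  # an undefined (zero / NA) baseline parameter is flagged, not Inf
  ks3 <- ks
  ks3$frequency <- 0
  dr3 <- drug_response(ks3, ks2)
  expect_false(dr3$defined[dr3$parameter == "frequency"])
  expect_true(is.na(dr3$fold[dr3$parameter == "frequency"]))
  # batch summary over two identical tissues
  sm <- drug_response_summary(list(dr, dr))
  expect_equal(sm$mean_fold[sm$parameter == "max_fs"], 0.5, tolerance = 0.02)
  expect_equal(sm$n[sm$parameter == "max_fs"], 2)
})

test_that("scaling the generator amplitude scales recovered max_fs linearly", {
  get_fs <- function(k) {
    wf <- cosine_waveform(fs_max = 0.02 * k, frequency = 0.4, duration = 10)
    extract_kinetics(segment_and_merge(wf))$max_fs
  }
  base <- get_fs(1)
  for (k in c(2, 3)) expect_equal(get_fs(k) / base, k, tolerance = 0.02)
})
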