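# Fixtures built in code: small stacks, shifted textures, analytic beats.

# stack whose second frame shows the first shifted by integer (dx, dy) px
shifted_stack <- function(dx, dy, n = 80, seed = 1, pixel_size = 0.5,
                          noise_sd = 0) {
  mbkit:::local_seed(seed, {
    tex <- mbkit:::bandlimited_texture(n, n, 2)
    fr <- array(0, c(n, n, 2))
    fr[, , 1] <- tex
    src_r <- seq_len(n - abs(dy)) + max(0, -dy)
    src_c <- seq_len(n - abs(dx)) + max(0, -dx)
    dst_r <- src_r + dy
    dst_c <- src_c + dx
    fr[dst_r, dst_c, 2] <- tex[src_r, src_c]
    if (noise_sd > 0) fr <- fr + array(rnorm(length(fr), sd = noise_sd),
                                       dim(fr))
    image_stack(fr, pixel_size, 0.02)
  })
}

# stack whose second frame is the first resampled by a subpixel x-shift
subpixel_stack <- function(shift, n = 110, seed = 1, noise_sd = 0.1) {
  mbkit:::local_seed(seed, {
    tex <- mbkit:::bandlimited_texture(n, n, 2.5)
    xq <- (0:(n - 1)) - shift
    keep <- xq >= 3 & xq < n - 3
    W <- mbkit:::lanczos_operator(xq[keep], n)
    fr <- array(0, c(n, sum(keep), 2))
    fr[, , 1] <- tex[, keep]
    fr[, , 2] <- as.matrix(tex %*% W)
    if (noise_sd > 0) fr <- fr + array(rnorm(length(fr), sd = noise_sd),
                                       dim(fr))
    image_stack(fr, 1, 0.02)
  })
}

# analytic raised-cosine shortening waveform (possibly repeated beats)
cosine_waveform <- function(fs_max = 0.05, t_con = 0.5, t_rel = 0.5,
                            frequency = 0, duration = 2.4, fps = 50) {
  tr <- contraction_truth(fs_max = fs_max, frequency = frequency,
                          t_con = t_con, t_rel = t_rel, noise_sd = 0)
  t <- seq(0, duration - 1 / fps, by = 1 / fps)
  shortening_waveform(t, fs_max * mbkit:::beat_shape(t, tr))
}

# minimal displacement_trace pair for waveform arithmetic tests
fake_trace_pair <- function(ap, ad, sep_um = 154, pixel_size = 0.5,
                            dt = 0.02) {
  mk <- function(a, label, cx) {
    df <- data.frame(frame = seq_along(a), t = (seq_along(a) - 1) * dt,
                     dx_um = a, dy_um = 0, score = 1)
    structure(df, class = c("displacement_trace", "data.frame"),
              roi = roi_spec(c(cx, 50), c(10, 10), label),
              reference = 1L, pixel_size = pixel_size,
              frame_interval = dt, border_peak = integer())
  }
  list(prox = mk(ap, "proximal", 0),
       dist = mk(ad, "distal", round(sep_um / pixel_size)))
}
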