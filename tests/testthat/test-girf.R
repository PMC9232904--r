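fine_freqs <- seq(-2e5, 2e5, by = 25)

test_that("girf_model enforces conjugate symmetry and DC gain bounds", {
  f <- seq(-1e4, 1e4, by = 100)
  ok <- lapply(1:3, function(a) exp(-2i * pi * f * 5e-6))
  expect_s3_class(girf_model(f, ok), "girf_model")
  bad <- ok; bad[[2]] <- exp(-2i * pi * abs(f) * 5e-6)   # even phase: breaks symmetry
  expect_error(girf_model(f, bad), "conjugate-symmetric")
  big <- lapply(1:3, function(a) rep(1.5 + 0i, length(f)))
  expect_error(girf_model(f, big), "transfer\\(0\\)")
})

test_that("identity transfer passes gradients through unchanged", {
  gp <- transform_to_physical(fx_spiral(32, 2), scan_geometry())
  id <- girf_model(fine_freqs,
                   lapply(1:3, function(a) rep(1 + 0i, length(fine_freqs))))
  out <- predict_gradients(gp, id)
  expect_lt(max(abs(out$samples - gp$samples)), 1e-10)
  # zero input stays zero
  g0 <- gradient_set(array(0, c(1, 64, 3)), 2.5e-6, frame = "physical")
  expect_true(all(predict_gradients(g0, id)$samples == 0))
})

test_that("a pure-delay transfer shifts the waveform by the delay", {
  tau <- 10e-6
  gp <- transform_to_physical(fx_spiral(32, 2), scan_geometry())
  dl <- girf_model(fine_freqs,
                   lapply(1:3, function(a) exp(-2i * pi * fine_freqs * tau)))
  out <- predict_gradients(gp, dl)
  # fractional-delay oracle: sinc interpolation via FFT phase ramp on the
  # same zero-padded support
  nk <- dim(gp$samples)[2]
  nfft <- 2^ceiling(log2(4 * nk))
  fg <- c(0:(nfft / 2 - 1), -(nfft / 2):-1) / (nfft * gp$raster_s)
  for (ax in 1:2) {
    w <- c(gp$samples[1, , ax], numeric(nfft - nk))
    oracle <- Re(stats::fft(stats::fft(w) * exp(-2i * pi * fg * tau),
                            inverse = TRUE) / nfft)[seq_len(nk)]
    expect_lt(max(abs(out$samples[1, , ax] - oracle)) / max(abs(w)), 1e-6)
  }
})

test_that("prediction is linear and passive transfers do not add energy", {
  set.seed(21)
  girf <- synthesize_girf(delay_s = 2e-6, cutoff_Hz = 3e4, osc_amp = 0,
                          freq_Hz = fine_freqs)
  g1 <- gradient_set(array(stats::rnorm(3 * 200 * 3, sd = 1e-3),
                           c(3, 200, 3)), 2.5e-6, frame = "physical")
  g2 <- gradient_set(array(stats::rnorm(3 * 200 * 3, sd = 1e-3),
                           c(3, 200, 3)), 2.5e-6, frame = "physical")
  gc <- gradient_set(0.7 * g1$samples - 1.3 * g2$samples, 2.5e-6,
                     frame = "physical")
  p1 <- predict_gradients(g1, girf); p2 <- predict_gradients(g2, girf)
  pc <- predict_gradients(gc, girf)
  expect_lt(max(abs(pc$samples - (0.7 * p1$samples - 1.3 * p2$samples))), 1e-10)
  # |transfer| <= 1 implies no energy gain
  expect_lte(sqrt(sum(p1$samples^2)), sqrt(sum(g1$samples^2)) * (1 + 1e-10))
})

test_that("zero-padding suppresses circular wrap-around", {
  gp <- transform_to_physical(fx_spiral(32, 2), scan_geometry())
  # GIRF tabulated exactly on the finer of the two FFT grids, so both
  # resamplings are node-exact and only the wrap-around itself differs;
  # resonance decay time 2q/(2 pi f0) ~ 0.2 ms, well inside the 4x pad
  df_fine <- 1 / (32768 * gp$raster_s)
  girf <- synthesize_girf(delay_s = 20e-6, cutoff_Hz = 2e4,
                          osc_freq_Hz = 5e3, osc_amp = 0.05, q = 3,
                          freq_Hz = (-16384:16384) * df_fine)
  out1 <- predict_gradients(gp, girf)
  # doubling the pad: emulate by running on a doubly padded waveform
  nk <- dim(gp$samples)[2]
  gpad <- gradient_set(array(0, c(1, 4 * nk, 3)), gp$raster_s,
                       frame = "physical")
  gpad$samples[1, seq_len(nk), ] <- gp$samples[1, , ]
  out2 <- predict_gradients(gpad, girf)
  expect_lt(max(abs(out2$samples[1, seq_len(nk), ] - out1$samples[1, , ])) /
              max(abs(gp$samples)), 1e-8)
})

test_that("synthesized GIRFs have the advertised structure", {
  f <- fine_freqs
  # degenerate parameters give the identity system
  flat <- synthesize_girf(delay_s = 0, cutoff_Hz = Inf, osc_amp = 0, freq_Hz = f)
  expect_lt(max(abs(flat$transfer[[1]] - 1)), 1e-12)
  # low-pass magnitude is non-increasing in |f|
  lp <- synthesize_girf(delay_s = 0, cutoff_Hz = 1e4, osc_amp = 0, freq_Hz = f)
  mag <- Mod(lp$transfer[[1]][f >= 0])
  expect_true(all(diff(mag) <= 1e-12))
  # impulse response is real and peaks after the delay
  gs <- synthesize_girf(delay_s = 50e-6, cutoff_Hz = 2e4, osc_amp = 0,
                        freq_Hz = seq(-2e5, 2e5 - 25, by = 25))
  tf <- gs$transfer[[1]]
  # order onto an FFT grid (DC first) for the inverse transform
  ord <- order((gs$freq_Hz %% 4e5))
  h <- stats::fft(tf[ord], inverse = TRUE) / length(tf)
  expect_lt(max(abs(Im(h))) / max(abs(h)), 1e-10)
  dt <- 1 / 4e5
  expect_gt(which.max(Re(h)) * dt, 50e-6 * 0.5)
})

test_that("out-of-band prediction warns and B0 cross-terms are not applied", {
  gp <- transform_to_physical(fx_spiral(32, 2), scan_geometry())
  nar <- seq(-5e3, 5e3, by = 50)
  girf <- synthesize_girf(delay_s = 0, cutoff_Hz = Inf, osc_amp = 0,
                          freq_Hz = nar)
  expect_warning(predict_gradients(gp, girf), "band")
  with_cross <- girf_model(girf$freq_Hz, girf$transfer,
                           b0_cross = lapply(1:3, function(a)
                             rep(0.5 + 0i, length(nar))))
  p1 <- suppressWarnings(predict_gradients(gp, girf))
  p2 <- suppressWarnings(predict_gradients(gp, with_cross))
  expect_identical(p1$samples, p2$samples)
})

test_that("prediction requires physical-frame input", {
  girf <- synthesize_girf(freq_Hz = fine_freqs)
  expect_error(predict_gradients(fx_spiral(32, 2), girf), "physical")
})
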