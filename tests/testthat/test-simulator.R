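test_that("phantom rasterization is additive and area-faithful", {
  grid <- fx_grid(64)
  # empty spec: zero image
  expect_true(all(make_phantom(default_phantom_spec()[0, ], grid) == 0))
  # single full-FOV ellipse: mask fraction close to the analytic area
  one <- data.frame(x0 = 0, y0 = 0, a = 0.4 * 0.24, b = 0.3 * 0.24,
                    angle_deg = 0, amp_re = 1, amp_im = 0)
  img <- make_phantom(one, grid)
  frac <- mean(Mod(img) > 0)
  area <- pi * one$a * one$b / 0.24^2
  perim_err <- 2 * (0.24 / 64) * pi * (one$a + one$b) / 0.24^2
  expect_lt(abs(frac - area), perim_err)
  # two disjoint ellipses add independently
  e1 <- data.frame(x0 = -0.06, y0 = 0, a = 0.02, b = 0.015, angle_deg = 0,
                   amp_re = 1, amp_im = 0.5)
  e2 <- data.frame(x0 = 0.07, y0 = 0.03, a = 0.018, b = 0.02, angle_deg = 30,
                   amp_re = -0.4, amp_im = 0)
  expect_equal(make_phantom(rbind(e1, e2), grid),
               make_phantom(e1, grid) + make_phantom(e2, grid))
})

test_that("coil maps are smooth with positive sum-of-squares", {
  grid <- fx_grid(64)
  cm <- make_coilmaps(8, grid)
  sos <- rowSums(Mod(cm$maps)^2)
  expect_true(all(sos > 0))
  # band-limited: > 99% spectral energy in the central quarter of k-space
  for (cc in c(1, 5)) {
    M <- matrix(cm$maps[, cc], 64, 64)
    S <- Mod(stats::fft(M))^2
    S <- S[c(33:64, 1:32), c(33:64, 1:32)]     # center the spectrum
    central <- S[17:48, 17:48]
    expect_gt(sum(central) / sum(S), 0.99)
  }
  # single coil: uniform unity map
  expect_true(all(make_coilmaps(1, grid)$maps == 1 + 0i))
})

test_that("off-resonance maps satisfy their scaling contracts", {
  grid <- fx_grid(48)
  expect_true(all(make_offresonance(grid, 0) == 0))
  df <- make_offresonance(grid, 150)
  expect_equal(max(abs(df)), 150, tolerance = 1e-9)
  fat <- data.frame(x0 = 0, y0 = -0.04, a = 0.02, b = 0.015, angle_deg = 0)
  dff <- make_offresonance(grid, 150, fat, fat_shift_Hz = -88)
  inside <- dff != df
  expect_true(any(inside))
  expect_equal(unique(round(dff[inside] - df[inside], 9)), -88)
})

test_that("simulation equals the encoding operator and is reproducible", {
  N <- 32
  geom <- geom_sagittal(0.04)
  grid <- fx_grid(N)
  g <- fx_spiral(N, 2)
  coils <- fx_coils(3, N)
  truth <- fx_truth(N)
  # zero phantom gives zero data even with noise sigma = 0
  z <- simulate_acquisition(complex(N * N), coils, NULL, geom, g, grid)
  expect_true(all(z$samples == 0))
  # concomitant disabled, no off-resonance: equals NUFFT of the
  # coil-weighted phantom (dense oracle, exact; gridding, to its accuracy)
  dat <- simulate_acquisition(truth, coils, NULL, scan_geometry(), g, grid)
  trL <- integrate_kspace(g, scan_geometry())
  op <- encoding_operator(trL, grid, coils, NULL, mode = "dense")
  ref <- forward(op, truth)
  expect_lt(max(Mod(dat$samples - ref)) / max(Mod(ref)), 1e-12)
  kc <- cbind(trL$k[1, , 1], trL$k[1, , 2]) * 0.24 / (2 * pi)
  pg <- nufft_plan(kc, c(N, N), mode = "grid")
  expect_lt(max(Mod(dat$samples[1, 1, ] -
                      nufft_forward(pg, coils$maps[, 1] * truth))) /
              max(Mod(ref)), 1e-6)
  # fixed seed: bit-identical noise
  n1 <- simulate_acquisition(truth, coils, NULL, geom, g, grid,
                             noise = list(sigma = 0.1, seed = 99))
  n2 <- simulate_acquisition(truth, coils, NULL, geom, g, grid,
                             noise = list(sigma = 0.1, seed = 99))
  expect_identical(n1$samples, n2$samples)
  # grid guard
  big <- spatial_grid(c(256, 256), 0.24)
  expect_error(simulate_acquisition(complex(256^2), make_coilmaps(1, big),
                                    NULL, geom, g, big), "guard")
})

test_that("uncorrected blur grows with offset and shrinks with B0", {
  # compact version of the field-strength / off-isocenter sweep: the
  # uncorrected error at strong settings exceeds the weak-setting error
  N <- 32
  grid <- fx_grid(N)
  g <- fx_spiral(N, 2)
  coils <- fx_coils(3, N)
  truth <- fx_truth(N)
  err <- function(B0, off) {
    geom <- geom_sagittal(off, B0)
    dat <- simulate_acquisition(truth, coils, NULL, geom, g, grid,
                                model = concomitant_model("lowest", B0))
    trP <- integrate_kspace(transform_to_physical(g, geom), geom)
    dat <- demodulate_offset(dat, trP, geom)
    trL <- transform_to_logical(trP, geom)
    op <- encoding_operator(trL, grid, coils, NULL, mode = "dense")
    rec <- maxgirf_recon(op, dat, method = "lsq",
                         weights = density_weights(trL))
    nrmse(truth, rec$image, scale = "global")
  }
  e_low_far  <- err(0.55, 0.10)
  e_low_near <- err(0.55, 0.00)
  e_high_far <- err(7.00, 0.10)
  expect_gt(e_low_far, e_low_near)
  expect_gt(e_low_far, e_high_far)
})
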