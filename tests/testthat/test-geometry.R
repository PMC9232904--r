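test_that("scan_geometry validates its invariants", {
  expect_error(scan_geometry(rotation = matrix(1:9, 3, 3)), "orthogonal")
  expect_error(scan_geometry(B0 = -1), "B0")
  g <- scan_geometry(rotation = random_rotation(), offset = c(0.01, 0, 0.05))
  expect_s3_class(g, "scan_geometry")
})

test_that("logical-to-physical transform handles identity and rotations", {
  geom_id <- scan_geometry()
  grid <- spatial_grid(c(8, 8), 0.2)
  out <- transform_to_physical(grid, geom_id)
  expect_equal(out$coords, grid$coords)
  expect_identical(out$frame, "physical")
  # 90 degree rotation about z sends (0.1, 0, 0) to (0, 0.1, 0)
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  g2 <- scan_geometry(rotation = Rz)
  grid1 <- spatial_grid(c(1, 1), 0.1, coords = matrix(c(0.1, 0, 0), 1, 3))
  p <- transform_to_physical(grid1, g2)
  expect_equal(as.numeric(p$coords), c(0, 0.1, 0), tolerance = 1e-14)
  # frame discipline: double transform is rejected
  expect_error(transform_to_physical(p, g2), "logical")
})

test_that("k-space phase splits into logical phase plus offset phase", {
  # k_P . r_P = k_L . r_L + k_P . offset, over random geometries
  set.seed(101)
  for (rep in 1:100) {
    R <- random_rotation()
    off <- stats::rnorm(3)
    kL <- stats::rnorm(3); rL <- stats::rnorm(3)
    kP <- R %*% kL
    rP <- R %*% rL + off
    expect_lt(abs(sum(kP * rP) - (sum(kL * rL) + sum(kP * off))), 1e-12)
  }
})

test_that("physical and logical transforms are exact inverses", {
  set.seed(102)
  geom <- scan_geometry(rotation = random_rotation(),
                        offset = c(0.02, -0.01, 0.08))
  g <- gradient_set(array(stats::rnorm(2 * 5 * 3), c(2, 5, 3)), 1e-5)
  tr <- trajectory(array(stats::rnorm(2 * 5 * 3), c(2, 5, 3)), (1:5) * 1e-5)
  grid <- spatial_grid(c(6, 6), 0.2)
  for (x in list(g, tr, grid)) {
    back <- transform_to_logical(transform_to_physical(x, geom), geom)
    expect_equal(back, x, tolerance = 1e-12)
  }
})

test_that("k-space integration matches closed forms and is linear", {
  geom <- scan_geometry()
  dt <- 1e-5
  # zero gradient
  g0 <- gradient_set(array(0, c(1, 50, 3)), dt)
  expect_true(all(integrate_kspace(g0, geom)$k == 0))
  # constant G: k = gamma * G * t; at t = 1 ms with G = 0.01 T/m
  nk <- 101
  gc <- array(0, c(1, nk, 3)); gc[1, , 1] <- 0.01
  tr <- integrate_kspace(gradient_set(gc, dt), geom)
  expect_equal(tr$k[1, nk, 1], geom$gamma * 0.01 * 1e-3, tolerance = 1e-12)
  expect_equal(tr$k[1, 1, 1], 0)
  # trapezoid (ramp-plateau-ramp): trapezoid rule is exact for linear G
  ramp <- c(seq(0, 0.01, length.out = 21), rep(0.01, 40),
            seq(0.01, 0, length.out = 21))
  gt <- array(0, c(1, length(ramp), 3)); gt[1, , 2] <- ramp
  trt <- integrate_kspace(gradient_set(gt, dt), geom)
  t_r <- 20 * dt; t_p <- 41 * dt   # plateau spans the inter-ramp intervals
  k_analytic <- geom$gamma * (0.5 * 0.01 * t_r + 0.01 * t_p + 0.5 * 0.01 * t_r)
  expect_equal(trt$k[1, length(ramp), 2], k_analytic, tolerance = 1e-9)
  # linearity
  ga <- gradient_set(array(stats::rnorm(300), c(1, 100, 3)), dt)
  gb <- gradient_set(array(stats::rnorm(300), c(1, 100, 3)), dt)
  gab <- gradient_set(2 * ga$samples - 3 * gb$samples, dt)
  expect_equal(integrate_kspace(gab, geom)$k,
               2 * integrate_kspace(ga, geom)$k -
               3 * integrate_kspace(gb, geom)$k, tolerance = 1e-12)
})

test_that("offset demodulation inverts the slice-offset modulation", {
  set.seed(103)
  geom <- geom_sagittal(0.07)
  g <- fx_spiral(16, 2)
  trP <- integrate_kspace(transform_to_physical(g, geom), geom)
  nk <- dim(trP$k)[2]
  dat <- kspace_data(array(crnorm(2 * 3 * nk), c(2, 3, nk)), dwell_s = 2.5e-6)
  # zero offset: unchanged
  dat0 <- demodulate_offset(dat, trP, scan_geometry(geom$rotation, c(0, 0, 0)))
  expect_equal(dat0$samples, dat$samples)
  # modulate then demodulate: identity
  rt <- demodulate_offset(modulate_offset(dat, trP, geom), trP, geom)
  expect_equal(rt$samples, dat$samples, tolerance = 1e-12)
  # sample-count mismatch
  trshort <- trajectory(trP$k[, 1:10, , drop = FALSE], trP$times_s[1:10],
                        frame = "physical")
  expect_error(demodulate_offset(dat, trshort, geom), "mismatch")
})

test_that("a point source reconstructs at its logical position after demodulation", {
  N <- 16
  grid <- fx_grid(N)
  geom <- geom_sagittal(0.06)
  g <- fx_spiral(N, 2)
  idx <- (7 - 1) * N + 11          # voxel (11, 7), column-major
  pt <- complex(N * N); pt[idx] <- 1
  coils <- coil_maps(matrix(1 + 0i, N * N, 1))
  dat <- simulate_acquisition(pt, coils, NULL, geom, g, grid)
  trP <- integrate_kspace(transform_to_physical(g, geom), geom)
  dat_dm <- demodulate_offset(dat, trP, geom)
  trL <- transform_to_logical(trP, geom)
  op <- encoding_operator(trL, grid, coils, NULL, mode = "dense")
  img <- maxgirf_recon(op, dat_dm, method = "cp",
                       dcf = density_weights(trL))$image
  expect_equal(which.max(Mod(img)), idx)
})
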