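test_that("dynamic coefficients match the symmetric-coil expressions", {
  # G = (0.01, 0, 0) T/m at 0.55 T: only h6 = 1e-4 / 1.1 survives
  g <- gradient_set(matrix(c(0.01, 0, 0), 1, 3), 1e-5, frame = "physical")
  h <- dynamic_coefficients(g, concomitant_model("lowest", 0.55))
  expect_equal(h[1, 1, 3], 1e-4 / 1.1, tolerance = 1e-12)
  expect_true(all(h[1, 1, -3] == 0))
  # G == 0 gives all-zero coefficients (both orders)
  g0 <- gradient_set(array(0, c(2, 4, 3)), 1e-5, frame = "physical")
  expect_true(all(dynamic_coefficients(g0, concomitant_model("full", 1)) == 0))
  # axial special case: G_z == 0 kills every lowest-order term except h6
  set.seed(31)
  gxy <- array(stats::rnorm(1 * 20 * 3, sd = 0.01), c(1, 20, 3))
  gxy[, , 3] <- 0
  hax <- dynamic_coefficients(gradient_set(gxy, 1e-5, frame = "physical"),
                              concomitant_model("lowest", 0.55))
  expect_true(all(hax[, , c(1, 2, 4, 5, 6)] == 0))   # h4 h5 h7 h8 h9
  expect_gt(max(abs(hax[, , 3])), 0)
  # frame discipline
  expect_error(dynamic_coefficients(gradient_set(gxy, 1e-5),
                                    concomitant_model("lowest", 0.55)),
               "physical")
})

test_that("coefficients scale quadratically in G and inversely in B0", {
  set.seed(32)
  g <- gradient_set(array(stats::rnorm(2 * 10 * 3, sd = 0.02), c(2, 10, 3)),
                    1e-5, frame = "physical")
  g2 <- gradient_set(2 * g$samples, 1e-5, frame = "physical")
  mf1 <- concomitant_model("full", 1.1); mf2 <- concomitant_model("full", 0.55)
  h1 <- dynamic_coefficients(g, mf1)
  h2 <- dynamic_coefficients(g, mf2)
  hg <- dynamic_coefficients(g2, mf1)
  quad <- 1:6; cub <- 7:16
  nz <- h1[, , quad] != 0
  expect_equal(h2[, , quad][nz] / h1[, , quad][nz], rep(2, sum(nz)))
  expect_equal(hg[, , quad][nz] / h1[, , quad][nz], rep(4, sum(nz)))
  nzc <- h1[, , cub] != 0
  expect_equal(h2[, , cub][nzc] / h1[, , cub][nzc], rep(4, sum(nzc)))
})

test_that("phase coefficients integrate from the reference time", {
  times <- (0:100) * 1e-5
  gamma <- 2 * pi * 42.5764e6
  h0 <- array(0, c(1, 101, 2))
  expect_true(all(phase_coefficients(h0, times) == 0))
  # constant h: k(t) = gamma h t, linear
  hc <- array(3e-6, c(1, 101, 1))
  k <- phase_coefficients(hc, times, gamma)
  expect_equal(k[1, , 1], gamma * 3e-6 * times, tolerance = 1e-12)
  expect_equal(k[1, 1, 1], 0)
  # piecewise-constant h: piecewise-linear k (trapezoid is exact away from
  # the jump; the jump sample contributes half a cell)
  hp <- array(c(rep(2e-6, 51), rep(5e-6, 50)), c(1, 101, 1))
  kp <- phase_coefficients(hp, times, gamma)
  expect_equal(kp[1, 40, 1], gamma * 2e-6 * times[40], tolerance = 1e-10)
  k_end <- gamma * (2e-6 * times[51] + 3.5e-6 * 1e-5 + 5e-6 * (times[101] - times[52]))
  expect_equal(kp[1, 101, 1], k_end, tolerance = 1e-10)
})

test_that("basis evaluation matches the monomial table and its parity", {
  gr <- spatial_grid(c(1, 1), 1, frame = "physical",
                     coords = matrix(c(0.1, 0.2, 0.3), 1, 3))
  b <- evaluate_basis(gr, concomitant_model("full", 0.55))
  expect_equal(unname(b[1, c("p4", "p8", "p19")]), c(0.01, 0.06, 0.006))
  # r = 0 gives all zeros
  g0 <- spatial_grid(c(1, 1), 1, frame = "physical", coords = matrix(0, 1, 3))
  expect_true(all(evaluate_basis(g0, concomitant_model("full", 1)) == 0))
  # parity: even-degree columns invariant under r -> -r, odd-degree negate
  set.seed(33)
  co <- matrix(stats::rnorm(15), 5, 3)
  gp <- spatial_grid(c(5, 1), 1, frame = "physical", coords = co)
  gm <- spatial_grid(c(5, 1), 1, frame = "physical", coords = -co)
  mf <- concomitant_model("full", 1)
  bp <- evaluate_basis(gp, mf); bm <- evaluate_basis(gm, mf)
  deg <- rowSums(mf$basis_index[, c("a", "b", "c")])
  expect_equal(bm[, deg %% 2 == 0], bp[, deg %% 2 == 0])
  expect_equal(bm[, deg %% 2 == 1], -bp[, deg %% 2 == 1])
  # logical-frame grids are rejected
  expect_error(evaluate_basis(spatial_grid(c(4, 4), 0.2),
                              concomitant_model("lowest", 1)), "physical")
})

test_that("time-averaged field map reduces to closed forms", {
  geom <- scan_geometry(B0 = 0.55)
  grid <- fx_grid(16)
  gridP <- transform_to_physical(grid, geom)
  mf <- concomitant_model("lowest", 0.55)
  # constant gradients over [0, T]: map = (gamma / 2 pi) * sum h_l p_l, any T
  nk <- 11
  gs <- array(0, c(1, nk, 3)); gs[1, , 1] <- 0.015; gs[1, , 3] <- 0.008
  for (dt in c(1e-5, 4e-5)) {
    g <- gradient_set(gs, dt, frame = "physical")
    ph <- higher_order_phase(g, gridP, geom, mf)
    fc <- time_averaged_field_map(ph)
    h <- dynamic_coefficients(g, mf)[1, 1, ]
    expected <- geom$gamma / (2 * pi) *
      as.numeric(evaluate_basis(gridP, mf) %*% h)
    expect_equal(fc, expected, tolerance = 1e-9)
  }
  # all-zero coefficients give a zero map
  g0 <- gradient_set(array(0, c(1, nk, 3)), 1e-5, frame = "physical")
  expect_true(all(time_averaged_field_map(
    higher_order_phase(g0, gridP, geom, mf)) == 0))
  # axial slice with G_z == 0 at offset z0: spatially constant map
  geo_ax <- geom_axial(0.05)
  gridPax <- transform_to_physical(fx_grid(16), geo_ax)
  gax <- transform_to_physical(fx_spiral(16, 2), geo_ax)
  ph_ax <- higher_order_phase(gax, gridPax, geo_ax,
                              concomitant_model("lowest", 0.55))
  fc_ax <- time_averaged_field_map(ph_ax)
  expect_lt(diff(range(fc_ax)), 1e-9 * max(abs(fc_ax)))
  nk_ax <- dim(ph_ax$k_coeffs)[2]
  T_ax <- ph_ax$times_s[nk_ax]
  expect_equal(fc_ax[1],
               ph_ax$k_coeffs[1, nk_ax, 3] * 0.05^2 / (2 * pi * T_ax),
               tolerance = 1e-12)
})

test_that("cubic corrections vanish as 1 / B0 relative to quadratic terms", {
  g <- transform_to_physical(fx_spiral(16, 2), geom_sagittal(0.05))
  ratios <- vapply(c(0.55, 1.5, 3, 7), function(B0) {
    geo <- geom_sagittal(0.05, B0)
    gridP <- transform_to_physical(fx_grid(16), geo)
    ph_f <- higher_order_phase(g, gridP, geo, concomitant_model("full", B0))
    ph_l <- higher_order_phase(g, gridP, geo, concomitant_model("lowest", B0))
    pf <- maxgirf:::phase_matrix(ph_f, 1)
    pl <- maxgirf:::phase_matrix(ph_l, 1)
    frob(pf - pl) / frob(pl)
  }, numeric(1))
  expect_equal(ratios * c(0.55, 1.5, 3, 7), rep(ratios[1] * 0.55, 4),
               tolerance = 1e-6)
})
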