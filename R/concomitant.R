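#' Concomitant (Maxwell) field model for a symmetric gradient system
#'
#' Describes the higher-order terms of the magnetic field magnitude that
#' accompany linear gradients on a symmetric gradient coil. With
#' `B_x = G_x z - G_z x / 2` and `B_y = G_y z - G_z y / 2`, expanding
#' `|B|` around `B0` yields quadratic terms scaling as `G^2 / B0`
#' ("lowest" order, basis indices 4..9) and cubic terms scaling as
#' `G^3 / B0^2` ("full" order adds indices 10..19).
#'
#' @param order `"lowest"` (quadratic terms only) or `"full"` (adds cubic).
#' @param B0 main field, Tesla.
#' @return object of class `concomitant_model` with the monomial basis table
#'   (`basis_index`: rows of `(l, a, b, c)` meaning `x^a y^b z^c`).
#' @export
concomitant_model <- function(order = c("lowest", "full"), B0 = 0.55) {
  order <- match.arg(order)
  stopifnot(B0 > 0)
  tab <- rbind(
    c(4L, 2L, 0L, 0L),   # x^2
    c(5L, 0L, 2L, 0L),   # y^2
    c(6L, 0L, 0L, 2L),   # z^2
    c(7L, 1L, 1L, 0L),   # xy
    c(8L, 0L, 1L, 1L),   # yz
    c(9L, 1L, 0L, 1L),   # xz
    c(10L, 3L, 0L, 0L),  # x^3
    c(11L, 0L, 3L, 0L),  # y^3
    c(12L, 0L, 0L, 3L),  # z^3
    c(13L, 2L, 1L, 0L),  # x^2 y
    c(14L, 2L, 0L, 1L),  # x^2 z
    c(15L, 1L, 2L, 0L),  # x y^2
    c(16L, 0L, 2L, 1L),  # y^2 z
    c(17L, 1L, 0L, 2L),  # x z^2
    c(18L, 0L, 1L, 2L),  # y z^2
    c(19L, 1L, 1L, 1L))  # xyz
  colnames(tab) <- c("l", "a", "b", "c")
  if (order == "lowest") tab <- tab[tab[, "l"] <= 9L, , drop = FALSE]
  structure(list(order = order, B0 = B0, basis_index = tab),
            class = "concomitant_model")
}

#' @export
print.concomitant_model <- function(x, ...) {
  cat(sprintf("<concomitant_model> order = %s (%d terms), B0 = %g T\n",
              x$order, nrow(x$basis_index), x$B0))
  invisible(x)
}

#' Dynamic concomitant-field coefficients from gradient waveforms
#'
#' Evaluates the per-term coefficients `h_l(t)` (Tesla/m^2 for quadratic
#' terms, Tesla/m^3 for cubic terms) from physical-frame gradients. The
#' quadratic set is `h4 = h5 = Gz^2/(8 B0)`, `h6 = (Gx^2+Gy^2)/(2 B0)`,
#' `h7 = 0`, `h8 = -Gy Gz/(2 B0)`, `h9 = -Gx Gz/(2 B0)`; the cubic set
#' carries `1/B0^2` and follows from the next order of the `|B|` expansion.
#'
#' @param g a physical-frame [gradient_set()].
#' @param model a [concomitant_model()].
#' @return array `N_i x N_k x N_l` matching `model$basis_index` rows.
#' @export
dynamic_coefficients <- function(g, model) {
  stopifnot(inherits(g, "gradient_set"), inherits(model, "concomitant_model"))
  if (g$frame != "physical")
    stop("concomitant coefficients are defined on physical-frame gradients")
  d <- dim(g$samples)
  B0 <- model$B0
  nl <- nrow(model$basis_index)
  h <- array(0, c(d[1], d[2], nl))
  for (i in seq_len(d[1])) {
    gx <- g$samples[i, , 1]; gy <- g$samples[i, , 2]; gz <- g$samples[i, , 3]
    quad <- list(
      `4` = gz^2 / (8 * B0),
      `5` = gz^2 / (8 * B0),
      `6` = (gx^2 + gy^2) / (2 * B0),
      `7` = 0 * gz,
      `8` = -gy * gz / (2 * B0),
      `9` = -gx * gz / (2 * B0))
    cub <- list(
      `10` = -gx * gz^2 / (8 * B0^2),
      `11` = -gy * gz^2 / (8 * B0^2),
      `12` = -gz * (gx^2 + gy^2) / (2 * B0^2),
      `13` = -gy * gz^2 / (8 * B0^2),
      `14` = -(gz^3 / 4 - gx^2 * gz) / (2 * B0^2),
      `15` = -gx * gz^2 / (8 * B0^2),
      `16` = -(gz^3 / 4 - gy^2 * gz) / (2 * B0^2),
      `17` = -(gx * (gx^2 + gy^2) - gx * gz^2) / (2 * B0^2),
      `18` = -(gy * (gx^2 + gy^2) - gy * gz^2) / (2 * B0^2),
      `19` = gx * gy * gz / B0^2)
    all_h <- c(quad, cub)
    for (j in seq_len(nl)) {
      h[i, , j] <- all_h[[as.character(model$basis_index[j, "l"])]]
    }
  }
  h
}

#' Integrate dynamic coefficients to phase coefficients
#'
#' `k_l(t) = gamma * integral_{t0}^{t} h_l(tau) d tau` by cumulative
#' trapezoid, so `k_l(t0) = 0` at the phase reference.
#'
#' @param h array `N_i x N_k x N_l` from [dynamic_coefficients()].
#' @param times_s sample times (length `N_k`, increasing).
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @return array `N_i x N_k x N_l` of phase coefficients (rad/m^2 or rad/m^3).
#' @export
phase_coefficients <- function(h, times_s, gamma = 2 * pi * 42.5764e6) {
  d <- dim(h)
  if (length(times_s) != d[2]) stop("'times_s' must have N_k entries")
  if (d[2] > 1 && any(diff(times_s) <= 0)) stop("'times_s' must be increasing")
  k <- array(0, d)
  if (d[2] > 1) {
    for (i in seq_len(d[1])) for (j in seq_len(d[3])) {
      k[i, , j] <- gamma * pracma::cumtrapz(as.numeric(times_s), h[i, , j])
    }
  }
  k
}

#' Evaluate the concomitant spatial basis on a physical-frame grid
#'
#' Column `l` holds the monomial `x^a y^b z^c` of the model's basis table
#' at each voxel's physical coordinates (m^2 or m^3).
#'
#' @param grid_P a physical-frame [spatial_grid()].
#' @param model a [concomitant_model()].
#' @return matrix `N x N_l`.
#' @export
evaluate_basis <- function(grid_P, model) {
  stopifnot(inherits(grid_P, "spatial_grid"), inherits(model, "concomitant_model"))
  if (grid_P$frame != "physical")
    stop("concomitant basis functions are physical-frame quantities; ",
         "pass a grid transformed with transform_to_physical()")
  x <- grid_P$coords[, 1]; y <- grid_P$coords[, 2]; z <- grid_P$coords[, 3]
  tab <- model$basis_index
  out <- matrix(0, nrow(grid_P$coords), nrow(tab))
  for (j in seq_len(nrow(tab))) {
    out[, j] <- x^tab[j, "a"] * y^tab[j, "b"] * z^tab[j, "c"]
  }
  colnames(out) <- paste0("p", tab[, "l"])
  out
}

#' Assemble the higher-order phase description
#'
#' Bundles everything needed to evaluate the per-voxel phase
#' `phi~(r, t) = 2 pi deltaf(r) (t - t0) + sum_l k_l(t) p_l(r)` that the
#' higher-order encoding matrix exponentiates.
#'
#' @param g physical-frame [gradient_set()] (GIRF-predicted or nominal).
#' @param grid_P physical-frame [spatial_grid()].
#' @param geom [scan_geometry()].
#' @param model [concomitant_model()]; `NULL` disables concomitant terms.
#' @param deltaf_Hz optional length-N static off-resonance map (Hz).
#' @return object of class `higher_order_phase` with fields `k_coeffs`
#'   (`N_i x N_k x N_l`), `basis_values` (`N x N_l`), `deltaf_Hz`, `times_s`,
#'   `t0_s`.
#' @export
higher_order_phase <- function(g, grid_P, geom, model = NULL, deltaf_Hz = NULL) {
  stopifnot(inherits(g, "gradient_set"))
  d <- dim(g$samples)
  times <- g$t0_s + (seq_len(d[2]) - 1) * g$raster_s
  if (!is.null(model)) {
    h <- dynamic_coefficients(g, model)
    kc <- phase_coefficients(h, times, geom$gamma)
    bv <- evaluate_basis(grid_P, model)
  } else {
    kc <- array(0, c(d[1], d[2], 1L))
    bv <- matrix(0, nrow(grid_P$coords), 1L)
  }
  n <- nrow(grid_P$coords)
  if (!is.null(deltaf_Hz) && length(deltaf_Hz) != n)
    stop("'deltaf_Hz' must have one entry per voxel")
  structure(list(k_coeffs = kc, basis_values = bv,
                 deltaf_Hz = deltaf_Hz, times_s = times, t0_s = g$t0_s),
            class = "higher_order_phase")
}

# N_k x N phase matrix phi~ for one interleaf (radians)
phase_matrix <- function(phase, interleaf = 1L, voxels = NULL) {
  kc <- matrix(phase$k_coeffs[interleaf, , ], nrow = dim(phase$k_coeffs)[2])
  bv <- phase$basis_values
  if (!is.null(voxels)) bv <- bv[voxels, , drop = FALSE]
  ph <- kc %*% t(bv)
  if (!is.null(phase$deltaf_Hz)) {
    df <- phase$deltaf_Hz
    if (!is.null(voxels)) df <- df[voxels]
    ph <- ph + outer(2 * pi * (phase$times_s - phase$t0_s), df)
  }
  ph
}

#' Time-averaged concomitant field map for the first interleaf
#'
#' `f_c(r) = 1/(2 pi T) * sum_l k_l,1(T) p_l(r)` in Hz, where `T` is the
#' readout duration of interleaf 1 -- a static summary of the concomitant
#' phase accrued over the readout, comparable to a static off-resonance map.
#'
#' @param phase a [higher_order_phase()].
#' @param T_s readout duration; defaults to the last sample time minus `t0`.
#' @return length-N map in Hz.
#' @export
time_averaged_field_map <- function(phase, T_s = NULL) {
  stopifnot(inherits(phase, "higher_order_phase"))
  nk <- dim(phase$k_coeffs)[2]
  if (is.null(T_s)) T_s <- phase$times_s[nk] - phase$t0_s
  kT <- phase$k_coeffs[1L, nk, ]
  as.numeric(phase$basis_values %*% kT) / (2 * pi * T_s)
}
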