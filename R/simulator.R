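#' Default ellipse phantom specification
#'
#' A head-like arrangement of ellipses with complex amplitudes (a large
#' support ellipse, an inner "skull" rim, ventricle-like voids and a few
#' small features), all dimensions as fractions of the field of view.
#'
#' @param fov_m field of view (isotropic), meters.
#' @return data.frame with columns `x0, y0, a, b, angle_deg, amp_re, amp_im`
#'   (centers/axes in meters).
#' @export
default_phantom_spec <- function(fov_m = 0.24) {
  f <- fov_m
  d <- rbind(
    c( 0.00,  0.00, 0.40, 0.36,   0,  0.80, 0.00),
    c( 0.00,  0.00, 0.36, 0.32,   0,  0.20, 0.05),
    c(-0.10,  0.02, 0.07, 0.14,  20, -0.40, 0.00),
    c( 0.10,  0.02, 0.07, 0.14, -20, -0.40, 0.00),
    c( 0.00, -0.18, 0.08, 0.05,   0,  0.30, 0.10),
    c( 0.00,  0.16, 0.05, 0.04,   0,  0.45, 0.00),
    c(-0.16, -0.12, 0.04, 0.03,  30,  0.35, 0.00),
    c( 0.16, -0.12, 0.04, 0.03, -30,  0.35, 0.00))
  colnames(d) <- c("x0", "y0", "a", "b", "angle_deg", "amp_re", "amp_im")
  d <- as.data.frame(d)
  d[c("x0", "y0", "a", "b")] <- d[c("x0", "y0", "a", "b")] * f
  d
}

#' Rasterize an ellipse phantom on a grid
#'
#' Voxel-center evaluation: a voxel takes the sum of the complex amplitudes
#' of all ellipses containing its center.
#'
#' @param spec data.frame as from [default_phantom_spec()] (meters); an
#'   empty data.frame gives a zero image.
#' @param grid a [spatial_grid()] (logical frame; in-plane coords used).
#' @return complex length-N image.
#' @export
make_phantom <- function(spec, grid) {
  stopifnot(inherits(grid, "spatial_grid"))
  x <- grid$coords[, 1]; y <- grid$coords[, 2]
  img <- complex(length(x))
  if (nrow(spec) == 0L) return(img)
  for (e in seq_len(nrow(spec))) {
    th <- spec$angle_deg[e] * pi / 180
    xr <- (x - spec$x0[e]) * cos(th) + (y - spec$y0[e]) * sin(th)
    yr <- -(x - spec$x0[e]) * sin(th) + (y - spec$y0[e]) * cos(th)
    inside <- (xr / spec$a[e])^2 + (yr / spec$b[e])^2 <= 1
    img[inside] <- img[inside] + complex(real = spec$amp_re[e],
                                         imaginary = spec$amp_im[e])
  }
  img
}

#' Smooth synthetic coil sensitivity maps
#'
#' Gaussian sensitivity lobes centered on a circle around the FOV perimeter
#' with a mild per-coil linear phase; analytic in position, so maps are
#' consistent across grid resolutions. `n_coils = 1` returns a uniform map.
#'
#' @param n_coils number of receive coils (>= 1).
#' @param grid a [spatial_grid()].
#' @param rel_width Gaussian width as a fraction of the FOV.
#' @return a [coil_maps()] with `N x n_coils` complex maps; the
#'   sum-of-squares is positive everywhere.
#' @export
make_coilmaps <- function(n_coils, grid, rel_width = 0.6) {
  stopifnot(n_coils >= 1, inherits(grid, "spatial_grid"))
  n <- nrow(grid$coords)
  if (n_coils == 1L) return(coil_maps(matrix(1 + 0i, n, 1)))
  f <- max(grid$fov_m)
  x <- grid$coords[, 1]; y <- grid$coords[, 2]
  sig <- rel_width * f / 2
  maps <- vapply(seq_len(n_coils), function(c) {
    ang <- 2 * pi * (c - 1) / n_coils
    cx <- 0.5 * f * cos(ang); cy <- 0.5 * f * sin(ang)
    mag <- exp(-((x - cx)^2 + (y - cy)^2) / (2 * sig^2))
    ph <- 2 * pi * (0.3 * (x * cos(ang) + y * sin(ang)) / f) + ang / 2
    mag * exp(1i * ph)
  }, complex(n))
  coil_maps(maps + 0.05)     # small floor keeps sum-of-squares > 0 everywhere
}

#' Smooth synthetic static off-resonance map
#'
#' A smooth low-order field (two Gaussian lobes of opposite sign) scaled so
#' its absolute peak equals `peak_Hz`, optionally plus a constant
#' chemical-shift offset on a sharply bounded elliptical "fat" region
#' (default -88 Hz, the water/fat shift at 0.55 T).
#'
#' @param grid a [spatial_grid()].
#' @param peak_Hz peak of the smooth component, Hz (0 gives a zero map).
#' @param fat_region optional one-row data.frame `(x0, y0, a, b, angle_deg)`
#'   in meters describing the fat ellipse.
#' @param fat_shift_Hz chemical-shift offset added inside `fat_region`.
#' @return length-N map in Hz.
#' @export
make_offresonance <- function(grid, peak_Hz, fat_region = NULL,
                              fat_shift_Hz = -88) {
  stopifnot(inherits(grid, "spatial_grid"))
  x <- grid$coords[, 1]; y <- grid$coords[, 2]
  f <- max(grid$fov_m)
  raw <- exp(-((x - 0.12 * f)^2 + (y - 0.10 * f)^2) / (2 * (0.28 * f)^2)) -
         0.7 * exp(-((x + 0.15 * f)^2 + (y + 0.12 * f)^2) / (2 * (0.33 * f)^2))
  df <- if (peak_Hz == 0) 0 * raw else peak_Hz * raw / max(abs(raw))
  if (!is.null(fat_region)) {
    th <- fat_region$angle_deg[1] * pi / 180
    xr <- (x - fat_region$x0[1]) * cos(th) + (y - fat_region$y0[1]) * sin(th)
    yr <- -(x - fat_region$x0[1]) * sin(th) + (y - fat_region$y0[1]) * cos(th)
    inside <- (xr / fat_region$a[1])^2 + (yr / fat_region$b[1])^2 <= 1
    df[inside] <- df[inside] + fat_shift_Hz
  }
  df
}

#' Synthesize multi-coil spiral k-space data
#'
#' Direct (dense, row-blocked) evaluation of the forward signal model: for
#' each interleaf and coil,
#' `d(t) = sum_rho m(rho) S_c(rho) exp(-j [k_P(t).r_P(rho) + phi~(r_P, t)])`
#' where the physical k-space phase splits into the logical Fourier phase
#' plus the slice-offset modulation -- the returned data therefore carry
#' the off-isocenter modulation, exactly as acquired data would, and must
#' be passed through [demodulate_offset()] before reconstruction when the
#' slice offset is nonzero. Optional i.i.d. complex Gaussian noise.
#'
#' @param phantom complex length-N image on `grid_L`.
#' @param coils a [coil_maps()] on the same grid.
#' @param deltaf_Hz static off-resonance map (length N) or `NULL`.
#' @param geom a [scan_geometry()].
#' @param g logical- or physical-frame [gradient_set()] of the waveforms
#'   that actually play out (nominal or GIRF-predicted).
#' @param grid_L logical-frame [spatial_grid()].
#' @param model a [concomitant_model()] or `NULL` to disable concomitant
#'   fields.
#' @param noise `NULL` (noiseless) or `list(sigma =, seed =)`: complex
#'   Gaussian with standard deviation `sigma` per real/imaginary channel.
#' @param guard_n refuse grids larger than this many voxels (dense
#'   synthesis); raise with care.
#' @param block_rows time-block size for the row-blocked evaluation.
#' @return a [kspace_data()] (`N_i x N_c x N_k`).
#' @export
simulate_acquisition <- function(phantom, coils, deltaf_Hz, geom, g, grid_L,
                                 model = NULL, noise = NULL,
                                 guard_n = 128^2, block_rows = 256L) {
  stopifnot(inherits(coils, "coil_maps"), inherits(geom, "scan_geometry"),
            inherits(g, "gradient_set"), inherits(grid_L, "spatial_grid"))
  n <- nrow(grid_L$coords)
  if (n > guard_n)
    stop("grid larger than the dense-synthesis guard (", guard_n,
         " voxels); raise 'guard_n' explicitly if intended")
  if (length(phantom) != n) stop("phantom does not match the grid")
  if (grid_L$frame != "logical") stop("'grid_L' must be logical-frame")
  gL <- if (g$frame == "logical") g else transform_to_logical(g, geom)
  gP <- if (g$frame == "physical") g else transform_to_physical(g, geom)
  trL <- integrate_kspace(gL, geom)
  trP <- integrate_kspace(gP, geom)
  gridP <- transform_to_physical(grid_L, geom)
  phase <- higher_order_phase(gP, gridP, geom, model = model,
                              deltaf_Hz = deltaf_Hz)
  d <- dim(gL$samples)
  ni <- d[1]; nk <- d[2]; nc <- ncol(coils$maps)
  W <- coils$maps * as.complex(phantom)      # N x Nc
  rL <- grid_L$coords
  out <- array(0i, c(ni, nc, nk))
  times <- trL$times_s
  for (i in seq_len(ni)) {
    kLi <- matrix(trL$k[i, , ], ncol = 3L)
    kPi <- matrix(trP$k[i, , ], ncol = 3L)
    off_ph <- as.numeric(kPi %*% geom$offset)          # slice-offset phase
    kc <- matrix(phase$k_coeffs[i, , ], nrow = nk)
    for (s in seq(1L, nk, by = block_rows)) {
      e <- min(s + block_rows - 1L, nk)
      ph <- kLi[s:e, 1:2, drop = FALSE] %*% t(rL[, 1:2, drop = FALSE])
      ph <- ph + kc[s:e, , drop = FALSE] %*% t(phase$basis_values)
      if (!is.null(deltaf_Hz))
        ph <- ph + outer(2 * pi * (times[s:e] - g$t0_s), deltaf_Hz)
      ph <- ph + off_ph[s:e]                           # recycled by column
      out[i, , s:e] <- t(exp(-1i * ph) %*% W)
    }
  }
  if (!is.null(noise) && noise$sigma > 0) {
    if (!is.null(noise$seed)) set.seed(noise$seed)
    out <- out + noise$sigma *
      array(complex(real = stats::rnorm(length(out)),
                    imaginary = stats::rnorm(length(out))), dim(out))
  }
  kspace_data(out, dwell_s = g$raster_s,
              noise_sigma = if (is.null(noise)) NULL else noise$sigma)
}

#' Restrict an image to the spiral-accessible k-space disk
#'
#' A spiral readout samples a disk in k-space; image content in the square
#' grid's corner frequencies is invisible to the acquisition. This helper
#' zeroes spectral content outside the inscribed disk (radius
#' `frac * N/2` cycles across the FOV), giving ground-truth images whose
#' full content is recoverable -- used by exact-recovery tests to separate
#' solver error from coverage physics.
#'
#' @param img complex image (length-N vector or `N1 x N2` matrix).
#' @param shape grid `(N1, N2)` (even dimensions).
#' @param frac disk radius as a fraction of the grid Nyquist radius.
#' @return complex vector of the filtered image.
#' @export
bandlimit_disk <- function(img, shape, frac = 0.95) {
  m <- matrix(img, shape[1], shape[2])
  F <- fftshift2(stats::fft(ifftshift2(m)))
  k1 <- seq_len(shape[1]) - 1 - shape[1] %/% 2
  k2 <- seq_len(shape[2]) - 1 - shape[2] %/% 2
  rr <- sqrt(outer(k1^2, k2^2, `+`))
  F[rr > frac * min(shape) / 2] <- 0
  as.vector(fftshift2(stats::fft(ifftshift2(F), inverse = TRUE)) / prod(shape))
}
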