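#' Multi-coil k-space data container
#'
#' @param samples complex array `N_i x N_c x N_k` (interleaves, coils,
#'   readout samples). A single-interleaf `N_c x N_k` matrix is promoted.
#' @param dwell_s ADC dwell time, seconds.
#' @param noise_sigma optional per-sample complex-noise standard deviation.
#' @return object of class `kspace_data`.
#' @export
kspace_data <- function(samples, dwell_s, noise_sigma = NULL) {
  if (is.matrix(samples)) samples <- array(samples, c(1L, dim(samples)))
  d <- dim(samples)
  if (length(d) != 3L) stop("'samples' must be an N_i x N_c x N_k array")
  structure(list(samples = samples, dwell_s = dwell_s,
                 noise_sigma = noise_sigma),
            class = "kspace_data")
}

#' @export
print.kspace_data <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<kspace_data> %d interleaf(s) x %d coil(s) x %d samples, dwell %.3g us\n",
              d[1], d[2], d[3], 1e6 * x$dwell_s))
  invisible(x)
}

#' Receive coil sensitivity maps
#'
#' @param maps complex `N x N_c` matrix (one column per coil) or a list of
#'   length-N vectors.
#' @return object of class `coil_maps`.
#' @export
coil_maps <- function(maps) {
  if (is.list(maps)) maps <- do.call(cbind, maps)
  maps <- as.matrix(maps)
  if (ncol(maps) < 1L || !all(is.finite(abs(maps))))
    stop("'maps' must be a finite N x N_c complex matrix with >= 1 coil")
  structure(list(maps = maps), class = "coil_maps")
}

#' Dense higher-order encoding matrix H for one interleaf
#'
#' `H[t, rho] = exp(-j (2 pi deltaf(r_rho) (t - t0) + sum_l k_l(t) p_l(r_rho)))`
#' -- a unit-modulus phase matrix collecting static off-resonance and
#' concomitant-field phase.
#'
#' @param phase a [higher_order_phase()].
#' @param interleaf which interleaf.
#' @param guard refuse to materialize more than this many entries
#'   (default `2^26`); use the low-rank path beyond.
#' @return complex `N_k x N` matrix.
#' @export
build_dense_H <- function(phase, interleaf = 1L, guard = 2^26) {
  stopifnot(inherits(phase, "higher_order_phase"))
  nk <- dim(phase$k_coeffs)[2]
  n <- nrow(phase$basis_values)
  if (as.double(nk) * n > guard)
    stop("H would have ", nk, " x ", n, " entries (> guard); ",
         "use the low-rank operator mode instead")
  exp(-1i * phase_matrix(phase, interleaf))
}

# H %*% X (or H^H %*% Y) without materializing H, in voxel blocks
h_matmul <- function(phase, interleaf, X, adjoint = FALSE, block = 4096L) {
  nk <- dim(phase$k_coeffs)[2]
  n <- nrow(phase$basis_values)
  if (!is.matrix(X)) X <- matrix(X, ncol = 1L)
  if (adjoint) {
    stopifnot(nrow(X) == nk)
    out <- matrix(0i, n, ncol(X))
    for (s in seq(1L, n, by = block)) {
      e <- min(s + block - 1L, n)
      Hb <- exp(-1i * phase_matrix(phase, interleaf, voxels = s:e))
      out[s:e, ] <- Conj(t(Hb)) %*% X
    }
  } else {
    stopifnot(nrow(X) == n)
    out <- matrix(0i, nk, ncol(X))
    for (s in seq(1L, n, by = block)) {
      e <- min(s + block - 1L, n)
      Hb <- exp(-1i * phase_matrix(phase, interleaf, voxels = s:e))
      out <- out + Hb %*% X[s:e, , drop = FALSE]
    }
  }
  out
}

#' Build the per-interleaf encoding operator E = F (*) H
#'
#' `F` is the non-uniform Fourier matrix over the *logical*-frame trajectory
#' and grid; `H` is the higher-order phase matrix over *physical*-frame
#' quantities; `E` is their Hadamard product. The operator maps a length-N
#' image to `N_i x N_c x N_k` k-space data (forward) and back (adjoint, the
#' exact conjugate transpose).
#'
#' @param traj_L logical-frame [trajectory()].
#' @param grid_L logical-frame [spatial_grid()].
#' @param coils a [coil_maps()].
#' @param phase optional [higher_order_phase()]; `NULL` means `H == 1`
#'   (the operator degenerates to SENSE encoding).
#' @param mode `"dense"` materializes each `E_i` (small problems; exact);
#'   `"lowrank"` uses SVD factors of `H_i` and a fast Fourier path;
#'   `"auto"` picks dense when the guard allows it and `factors` is absent.
#' @param factors list of [lowrank_factors] (one per interleaf), required
#'   for `"lowrank"` unless `phase` is `NULL`.
#' @param L rank to use in low-rank mode (default: all columns in factors).
#' @param nufft_mode forwarded to [nufft_plan()].
#' @param guard dense-entry guard per interleaf.
#' @return object of class `encoding_operator`.
#' @export
encoding_operator <- function(traj_L, grid_L, coils, phase = NULL,
                              mode = c("auto", "dense", "lowrank"),
                              factors = NULL, L = NULL,
                              nufft_mode = "auto", guard = 2^26) {
  mode <- match.arg(mode)
  stopifnot(inherits(traj_L, "trajectory"), inherits(grid_L, "spatial_grid"),
            inherits(coils, "coil_maps"))
  if (traj_L$frame != "logical" || grid_L$frame != "logical")
    stop("F is built from the logical-frame trajectory and grid; got ",
         traj_L$frame, " trajectory / ", grid_L$frame, " grid")
  ni <- dim(traj_L$k)[1]; nk <- dim(traj_L$k)[2]
  n <- prod(grid_L$shape)
  if (nrow(coils$maps) != n) stop("coil maps do not match the grid")
  if (!is.null(phase)) {
    stopifnot(inherits(phase, "higher_order_phase"))
    if (nrow(phase$basis_values) != n)
      stop("higher-order phase does not match the grid")
    if (dim(phase$k_coeffs)[1] != ni || dim(phase$k_coeffs)[2] != nk)
      stop("higher-order phase does not match the trajectory")
  }
  if (mode == "auto") {
    mode <- if (!is.null(factors)) "lowrank"
            else if (as.double(nk) * n <= guard) "dense" else "lowrank"
  }
  # k in cycles across the FOV for the Fourier factor
  kc <- lapply(seq_len(ni), function(i)
    cbind(traj_L$k[i, , 1] * grid_L$fov_m[1],
          traj_L$k[i, , 2] * grid_L$fov_m[2]) / (2 * pi))
  op <- list(mode = mode, ni = ni, nk = nk, n = n, nc = ncol(coils$maps),
             shape = grid_L$shape, coils = coils, phase = phase)
  if (mode == "dense") {
    if (as.double(nk) * n > guard)
      stop("dense mode exceeds the entry guard; use lowrank mode")
    op$E <- lapply(seq_len(ni), function(i) {
      Fi <- nufft_plan(kc[[i]], grid_L$shape, mode = "dense")$F
      if (!is.null(phase)) Fi <- Fi * build_dense_H(phase, i, guard = guard)
      Fi
    })
  } else {
    op$plans <- lapply(kc, nufft_plan, shape = grid_L$shape, mode = nufft_mode)
    if (!is.null(phase)) {
      if (is.null(factors))
        stop("lowrank mode with a higher-order phase needs 'factors' ",
             "(see randomized_svd())")
      if (length(factors) != ni) stop("need one factor set per interleaf")
      Lmax <- min(vapply(factors, function(f) as.integer(f$L_max), 1L))
      if (is.null(L)) L <- Lmax
      if (L > Lmax) stop("requested rank exceeds the computed factors")
      op$factors <- factors
      op$L <- as.integer(L)
    }
  }
  class(op) <- "encoding_operator"
  op
}

#' @export
print.encoding_operator <- function(x, ...) {
  cat(sprintf("<encoding_operator> %s mode: %d interleaf(s) x %d coil(s), %d samples -> %d voxels%s%s\n",
              x$mode, x$ni, x$nc, x$nk, x$n,
              if (is.null(x$phase)) " (H == 1, SENSE model)" else "",
              if (!is.null(x$factors)) sprintf(", rank L = %d", x$L) else ""))
  invisible(x)
}

#' Forward encoding: image to multi-coil k-space
#'
#' `d[i, c, ] = E_i (S_c * m)`, noiseless and deterministic.
#'
#' @param op an [encoding_operator()].
#' @param m complex image vector (length N).
#' @return complex array `N_i x N_c x N_k`.
#' @export
forward <- function(op, m) UseMethod("forward")

#' Adjoint encoding: multi-coil k-space to image
#'
#' `sum_i sum_c S_c^H E_i^H d[i, c, ]` -- the conjugate-phase image when `d`
#' holds (density-compensated) measured data.
#'
#' @param op an [encoding_operator()].
#' @param d complex array `N_i x N_c x N_k` (a [kspace_data()] is accepted).
#' @return complex image vector (length N).
#' @export
adjoint <- function(op, d) UseMethod("adjoint")

#' @export
forward.encoding_operator <- function(op, m) {
  stopifnot(length(m) == op$n)
  m <- as.complex(m)
  S <- op$coils$maps
  out <- array(0i, c(op$ni, op$nc, op$nk))
  W <- S * m                                    # N x Nc, columns S_c * m
  for (i in seq_len(op$ni)) {
    if (op$mode == "dense") {
      out[i, , ] <- t(op$E[[i]] %*% W)
    } else if (is.null(op$phase)) {
      out[i, , ] <- t(nufft_forward(op$plans[[i]], W))
    } else {
      f <- op$factors[[i]]
      L <- op$L
      # columns: (conj(v_l) * S_c * m) for l = 1..L, c = 1..Nc
      X <- matrix(0i, op$n, L * op$nc)
      for (l in seq_len(L))
        X[, (l - 1) * op$nc + seq_len(op$nc)] <- Conj(f$V[, l]) * W
      Y <- nufft_forward(op$plans[[i]], X)      # N_k x (L*Nc)
      acc <- matrix(0i, op$nk, op$nc)
      for (l in seq_len(L))
        acc <- acc + f$U[, l] * Y[, (l - 1) * op$nc + seq_len(op$nc)]
      out[i, , ] <- t(acc)
    }
  }
  out
}

#' @export
adjoint.encoding_operator <- function(op, d) {
  if (inherits(d, "kspace_data")) d <- d$samples
  stopifnot(all(dim(d) == c(op$ni, op$nc, op$nk)))
  S <- op$coils$maps
  img <- numeric(op$n) + 0i
  for (i in seq_len(op$ni)) {
    Y <- t(matrix(d[i, , ], nrow = op$nc))      # N_k x Nc
    if (op$mode == "dense") {
      A <- Conj(crossprod(op$E[[i]], Conj(Y)))  # E^H Y, N x Nc
    } else if (is.null(op$phase)) {
      A <- nufft_adjoint(op$plans[[i]], Y)
    } else {
      f <- op$factors[[i]]
      L <- op$L
      X <- matrix(0i, op$nk, L * op$nc)
      for (l in seq_len(L))
        X[, (l - 1) * op$nc + seq_len(op$nc)] <- Conj(f$U[, l]) * Y
      Z <- nufft_adjoint(op$plans[[i]], X)      # N x (L*Nc)
      A <- matrix(0i, op$n, op$nc)
      for (l in seq_len(L))
        A <- A + f$V[, l] * Z[, (l - 1) * op$nc + seq_len(op$nc)]
    }
    img <- img + rowSums(Conj(S) * A)
  }
  img
}
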