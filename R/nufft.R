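# Non-uniform discrete Fourier transform between a Cartesian image grid and
# arbitrary 2-D k-space sample locations.
#
# Forward (type 2):  d(k) = sum_rho m(r_rho) exp(-j k . r_rho)
# Adjoint (type 1):  exact conjugate transpose of the forward map.
#
# Two execution modes:
#   dense -- the DFT matrix is materialized; exact, used for small grids and
#            as the oracle path.
#   grid  -- Kaiser-Bessel gridding with 2x oversampling and an FFT; the
#            interpolation is a precomputed real sparse matrix, so both
#            directions are exact transposes of each other by construction.

#' Plan a non-uniform Fourier transform
#'
#' @param k_cycles `N_k x 2` matrix of sample locations in cycles across the
#'   field of view (`k_rad_per_m * fov / (2*pi)`); the Nyquist box is
#'   `[-N/2, N/2)` per axis.
#' @param shape image grid `(N1, N2)`.
#' @param mode `"auto"` uses the dense DFT for grids up to 32 on a side and
#'   gridding beyond; `"dense"`/`"grid"` force a path.
#' @param width Kaiser-Bessel kernel width in oversampled grid samples.
#' @param os oversampling factor of the gridding path.
#' @return a plan object for [nufft_forward()] / [nufft_adjoint()].
#' @export
nufft_plan <- function(k_cycles, shape, mode = c("auto", "dense", "grid"),
                       width = 8L, os = 2L) {
  mode <- match.arg(mode)
  k_cycles <- as.matrix(k_cycles)
  stopifnot(ncol(k_cycles) == 2L, length(shape) == 2L)
  shape <- as.integer(shape)
  if (mode == "auto") mode <- if (max(shape) <= 32L) "dense" else "grid"
  if (mode == "grid" && any(shape %% 2L != 0L))
    stop("gridding mode requires even grid dimensions")
  n1 <- shape[1]; n2 <- shape[2]
  if (mode == "dense") {
    ax1 <- (seq_len(n1) - 1 - n1 %/% 2)
    ax2 <- (seq_len(n2) - 1 - n2 %/% 2)
    # N_k x N matrix, column-major voxel order (axis 1 fastest)
    ph <- outer(k_cycles[, 1] / n1, rep(ax1, times = n2)) +
          outer(k_cycles[, 2] / n2, rep(ax2, each = n1))
    F <- exp(-2i * pi * ph)
    return(structure(list(mode = "dense", shape = shape, F = F,
                          n_samples = nrow(k_cycles)),
                     class = "nufft_plan"))
  }
  J <- as.integer(width)
  beta <- pi * sqrt((J / os)^2 * (os - 0.5)^2 - 0.8)   # Beatty et al. choice
  ng1 <- os * n1; ng2 <- os * n2
  nk <- nrow(k_cycles)
  # sparse interpolation matrix: rows = samples, cols = oversampled grid
  j1 <- os * k_cycles[, 1]; j2 <- os * k_cycles[, 2]
  off <- seq_len(J) - 1L
  m1 <- outer(ceiling(j1 - J / 2), off, `+`)           # N_k x J integer grid idx
  m2 <- outer(ceiling(j2 - J / 2), off, `+`)
  w1 <- kb_kernel(m1 - j1, J, beta)
  w2 <- kb_kernel(m2 - j2, J, beta)
  i1 <- ((m1 + ng1 %/% 2) %% ng1)                      # wrap, 0-based
  i2 <- ((m2 + ng2 %/% 2) %% ng2)
  rows <- rep(seq_len(nk), times = J * J)
  cols <- integer(nk * J * J); vals <- numeric(nk * J * J)
  idx <- 1L
  for (b in seq_len(J)) for (a in seq_len(J)) {
    sl <- seq.int(idx, idx + nk - 1L)
    cols[sl] <- i1[, a] + ng1 * i2[, b] + 1L
    vals[sl] <- w1[, a] * w2[, b]
    idx <- idx + nk
  }
  P <- Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                            dims = c(nk, ng1 * ng2))
  apod <- outer(kb_apod(n1, ng1, J, beta), kb_apod(n2, ng2, J, beta))
  structure(list(mode = "grid", shape = shape, os = os, J = J, beta = beta,
                 ng = c(ng1, ng2), P = P, apod = apod, n_samples = nk),
            class = "nufft_plan")
}

kb_kernel <- function(x, J, beta) {
  t <- 1 - (2 * x / J)^2
  out <- numeric(length(t))
  ok <- t > 0
  out[ok] <- besselI(beta * sqrt(t[ok]), 0) / besselI(beta, 0)
  dim(out) <- dim(x)
  out
}

# continuous Fourier transform of the (normalized) KB kernel at image
# positions n/Ng; used as the deapodization weight
kb_apod <- function(n, ng, J, beta) {
  nu <- (seq_len(n) - 1 - n %/% 2) / ng
  arg <- beta^2 - (pi * J * nu)^2
  s <- sqrt(abs(arg))
  w <- ifelse(arg > 0, sinh(s) / s, sin(s) / s)
  J * w / besselI(beta, 0)
}

fftshift2 <- function(m) {
  d <- dim(m)
  m[c((d[1] %/% 2 + 1):d[1], 1:(d[1] %/% 2)),
    c((d[2] %/% 2 + 1):d[2], 1:(d[2] %/% 2))]
}
ifftshift2 <- fftshift2   # even dimensions only; shifts are involutions

sparse_cmult <- function(P, z, adjoint = FALSE) {
  if (adjoint) {
    out <- Matrix::crossprod(P, cbind(Re(z), Im(z)))
    complex(real = out[, 1], imaginary = out[, 2])
  } else {
    out <- P %*% cbind(Re(z), Im(z))
    complex(real = out[, 1], imaginary = out[, 2])
  }
}

#' Apply the forward (image to k-space) non-uniform transform
#'
#' @param plan a [nufft_plan()].
#' @param img complex image: length-N vector or `N1 x N2` matrix, or a
#'   matrix with N rows to transform several images at once.
#' @return complex `N_k` vector (or `N_k x ncol` matrix for batched input).
#' @export
nufft_forward <- function(plan, img) {
  n <- prod(plan$shape)
  if (is.matrix(img) && all(dim(img) == plan$shape)) img <- as.vector(img)
  if (!is.matrix(img)) img <- matrix(img, ncol = 1L)
  stopifnot(nrow(img) == n)
  if (plan$mode == "dense") return(drop(plan$F %*% img))
  out <- matrix(0i, plan$n_samples, ncol(img))
  for (j in seq_len(ncol(img))) {
    x <- matrix(img[, j], plan$shape[1], plan$shape[2]) / plan$apod
    big <- matrix(0i, plan$ng[1], plan$ng[2])
    r1 <- (plan$ng[1] - plan$shape[1]) %/% 2 + seq_len(plan$shape[1])
    r2 <- (plan$ng[2] - plan$shape[2]) %/% 2 + seq_len(plan$shape[2])
    big[r1, r2] <- x
    D <- fftshift2(stats::fft(ifftshift2(big)))
    out[, j] <- sparse_cmult(plan$P, as.vector(D))
  }
  drop(out)
}

#' Apply the adjoint (k-space to image) non-uniform transform
#'
#' Exact conjugate transpose of [nufft_forward()].
#'
#' @param plan a [nufft_plan()].
#' @param d complex length-`N_k` vector (or `N_k x ncol` matrix).
#' @return complex length-N vector (or `N x ncol` matrix).
#' @export
nufft_adjoint <- function(plan, d) {
  if (!is.matrix(d)) d <- matrix(d, ncol = 1L)
  stopifnot(nrow(d) == plan$n_samples)
  if (plan$mode == "dense") return(drop(Conj(t(plan$F)) %*% d))
  n <- prod(plan$shape)
  out <- matrix(0i, n, ncol(d))
  r1 <- (plan$ng[1] - plan$shape[1]) %/% 2 + seq_len(plan$shape[1])
  r2 <- (plan$ng[2] - plan$shape[2]) %/% 2 + seq_len(plan$shape[2])
  for (j in seq_len(ncol(d))) {
    g <- matrix(sparse_cmult(plan$P, d[, j], adjoint = TRUE),
                plan$ng[1], plan$ng[2])
    X <- fftshift2(stats::fft(ifftshift2(g), inverse = TRUE))
    out[, j] <- as.vector(X[r1, r2] / plan$apod)
  }
  drop(out)
}
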