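#' Multi-echo coil-combined image data
#'
#' @param echoes complex `N x N_e` matrix (one column per echo) or list of
#'   length-N vectors.
#' @param TE_s echo times, seconds, strictly increasing, `N_e >= 2`.
#' @param shape image grid `(N1, N2)` (needed by the spectral
#'   preconditioner).
#' @return object of class `multi_echo_data`.
#' @export
multi_echo_data <- function(echoes, TE_s, shape) {
  if (is.list(echoes)) echoes <- do.call(cbind, echoes)
  echoes <- as.matrix(echoes)
  if (length(TE_s) < 2L) stop("need at least two echoes")
  if (any(diff(TE_s) <= 0)) stop("'TE_s' must be strictly increasing")
  if (ncol(echoes) != length(TE_s)) stop("one echo column per TE required")
  shape <- as.integer(shape)
  if (prod(shape) != nrow(echoes)) stop("'shape' does not match echo length")
  structure(list(echoes = echoes, TE_s = as.numeric(TE_s), shape = shape),
            class = "multi_echo_data")
}

#' Multi-echo forward signal model
#'
#' `F_m = rho * exp(j 2 pi deltaf TE_m)` elementwise; the magnitude of every
#' echo equals `|rho|` (phase-only evolution).
#'
#' @param rho complex content (water + fat), length N.
#' @param deltaf_Hz off-resonance map, Hz (B0 inhomogeneity plus chemical
#'   shift; the model does not separate water/fat).
#' @param TE_s echo times, seconds.
#' @return complex `N x N_e` matrix.
#' @export
forward_echo_model <- function(rho, deltaf_Hz, TE_s) {
  vapply(TE_s, function(te) rho * exp(2i * pi * deltaf_Hz * te),
         complex(length(rho)))
}

#' Sobolev-norm spectral filter
#'
#' Multiplies the image's spatial-frequency content by
#' `(1 + w ||k||^2)^(-h)` (`direction = "forward"`) or its reciprocal
#' (`"inverse"`), with `k` the normalized Cartesian frequencies in
#' `[-0.5, 0.5]^2`. Used as the preconditioner that confines the estimated
#' off-resonance map to smooth spatial variations.
#'
#' @param vec complex or real length-N image vector.
#' @param shape grid `(N1, N2)`.
#' @param w,h Sobolev constants (defaults 32 and 16).
#' @param direction `"forward"` applies the smoothing weight, `"inverse"`
#'   removes it.
#' @return filtered vector (real input stays real up to round-off).
#' @export
apply_sobolev <- function(vec, shape, w = 32, h = 16,
                          direction = c("forward", "inverse")) {
  direction <- match.arg(direction)
  was_real <- is.numeric(vec)
  m <- matrix(vec, shape[1], shape[2])
  k1 <- (seq_len(shape[1]) - 1 - shape[1] %/% 2) / shape[1]
  k2 <- (seq_len(shape[2]) - 1 - shape[2] %/% 2) / shape[2]
  wt <- (1 + w * outer(k1^2, k2^2, `+`))^(if (direction == "forward") -h else h)
  M <- fftshift2(stats::fft(ifftshift2(m)))
  out <- fftshift2(stats::fft(ifftshift2(M * wt), inverse = TRUE)) / prod(shape)
  out <- as.vector(out)
  if (was_real) Re(out) else out
}

#' Estimate a smooth static off-resonance map from multi-echo images
#'
#' Iteratively regularized Gauss-Newton on the model
#' `y_m = rho * exp(j 2 pi deltaf TE_m)` over preconditioned variables
#' `x = W xhat` -- identity on `rho`, Sobolev weight
#' `(1 + w ||k||^2)^(-h)` on the off-resonance channel -- minimizing
#' `||y - G(xhat)||^2 + alpha ||xhat - xhat0||^2` with `alpha` halved each
#' iteration and floored at `alpha_min`. Inner linearized problems are
#' solved with LSQR. The estimated map absorbs the water/fat chemical shift
#' (e.g. -88 Hz at 0.55 T) rather than separating it.
#'
#' @param data a [multi_echo_data()].
#' @param w,h Sobolev constants (defaults 32, 16).
#' @param alpha_min regularization floor (default 1e-6).
#' @param gn_iters Gauss-Newton iterations (default 35).
#' @param inner_iters,inner_tol LSQR controls (defaults 250, 1e-10).
#' @return object of class `fieldmap_fit`: complex content `rho`, map
#'   `deltaf_Hz` (Hz), `alpha_history`, data-residual `resid_history`,
#'   parameters, and convergence info.
#' @export
estimate_fieldmap <- function(data, w = 32, h = 16, alpha_min = 1e-6,
                              gn_iters = 35L, inner_iters = 250L,
                              inner_tol = 1e-10) {
  stopifnot(inherits(data, "multi_echo_data"))
  y <- data$echoes
  TE <- data$TE_s
  shape <- data$shape
  n <- nrow(y); ne <- ncol(y)
  # fix the data scale so the dimensional regularization floor alpha_min is
  # meaningful regardless of input units (the nonlinear-inversion lineage's
  # convention: normalize ||y|| to 100); undone on the returned rho
  yscale <- 100 / sqrt(sum(Mod(y)^2))
  y <- y * yscale
  W <- function(v) apply_sobolev(v, shape, w, h, "forward")
  # preconditioned unknowns: xhat = (rho complex, fhat real); deltaf = W fhat
  rho <- y[, 1]
  fhat <- numeric(n)
  rho0 <- rho; fhat0 <- fhat
  pack <- function(drho, dfhat) c(Re(drho), Im(drho), dfhat)
  unpack <- function(v) list(drho = complex(real = v[seq_len(n)],
                                            imaginary = v[n + seq_len(n)]),
                             dfhat = v[2 * n + seq_len(n)])
  resid_hist <- numeric(0); alpha_hist <- numeric(0)
  best <- list(rho = rho, fhat = fhat, resid = Inf)
  bad_steps <- 0L
  for (it in seq_len(gn_iters)) {
    alpha <- max(2^(-(it - 1)), alpha_min)
    deltaf <- W(fhat)
    E <- vapply(TE, function(te) exp(2i * pi * deltaf * te), complex(n))
    Fm <- rho * E
    r <- y - Fm
    resid <- sqrt(sum(Mod(r)^2))
    resid_hist <- c(resid_hist, resid); alpha_hist <- c(alpha_hist, alpha)
    if (resid < best$resid) {
      best <- list(rho = rho, fhat = fhat, resid = resid)
      bad_steps <- 0L
    } else {
      bad_steps <- bad_steps + 1L
      if (bad_steps >= 3L) break
    }
    sa <- sqrt(alpha)
    # J [drho, dfhat] = E drho + (2i pi TE) rho E (W dfhat), per echo
    aprod <- function(v) {
      p <- unpack(v)
      wdf <- W(p$dfhat)
      out <- vapply(seq_len(ne), function(m)
        E[, m] * p$drho + (2i * pi * TE[m]) * rho * E[, m] * wdf,
        complex(n))
      c(Re(out), Im(out), sa * v)
    }
    atprod <- function(u) {
      z <- matrix(complex(real = u[seq_len(n * ne)],
                          imaginary = u[n * ne + seq_len(n * ne)]), n, ne)
      reg <- u[2 * n * ne + seq_len(3 * n)]
      drho <- rowSums(Conj(E) * z)
      g <- rowSums(vapply(seq_len(ne), function(m)
        Re(Conj(2i * pi * TE[m] * rho * E[, m]) * z[, m]), numeric(n)))
      pack(drho, W(g)) + sa * reg
    }
    rhs <- c(Re(r), Im(r), -sa * pack(rho - rho0, fhat - fhat0))
    sol <- lsqr_solve(aprod, atprod, rhs, max_iter = inner_iters,
                      tol = inner_tol)
    step <- unpack(sol$x)
    rho <- rho + step$drho
    fhat <- fhat + step$dfhat
  }
  # final evaluation; keep the best iterate if the last one diverged
  deltaf <- W(fhat)
  resid <- sqrt(sum(Mod(y - rho * vapply(TE, function(te)
    exp(2i * pi * deltaf * te), complex(n)))^2))
  if (resid > best$resid) {
    rho <- best$rho; fhat <- best$fhat
    deltaf <- W(fhat)
  }
  structure(list(rho = rho / yscale, deltaf_Hz = Re(deltaf), shape = shape,
                 w = w, h = h, alpha_min = alpha_min,
                 alpha_history = alpha_hist, resid_history = resid_hist,
                 iterations = length(resid_hist)),
            class = "fieldmap_fit")
}

#' @export
print.fieldmap_fit <- function(x, ...) {
  cat(sprintf("<fieldmap_fit> %d x %d, deltaf in [%.1f, %.1f] Hz, %d GN iteration(s)\n",
              x$shape[1], x$shape[2], min(x$deltaf_Hz), max(x$deltaf_Hz),
              x$iterations))
  invisible(x)
}

#' @export
summary.fieldmap_fit <- function(object, ...) {
  print(object)
  cat(sprintf("Sobolev w = %g, h = %g, alpha floor %g\n",
              object$w, object$h, object$alpha_min))
  cat(sprintf("Data residual: %.4g -> %.4g\n",
              object$resid_history[1], utils::tail(object$resid_history, 1)))
  invisible(object)
}

#' @export
plot.fieldmap_fit <- function(x, ...) {
  m <- matrix(x$deltaf_Hz, x$shape[1], x$shape[2])
  graphics::image(m, asp = x$shape[2] / x$shape[1], axes = FALSE,
                  col = grDevices::hcl.colors(256, "RdBu"), ...)
  invisible(x)
}
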