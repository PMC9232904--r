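#' Normalized root-mean-square error between complex images
#'
#' `||ref - test||_2 / ||ref||_2` on the complex values, optionally
#' restricted to a mask and optionally after fitting a single global
#' complex scale to `test` (useful when comparing reconstructions whose
#' absolute intensity is defined only up to scale, e.g. conjugate-phase
#' or adjoint-NUFFT images).
#'
#' @param ref reference image (not all-zero).
#' @param test image under test, same length.
#' @param mask optional logical mask.
#' @param scale `"none"` (default) or `"global"` (least-squares complex
#'   scalar fit of `test` to `ref` before the error).
#' @return scalar NRMSE.
#' @export
nrmse <- function(ref, test, mask = NULL, scale = c("none", "global")) {
  scale <- match.arg(scale)
  if (length(ref) != length(test)) stop("'ref' and 'test' must have equal length")
  if (!is.null(mask)) { ref <- ref[mask]; test <- test[mask] }
  nref <- sqrt(sum(Mod(ref)^2))
  if (nref == 0) stop("zero reference image")
  if (scale == "global") {
    a <- sum(Conj(test) * ref) / sum(Mod(test)^2)
    test <- a * test
  }
  sqrt(sum(Mod(ref - test)^2)) / nref
}

#' Density-compensation weights for a 2-D readout
#'
#' For spiral-like (radially monotone) readouts uses the analytic Jacobian
#' `w ~ |k| * d|k|/dt`; for arbitrary trajectories falls back to a local
#' k-space occupancy estimate on Nyquist-sized cells. Weights are positive
#' and normalized to unit mean.
#'
#' @param traj a [trajectory()] (first interleaf's weights are returned;
#'   rotated interleaves share them).
#' @param fov_m field of view (needed for the occupancy fallback's cell
#'   size).
#' @param method `"auto"`, `"jacobian"` or `"cells"`.
#' @return positive length-`N_k` weights with mean 1.
#' @export
density_weights <- function(traj, fov_m = NULL,
                            method = c("auto", "jacobian", "cells")) {
  method <- match.arg(method)
  stopifnot(inherits(traj, "trajectory"))
  k <- matrix(traj$k[1, , 1:2], ncol = 2L)
  r <- sqrt(rowSums(k^2))
  if (max(r) == 0) stop("degenerate (all-zero) trajectory")
  if (method == "auto") {
    drh <- diff(r)
    method <- if (mean(drh >= -1e-9 * max(r)) > 0.99) "jacobian" else "cells"
  }
  if (method == "jacobian") {
    t <- traj$times_s
    drdt <- c(diff(r) / diff(t), 0)
    drdt[length(drdt)] <- drdt[length(drdt) - 1]
    w <- r * abs(drdt)
    w <- pmax(w, max(w) * 1e-6)          # strictly positive (k = 0 sample)
  } else {
    if (is.null(fov_m)) stop("'fov_m' is required for the cell-occupancy method")
    cell <- 2 * pi / fov_m[1]
    kk <- matrix(traj$k[, , 1:2], ncol = 2L)   # all interleaves
    ix <- round(kk[, 1] / cell); iy <- round(kk[, 2] / cell)
    key <- paste(ix, iy)
    cnt <- table(key)
    k1 <- paste(round(k[, 1] / cell), round(k[, 2] / cell))
    w <- 1 / as.numeric(cnt[k1])
  }
  w / mean(w)
}

#' Reconstruct an image from non-Cartesian multi-coil data
#'
#' The single entry point for image reconstruction under the higher-order
#' encoding model `d_{i,c} = E_i S_c m`, with `E_i = F_i (*) H_i`.
#'
#' * `method = "lsq"`: iterative least squares
#'   `argmin_m sum_i sum_c || d_{i,c} - E_i S_c m ||^2` via LSQR
#'   (defaults: 15 iterations, tolerance 1e-5 on the relative normal-
#'   equations residual).
#' * `method = "cp"`: non-iterative conjugate-phase image
#'   `sum_i sum_c S_c^H E_i^H (dcf * d_{i,c})`; needs density weights and is
#'   defined up to a global scale.
#'
#' When the operator carries no higher-order phase (`H == 1`) the model
#' degenerates to (CG-)SENSE; with a single uniform coil and `"cp"` it is a
#' plain density-compensated adjoint-NUFFT reconstruction.
#'
#' @param op an [encoding_operator()].
#' @param data a [kspace_data()] (or bare `N_i x N_c x N_k` array).
#' @param method `"lsq"` or `"cp"`.
#' @param dcf density-compensation weights for `"cp"` (length `N_k`,
#'   positive); computed from `traj` via [density_weights()] by callers that
#'   have one.
#' @param weights optional positive length-`N_k` sample weights for `"lsq"`:
#'   the solver then minimizes `sum || sqrt(w) (d - E S m) ||^2`. With
#'   density weights this is the usual left preconditioner for non-Cartesian
#'   least squares -- for consistent data the minimizer is unchanged and
#'   convergence is much faster.
#' @param max_iter,tol LSQR controls for `"lsq"`.
#' @return object of class `maxgirf_recon` with the complex `image`, the
#'   grid `shape`, `method`, rank `L` (if low-rank), `iterations` and the
#'   LSQR `residuals` history.
#' @export
maxgirf_recon <- function(op, data, method = c("lsq", "cp"), dcf = NULL,
                          weights = NULL, max_iter = 15L, tol = 1e-5) {
  method <- match.arg(method)
  stopifnot(inherits(op, "encoding_operator"))
  d <- if (inherits(data, "kspace_data")) data$samples else data
  stopifnot(all(dim(d) == c(op$ni, op$nc, op$nk)))
  if (method == "cp") {
    if (is.null(dcf)) dcf <- rep(1, op$nk)
    if (length(dcf) != op$nk || any(dcf <= 0))
      stop("'dcf' must be positive and of length N_k")
    dw <- d
    for (i in seq_len(op$ni))
      dw[i, , ] <- sweep(matrix(dw[i, , ], nrow = op$nc), 2L, dcf, `*`)
    img <- adjoint(op, dw)
    res <- list(image = img, shape = op$shape, method = "cp",
                L = op$L, iterations = 0L, residuals = numeric(0),
                converged = TRUE)
  } else {
    if (!is.null(weights)) {
      if (length(weights) != op$nk || any(weights <= 0))
        stop("'weights' must be positive and of length N_k")
      sw <- array(rep(sqrt(weights), each = op$ni * op$nc),
                  c(op$ni, op$nc, op$nk))
      b <- as.vector(d * sw)
      aprod <- function(x) as.vector(forward(op, x) * sw)
      atprod <- function(y) adjoint(op, array(y, c(op$ni, op$nc, op$nk)) * sw)
    } else {
      b <- as.vector(d)
      aprod <- function(x) as.vector(forward(op, x))
      atprod <- function(y) adjoint(op, array(y, c(op$ni, op$nc, op$nk)))
    }
    sol <- lsqr_solve(aprod, atprod, b, max_iter = max_iter, tol = tol)
    res <- list(image = sol$x, shape = op$shape, method = "lsq",
                L = op$L, iterations = sol$iterations,
                residuals = sol$residuals, converged = sol$converged)
  }
  res$op <- op
  class(res) <- "maxgirf_recon"
  res
}

#' @export
print.maxgirf_recon <- function(x, ...) {
  cat(sprintf("<maxgirf_recon> %s, %d x %d image%s%s\n",
              switch(x$method, lsq = "iterative least squares (LSQR)",
                     cp = "conjugate phase"),
              x$shape[1], x$shape[2],
              if (!is.null(x$L)) sprintf(", rank L = %d", x$L) else "",
              if (x$method == "lsq")
                sprintf(", %d iteration(s)%s", x$iterations,
                        if (x$converged) "" else " (max_iter reached)")
              else ""))
  invisible(x)
}

#' @export
summary.maxgirf_recon <- function(object, ...) {
  cat(sprintf("Reconstruction: %s\n", object$method))
  cat(sprintf("Image: %d x %d, |m| in [%.3g, %.3g]\n",
              object$shape[1], object$shape[2],
              min(Mod(object$image)), max(Mod(object$image))))
  if (object$method == "lsq" && length(object$residuals)) {
    cat(sprintf("LSQR: %d iterations, residual %.3g -> %.3g (%s)\n",
                object$iterations, object$residuals[1],
                utils::tail(object$residuals, 1),
                if (object$converged) "converged" else "max_iter reached"))
  }
  if (!is.null(object$L)) cat(sprintf("Low-rank operator, L = %d\n", object$L))
  invisible(object)
}

#' @export
plot.maxgirf_recon <- function(x, what = c("magnitude", "phase"), ...) {
  what <- match.arg(what)
  m <- matrix(if (what == "magnitude") Mod(x$image) else Arg(x$image),
              x$shape[1], x$shape[2])
  graphics::image(m, asp = x$shape[2] / x$shape[1], axes = FALSE,
                  col = grDevices::gray.colors(256, 0, 1), ...)
  invisible(x)
}

#' @export
coef.maxgirf_recon <- function(object, ...) object$image

#' @export
fitted.maxgirf_recon <- function(object, ...) forward(object$op, object$image)

#' @export
residuals.maxgirf_recon <- function(object, data = NULL, ...) {
  if (is.null(data)) return(object$residuals)
  d <- if (inherits(data, "kspace_data")) data$samples else data
  d - fitted(object)
}
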