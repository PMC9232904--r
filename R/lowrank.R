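#' Randomized SVD of a (possibly implicit) higher-order encoding matrix
#'
#' Range-finder randomized SVD with Gaussian test vectors, subspace
#' (power) iteration with re-orthonormalization, and an exact SVD of the
#' small projected matrix. `H` may be a dense complex matrix or an implicit
#' operator `list(mul = function(X) H %*% X, hmul = function(Y) H^H %*% Y,
#' nrow =, ncol =)` so `H` never needs to be materialized (row-block
#' evaluation keeps memory bounded; see [higher_order_phase()]).
#'
#' When the sketch size `L_max + oversample` reaches `min(nrow, ncol)` the
#' range finder spans the whole column space and the decomposition is exact
#' (up to round-off) regardless of the spectrum.
#'
#' @param H dense complex matrix or implicit-operator list.
#' @param L_max number of singular triplets to keep (`<= min(dim)`).
#' @param oversample extra sketch columns beyond `L_max`.
#' @param n_power_iter subspace iterations (>= 1 recommended for slowly
#'   decaying spectra).
#' @param seed RNG seed for the Gaussian sketch (required, reproducibility).
#' @return object of class `lowrank_factors`: `U` (`N_k x L_max`, orthonormal
#'   temporal basis), `sigma` (non-increasing singular values), `V`
#'   (`N x L_max` spatial basis with singular values absorbed:
#'   `v_l = sigma_l * vtilde_l`), `L`, `L_max`.
#' @export
randomized_svd <- function(H, L_max, oversample = 10L, n_power_iter = 2L, seed) {
  if (missing(seed) || is.null(seed))
    stop("'seed' is required for a reproducible sketch")
  if (is.matrix(H)) {
    nr <- nrow(H); nc <- ncol(H)
    mul <- function(X) H %*% X
    hmul <- function(Y) Conj(crossprod(H, Conj(Y)))
  } else {
    nr <- H$nrow; nc <- H$ncol
    mul <- H$mul; hmul <- H$hmul
  }
  if (L_max > min(nr, nc)) stop("'L_max' exceeds min(dim(H))")
  p <- min(L_max + oversample, min(nr, nc))
  set.seed(seed)
  omega <- matrix(complex(real = stats::rnorm(nc * p),
                          imaginary = stats::rnorm(nc * p)), nc, p)
  Y <- mul(omega)
  for (q in seq_len(n_power_iter)) {
    Y <- qr.Q(qr(Y, LAPACK = TRUE))
    Z <- hmul(Y)
    Z <- qr.Q(qr(Z, LAPACK = TRUE))
    Y <- mul(Z)
  }
  Q <- qr.Q(qr(Y, LAPACK = TRUE))              # N_k x p orthonormal
  B <- Conj(t(hmul(Q)))                        # p x N (Q^H H)
  sv <- La.svd(B, nu = p, nv = min(dim(B)))
  keep <- seq_len(L_max)
  U <- Q %*% sv$u[, keep, drop = FALSE]
  sigma <- sv$d[keep]
  Vt <- Conj(t(sv$vt))[, keep, drop = FALSE]   # N x L_max, right vectors
  V <- sweep(Vt, 2L, sigma, `*`)
  structure(list(U = U, sigma = sigma, V = V,
                 L = as.integer(L_max), L_max = as.integer(L_max)),
            class = "lowrank_factors")
}

#' @export
print.lowrank_factors <- function(x, ...) {
  cat(sprintf("<lowrank_factors> L_max = %d, sigma in [%.3g, %.3g]\n",
              x$L_max, min(x$sigma), max(x$sigma)))
  invisible(x)
}

#' SVD factors of the higher-order phase matrices for all interleaves
#'
#' Convenience wrapper running [randomized_svd()] on each interleaf's `H`
#' without materializing it (unless small).
#'
#' @param phase a [higher_order_phase()].
#' @param L_max singular triplets to compute per interleaf.
#' @param seed RNG seed (interleaf `i` uses `seed + i - 1`).
#' @inheritParams randomized_svd
#' @return list of [lowrank_factors] of length `N_i`.
#' @export
svd_higher_order <- function(phase, L_max, oversample = 10L,
                             n_power_iter = 2L, seed = 1L) {
  ni <- dim(phase$k_coeffs)[1]
  nk <- dim(phase$k_coeffs)[2]
  n <- nrow(phase$basis_values)
  lapply(seq_len(ni), function(i) {
    Hop <- list(
      mul = function(X) h_matmul(phase, i, X, adjoint = FALSE),
      hmul = function(Y) h_matmul(phase, i, Y, adjoint = TRUE),
      nrow = nk, ncol = n)
    randomized_svd(Hop, L_max, oversample, n_power_iter, seed = seed + i - 1L)
  })
}

#' Frobenius error of rank-L truncation
#'
#' By the Eckart-Young theorem the best rank-L approximation error equals
#' the root-sum-square of the discarded singular values:
#' `sqrt(sigma_{L+1}^2 + ... + sigma_{L_max}^2)`.
#'
#' @param factors a [lowrank_factors] object.
#' @param L truncation rank (`<= L_max`).
#' @return Frobenius-norm error against the rank-`L_max` representation.
#' @export
truncation_error <- function(factors, L) {
  stopifnot(inherits(factors, "lowrank_factors"), L <= factors$L_max, L >= 0)
  if (L == factors$L_max) return(0)
  sqrt(sum(factors$sigma[(L + 1):factors$L_max]^2))
}

# Per-rank conjugate-phase contribution images:
# contrib[, l] = sum_i sum_c S_c^H diag(v_l,i) F_i^H diag(conj(u_l,i)) (dcf * d_i,c)
# so the rank-L conjugate-phase image is rowSums(contrib[, 1:L]).
cp_rank_contributions <- function(op, d, dcf = NULL) {
  stopifnot(op$mode == "lowrank", !is.null(op$factors))
  if (inherits(d, "kspace_data")) d <- d$samples
  L <- op$L
  S <- op$coils$maps
  contrib <- matrix(0i, op$n, L)
  for (i in seq_len(op$ni)) {
    f <- op$factors[[i]]
    Y <- t(matrix(d[i, , ], nrow = op$nc))          # N_k x Nc
    if (!is.null(dcf)) Y <- Y * dcf
    X <- matrix(0i, op$nk, L * op$nc)
    for (l in seq_len(L))
      X[, (l - 1) * op$nc + seq_len(op$nc)] <- Conj(f$U[, l]) * Y
    Z <- nufft_adjoint(op$plans[[i]], X)            # N x (L*Nc)
    for (l in seq_len(L)) {
      A <- f$V[, l] * Z[, (l - 1) * op$nc + seq_len(op$nc), drop = FALSE]
      contrib[, l] <- contrib[, l] + rowSums(Conj(S) * A)
    }
  }
  contrib
}

#' NRMSE of low-rank versus full-rank conjugate-phase reconstruction
#'
#' Computes the conjugate-phase image at every rank `1..L_max` in one pass
#' (rank-wise contributions are cumulative) and returns the NRMSE of each
#' rank-L image against the rank-`L_max` one.
#'
#' @param op a low-rank [encoding_operator()] with factors at full `L_max`.
#' @param data a [kspace_data()] (or bare array).
#' @param dcf optional density-compensation weights (length `N_k`).
#' @param mask optional voxel mask for the error metric.
#' @return data.frame with columns `L` and `nrmse`.
#' @export
rank_nrmse_curve <- function(op, data, dcf = NULL, mask = NULL) {
  contrib <- cp_rank_contributions(op, data, dcf)
  L_max <- ncol(contrib)
  cum <- contrib
  for (l in seq_len(L_max - 1) + 1) cum[, l] <- cum[, l - 1] + contrib[, l]
  full <- cum[, L_max]
  if (is.null(mask)) mask <- rep(TRUE, length(full))
  nr <- vapply(seq_len(L_max), function(l)
    nrmse(full[mask], cum[mask, l]), numeric(1))
  data.frame(L = seq_len(L_max), nrmse = nr)
}

#' Select the shared truncation rank
#'
#' Picks the smallest rank `L` whose conjugate-phase reconstruction differs
#' from the full-rank one by less than `threshold` in NRMSE; one `L` is
#' shared across all interleaves.
#'
#' @inheritParams rank_nrmse_curve
#' @param threshold NRMSE threshold (default 0.02, i.e. 2%).
#' @return integer rank, with the full curve attached as attribute
#'   `"curve"`. If the threshold is unreachable at `L_max`, returns `L_max`
#'   with a warning.
#' @export
select_rank <- function(op, data, dcf = NULL, threshold = 0.02, mask = NULL) {
  curve <- rank_nrmse_curve(op, data, dcf, mask)
  ok <- which(curve$nrmse < threshold)
  if (length(ok) == 0L) {
    warning("NRMSE threshold not reached at L_max; returning L_max")
    L <- max(curve$L)
  } else L <- min(ok)
  structure(as.integer(L), curve = curve)
}
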