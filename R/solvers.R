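# LSQR (Paige & Saunders) for complex linear least squares ||A x - b||_2.
# Golub-Kahan bidiagonalization; works for any aprod/atprod pair that passes
# the adjoint (dot-product) test. The returned residual norms are
# monotonically non-increasing by construction.
lsqr_solve <- function(aprod, atprod, b, max_iter = 15L, tol = 1e-5,
                       x0 = NULL) {
  u <- b
  x <- if (is.null(x0)) NULL else x0
  if (!is.null(x0)) u <- b - aprod(x0)
  beta <- sqrt(sum(Mod(u)^2))
  resid_hist <- numeric(0)
  if (beta == 0) {
    v0 <- atprod(b)
    x <- if (is.null(x)) 0 * v0 else x
    return(list(x = x, iterations = 0L, residuals = 0, converged = TRUE))
  }
  u <- u / beta
  v <- atprod(u)
  alpha <- sqrt(sum(Mod(v)^2))
  if (alpha == 0) {
    x <- if (is.null(x)) 0 * v else x
    return(list(x = x, iterations = 0L, residuals = beta, converged = TRUE))
  }
  v <- v / alpha
  w <- v
  if (is.null(x)) x <- 0 * v
  phibar <- beta
  rhobar <- alpha
  arnorm0 <- alpha * beta                     # ||A^H r_0||
  converged <- FALSE
  it <- 0L
  for (it in seq_len(max_iter)) {
    u <- aprod(v) - alpha * u
    beta <- sqrt(sum(Mod(u)^2))
    if (beta > 0) {
      u <- u / beta
      v <- atprod(u) - beta * v
      alpha <- sqrt(sum(Mod(v)^2))
      if (alpha > 0) v <- v / alpha
    }
    rho <- sqrt(rhobar^2 + beta^2)
    cs <- rhobar / rho
    sn <- beta / rho
    theta <- sn * alpha
    rhobar <- -cs * alpha
    phi <- cs * phibar
    phibar <- sn * phibar
    x <- x + (phi / rho) * w
    w <- v - (theta / rho) * w
    resid_hist <- c(resid_hist, phibar)
    # ||A^H r|| = phibar * alpha * |cs|; relative to ||A^H b||
    arnorm <- phibar * alpha * abs(cs)
    if (arnorm <= tol * arnorm0) { converged <- TRUE; break }
    if (beta == 0 || alpha == 0) { converged <- TRUE; break }
  }
  list(x = x, iterations = it, residuals = resid_hist, converged = converged)
}
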