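#' Design a constant-density Archimedean spiral readout
#'
#' Generates `n_interleaves` rotated copies of a slew- and amplitude-limited
#' Archimedean spiral `k(theta) = a * theta * exp(i theta)` with
#' `a = n_interleaves / fov_m` (rad/m per rad), so the adjacent-turn radial
#' spacing of the full interleaf set equals the Nyquist spacing `2*pi/fov`.
#' The angular velocity is integrated forward at the ADC dwell under the
#' slew-rate constraint, capped by the amplitude constraint, until the
#' trajectory reaches the edge of k-space (`|k| >= pi/resolution`).
#'
#' This is a fixture-grade designer: constraint-satisfying and
#' Nyquist-valid, with no variable-density schedule and no rewinder.
#'
#' @param fov_m field of view, meters.
#' @param resolution_m in-plane resolution, meters.
#' @param n_interleaves number of interleaves (>= 1).
#' @param gmax_T_per_m peak gradient amplitude, T/m.
#' @param smax_T_per_m_s peak slew rate, T/m/s.
#' @param dwell_s ADC dwell time (also the gradient raster here), seconds.
#' @param gamma gyromagnetic ratio, rad/s/T.
#' @param max_duration_s give up (error) if the readout would exceed this.
#' @param t0_s phase reference time tag for the returned waveforms.
#' @return a logical-frame [gradient_set()] with `n_interleaves` interleaves.
#' @export
design_spiral <- function(fov_m, resolution_m, n_interleaves,
                          gmax_T_per_m = 24e-3, smax_T_per_m_s = 144,
                          dwell_s = 2.5e-6, gamma = 2 * pi * 42.5764e6,
                          max_duration_s = 0.1, t0_s = 0) {
  stopifnot(fov_m > 0, resolution_m > 0, n_interleaves >= 1,
            gmax_T_per_m > 0, smax_T_per_m_s > 0, dwell_s > 0)
  a <- n_interleaves / fov_m              # rad/m per rad of theta
  kmax <- pi / resolution_m               # edge of k-space, rad/m
  theta_max <- kmax / a
  # small design margins absorb first-order discretization of the constraints
  gm <- 0.999 * gmax_T_per_m
  sm <- 0.995 * smax_T_per_m_s
  s_ang <- sm * gamma / a                 # slew constraint in angular units
  dt <- dwell_s
  nmax <- ceiling(max_duration_s / dt)

  theta <- numeric(nmax); thetad <- numeric(nmax)
  th <- 0; thd <- 0
  n <- 0L
  while (th < theta_max) {
    n <- n + 1L
    if (n > nmax)
      stop("infeasible spiral: resolution not reached within max_duration_s ",
           "under the given amplitude/slew constraints")
    theta[n] <- th; thetad[n] <- thd
    # max angular acceleration at the slew limit:
    # A^2 (1+th^2) + 2 A thd^2 th + thd^4 (4+th^2) - s_ang^2 = 0
    disc <- (thd^2 * th)^2 - (1 + th^2) * (thd^4 * (4 + th^2) - s_ang^2)
    if (disc >= 0) {
      A <- (-thd^2 * th + sqrt(disc)) / (1 + th^2)
    } else {
      A <- -thd^2 * th / (1 + th^2)      # fall back to tangential hold
    }
    thd_new <- thd + A * dt
    th_pred <- th + thd * dt
    thd_amp <- gm * gamma / (a * sqrt(1 + th_pred^2))   # amplitude cap
    # curvature cap: centripetal slew |G| * thetad alone must stay inside
    # the budget, with 5% headroom kept for the tangential component
    thd_curv <- sqrt(0.95 * sm * gamma / (a * sqrt(1 + th^2)))
    thd_new <- min(max(thd_new, 0), thd_amp, thd_curv)
    # enforce the *discrete* slew constraint (the continuous formula is
    # first-order; near theta = 0 the higher-order terms matter)
    gfun <- function(t1, t1d) (a / gamma) * t1d * (1 + 1i * t1) * exp(1i * t1)
    g0 <- gfun(th, thd)
    step_ok <- function(t2d) {
      t2 <- th + 0.5 * (thd + t2d) * dt
      abs(gfun(t2, t2d) - g0) / dt <= sm
    }
    if (!step_ok(thd_new)) {
      lo <- thd; hi <- thd_new
      if (!step_ok(lo)) {
        # even holding the angular rate violates slew (centripetal term);
        # decelerate: find the largest feasible rate below the current one
        dec <- thd
        while (dec > 0.25 * thd && !step_ok(dec)) dec <- dec - 0.02 * thd
        lo2 <- dec; hi2 <- thd
        for (b in 1:30) {
          mid <- 0.5 * (lo2 + hi2)
          if (step_ok(mid)) lo2 <- mid else hi2 <- mid
        }
        thd_new <- lo2
      } else {
        for (b in 1:30) {
          mid <- 0.5 * (lo + hi)
          if (step_ok(mid)) lo <- mid else hi <- mid
        }
        thd_new <- lo
      }
    }
    th <- th + 0.5 * (thd + thd_new) * dt          # midpoint advance
    thd <- thd_new
  }
  # store the k-edge crossing state so the terminal radius meets pi/resolution
  n <- n + 1L
  if (n > nmax) stop("infeasible spiral: max_duration_s exceeded")
  theta[n] <- th; thetad[n] <- thd
  nk <- n
  theta <- theta[seq_len(nk)]; thetad <- thetad[seq_len(nk)]

  # analytic gradient of the base interleaf: G = (a/gamma) thd (1+i th) e^{i th}
  gc <- (a / gamma) * thetad * (1 + 1i * theta) * exp(1i * theta)
  gx <- Re(gc); gy <- Im(gc)

  samples <- array(0, c(n_interleaves, nk, 3L))
  for (j in seq_len(n_interleaves)) {
    phi <- 2 * pi * (j - 1) / n_interleaves
    samples[j, , 1] <- cos(phi) * gx - sin(phi) * gy
    samples[j, , 2] <- sin(phi) * gx + cos(phi) * gy
  }
  gradient_set(samples, raster_s = dt, frame = "logical", t0_s = t0_s)
}
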