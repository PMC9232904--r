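#' Per-axis gradient impulse response model
#'
#' A linear-time-invariant model of the gradient chain: one complex transfer
#' function per physical axis on a common frequency grid. Transfer functions
#' must be conjugate-symmetric (`T(-f) = Conj(T(f))`) so that the impulse
#' response is real. B0 cross-terms may be stored but are never applied by
#' [predict_gradients()] (self-terms only).
#'
#' @param freq_Hz frequency grid, length M (must cover negative and positive
#'   frequencies symmetrically for the symmetry check).
#' @param transfer list of 3 complex length-M vectors (x, y, z self-terms).
#' @param b0_cross optional list of 3 complex length-M vectors; stored only.
#' @return object of class `girf_model`.
#' @export
girf_model <- function(freq_Hz, transfer, b0_cross = NULL) {
  freq_Hz <- as.numeric(freq_Hz)
  if (length(transfer) != 3L) stop("'transfer' must be a list of 3 vectors")
  transfer <- lapply(transfer, as.complex)
  if (any(vapply(transfer, length, 1L) != length(freq_Hz)))
    stop("each transfer function must match the frequency grid length")
  # real impulse response: T(-f) = Conj(T(f)) wherever -f is on the grid
  for (ax in 1:3) {
    tf <- transfer[[ax]]
    idx <- match(round(-freq_Hz, 9), round(freq_Hz, 9))
    ok <- !is.na(idx)
    if (max(abs(tf[ok] - Conj(tf[idx[ok]]))) > 1e-9)
      stop("transfer function is not conjugate-symmetric (impulse response would be complex)")
    dc <- abs(tf[which.min(abs(freq_Hz))])
    if (dc <= 0 || dc > 1.2)
      stop("|transfer(0)| must lie in (0, 1.2]")
  }
  structure(list(freq_Hz = freq_Hz, transfer = transfer, b0_cross = b0_cross),
            class = "girf_model")
}

#' @export
print.girf_model <- function(x, ...) {
  cat(sprintf("<girf_model> %d frequency samples, band %.1f .. %.1f kHz%s\n",
              length(x$freq_Hz), 1e-3 * min(x$freq_Hz), 1e-3 * max(x$freq_Hz),
              if (is.null(x$b0_cross)) "" else ", B0 cross-terms stored (not applied)"))
  invisible(x)
}

#' Synthesize a plausible GIRF for testing
#'
#' Builds a conjugate-symmetric transfer function
#' `lowpass(cutoff) * exp(-j 2 pi f delay) * (1 + osc_amp * resonance(f))`
#' per axis: a first-order-like low-pass magnitude, a pure group delay and an
#' optional damped mechanical resonance (conjugate-symmetric Lorentzian).
#'
#' @param delay_s group delay, seconds (may be length 3 for per-axis delays).
#' @param cutoff_Hz low-pass cutoff (> 0, `Inf` for flat magnitude).
#' @param osc_freq_Hz resonance frequency, Hz (ignored when `osc_amp = 0`).
#' @param osc_amp resonance amplitude (0 disables).
#' @param freq_Hz frequency grid for the model.
#' @param q quality factor of the resonance.
#' @return a [girf_model()].
#' @export
synthesize_girf <- function(delay_s = 1e-6, cutoff_Hz = 20e3,
                            osc_freq_Hz = 1.1e3, osc_amp = 0,
                            freq_Hz = seq(-50e3, 50e3, by = 50), q = 10) {
  stopifnot(cutoff_Hz > 0)
  if (length(delay_s) == 1L) delay_s <- rep(delay_s, 3L)
  f <- as.numeric(freq_Hz)
  transfer <- lapply(1:3, function(ax) {
    mag <- 1 / sqrt(1 + (f / cutoff_Hz)^4)      # monotone low-pass in |f|
    tf <- mag * exp(-2i * pi * f * delay_s[ax])
    if (osc_amp != 0) {
      res <- osc_freq_Hz^2 / (osc_freq_Hz^2 - f^2 + 1i * f * osc_freq_Hz / q)
      tf <- tf * (1 + osc_amp * (res - 1))      # res(0) = 1 keeps |T(0)| = 1
    }
    tf
  })
  girf_model(f, transfer)
}

#' Apply GIRF transfer functions to nominal physical-frame gradients
#'
#' Per physical axis, the waveform is zero-padded to at least 4x its length
#' (next power of two), transformed with the FFT, multiplied by the transfer
#' function resampled onto the waveform's frequency grid, and transformed
#' back. Outside the measured GIRF band the transfer is held at its edge
#' magnitude with linear phase extrapolation of the fitted delay.
#'
#' @param g_nom a physical-frame [gradient_set()] of nominal waveforms.
#' @param girf a [girf_model()].
#' @return a physical-frame [gradient_set()] of predicted waveforms with the
#'   same dimensions and raster.
#' @export
predict_gradients <- function(g_nom, girf) {
  stopifnot(inherits(g_nom, "gradient_set"), inherits(girf, "girf_model"))
  if (g_nom$frame != "physical")
    stop("predict_gradients() requires physical-frame gradients; ",
         "call transform_to_physical() first")
  d <- dim(g_nom$samples)
  ni <- d[1]; nk <- d[2]
  nfft <- 2^ceiling(log2(4 * nk))
  fgrid <- fft_freqs(nfft, g_nom$raster_s)
  if (max(abs(fgrid)) > max(abs(girf$freq_Hz)) + 1e-9)
    warning("waveform bandwidth exceeds the GIRF band; ",
            "transfer extrapolated beyond the measured band")
  out <- g_nom
  for (ax in 1:3) {
    tf <- resample_transfer(girf$freq_Hz, girf$transfer[[ax]], fgrid)
    for (i in seq_len(ni)) {
      w <- c(g_nom$samples[i, , ax], numeric(nfft - nk))
      y <- stats::fft(stats::fft(w) * tf, inverse = TRUE) / nfft
      out$samples[i, , ax] <- Re(y[seq_len(nk)])
    }
  }
  out
}

# FFT frequency grid in fft() ordering (DC first, then positive, then negative)
fft_freqs <- function(n, dt) {
  k <- c(0:(ceiling(n / 2) - 1), -(floor(n / 2):1))
  k / (n * dt)
}

# Interpolate a measured transfer function onto an FFT frequency grid.
# Inside the band: linear interpolation of Re/Im. Outside: hold the edge
# magnitude and extrapolate the phase linearly with the delay fitted from
# the outer 10% of the measured band (conjugate symmetry preserved by
# construction from the positive-frequency half).
resample_transfer <- function(f_meas, tf_meas, f_out) {
  o <- order(f_meas)
  f_meas <- f_meas[o]; tf_meas <- tf_meas[o]
  fmax <- max(f_meas)
  pos <- f_out >= 0
  fo <- abs(f_out)
  tf_at <- function(fq) {
    re <- stats::approx(f_meas, Re(tf_meas), xout = fq, rule = 2)$y
    im <- stats::approx(f_meas, Im(tf_meas), xout = fq, rule = 2)$y
    complex(real = re, imaginary = im)
  }
  out <- tf_at(fo)
  oob <- fo > fmax
  if (any(oob)) {
    # fit the group delay on the outer 10% of the positive band
    sel <- f_meas >= 0.9 * fmax & f_meas <= fmax
    if (sum(sel) >= 2) {
      ph <- unwrap_phase(Arg(tf_meas[sel]))
      slope <- stats::coef(stats::lm(ph ~ f_meas[sel]))[2]
    } else slope <- 0
    edge <- tf_meas[which.max(f_meas)]
    out[oob] <- abs(edge) *
      exp(1i * (Arg(edge) + slope * (fo[oob] - fmax)))
  }
  out[!pos] <- Conj(out[!pos])
  out
}

unwrap_phase <- function(p) {
  dp <- diff(p)
  dp <- dp - 2 * pi * round(dp / (2 * pi))
  cumsum(c(p[1], dp))
}
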