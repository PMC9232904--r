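#' Scan geometry: slice orientation, offset and main field
#'
#' Bundles the orthogonal rotation from the logical (slice-aligned) to the
#' physical (gradient-coil) coordinate system, the slice offset from
#' isocenter, the main field strength and the gyromagnetic ratio. All units
#' are SI: meters, Tesla, rad/s/T.
#'
#' @param rotation 3x3 orthogonal matrix mapping logical to physical
#'   coordinates (`R_LtoP`). Its transpose maps back.
#' @param offset length-3 slice offset from isocenter in the physical frame,
#'   meters.
#' @param B0 main magnetic field, Tesla (> 0).
#' @param gamma gyromagnetic ratio, rad/s/T. Default is the proton value
#'   \eqn{2\pi \cdot 42.5764\times 10^6}.
#' @return object of class `scan_geometry`.
#' @export
scan_geometry <- function(rotation = diag(3), offset = c(0, 0, 0),
                          B0 = 0.55, gamma = 2 * pi * 42.5764e6) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3L, 3L)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-12) {
    stop("'rotation' must be a 3x3 orthogonal matrix (R'R = I to 1e-12)")
  }
  offset <- as.numeric(offset)
  if (length(offset) != 3L) stop("'offset' must be a length-3 vector (meters)")
  if (!is.numeric(B0) || B0 <= 0) stop("'B0' must be > 0 (Tesla)")
  structure(list(rotation = rotation, offset = offset,
                 B0 = B0, gamma = gamma),
            class = "scan_geometry")
}

#' @export
print.scan_geometry <- function(x, ...) {
  cat("<scan_geometry>\n")
  cat("  B0:", x$B0, "T;  gamma/2pi:", format(x$gamma / (2 * pi), digits = 8), "Hz/T\n")
  cat("  offset (m):", paste(format(x$offset), collapse = ", "), "\n")
  cat("  rotation L->P:\n")
  print(unname(x$rotation))
  invisible(x)
}

#' Per-interleaf gradient waveforms
#'
#' @param samples numeric array `N_i x N_k x 3`, Tesla/meter. A single
#'   interleaf may be given as an `N_k x 3` matrix.
#' @param raster_s sample spacing of the waveform raster, seconds.
#' @param frame `"logical"` or `"physical"`; consumers check this tag.
#' @param t0_s phase reference time (isodelay for gradient echo, TE for spin
#'   echo); readout sample `n` sits at `t0_s + (n-1) * raster_s`.
#' @return object of class `gradient_set`.
#' @export
gradient_set <- function(samples, raster_s, frame = c("logical", "physical"),
                         t0_s = 0) {
  frame <- match.arg(frame)
  if (is.matrix(samples)) samples <- array(samples, c(1L, dim(samples)))
  d <- dim(samples)
  if (length(d) != 3L || d[3] != 3L)
    stop("'samples' must be an N_i x N_k x 3 array")
  if (!is.numeric(raster_s) || raster_s <= 0) stop("'raster_s' must be > 0")
  structure(list(samples = samples, raster_s = raster_s, frame = frame,
                 t0_s = t0_s),
            class = "gradient_set")
}

#' @export
print.gradient_set <- function(x, ...) {
  d <- dim(x$samples)
  cat(sprintf("<gradient_set> %d interleaf(s), %d samples, raster %.3g us, %s frame\n",
              d[1], d[2], x$raster_s * 1e6, x$frame))
  cat(sprintf("  |G| max = %.3f mT/m, readout %.3f ms, t0 = %.3f ms\n",
              1e3 * max(sqrt(rowSums(matrix(x$samples^2, ncol = 3), dims = 1))),
              1e3 * d[2] * x$raster_s, 1e3 * x$t0_s))
  invisible(x)
}

#' k-space trajectory
#'
#' @param k numeric array `N_i x N_k x 3`, rad/meter.
#' @param times_s sample times, length `N_k`, strictly increasing.
#' @param frame `"logical"` or `"physical"`.
#' @param t0_s phase reference time (k = 0 there).
#' @return object of class `trajectory`.
#' @export
trajectory <- function(k, times_s, frame = c("logical", "physical"), t0_s = times_s[1]) {
  frame <- match.arg(frame)
  if (is.matrix(k)) k <- array(k, c(1L, dim(k)))
  d <- dim(k)
  if (length(d) != 3L || d[3] != 3L) stop("'k' must be an N_i x N_k x 3 array")
  if (length(times_s) != d[2]) stop("'times_s' must have N_k entries")
  if (d[2] > 1 && any(diff(times_s) <= 0)) stop("'times_s' must be strictly increasing")
  structure(list(k = k, times_s = as.numeric(times_s), frame = frame, t0_s = t0_s),
            class = "trajectory")
}

#' Cartesian image grid with voxel-center coordinates
#'
#' 2D slice grid; the logical through-plane coordinate is identically zero.
#' Coordinates are voxel centers, origin at the matrix center
#' (`(0:(N-1) - N/2) * fov/N` per axis), flattened column-major (first axis
#' fastest) -- the single flattening convention used by every module.
#'
#' @param shape integer `(N1, N2)`.
#' @param fov_m field of view `(f1, f2)`, meters.
#' @param frame coordinate frame tag.
#' @param coords optional `N x 3` coordinate matrix (meters); computed from
#'   `shape`/`fov_m` when missing.
#' @param mask optional length-N logical support mask (defaults to all TRUE).
#' @return object of class `spatial_grid` with fields `shape`, `fov_m`,
#'   `coords`, `mask`, `frame`.
#' @export
spatial_grid <- function(shape, fov_m, frame = c("logical", "physical"),
                         coords = NULL, mask = NULL) {
  frame <- match.arg(frame)
  shape <- as.integer(shape)
  if (length(shape) != 2L || any(shape < 1L)) stop("'shape' must be (N1, N2)")
  if (length(fov_m) == 1L) fov_m <- rep(fov_m, 2L)
  n <- prod(shape)
  if (is.null(coords)) {
    ax <- function(N, f) (seq_len(N) - 1 - N %/% 2) * (f / N)
    x <- ax(shape[1], fov_m[1])
    y <- ax(shape[2], fov_m[2])
    coords <- cbind(rep(x, times = shape[2]),
                    rep(y, each = shape[1]),
                    0)
  }
  coords <- as.matrix(coords)
  if (nrow(coords) != n || ncol(coords) != 3L) stop("'coords' must be N x 3")
  if (is.null(mask)) mask <- rep(TRUE, n)
  if (length(mask) != n) stop("'mask' must have N entries")
  structure(list(shape = shape, fov_m = as.numeric(fov_m), coords = coords,
                 mask = as.logical(mask), frame = frame),
            class = "spatial_grid")
}

#' @export
print.spatial_grid <- function(x, ...) {
  cat(sprintf("<spatial_grid> %d x %d, FOV %.3g x %.3g mm, %s frame, %d/%d voxels in mask\n",
              x$shape[1], x$shape[2], 1e3 * x$fov_m[1], 1e3 * x$fov_m[2],
              x$frame, sum(x$mask), prod(x$shape)))
  invisible(x)
}

#' Transform gradients, trajectories or grids to the physical frame
#'
#' Applies the logical-to-physical rotation to vector quantities; spatial
#' grids are additionally translated by the slice offset. The inverse
#' transform is the transpose rotation (see [transform_to_logical()]).
#'
#' @param x a [gradient_set()], [trajectory()] or [spatial_grid()] in the
#'   logical frame.
#' @param geom a [scan_geometry()].
#' @return the same type of object, tagged `frame = "physical"`.
#' @export
transform_to_physical <- function(x, geom) UseMethod("transform_to_physical")

rotate_ik3 <- function(a, R) {
  d <- dim(a)
  m <- matrix(a, ncol = 3L)          # (N_i*N_k) x 3, column-major
  array(m %*% t(R), d)
}

#' @export
transform_to_physical.gradient_set <- function(x, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (x$frame != "logical") stop("input gradient_set is not in the logical frame")
  x$samples <- rotate_ik3(x$samples, geom$rotation)
  x$frame <- "physical"
  x
}

#' @export
transform_to_physical.trajectory <- function(x, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (x$frame != "logical") stop("input trajectory is not in the logical frame")
  x$k <- rotate_ik3(x$k, geom$rotation)
  x$frame <- "physical"
  x
}

#' @export
transform_to_physical.spatial_grid <- function(x, geom) {
  stopifnot(inherits(geom, "scan_geometry"))
  if (x$frame != "logical") stop("input spatial_grid is not in the logical frame")
  x$coords <- sweep(x$coords %*% t(geom$rotation), 2L, -geom$offset)
  x$frame <- "physical"
  x
}

#' Transform back to the logical frame
#'
#' Exact inverse of [transform_to_physical()] (`R_PtoL = t(R_LtoP)`).
#' @inheritParams transform_to_physical
#' @export
transform_to_logical <- function(x, geom) UseMethod("transform_to_logical")

#' @export
transform_to_logical.gradient_set <- function(x, geom) {
  if (x$frame != "physical") stop("input is not in the physical frame")
  x$samples <- rotate_ik3(x$samples, t(geom$rotation))
  x$frame <- "logical"
  x
}

#' @export
transform_to_logical.trajectory <- function(x, geom) {
  if (x$frame != "physical") stop("input is not in the physical frame")
  x$k <- rotate_ik3(x$k, t(geom$rotation))
  x$frame <- "logical"
  x
}

#' @export
transform_to_logical.spatial_grid <- function(x, geom) {
  if (x$frame != "physical") stop("input is not in the physical frame")
  x$coords <- sweep(x$coords, 2L, geom$offset) %*% geom$rotation
  x$frame <- "logical"
  x
}

#' Integrate gradients to a k-space trajectory
#'
#' `k(t) = gamma * integral of G from the phase reference t0`, cumulative
#' trapezoid on the gradient raster, so `k(t0) = 0` when the readout starts
#' at the reference. The frame tag is inherited from the input.
#'
#' @param g a [gradient_set()].
#' @param geom a [scan_geometry()] (supplies `gamma`).
#' @return a [trajectory()] in rad/m, same frame as `g`.
#' @export
integrate_kspace <- function(g, geom) {
  stopifnot(inherits(g, "gradient_set"), inherits(geom, "scan_geometry"))
  d <- dim(g$samples)
  ni <- d[1]; nk <- d[2]
  times <- g$t0_s + (seq_len(nk) - 1) * g$raster_s
  k <- array(0, d)
  for (i in seq_len(ni)) {
    gi <- matrix(g$samples[i, , ], nrow = nk)   # N_k x 3
    if (nk > 1) {
      k[i, , ] <- geom$gamma * apply(gi, 2L, function(col) pracma::cumtrapz(times, col))
    }
  }
  trajectory(k, times, frame = g$frame, t0_s = g$t0_s)
}

#' Demodulate the slice-offset phase from k-space data
#'
#' An off-isocenter slice modulates the received samples by
#' `exp(-j k_P(t) . offset_P)`; this multiplies by the conjugate phase so
#' that downstream higher-order correction sees voxels at their true
#' physical positions.
#'
#' @param data a [kspace_data()].
#' @param traj_P physical-frame [trajectory()] matching `data`.
#' @param geom a [scan_geometry()].
#' @return `data` with the offset phase removed.
#' @export
demodulate_offset <- function(data, traj_P, geom) {
  stopifnot(inherits(data, "kspace_data"), inherits(traj_P, "trajectory"),
            inherits(geom, "scan_geometry"))
  if (traj_P$frame != "physical") stop("trajectory must be in the physical frame")
  d <- dim(data$samples)                       # N_i x N_c x N_k
  dk <- dim(traj_P$k)
  if (d[1] != dk[1] || d[3] != dk[2])
    stop("sample count mismatch between data and trajectory")
  for (i in seq_len(d[1])) {
    ph <- matrix(traj_P$k[i, , ], ncol = 3L) %*% geom$offset   # N_k
    data$samples[i, , ] <- sweep(matrix(data$samples[i, , ], nrow = d[2]),
                                 2L, exp(1i * as.numeric(ph)), `*`)
  }
  data
}

#' Apply the slice-offset modulation (inverse of [demodulate_offset()])
#' @inheritParams demodulate_offset
#' @export
modulate_offset <- function(data, traj_P, geom) {
  g2 <- geom
  g2$offset <- -geom$offset
  demodulate_offset(data, traj_P, g2)
}
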