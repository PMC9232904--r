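---
title: "Higher-order encoding and reconstruction for spiral MRI: models, parameters and design choices"
author: "maxgirf package"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Higher-order encoding and reconstruction for spiral MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Spiral readouts are fast and SNR-efficient, but every millisecond of
readout accrues phase beyond the nominal Fourier encoding:

* **static off-resonance** `deltaf(r)` (B0 inhomogeneity plus the water/fat
  chemical shift, about -88 Hz at 0.55 T), causing local blurring;
* **gradient-chain distortion** (delays, eddy currents, mechanical
  resonances), causing trajectory errors;
* **concomitant (Maxwell) fields** — higher-order spatial terms that
  necessarily accompany linear gradients, scale as `G^2 / B0`, and grow with
  distance from isocenter. They dominate at low field, high gradient
  amplitude and long readouts.

This package implements the higher-order encoding strategy known in the
field as MaxGIRF: a gradient impulse response function (GIRF) predicts the
waveforms the gradient chain actually plays; an analytic concomitant-field
model for a symmetric gradient coil converts those waveforms into
spatiotemporal phase; and the reconstruction inverts the resulting encoding
operator, so all three corruptions are corrected jointly at reconstruction
time with no extra hardware.

## The signal model

For interleaf `i` and coil `c`, the noiseless sample at time `t` is

    d_ic(t) = sum_rho m(r_rho) S_c(r_rho) exp(-j phi_i(r_rho, t))
    phi_i(r, t) = k_i(t) . r + 2 pi deltaf(r) (t - t0) + sum_l k_l,i(t) p_l(r)

with `k_i(t) = gamma * integral G_i` the (GIRF-predicted) trajectory,
`p_l(r)` the concomitant monomial basis (quadratic terms `x^2, y^2, z^2,
yz, xz` at "lowest" order, ten cubic terms carrying `1/B0^2` at "full"
order) and `k_l,i(t)` the time-integrals of the dynamic coefficients
`h_l,i(t)` (e.g. `h6 = (Gx^2 + Gy^2) / (2 B0)`). The cubic coefficient
table was re-derived from the `|B|` expansion of the symmetric-coil field
(`B_x = G_x z - G_z x / 2`, `B_y = G_y z - G_z y / 2`), and the quadratic
and cubic rows are covered by unit tests including the `G -> 2G` (times 4)
and `B0 -> B0/2` (times 2 / times 4) scaling laws.

Two coordinate frames matter. The Fourier factor lives in the *logical*
(slice-aligned) frame; concomitant fields are physics of the gradient coil
and live in the *physical* frame; the two are related by an orthogonal
rotation plus the slice offset. The identity
`k_P . r_P = k_L . r_L + k_P . offset_P` splits the physical-frame phase
into the logical Fourier phase plus a slice-offset modulation of the data;
`demodulate_offset()` removes the latter before reconstruction, and the
package enforces the frame of every input (`F` from logical quantities,
`H` from physical ones) with hard errors rather than conventions.

Discretized on an `N1 x N2` voxel-center grid (column-major flattening —
the natural R convention, used consistently by every module), the encoding
matrix factorizes as `E_i = F_i (*) H_i`: a non-uniform Fourier matrix
Hadamard-multiplied by a unit-modulus phase matrix `H_i` collecting
off-resonance and concomitant phase.

Sign convention: the forward model uses `exp(-j phi)`; which direction a
vendor calls "FFT" varies, so `nrmse()` offers a global complex-scale fit
and the simulator/reconstruction pair is self-consistent by construction.

## Reconstruction

`maxgirf_recon()` solves

    argmin_m sum_i sum_c || d_ic - E_i S_c m ||^2

with LSQR (`method = "lsq"`, defaults 15 iterations, tolerance 1e-5 on the
relative normal-equations residual — the defaults used by the method's
reference implementation), or forms the non-iterative conjugate-phase image
`sum S_c^H E_i^H (dcf * d_ic)` (`method = "cp"`), which needs
density-compensation weights and is defined up to a global scale.

Two numerical choices deserve note:

* **Density weighting as a preconditioner.** For spiral sampling the
  normal equations are badly conditioned by the heavy center
  oversampling; `weights = density_weights(traj)` minimizes the
  `sqrt(dcf)`-weighted residual instead. For consistent data the minimizer
  is unchanged and LSQR reaches ~1e-4 NRMSE in 15 iterations where the
  unweighted problem is still at ~1e-3.
* **Density weights themselves** use the analytic spiral Jacobian
  `w ~ |k| d|k|/dt` (exact for the generated constant-density spirals, with
  a positivity floor at the k-space origin) and fall back to a Nyquist-cell
  occupancy estimate for trajectories whose radius is not monotone.
  Conjugate phase only needs approximate weights; the iterative path uses
  them only as a preconditioner.

With the higher-order phase disabled the operator degenerates exactly to
(CG-)SENSE, which doubles as a cross-check in the tests.

## Low-rank factorization

`H_i` is `N_k x N` and dense, but its singular values decay quickly:
`H_i ~ sum_{l<=L} u_l v_l^H` turns `E_i` into `L` diagonal-NUFFT-diagonal
terms, so one operator application costs `L` NUFFTs instead of a dense
matrix product. The factors come from a seeded randomized SVD
(`randomized_svd()`; Gaussian sketch, oversampling 10, two subspace
iterations with re-orthonormalization) that applies `H` in voxel blocks so
the matrix is never materialized. When the sketch reaches `min(N_k, N)`
columns the range finder is exact regardless of the spectrum — the tests
use that regime when they compare against an exact SVD on matrices with
flat (Gaussian) spectra, where a small sketch cannot converge. Truncation
error follows the Eckart-Young identity
`||H - H_L||_F = sqrt(sum_{l>L} sigma_l^2)`, verified against explicit
truncations.

`select_rank()` picks the smallest `L` (shared by all interleaves) whose
conjugate-phase reconstruction is within 2% NRMSE of the full-rank one,
computed in a single pass because the rank-wise contributions to the
conjugate-phase image are cumulative. Geometry matters: for a non-oblique
axial slice the in-plane concomitant terms vanish (`G_z = 0` kills every
lowest-order coefficient except `h6`, whose basis `z^2 = z0^2` is constant
on the slice), so the concomitant part of `H` is exactly rank 1 — a
time-dependent global frequency shift — and the off-resonance map alone
sets the rank. Sagittal slices keep in-plane quadratic terms and need more.
The NRMSE-versus-rank curve falls steeply and is monotone in exactly
low-rank instances; because the conjugate-phase functional is not an
orthogonal projection, strongly concomitant-dominated geometries can show
isolated upticks of order 1e-5 deep in the curve's tail (stable under SVD
accuracy and coil count — a property of the functional, not a numerical
artifact).

## Off-resonance mapping

`estimate_fieldmap()` fits multi-echo coil-combined images to
`y_m = rho * exp(j 2 pi deltaf TE_m)` by an iteratively regularized
Gauss-Newton method: minimize
`||y - G(xhat)||^2 + alpha ||xhat - xhat0||^2` over preconditioned
variables in which the off-resonance channel is expressed through a
Sobolev weight `(1 + w ||k||^2)^(-h)` (defaults `w = 32`, `h = 16`;
normalized frequencies in `[-0.5, 0.5]^2`), `alpha` halves per iteration
from 1 down to `alpha_min = 1e-6` (35 iterations, inner LSQR 250
iterations at tolerance 1e-10 — the reference settings). `rho` is complex
and effectively unregularized; `deltaf` is confined to smooth variations.
The model deliberately folds the water/fat chemical shift into `deltaf`
rather than separating species.

Choices the reference description leaves open, decided here:

* initialization `rho = first echo`, `deltaf = 0`; `alpha` schedule
  `max(2^-n, alpha_min)`;
* the Gauss-Newton normal equations are solved in real variables
  (`Re rho`, `Im rho`, real `fhat`) so the off-resonance channel stays
  real by construction;
* the data are normalized to `||y|| = 100` before fitting (undone on the
  returned `rho`) — the convention of the nonlinear-inversion family this
  estimator belongs to. Without a normalization the dimensional floor
  `alpha_min` would mean nothing for arbitrarily scaled input;
* divergence guard: three consecutive non-improving Gauss-Newton steps
  stop the iteration and the best iterate is returned.

**What this estimator can and cannot do.** The order-`2h` Sobolev weight
is an extremely strong smoothness prior: with the default constants the
recovered map is effectively band-limited to roughly a tenth of the
spatial Nyquist rate (the exact cutoff shifts with the data-to-`alpha_min`
ratio). Smooth fields (peaks of ~150 Hz over a head-sized extent) are
recovered to well under 1 Hz RMSE in the interior of the object; errors
concentrate where the signal support ends. A *sharp* chemical-shift
boundary — the -88 Hz step at a fat/water interface — cannot be
represented below the cutoff at any iteration count: the estimate smooths
the step over ~10 voxels and the voxels in that band carry tens of Hz of
bias (several Hz RMSE over the object). That is a property of the stated
method and constants, not of this implementation; applications needing
sharp fat boundaries should map fat separately or relax `h`.

## The spiral designer

`design_spiral()` generates constant-density Archimedean interleaves
`k = a theta exp(j theta)` with `a = n_interleaves / fov`, integrating the
angular rate forward at the ADC dwell under three simultaneous caps:
the amplitude limit `|G| <= gmax`, the slew limit enforced on the
*discrete* waveform difference (with a bisection fallback near `theta = 0`
where the continuous slew formula is first-order), and a curvature cap
that keeps the centripetal term inside 95% of the slew budget (without it
the integrator oscillates in the curvature-limited regime typical of
coarse matrices). Design margins of 0.1%/0.5% absorb discretization. The
readout ends one sample after `|k|` crosses `pi / resolution`, so the
terminal radius always meets the requested resolution; interleaves are
rotated copies spanning `2 pi`, giving adjacent-turn spacing exactly at
the Nyquist limit. No rewinders and no variable-density schedule: these
are acquisition fixtures, not sequence exports.

## GIRF model and prediction

`predict_gradients()` filters each physical axis with its measured (or
synthesized) transfer function: zero-pad to at least 4x the waveform
length (next power of two), FFT, multiply, inverse FFT, take the real
part. The pad suppresses circular wrap-around for impulse responses whose
tails are short against 3x the readout (delays, low-pass decay, moderately
damped resonances); a resonance with a decay time comparable to the pad
will wrap, which the energy/pad-doubling tests make observable.
Transfer functions are linearly interpolated onto the waveform's frequency
grid; outside the measured band the edge magnitude is held and the phase
extrapolated linearly with the delay fitted on the outer 10% of the band
(a decision — the reference material is silent on out-of-band behavior).
Only self-terms are applied; B0 cross-terms are stored but ignored,
matching the method's published usage. `synthesize_girf()` builds
conjugate-symmetric fixtures (low-pass magnitude, pure delay, optional
damped resonance) for testing without measurement data.

## The simulator and what passing tests mean

`simulate_acquisition()` evaluates the forward model *densely* (row-blocked
`exp` evaluation, never through the reconstruction operator's fast path),
including the slice-offset modulation that real receivers see; noise is
i.i.d. complex Gaussian with a recorded seed. The phantom is an analytic
ellipse set (head-like support, complex amplitudes); coil maps are wide
Gaussian lobes with mild linear phase, analytic in position so the same
physical coils can be sampled on any grid; off-resonance maps are two
opposed Gaussian lobes scaled to a requested peak, optionally with a
sharp-edged elliptical fat region at -88 Hz.

Desk-scale study conditions used throughout the tests: 64 x 64 matrix,
0.24 m FOV, 4 coils, 0.55 T, and the reference simulation gradient set
(24 mT/m, 144 T/m/s, 2.5 us dwell). Interleaf count trades readout length
against shots: 6 interleaves give a 3.4 ms readout (field-sweep tests),
2 interleaves give ~10 ms (long-readout rank experiments; the in-vivo
scans this mirrors used ~12 ms). The rank-selection comparison uses a
0.48 m sagittal FOV, matching the large sagittal coverage at which the
method's geometry dependence was originally demonstrated — at a 0.24 m FOV
the in-plane `z^2` phase is four times smaller and off-resonance dominates
the rank for both orientations. The default pipeline configuration
(`pipeline_config()`) instead uses 6 mT/m and a 10 us dwell for a 9 ms
readout — a realistic low-field protocol that keeps every stage fast.

Two synthesis modes are exercised: *same-grid* (inverse-crime) synthesis
isolates solver behavior — there the ground truth is band-limited to the
spiral's k-space disk (`bandlimit_disk()`), because content in the
unsampled square-grid corners is invisible to the acquisition and would
appear as a ~6% error floor attributable to coverage, not to the solver —
and *fine-grid* synthesis (2x resolution) introduces honest discretization
mismatch, reproducing the familiar floor between Cartesian references and
spiral reconstructions (~8% here). Against that floor, the uncorrected
error grows monotonically with off-isocenter distance and with `1/B0`,
while the corrected error is flat — the method's headline behavior.

What the simulator does **not** model: relaxation during the readout (the
reference simulation also ignores it), coil noise covariance, RF/slice
profiles, gradient nonlinearity, anatomical phantoms, and sequence-level
concomitant phase accrued before the readout (assumed nulled by waveform
reshaping, as in the spin-echo acquisitions this follows). Passing tests
therefore validate the encoding/inversion machinery, not robustness to
those effects.

## Known limitations

* 2-D slices only; through-plane position enters via the slice offset.
* The concomitant basis assumes a symmetric gradient coil; asymmetric-coil
  expressions and gradient-nonlinearity coupling are out of scope.
* Conjugate-phase image intensity is defined up to scale (density weights
  are normalized to unit mean); comparisons use a fitted global scale.
* The dense operator path is quadratic in memory (guarded at 2^26 entries
  per interleaf); beyond that the low-rank path is mandatory.
* Sharp off-resonance boundaries are smoothed by the mapping prior (see
  above) — by design of the method's constants.
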