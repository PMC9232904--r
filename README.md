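# maxgirf

Higher-order image reconstruction for spiral (non-Cartesian) MRI with
joint correction of static off-resonance, gradient-chain distortion and
concomitant (Maxwell) fields.

## The problem

Long spiral readouts accrue phase that plain Fourier reconstruction
ignores: local off-resonance Δf(r) blurs, gradient imperfections warp the
trajectory, and concomitant fields — the higher-order terms that
necessarily accompany linear gradients, scaling as G²/B₀ and growing with
distance from isocenter — blur and shift, worst at low field. This package
is for MRI reconstruction researchers who want those effects corrected
jointly at reconstruction time, with no field probes or extra hardware,
following the higher-order encoding strategy known as MaxGIRF.

## The model

Per interleaf `i` and coil `c`, with phase reference `t0`:

    d_ic(t) = Σ_ρ m(r_ρ) S_c(r_ρ) exp(-j φ_i(r_ρ, t))
    φ_i(r, t) = k_i(t)·r + 2π Δf(r) (t - t0) + Σ_ℓ k_ℓ,i(t) p_ℓ(r)

`k_i(t)` is integrated from GIRF-predicted gradients; `p_ℓ(r)` are the
concomitant monomials of a symmetric gradient coil (x², y², z², yz, xz at
lowest order; ten cubic 1/B₀² terms at full order) with dynamic
coefficients such as `h6 = (Gx² + Gy²)/(2B₀)`. Discretized, the encoding
matrix factorizes as `E_i = F_i ⊙ H_i` — a non-uniform Fourier matrix
(logical frame) Hadamard-multiplied by a unit-modulus higher-order phase
matrix (physical frame). Images are estimated by

    m̂ = argmin_m Σ_i Σ_c ‖ d_ic − E_i S_c m ‖²

via LSQR, or by the non-iterative conjugate-phase image
`Σ S_c^H E_i^H (dcf ⊙ d_ic)`. A rank-L SVD truncation
`H_i ≈ Σ_ℓ u_ℓ v_ℓ^H` replaces each dense operator product with L
diagonal–NUFFT–diagonal terms; the Eckart–Young identity gives the
truncation error and a 2% NRMSE rule selects L. A multi-echo, iteratively
regularized Gauss–Newton estimator with a Sobolev-norm preconditioner
(`(1 + w‖k‖²)^(-h)`, defaults w = 32, h = 16) supplies the smooth Δf map.
A slew/amplitude-constrained spiral designer and a dense forward simulator
(ellipse phantom, analytic coil maps, smooth + fat-shift off-resonance
maps, seeded complex Gaussian noise) make every stage testable without
scanner data.

## Worked example

Simulate a 32×32, 2-interleaf spiral acquisition of an off-isocenter
(40 mm) slice at 0.55 T with an 80 Hz off-resonance peak and lowest-order
concomitant fields, then reconstruct with and without the higher-order
model:

```r
library(maxgirf)
cfg <- pipeline_config(matrix = 32L, n_interleaves = 2L, n_coils = 3L,
                       gmax_T_per_m = 24e-3, smax_T_per_m_s = 144,
                       dwell_s = 2.5e-6, offset_m = 0.04,
                       peak_offres_Hz = 80)
res <- run_pipeline(cfg)
print(res$recon)
#> <maxgirf_recon> iterative least squares (LSQR), 32 x 32 image, 15 iteration(s) (max_iter reached)
res$metrics$nrmse_vs_truth
#> [1] 0.0613

cfg$concomitant_order <- "none"; cfg$use_b0 <- FALSE
run_pipeline(cfg)$metrics$nrmse_vs_truth     # uncorrected
#> [1] 0.1216
```

The corrected reconstruction reaches the discretization floor of this
simulation (≈6% NRMSE, set by rasterization and k-space disk coverage);
dropping the higher-order phase doubles the error — that factor is what
the correction buys at these settings, and it grows with readout length,
offset and 1/B₀. `plot(res$recon)` shows the magnitude image;
`summary(res$recon)` reports the LSQR residual history.

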