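# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fx_cached <- function(key, expr) {
  if (!exists(key, envir = .fx)) assign(key, expr, envir = .fx)
  get(key, envir = .fx)
}

# spiral with the reference simulation gradient specs (24 mT/m, 144 T/m/s,
# 2.5 us dwell) at a given matrix size
fx_spiral <- function(N = 64, ni = 6) {
  fx_cached(sprintf("spiral_%d_%d", N, ni),
            design_spiral(0.24, 0.24 / N, ni, 24e-3, 144, 2.5e-6))
}

fx_grid <- function(N = 64) fx_cached(sprintf("grid_%d", N),
                                      spatial_grid(c(N, N), 0.24))

fx_coils <- function(nc, N = 64) fx_cached(sprintf("coils_%d_%d", nc, N),
                                           make_coilmaps(nc, fx_grid(N)))

fx_truth <- function(N = 64) fx_cached(sprintf("truth_%d", N),
                                       make_phantom(default_phantom_spec(0.24),
                                                    fx_grid(N)))

geom_axial <- function(z0 = 0, B0 = 0.55)
  scan_geometry(offset = c(0, 0, z0), B0 = B0)

geom_sagittal <- function(x0 = 0, B0 = 0.55)
  scan_geometry(rotation = slice_rotation("sagittal"),
                offset = c(x0, 0, 0), B0 = B0)

crnorm <- function(n) complex(real = stats::rnorm(n),
                              imaginary = stats::rnorm(n))

random_rotation <- function() {
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  q
}

frob <- function(M) sqrt(sum(Mod(M)^2))

# full higher-order operator pair (dense + low-rank at full rank) on a small
# sagittal off-isocenter instance with off-resonance and full-order terms
fx_small_ops <- function() {
  fx_cached("small_ops", {
    N <- 16
    geom <- geom_sagittal(0.08)
    grid <- fx_grid(N)
    g <- fx_spiral(N, 2)
    gp <- transform_to_physical(g, geom)
    gridP <- transform_to_physical(grid, geom)
    df <- make_offresonance(grid, 150)
    hop <- higher_order_phase(gp, gridP, geom,
                              concomitant_model("full", 0.55), df)
    trL <- integrate_kspace(g, geom)
    coils <- fx_coils(3, N)
    nk <- dim(g$samples)[2]
    L_max <- min(nk, N * N)
    fac <- svd_higher_order(hop, L_max, oversample = 0, seed = 17)
    list(dense = encoding_operator(trL, grid, coils, hop, mode = "dense"),
         lowrank = encoding_operator(trL, grid, coils, hop,
                                     mode = "lowrank", factors = fac),
         phase = hop, traj = trL, grid = grid, coils = coils, geom = geom)
  })
}
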