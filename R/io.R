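#' Rotation matrix for a standard slice orientation
#'
#' Maps logical (readout, phase, slice-normal) axes onto physical
#' (gradient-coil) axes: `"axial"` is the identity, `"sagittal"` puts the
#' slice normal along physical x, `"coronal"` along physical y.
#'
#' @param orientation `"axial"`, `"sagittal"` or `"coronal"`.
#' @return 3x3 orthogonal matrix suitable for [scan_geometry()].
#' @export
slice_rotation <- function(orientation = c("axial", "sagittal", "coronal")) {
  switch(match.arg(orientation),
    axial    = diag(3),
    sagittal = matrix(c(0, 1, 0,  0, 0, 1,  1, 0, 0), 3, 3),
    coronal  = matrix(c(1, 0, 0,  0, 0, 1,  0, -1, 0), 3, 3))
}

DATASET_SCHEMA <- "maxgirf-dataset-1"

#' Write a reconstruction dataset container
#'
#' Serializes k-space data, trajectory, geometry, coil maps, gradients and
#' optional off-resonance map / ground truth into one schema-versioned
#' container file (RDS). Units are SI throughout.
#'
#' @param path output file path.
#' @param kspace a [kspace_data()].
#' @param traj a [trajectory()].
#' @param geom a [scan_geometry()].
#' @param coils a [coil_maps()].
#' @param grid a [spatial_grid()].
#' @param gradients optional [gradient_set()].
#' @param deltaf_Hz optional off-resonance map.
#' @param ground_truth optional complex image used to generate the data.
#' @param config optional list recorded verbatim (seeds, parameters).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(path, kspace, traj, geom, coils, grid,
                          gradients = NULL, deltaf_Hz = NULL,
                          ground_truth = NULL, config = NULL) {
  stopifnot(inherits(kspace, "kspace_data"), inherits(traj, "trajectory"),
            inherits(geom, "scan_geometry"), inherits(coils, "coil_maps"),
            inherits(grid, "spatial_grid"))
  obj <- list(schema = DATASET_SCHEMA, kspace = kspace, trajectory = traj,
              geometry = geom, coilmaps = coils, grid = grid,
              gradients = gradients, deltaf_Hz = deltaf_Hz,
              ground_truth = ground_truth, config = config,
              version = as.character(utils::packageVersion("maxgirf")))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a reconstruction dataset container
#'
#' Validates the schema version and cross-checks dimensions (samples vs
#' trajectory, coils vs grid) before returning the typed components.
#'
#' @param path file written by [write_dataset()].
#' @return list with elements `kspace`, `trajectory`, `geometry`,
#'   `coilmaps`, `grid` and, when present, `gradients`, `deltaf_Hz`,
#'   `ground_truth`, `config`.
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  obj <- readRDS(path)
  if (!identical(obj$schema, DATASET_SCHEMA))
    stop("schema-version mismatch: expected '", DATASET_SCHEMA, "', got '",
         obj$schema, "'")
  d <- dim(obj$kspace$samples); dk <- dim(obj$trajectory$k)
  if (d[1] != dk[1] || d[3] != dk[2])
    stop("inconsistent dimensions: /kspace is ", d[1], "x", d[2], "x", d[3],
         " but /trajectory has ", dk[1], " interleaves x ", dk[2], " samples")
  if (nrow(obj$coilmaps$maps) != prod(obj$grid$shape))
    stop("inconsistent dimensions: coil maps do not match the grid")
  if (!is.null(obj$deltaf_Hz) &&
      length(obj$deltaf_Hz) != prod(obj$grid$shape))
    stop("inconsistent dimensions: deltaf map does not match the grid")
  obj[!vapply(obj, is.null, TRUE)]
}

#' Default pipeline configuration
#'
#' @param ... overrides for the desk-scale defaults (64 x 64 matrix, 6
#'   interleaves, 4 coils, 0.55 T, sagittal, lowest-order concomitant
#'   model). Unknown keys are rejected.
#' @return a validated config list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    seed = 1L,
    matrix = 64L, fov_m = 0.24, n_interleaves = 6L, n_coils = 4L,
    B0 = 0.55, gmax_T_per_m = 24e-3, smax_T_per_m_s = 144, dwell_s = 5e-6,
    orientation = "sagittal", offset_m = 0, peak_offres_Hz = 0,
    fat_region = FALSE, noise_sigma = 0, sim_oversample = 1L,
    girf = NULL,
    concomitant_order = "lowest", use_b0 = TRUE,
    recon_method = "lsq", rank = NULL, rank_threshold = 0.02,
    max_iter = 15L, tol = 1e-5)
  ov <- list(...)
  if (length(ov) == 1L && is.list(ov[[1]]) && is.null(names(ov)[1]))
    ov <- ov[[1]]
  bad <- setdiff(names(ov), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(ov)] <- ov
  cfg
}

#' Run the simulate-predict-reconstruct pipeline
#'
#' Executes the full flow on synthetic data: spiral design, (optional) GIRF
#' prediction, logical/physical transforms, slice-offset demodulation,
#' concomitant-phase computation, (optional) low-rank SVD and rank
#' selection, then reconstruction -- and reports NRMSE against the known
#' ground truth. With `out_dir` set, writes the dataset container, the
#' reconstruction and a deterministic `metrics.json`.
#'
#' @param config list from [pipeline_config()] (or a YAML file path whose
#'   contents are passed through it).
#' @param out_dir optional output directory.
#' @return list with the reconstruction (`recon`), the `metrics` list, and
#'   the intermediate objects (`dataset`, `operator`).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- pipeline_config(yaml::read_yaml(config))
  cfg <- do.call(pipeline_config, config)
  n <- cfg$matrix
  geom <- scan_geometry(rotation = slice_rotation(cfg$orientation),
                        offset = slice_rotation(cfg$orientation) %*%
                                   c(0, 0, 1) * cfg$offset_m,
                        B0 = cfg$B0)
  grid <- spatial_grid(c(n, n), cfg$fov_m)
  g_nom <- design_spiral(cfg$fov_m, cfg$fov_m / n, cfg$n_interleaves,
                         cfg$gmax_T_per_m, cfg$smax_T_per_m_s, cfg$dwell_s)
  # actual waveforms: GIRF-filtered when a GIRF is configured
  g_act_P <- transform_to_physical(g_nom, geom)
  if (!is.null(cfg$girf)) {
    girf <- do.call(synthesize_girf, cfg$girf)
    g_act_P <- predict_gradients(g_act_P, girf)
  }
  model <- if (cfg$concomitant_order == "none") NULL
           else concomitant_model(cfg$concomitant_order, cfg$B0)
  # simulation (optionally on a finer grid to avoid the inverse crime)
  simfac <- as.integer(cfg$sim_oversample)
  simgrid <- if (simfac > 1L) spatial_grid(c(n, n) * simfac, cfg$fov_m) else grid
  truth_sim <- make_phantom(default_phantom_spec(cfg$fov_m), simgrid)
  coils_sim <- make_coilmaps(cfg$n_coils, simgrid)
  fat <- if (isTRUE(cfg$fat_region))
    data.frame(x0 = 0, y0 = -0.18 * cfg$fov_m, a = 0.08 * cfg$fov_m,
               b = 0.05 * cfg$fov_m, angle_deg = 0) else NULL
  df_sim <- if (cfg$peak_offres_Hz != 0 || !is.null(fat))
    make_offresonance(simgrid, cfg$peak_offres_Hz, fat) else NULL
  noise <- if (cfg$noise_sigma > 0)
    list(sigma = cfg$noise_sigma, seed = cfg$seed) else NULL
  dat <- simulate_acquisition(truth_sim, coils_sim, df_sim, geom, g_act_P,
                              simgrid, model = model, noise = noise,
                              guard_n = max(128^2, prod(simgrid$shape)))
  # reconstruction-side quantities (recon grid, recon-grid maps)
  truth <- make_phantom(default_phantom_spec(cfg$fov_m), grid)
  coils <- make_coilmaps(cfg$n_coils, grid)
  df <- if (cfg$use_b0 && !is.null(df_sim))
    make_offresonance(grid, cfg$peak_offres_Hz, fat) else NULL
  trP <- integrate_kspace(g_act_P, geom)
  trL <- transform_to_logical(trP, geom)
  dat_dm <- demodulate_offset(dat, trP, geom)
  gridP <- transform_to_physical(grid, geom)
  phase <- if (is.null(model) && is.null(df)) NULL
           else higher_order_phase(g_act_P, gridP, geom, model, df)
  dcf <- density_weights(trL)
  metrics <- list(config = cfg)
  if (!is.null(cfg$rank) && !is.null(phase)) {
    L_max <- if (identical(cfg$rank, "auto")) 30L else as.integer(cfg$rank)
    factors <- svd_higher_order(phase, L_max, seed = cfg$seed)
    op <- encoding_operator(trL, grid, coils, phase, mode = "lowrank",
                            factors = factors)
    if (identical(cfg$rank, "auto")) {
      L <- select_rank(op, dat_dm, dcf, threshold = cfg$rank_threshold)
      op$L <- as.integer(L)
      metrics$selected_L <- as.integer(L)
    }
  } else {
    op <- encoding_operator(trL, grid, coils, phase)
  }
  rec <- maxgirf_recon(op, dat_dm, method = cfg$recon_method, dcf = dcf,
                       weights = if (cfg$recon_method == "lsq") dcf else NULL,
                       max_iter = cfg$max_iter, tol = cfg$tol)
  metrics$method <- cfg$recon_method
  metrics$iterations <- rec$iterations
  metrics$nrmse_vs_truth <- nrmse(truth, rec$image,
                                  scale = if (cfg$recon_method == "cp")
                                    "global" else "none")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset(file.path(out_dir, "dataset.rds"), dat, trL, geom, coils,
                  grid, gradients = g_act_P, deltaf_Hz = df,
                  ground_truth = truth, config = cfg)
    saveRDS(rec, file.path(out_dir, "recon.rds"))
    jsonlite::write_json(metrics, file.path(out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(recon = rec, metrics = metrics,
       dataset = list(kspace = dat, trajectory = trL, geometry = geom,
                      coilmaps = coils, grid = grid, deltaf_Hz = df,
                      ground_truth = truth),
       operator = op)
}
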