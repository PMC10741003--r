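#' Configuration of the one-layer simulation study
#'
#' Bundles every parameter of the simulated validation study. The `"full"`
#' profile is the reference configuration: a 26 x 37 x 1 sheet of 2.5 mm
#' voxels (Nv = 962, 2886 states), 1 s simulated at 2000 Hz, a 4 x 4 x 3
#' tri-axial magnetometer array (144 channels) spanning
#' 250 x 250 x 100 mm centered 200 mm above the sheet, measurement gain 70,
#' sensor noise of 40 fT/sqrt(Hz) equivalent noise spectral density, and
#' gradient refinement with learning rate 200 and regularization strength 1
#' over 2000 epochs. The `"reduced"` profile is the same study rendered
#' small -- a 10 x 14 sheet with the sensor array scaled and moved closer by
#' the same factor (preserving the angular resolution of the inverse
#' problem), 0.45 s at 1000 Hz, and a short refinement budget -- sized so
#' the complete nested optimization runs in about a minute; region layout,
#' velocities, tissue types, noise density and measurement gain are
#' unchanged.
#'
#' @param profile `"full"` or `"reduced"`.
#' @param ... Named overrides of any configuration field.
#' @return An `mcg_config` list.
#' @export
mcg_config <- function(profile = c("full", "reduced"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    profile = profile,
    dims = c(26L, 37L, 1L),
    voxel_size = 2.5,                 # mm
    fs = 2000,                        # Hz
    duration = 1,                     # s
    sensor_counts = c(4L, 4L, 3L),
    sensor_extent = c(250, 250, 100), # mm
    sensor_height = 200,              # mm above the sheet center
    scale = 70,                       # measurement gain folded into H
    ensd_fT = 40,                     # sensor noise, fT/sqrt(Hz)
    velocities = default_velocities(),
    layout = default_layout(with_patch = TRUE),
    control = list(onset_ms = 0, rise_ms = 3, plateau_ms = 200,
                   repol_ms = 100),
    kalman = kalman_config(r_diag = NA),   # NA: derived from the noise level
    refine = refinement_config(eta = 200, gamma = 1, epochs = 2000),
    sweep = list(lo = 0.6, hi = 1.0, step = 0.01),
    seed = 1L
  )
  if (profile == "reduced") {
    # the same study scaled down: the sheet shrinks, and the sensor array
    # shrinks and moves closer by the same factor so the angular resolution
    # of the inverse problem (patch size relative to sensor distance) is
    # preserved; sampling rate, duration and epoch budget are sized for a
    # minutes-scale run
    cfg$dims <- c(10L, 14L, 1L)
    cfg$fs <- 1000
    cfg$duration <- 0.45
    cfg$sensor_counts <- c(4L, 4L, 1L)
    cfg$sensor_extent <- c(95, 95, 38)
    cfg$sensor_height <- 76
    cfg$kalman <- kalman_config(q_diag = 1e-3, r_diag = NA, p0_diag = 1e-2)
    cfg$refine <- refinement_config(eta = 0.03, gamma = 1, epochs = 25L)
  }
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  for (f in c("voxel_size", "fs", "duration", "scale"))
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
      stop(sprintf("configuration field `%s` must be a positive scalar", f))
  if (cfg$ensd_fT < 0) stop("`ensd_fT` must be >= 0")
  cfg$n_steps <- as.integer(round(cfg$fs * cfg$duration))
  if (is.na(cfg$kalman$r_diag))
    cfg$kalman$r_diag <- noise_sigma_pT(cfg$ensd_fT, cfg$fs)^2
  structure(cfg, class = "mcg_config")
}

#' Per-sample noise standard deviation from a noise spectral density
#'
#' White sensor noise of equivalent noise spectral density `ensd` (in
#' fT/sqrt(Hz)) sampled at `fs` occupies the Nyquist bandwidth `fs/2`, so
#' the per-sample standard deviation is `ensd * sqrt(fs/2)` -- returned in
#' pT. 40 fT/sqrt(Hz) at 2000 Hz gives 1.2649 pT.
#'
#' @param ensd_fT Equivalent noise spectral density, fT/sqrt(Hz).
#' @param fs Sampling rate, Hz.
#' @return Standard deviation in pT.
#' @export
noise_sigma_pT <- function(ensd_fT, fs) ensd_fT * sqrt(fs / 2) / 1000

#' Build the geometry of a study configuration
#'
#' @param config An [mcg_config()].
#' @return List with `grid` and `sensors` (array centered `sensor_height`
#'   above the sheet center).
#' @export
build_geometry <- function(config) {
  grid <- build_grid(config$dims, config$voxel_size)
  sheet_center <- grid$origin + config$dims * config$voxel_size / 2
  sensors <- build_sensor_array(
    config$sensor_counts, config$sensor_extent,
    center = sheet_center + c(0, 0, config$sensor_height), triaxial = TRUE)
  list(grid = grid, sensors = sensors)
}

# Measurement operator of the study: normalized current units in, pT out,
# global gain folded in.
study_measurement_matrix <- function(grid, sensors, config) {
  measurement_matrix(grid, sensors, scale = config$scale,
                     current_unit = "A/m^2", field_unit = "pT")
}

#' Generate the ground-truth simulation
#'
#' Builds the pathology-containing layout, initializes its state-space
#' model, rolls it forward open loop, and applies the scaled forward model
#' to obtain noiseless measurements (pT).
#'
#' @param config An [mcg_config()].
#' @return List: `grid`, `sensors`, `types`, `model`, `J` (Nm x 3Nv),
#'   `H` (pT per normalized current unit), `Z_clean` (Nm x Ns, pT).
#' @export
generate_ground_truth <- function(config) {
  geo <- build_geometry(config)
  types <- assign_default_types(geo$grid, config$layout)
  model <- build_model(geo$grid, types, config$fs, config$n_steps,
                       velocities = config$velocities,
                       control_params = config$control)
  J <- simulate_model(model, config$n_steps)
  H <- study_measurement_matrix(geo$grid, geo$sensors, config)
  Z <- predict_measurements(H, J)
  list(grid = geo$grid, sensors = geo$sensors, types = types, model = model,
       J = J, H = H, Z_clean = Z)
}

#' Build the healthy initial model of a study configuration
#'
#' Identical to the ground-truth construction but with the pathological
#' patch removed: the estimation pipeline starts from the assumption of a
#' healthy heart.
#'
#' @param config An [mcg_config()].
#' @param grid Optional pre-built grid (shared with the ground truth).
#' @return List with `types` and `model`.
#' @export
build_initial_model <- function(config, grid = NULL) {
  if (is.null(grid)) grid <- build_grid(config$dims, config$voxel_size)
  layout <- config$layout
  layout$patch <- NULL
  types <- assign_default_types(grid, layout)
  model <- build_model(grid, types, config$fs, config$n_steps,
                       velocities = config$velocities,
                       control_params = config$control)
  list(types = types, model = model)
}

#' Add white sensor noise
#'
#' Adds independent Gaussian noise with per-sample standard deviation
#' `ensd * sqrt(fs/2)` to every channel and sample. The RNG state is set
#' from `seed` and restored afterwards, so identical seeds give identical
#' noise and the caller's RNG stream is untouched.
#'
#' @param Z Nm x Ns measurement matrix (pT).
#' @param ensd_fT Noise spectral density, fT/sqrt(Hz); 0 returns `Z`
#'   unchanged.
#' @param fs Sampling rate (Hz).
#' @param seed Integer seed (mandatory).
#' @return Noisy copy of `Z`.
#' @export
add_noise <- function(Z, ensd_fT, fs, seed) {
  if (missing(seed) || is.null(seed) || is.na(seed))
    stop("a seed is required for noise generation")
  if (ensd_fT == 0) return(Z)
  sigma <- noise_sigma_pT(ensd_fT, fs)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  Z + matrix(rnorm(length(Z), sd = sigma), nrow(Z), ncol(Z))
}

#' Nested state-space optimization
#'
#' The main loop: starting from the healthy initial model M(0), alternate
#' sparse Kalman state estimation and gradient-descent model refinement for
#' a fixed number of epochs, then run one final state estimation with the
#' refined model to obtain the final current-density estimates.
#'
#' @param config An [mcg_config()].
#' @param Z Nm x Ns measurements (pT); typically
#'   `add_noise(generate_ground_truth(config)$Z_clean, ...)`.
#' @param H Optional measurement operator (rebuilt from the config when
#'   omitted).
#' @param verbose Print an epoch summary line every `verbose` epochs
#'   (0 = silent).
#' @return List: `model` (refined), `estimates` (final [run_filter()]
#'   result), `loss_history` (data frame epoch/Lm/Lv/L), `activity`
#'   (activity map of the final estimates), `initial_model`, `config`.
#' @export
nested_optimization <- function(config, Z, H = NULL, verbose = 0) {
  geo <- build_geometry(config)
  if (is.null(H)) H <- study_measurement_matrix(geo$grid, geo$sensors, config)
  init <- build_initial_model(config, geo$grid)
  model <- init$model
  support <- covariance_support(geo$grid)
  epochs <- config$refine$epochs
  hist <- data.frame(epoch = seq_len(epochs), Lm = NA_real_, Lv = NA_real_,
                     L = NA_real_)
  for (e in seq_len(epochs)) {
    est <- run_filter(model, H, Z, config$kalman, support = support)
    step <- refine_epoch(model, H, Z, est, config$refine)
    model <- step$model
    hist[e, c("Lm", "Lv", "L")] <-
      c(step$loss$Lm, step$loss$Lv, step$loss$L)
    if (!is.finite(step$loss$L))
      stop(sprintf("non-finite loss at epoch %d", e))
    if (verbose > 0 && (e %% verbose == 0 || e == 1))
      message(sprintf("epoch %4d | Lm %.4e Lv %.4e L %.4e",
                      e, step$loss$Lm, step$loss$Lv, step$loss$L))
  }
  est <- run_filter(model, H, Z, config$kalman, support = support)
  list(model = model, estimates = est, loss_history = hist,
       activity = activity_map(est$filtered),
       initial_model = init$model, config = config)
}

#' Pseudoinverse baseline
#'
#' Per-time-step minimum-norm estimate of the current densities, evaluated
#' with the same activity-map machinery as the state-space result.
#'
#' @param config An [mcg_config()].
#' @param Z Nm x Ns measurements (pT).
#' @param H Optional measurement operator.
#' @param svd_tolerance Relative SVD truncation.
#' @return List: `J` (estimates), `activity`, `residual` (max abs
#'   reconstruction residual), `H`.
#' @export
pseudoinverse_baseline <- function(config, Z, H = NULL,
                                   svd_tolerance = 1e-10) {
  if (is.null(H)) {
    geo <- build_geometry(config)
    H <- study_measurement_matrix(geo$grid, geo$sensors, config)
  }
  J <- pseudoinverse_estimate(H, Z, svd_tolerance)
  list(J = J, activity = activity_map(J),
       residual = max(abs(Z - predict_measurements(H, J))), H = H)
}
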