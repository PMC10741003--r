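#' Deterministic toy scenarios
#'
#' Small fully deterministic fixtures used throughout the test suite and in
#' examples:
#' \describe{
#'   \item{`chain3`}{A 1 x 3 x 1 chain (sinoatrial node + two atrial
#'     voxels) at 2.5 mm spacing, fs = 2000 Hz: activation times are the
#'     analytic cascade 0, 2.273, 4.545 ms.}
#'   \item{`pair2`}{Two coupled voxels with two nearby tri-axial sensor
#'     sites (18 channels): small enough that the sparse Kalman filter's
#'     support covers every state pair, so it must agree with a dense
#'     filter exactly.}
#'   \item{`sheet5x5`}{A 5 x 5 one-layer sheet with a single-voxel
#'     non-conducting patch; the smallest patch-localization scenario.}
#' }
#'
#' @param name Fixture name.
#' @param n_steps Simulation length (samples); defaults per fixture.
#' @return List with `grid`, `types`, `sensors`, `model`, `H` (pT output,
#'   normalized current input), `J` (ground-truth open-loop trajectory) and
#'   `Z_clean`.
#' @export
make_fixture <- function(name = c("chain3", "pair2", "sheet5x5"),
                         n_steps = NULL) {
  name <- match.arg(name)
  fs <- 2000
  ctrl <- list(onset_ms = 0, rise_ms = 2, plateau_ms = 30, repol_ms = 15)
  if (name == "chain3") {
    if (is.null(n_steps)) n_steps <- 300L
    grid <- build_grid(c(1, 3, 1), 2.5)
    types <- c("sinoatrial_node", "atrium", "atrium")
    sensors <- build_sensor_array(c(2, 1, 1), c(60, 0, 0),
                                  center = c(1.25, 3.75, 101.25))
  } else if (name == "pair2") {
    if (is.null(n_steps)) n_steps <- 120L
    grid <- build_grid(c(2, 1, 1), 2.5)
    types <- c("sinoatrial_node", "atrium")
    sensors <- build_sensor_array(c(2, 1, 1), c(40, 0, 0),
                                  center = c(2.5, 1.25, 51.25))
  } else {
    if (is.null(n_steps)) n_steps <- 400L
    grid <- build_grid(c(5, 5, 1), 2.5)
    types <- rep("atrium", 25)
    types[13] <- "sinoatrial_node"      # center
    types[7] <- "pathological"
    sensors <- build_sensor_array(c(2, 2, 1), c(60, 60, 0),
                                  center = c(6.25, 6.25, 101.25))
  }
  model <- build_model(grid, types, fs, n_steps, control_params = ctrl)
  H <- measurement_matrix(grid, sensors, scale = 70,
                          current_unit = "A/m^2", field_unit = "pT")
  J <- simulate_model(model, n_steps)
  Z <- predict_measurements(H, J)
  list(grid = grid, types = types, sensors = sensors, model = model,
       H = H, J = J, Z_clean = Z, fs = fs, n_steps = n_steps)
}
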