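#' Load a study configuration from YAML or JSON
#'
#' Reads a configuration file, validates it against the known fields of
#' [mcg_config()] (unknown keys are an error listing the offending names)
#' and applies the values as overrides on the chosen profile.
#'
#' @param path File path; `.yaml`/`.yml` parsed with the yaml package,
#'   anything else as JSON.
#' @return An `mcg_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the yaml package is required to read YAML configs")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  profile <- raw$profile %||% "full"
  raw$profile <- NULL
  raw$n_steps <- NULL
  for (nm in c("kalman", "refine")) {
    if (!is.null(raw[[nm]])) {
      builder <- if (nm == "kalman") kalman_config else refinement_config
      raw[[nm]] <- do.call(builder, raw[[nm]])
    }
  }
  if (!is.null(raw$velocities)) raw$velocities <- unlist(raw$velocities)
  do.call(mcg_config, c(list(profile = profile), raw))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a configuration as JSON
#' @param config An [mcg_config()].
#' @param path Output path.
#' @export
save_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, force = TRUE)
  invisible(path)
}

#' Serialize a state-space model to a JSON file
#'
#' Round-trippable plain-text representation of a model (geometry, types,
#' connection table, gains, control vector and waveform parameters).
#'
#' @param model A [state_space_model].
#' @param path Output path.
#' @export
save_model_json <- function(model, path) {
  obj <- list(
    grid = list(dims = model$grid$dims, voxel_size = model$grid$voxel_size,
                origin = model$grid$origin),
    types = model$types,
    fs = model$fs,
    convention = model$convention,
    connections = model$connections,
    gains = model$gains,
    b = model$b,
    control = model$control[c("fs", "onset_ms", "rise_ms", "plateau_ms",
                              "repol_ms")],
    n_steps = length(model$control$u),
    activation = if (!is.null(model$activation)) list(
      sigma_ms = model$activation$sigma_ms,
      delta = model$activation$delta,
      parent = model$activation$parent,
      root = model$activation$root) else NULL
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE, na = "null")
  invisible(path)
}

#' Load a state-space model from JSON
#' @param path Path written by [save_model_json()].
#' @return A [state_space_model].
#' @export
load_model_json <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  grid <- build_grid(obj$grid$dims, obj$grid$voxel_size, obj$grid$origin)
  control <- do.call(make_control_function,
                     c(list(n_steps = obj$n_steps), obj$control))
  conn <- as.data.frame(obj$connections)
  conn$k <- as.integer(conn$k)
  activation <- NULL
  if (!is.null(obj$activation)) {
    activation <- list(
      sigma_ms = as.numeric(obj$activation$sigma_ms),
      delta = matrix(as.numeric(obj$activation$delta), ncol = 3),
      parent = as.integer(obj$activation$parent),
      root = as.integer(obj$activation$root))
  }
  new_state_space_model(grid, obj$types, conn,
                        matrix(as.numeric(obj$gains), ncol = 9), obj$b,
                        control, obj$fs, activation = activation,
                        convention = obj$convention)
}

#' Export an activation state to CSV
#'
#' One row per voxel: activation time (ms) and unit-L1 current direction.
#'
#' @param model A model built by [build_model()].
#' @param path Output path.
#' @export
export_activation_csv <- function(model, path) {
  act <- model$activation
  if (is.null(act)) stop("model carries no activation state")
  df <- data.frame(voxel = seq_along(act$sigma_ms),
                   sigma_ms = act$sigma_ms,
                   dx = act$delta[, 1], dy = act$delta[, 2],
                   dz = act$delta[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a measurement series to CSV
#'
#' Long format: `time_s`, `channel`, `value_pT`.
#'
#' @param Z Nm x Ns matrix in pT.
#' @param fs Sampling rate (Hz).
#' @param path Output path.
#' @export
export_measurements_csv <- function(Z, fs, path) {
  df <- data.frame(
    time_s = rep((seq_len(nrow(Z)) - 1) / fs, times = ncol(Z)),
    channel = rep(seq_len(ncol(Z)), each = nrow(Z)),
    value_pT = as.vector(Z))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a loss history to CSV
#' @param history Data frame from [nested_optimization()].
#' @param path Output path.
#' @export
export_loss_csv <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}

#' Save a complete run container
#'
#' Single-file JSON provenance of a run: configuration, seed, activity
#' maps, segmentation report and loss history. Large trajectories are not
#' stored by default (they are cheap to regenerate from config + seed).
#'
#' @param path Output path.
#' @param config An [mcg_config()].
#' @param ... Named result components (arrays, data frames, lists).
#' @export
save_run_container <- function(path, config, ...) {
  jsonlite::write_json(
    list(package = "mcgss", version = as.character(utils::packageVersion("mcgss")),
         config = unclass(config), results = list(...)),
    path, auto_unbox = TRUE, digits = NA, na = "null", force = TRUE)
  invisible(path)
}

#' Load a run container written by [save_run_container()]
#' @param path Container path.
#' @return Parsed list.
#' @export
load_run_container <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}
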