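#' @title State-space propagation model
#' @description
#' A `state_space_model` couples every allowed ordered pair of neighboring
#' voxels (plus a self-connection slot per voxel) through a bank of
#' first-order Thiran all-pass filters. Each connection carries one shared
#' all-pass coefficient `a`, an integer delay `k`, and a 3x3 gain block `C`
#' mapping the delayed source-voxel current-density components into the
#' target voxel. The per-voxel prediction is
#' `j_v(n) = sum_connections C_(v,o) y_(v,o)(n) + b_v u(n)`,
#' where `y` are the all-pass outputs and `u` the control waveform injected
#' at the sinoatrial node through the control vector `b`.
#'
#' Connections are stored in `model$connections` (columns `src`, `dst`,
#' `tau`, `k`, `a`; `src == dst` marks the self slot) and the gains in
#' `model$gains`, an Ncon x 9 matrix whose columns hold the 3x3 block in
#' column-major order (`C[j, k] = gains[, 3*(k-1) + j]`, `j` = target
#' component, `k` = source component).
#' @name state_space_model
NULL

new_state_space_model <- function(grid, types, connections, gains, b,
                                  control, fs, activation = NULL,
                                  convention = "group_delay") {
  stopifnot(nrow(connections) == nrow(gains), ncol(gains) == 9L,
            length(b) == 3L * grid$n_voxels)
  structure(list(
    grid = grid, types = types, connections = connections, gains = gains,
    b = b, control = control, fs = fs, activation = activation,
    convention = convention
  ), class = "state_space_model")
}

#' @export
print.state_space_model <- function(x, ...) {
  cat(sprintf(
    "<state_space_model> %d voxels (%d states), %d connections (%d active), fs = %g Hz\n",
    x$grid$n_voxels, 3 * x$grid$n_voxels, nrow(x$connections),
    sum(rowSums(abs(x$gains)) > 0), x$fs))
  invisible(x)
}

#' Number of system states of a model
#' @param model A `state_space_model`.
#' @return `3 * Nv`.
#' @export
n_states <- function(model) 3L * model$grid$n_voxels

#' Simulate a model open loop
#'
#' Rolls the propagation model forward for `n_steps` samples, feeding every
#' connection's delay line with the model's own predicted current densities
#' (no measurement correction). Filter memories start at zero (diastole).
#'
#' @param model A `state_space_model`.
#' @param n_steps Number of samples; defaults to the length of the control
#'   waveform.
#' @param engine `"cpp"` (fast path) or `"r"` (plain-R reference
#'   implementation, used for cross-checking).
#' @param active_only Skip connections whose gain block is identically zero
#'   (their outputs cannot influence the trajectory); `FALSE` runs every
#'   filter, which is only useful for debugging.
#' @return Nm x 3Nv matrix `J` of current densities (normalized A/mm^2).
#' @export
simulate_model <- function(model, n_steps = length(model$control$u),
                           engine = c("cpp", "r"), active_only = TRUE) {
  engine <- match.arg(engine)
  if (n_steps == 0) return(matrix(0, 0, n_states(model)))
  u <- control_at(model, n_steps)
  conn <- model$connections
  gains <- model$gains
  if (active_only) {
    keep <- rowSums(abs(gains)) > 0
    conn <- conn[keep, , drop = FALSE]
    gains <- gains[keep, , drop = FALSE]
  }
  k_eff <- effective_k(conn$k, model$convention)
  if (engine == "cpp") {
    cpp_simulate(conn$src, conn$dst, k_eff, conn$a, gains, model$b, u,
                 model$grid$n_voxels, as.integer(n_steps))
  } else {
    r_simulate(conn, k_eff, gains, model$b, u, model$grid$n_voxels, n_steps)
  }
}

# control waveform padded / truncated to n_steps
control_at <- function(model, n_steps) {
  u <- model$control$u
  if (length(u) >= n_steps) u[seq_len(n_steps)] else c(u, numeric(n_steps - length(u)))
}

# The "printed" recursion is the same filter with one extra sample of delay.
effective_k <- function(k, convention) {
  if (identical(convention, "printed")) as.integer(k + 1L) else as.integer(k)
}

# Plain-R open-loop rollout; mirrors the C++ kernel step for step.
r_simulate <- function(conn, k_eff, gains, b, u, nv, n_steps) {
  nc <- nrow(conn)
  J <- matrix(0, n_steps, 3L * nv)
  y_prev <- matrix(0, nc, 3)            # per connection, per source component
  src_col <- 3L * (conn$src - 1L)       # state offset of source voxel
  for (n in seq_len(n_steps)) {
    jn <- b * u[n]
    if (nc > 0) {
      y <- matrix(0, nc, 3)
      for (cc in seq_len(nc)) {
        n1 <- n - k_eff[cc]
        x1 <- if (n1 >= 1) J[n1, src_col[cc] + 1:3] else c(0, 0, 0)
        x2 <- if (n1 - 1 >= 1) J[n1 - 1, src_col[cc] + 1:3] else c(0, 0, 0)
        y[cc, ] <- conn$a[cc] * (x1 - y_prev[cc, ]) + x2
        C <- matrix(gains[cc, ], 3, 3)
        d <- 3L * (conn$dst[cc] - 1L)
        jn[d + 1:3] <- jn[d + 1:3] + C %*% y[cc, ]
      }
      y_prev <- y
    }
    J[n, ] <- jn
  }
  J
}
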