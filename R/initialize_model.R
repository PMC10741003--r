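#' Initial propagation delays between neighboring voxels
#'
#' The delay, in samples, for propagation from voxel `src` into voxel `dst`
#' is `tau = ||p_dst - p_src|| / phi(type_dst) * fs`: the Euclidean center
#' distance divided by the conduction velocity of the *receiving* voxel's
#' tissue type (a wavefront slows down on entering slower tissue). Delays
#' below one sample (possible for fast His-Purkinje tissue at coarse
#' sampling) are clamped to 1 -- the validity limit of the first-order
#' Thiran fractional-delay filter -- with a warning.
#'
#' @param grid A [build_grid()] object.
#' @param types Voxel type vector.
#' @param src,dst Parallel vectors of voxel indices (source, target).
#' @param velocities Named velocity table (m/s), see [default_velocities()].
#' @param fs Sampling rate (Hz).
#' @return Numeric vector of delays in samples (>= 1).
#' @export
initial_delays <- function(grid, types, src, dst,
                           velocities = default_velocities(), fs) {
  phi <- unname(velocities[types[dst]])
  if (any(!is.na(phi) & phi <= 0)) stop("zero or negative propagation velocity")
  d_mm <- sqrt(rowSums((grid$positions[dst, , drop = FALSE] -
                        grid$positions[src, , drop = FALSE])^2))
  tau <- (d_mm / 1000) / phi * fs
  if (any(tau < 1, na.rm = TRUE)) {
    warning(sprintf(
      "%d propagation delay(s) below 1 sample clamped to 1 (Thiran validity)",
      sum(tau < 1, na.rm = TRUE)))
    tau[tau < 1] <- 1
  }
  tau
}

#' Enumerate the model's connection slots
#'
#' All ordered neighbor pairs `(src -> dst)` whose types are compatible under
#' the directed connectivity predicate, plus one self-connection slot per
#' non-pathological voxel (zero gains; available to the refinement step).
#' Rows are sorted by `(dst, src)` so rebuilding is deterministic.
#'
#' @param grid,types Geometry and voxel types.
#' @param connectivity 6x6 logical predicate, see [type_connectivity()].
#' @param adjacency Optional precomputed [adjacency_list()].
#' @return Data frame with columns `src`, `dst`.
#' @keywords internal
connection_slots <- function(grid, types, connectivity = type_connectivity(),
                             adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- adjacency_list(grid)
  src <- integer(0); dst <- integer(0)
  for (v in seq_len(grid$n_voxels)) {
    nb <- adjacency[[v]]
    ok <- if (length(nb) > 0)
      nb[connectivity[cbind(types[nb], types[v])]] else integer(0)
    if (types[v] != "pathological") ok <- c(ok, v)   # self slot
    src <- c(src, ok)
    dst <- c(dst, rep.int(v, length(ok)))
  }
  data.frame(src = src, dst = dst)
}

#' Wavefront initialization of gains and activation times
#'
#' Implements the iterative activation algorithm that turns geometry and
#' tissue types into the initial gain blocks. Starting from the designated
#' sinoatrial root (activation time `sigma = 0` ms, current direction
#' `delta = (1,0,0)`), the wavefront at iteration time `t`:
#' for every voxel `o` with `sigma_o == t` (ascending index; first parent
#' wins ties), (a) finds its not-yet-connected neighbors, (b) discards
#' type-incompatible ones, (c) sets the child direction
#' `delta_i = (p_i - p_o) / ||p_i - p_o||_1`, (d) sets the gain block
#' `c[j,k] = delta_i[j] * sign(delta_o[k])` (with `sign(0) = 0`), and
#' (e) sets `sigma_i = sigma_o + tau_io * Ts`. Then `t` advances to the
#' smallest activation time larger than `t`; the loop stops when none is
#' left. Each voxel is activated at most once, fast paths are preferred, and
#' every reachable voxel gets connected; pathological voxels never connect.
#'
#' @param grid,types Geometry and voxel types.
#' @param slots Connection table from [connection_slots()].
#' @param tau Per-slot delays in samples (parallel to `slots`).
#' @param fs Sampling rate (Hz).
#' @param connectivity Directed type predicate.
#' @param adjacency Optional precomputed [adjacency_list()].
#' @param root Index of the driven sinoatrial voxel; default: the
#'   lowest-index sinoatrial voxel.
#' @return List: `gains` (Ncon x 9, column-major 3x3 blocks), `sigma_ms`
#'   (activation times, `NA` = never activated), `delta` (Nv x 3 unit-L1
#'   directions), `parent` (incoming connection's source, `NA` at the root /
#'   unreached voxels), `root`.
#' @export
initialize_gains <- function(grid, types, slots, tau, fs,
                             connectivity = type_connectivity(),
                             adjacency = NULL, root = NULL) {
  if (is.null(adjacency)) adjacency <- adjacency_list(grid)
  if (is.null(root)) {
    sa <- which(types == "sinoatrial_node")
    if (length(sa) == 0) stop("no sinoatrial voxel: cannot start the wavefront")
    root <- sa[1]
  }
  nv <- grid$n_voxels
  slot_row <- slot_lookup(slots, nv)
  gains <- matrix(0, nrow(slots), 9)
  sigma <- rep(NA_real_, nv)
  delta <- matrix(0, nv, 3)
  parent <- rep(NA_integer_, nv)
  sigma[root] <- 0
  delta[root, ] <- c(1, 0, 0)

  t_i <- 0
  repeat {
    for (o in which(sigma == t_i)) {
      for (i in adjacency[[o]]) {
        if (!is.na(sigma[i])) next                       # activated once only
        if (!connectivity[types[o], types[i]]) next
        row <- slot_row[[key_of(i, o, nv)]]
        if (is.null(row)) next
        step <- grid$positions[i, ] - grid$positions[o, ]
        d_i <- step / sum(abs(step))
        delta[i, ] <- d_i
        gains[row, ] <- as.vector(outer(d_i, sign(delta[o, ])))
        sigma[i] <- sigma[o] + tau[row] / fs * 1000      # ms
        parent[i] <- o
      }
    }
    remaining <- sigma[!is.na(sigma) & sigma > t_i]
    if (length(remaining) == 0) break
    t_i <- min(remaining)
  }
  list(gains = gains, sigma_ms = sigma, delta = delta, parent = parent,
       root = root)
}

key_of <- function(dst, src, nv) as.character((dst - 1) * nv + src)

slot_lookup <- function(slots, nv) {
  env <- new.env(hash = TRUE, size = nrow(slots) * 2L)
  for (r in seq_len(nrow(slots)))
    if (slots$src[r] != slots$dst[r])
      assign(key_of(slots$dst[r], slots$src[r], nv), r, envir = env)
  as.list(env)
}

#' Control vector b
#'
#' The scalar control waveform drives exactly one state: the x-component of
#' the designated sinoatrial voxel gets entry 1, all other entries are 0.
#'
#' @param grid,types Geometry and voxel types.
#' @param root Driven voxel; default: lowest-index sinoatrial voxel.
#' @return Numeric vector of length 3Nv.
#' @export
control_vector <- function(grid, types, root = NULL) {
  if (is.null(root)) {
    sa <- which(types == "sinoatrial_node")
    if (length(sa) == 0) stop("no sinoatrial voxel: control vector undefined")
    root <- sa[1]
  }
  b <- numeric(3L * grid$n_voxels)
  b[3L * (root - 1L) + 1L] <- 1
  b
}

#' Build the initial state-space model M(0)
#'
#' Composes [initial_delays()], [thiran_coefficients()],
#' [initialize_gains()], [control_vector()] and [make_control_function()]
#' into a complete model. Connection slots not established by the wavefront
#' keep their delay parameters but zero gains, so the refinement step can
#' grow them later.
#'
#' @param grid A [build_grid()] object.
#' @param types Voxel type vector.
#' @param fs Sampling rate (Hz).
#' @param n_steps Number of simulation samples Nm.
#' @param velocities Velocity table (m/s).
#' @param connectivity Directed type predicate.
#' @param control_params List of [make_control_function()] arguments
#'   (`onset_ms`, `rise_ms`, `plateau_ms`, `repol_ms`).
#' @param convention All-pass index convention (see [allpass_filter()]).
#' @param root Driven sinoatrial voxel (default: lowest-index one).
#' @return A [state_space_model] object.
#' @export
build_model <- function(grid, types, fs, n_steps,
                        velocities = default_velocities(),
                        connectivity = type_connectivity(),
                        control_params = list(), convention = "group_delay",
                        root = NULL) {
  stopifnot(length(types) == grid$n_voxels)
  adjacency <- adjacency_list(grid)
  slots <- connection_slots(grid, types, connectivity, adjacency)
  tau <- numeric(nrow(slots))
  nb <- slots$src != slots$dst
  tau[nb] <- initial_delays(grid, types, slots$src[nb], slots$dst[nb],
                            velocities, fs)
  tau[!nb] <- 1                        # self slots: minimal valid delay
  th <- thiran_coefficients(tau)
  conn <- data.frame(src = slots$src, dst = slots$dst, tau = tau,
                     k = th$k, a = th$a)
  init <- initialize_gains(grid, types, conn, tau, fs, connectivity,
                           adjacency, root)
  b <- control_vector(grid, types, root = init$root)
  control <- do.call(make_control_function,
                     c(list(n_steps = n_steps, fs = fs), control_params))
  new_state_space_model(grid, types, conn, init$gains, b, control, fs,
                        activation = init[c("sigma_ms", "delta", "parent", "root")],
                        convention = convention)
}
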