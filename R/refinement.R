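#' Refinement configuration
#'
#' @param eta Learning rate for the gradient-descent parameter updates.
#' @param gamma Regularization strength weighting the constraint loss.
#' @param epochs Number of outer-loop epochs.
#' @param hinge Constraint threshold on the per-voxel L1 current density
#'   (normalized units); the constraint loss is zero below it.
#' @param update_self Allow gradient updates of the self-connection slots.
#'   A voxel's self slot is a one-sample feedback loop; letting it adapt
#'   makes the network an adaptive IIR integrator whose gradient descent is
#'   violently unstable at practical learning rates, so self slots are
#'   frozen at zero gain by default and only the voxel-to-voxel couplings
#'   are learned.
#' @return A `refinement_config` list.
#' @export
refinement_config <- function(eta = 200, gamma = 1, epochs = 2000,
                              hinge = 1.01, update_self = FALSE) {
  if (eta <= 0) stop("eta must be > 0")
  if (gamma < 0) stop("gamma must be >= 0")
  structure(list(eta = eta, gamma = gamma, epochs = as.integer(epochs),
                 hinge = hinge, update_self = isTRUE(update_self)),
            class = "refinement_config")
}

#' Measurement loss
#'
#' Mean squared difference between measured and predicted sensor values at
#' one time step: `Lm = (1/Ns) sum_k (z_k - z_hat_k)^2`.
#'
#' @param z,z_hat Sensor vectors of equal length.
#' @return Scalar loss (squared measurement units).
#' @export
measurement_loss <- function(z, z_hat) {
  if (length(z) != length(z_hat)) stop("z and z_hat lengths differ")
  mean((z - z_hat)^2)
}

#' Constraint loss
#'
#' Electrophysiological regularization: a voxel's L1 current density may
#' fall below the control-function maximum (partial tissue filling) but has
#' no reason to exceed it. The loss is the squared positive excess over the
#' hinge threshold, summed over voxels:
#' `Lv = sum_v max(0, ||j_v||_1 - hinge)^2`.
#'
#' @param j All current densities at one time step (length 3Nv).
#' @param hinge Threshold (default 1.01 in normalized units).
#' @return Scalar loss.
#' @export
constraint_loss <- function(j, hinge = 1.01) {
  l1 <- colSums(abs(matrix(j, nrow = 3)))
  sum(pmax(0, l1 - hinge)^2)
}

#' Accumulated gradients of one refinement forward pass
#'
#' Runs the propagation model open loop with the all-pass delay lines fed by
#' a fixed input trajectory (normally the Kalman-filtered estimates),
#' computes the predicted measurements, and accumulates over all time steps
#' the analytic gradients of the loss `L = Lm + gamma Lv` with respect to
#' every gain `c` and (shared per connection) all-pass coefficient `a`.
#' For a gain feeding state `s` of voxel `v` from all-pass output `y`:
#' `dLm/dc = y * h_s' (2/Ns) (z_hat - z)` and
#' `dLv/dc = 2 y sign(j_s) max(0, ||j_v||_1 - hinge)`;
#' the coefficient gradient sums `dy/da * c * h_s' (2/Ns)(z_hat - z)` over
#' the nine gains sharing `a`, with the sensitivity recursion
#' `dy/da(n) = (x(n-k) - y(n-1)) - a dy/da(n-1)`. The constraint loss does
#' not contribute to the `a` gradients.
#'
#' @param model A [state_space_model].
#' @param J_in Nm x 3Nv input trajectory feeding the delay lines.
#' @param H Measurement matrix.
#' @param Z Nm x Ns measurements.
#' @param gamma Regularization strength.
#' @param hinge Constraint threshold.
#' @param engine `"cpp"` or `"r"` (reference, small systems).
#' @return List: `grad_c` (Ncon x 9), `grad_a` (Ncon), per-step `Lm`, `Lv`,
#'   `J_pred`, `z_hat`.
#' @export
refine_gradients <- function(model, J_in, H, Z, gamma = 1, hinge = 1.01,
                             engine = c("cpp", "r")) {
  engine <- match.arg(engine)
  conn <- model$connections
  k_eff <- effective_k(conn$k, model$convention)
  u <- control_at(model, nrow(Z))
  if (engine == "cpp") {
    cpp_refine_forward(conn$src, conn$dst, k_eff, conn$a, model$gains,
                       model$b, u, H, as.matrix(Z), as.matrix(J_in),
                       gamma, hinge)
  } else {
    r_refine_forward(model, conn, k_eff, u, H, as.matrix(Z),
                     as.matrix(J_in), gamma, hinge)
  }
}

# Plain-R reference of the refinement forward pass.
r_refine_forward <- function(model, conn, k_eff, u, H, Z, J_in, gamma, hinge) {
  nc <- nrow(conn)
  N <- ncol(H); ns <- nrow(H); nm <- nrow(Z)
  y_prev <- matrix(0, max(nc, 1), 3)
  d_prev <- matrix(0, max(nc, 1), 3)
  grad_c <- matrix(0, max(nc, 1), 9)
  grad_a <- numeric(max(nc, 1))
  Lm <- numeric(nm); Lv <- numeric(nm)
  Jp <- matrix(0, nm, N); Zh <- matrix(0, nm, ns)
  src_col <- 3L * (conn$src - 1L)
  for (n in seq_len(nm)) {
    jp <- model$b * u[n]
    ycur <- matrix(0, max(nc, 1), 3); dcur <- ycur
    for (cc in seq_len(nc)) {
      n1 <- n - k_eff[cc]
      # strictly causal: only rows <= n-1 of the input trajectory are visible
      x1 <- if (n1 >= 1 && n1 < n) J_in[n1, src_col[cc] + 1:3] else c(0, 0, 0)
      x2 <- if (n1 - 1 >= 1) J_in[n1 - 1, src_col[cc] + 1:3] else c(0, 0, 0)
      y <- conn$a[cc] * (x1 - y_prev[cc, ]) + x2
      dcur[cc, ] <- (x1 - y_prev[cc, ]) - conn$a[cc] * d_prev[cc, ]
      ycur[cc, ] <- y
      d <- 3L * (conn$dst[cc] - 1L)
      jp[d + 1:3] <- jp[d + 1:3] + matrix(model$gains[cc, ], 3, 3) %*% y
    }
    y_prev <- ycur; d_prev <- dcur
    zh <- as.numeric(H %*% jp)
    resid <- zh - Z[n, ]
    Lm[n] <- mean(resid^2)
    g <- as.numeric(2 / ns * (t(H) %*% resid))
    l1 <- colSums(abs(matrix(jp, nrow = 3)))
    hv <- pmax(0, l1 - hinge)
    Lv[n] <- sum(hv^2)
    for (cc in seq_len(nc)) {
      dvox <- conn$dst[cc]
      d <- 3L * (dvox - 1L)
      for (kk in 1:3) {
        gj <- g[d + 1:3] + gamma * 2 * sign(jp[d + 1:3]) * hv[dvox]
        grad_c[cc, 3 * (kk - 1) + 1:3] <-
          grad_c[cc, 3 * (kk - 1) + 1:3] + ycur[cc, kk] * gj
        grad_a[cc] <- grad_a[cc] +
          dcur[cc, kk] * sum(model$gains[cc, 3 * (kk - 1) + 1:3] * g[d + 1:3])
      }
    }
    Jp[n, ] <- jp; Zh[n, ] <- zh
  }
  list(grad_c = grad_c, grad_a = grad_a, Lm = Lm, Lv = Lv,
       J_pred = Jp, z_hat = Zh)
}

#' Gradient-descent parameter update with all-pass wrap rules
#'
#' Applies `c <- c - (eta/Nm) sum_n dL/dc(n)` and
#' `a <- a - (eta/Nm) sum_n dL/da(n)`, then restores each all-pass
#' coefficient to its valid range [0, 1] by trading fractional against
#' integer delay: `a < 0` becomes `(a + 1, k + 1)`; `a > 1` with `k >= 1`
#' becomes `(a - 1, k - 1)`; `a > 1` with `k = 0` is clamped to `a = 1`.
#' Control vector and integer delays are otherwise untouched. Self slots
#' keep `tau >= 1` by the same rules.
#'
#' @param model A [state_space_model].
#' @param grads Gradient set from [refine_gradients()].
#' @param eta Learning rate.
#' @param n_steps Number of accumulated time steps Nm.
#' @return The updated model (filter memories are implicitly reset: models
#'   are stateless between calls).
#' @export
update_parameters <- function(model, grads, eta, n_steps) {
  if (any(!is.finite(grads$grad_c)) || any(!is.finite(grads$grad_a))) {
    bad <- unique(c(which(rowSums(!is.finite(grads$grad_c)) > 0),
                    which(!is.finite(grads$grad_a))))
    stop(sprintf("non-finite gradient at connection(s) %s",
                 paste(utils::head(bad, 5), collapse = ", ")))
  }
  model$gains <- model$gains - (eta / n_steps) * grads$grad_c
  a <- model$connections$a - (eta / n_steps) * grads$grad_a
  k <- model$connections$k
  if (any(abs(a) > 1e6))
    stop("all-pass coefficient update diverged (|a| > 1e6); reduce the learning rate")
  # wrap until a is back in [0, 1], trading fractional against integer delay
  low <- a < 0
  w <- ceiling(-a[low])
  a[low] <- a[low] + w
  k[low] <- k[low] + as.integer(w)
  high <- a > 1 & k >= 1L
  w <- pmin(k[high], ceiling(a[high] - 1))
  a[high] <- a[high] - w
  k[high] <- k[high] - as.integer(w)
  a[a > 1] <- 1
  model$connections$a <- a
  model$connections$k <- as.integer(k)
  model$connections$tau <- thiran_delay(k, a)
  model
}

#' One refinement epoch
#'
#' Forward pass (delay lines fed with the filtered trajectory), full-batch
#' gradient accumulation over all time steps, one parameter update.
#'
#' @param model A [state_space_model].
#' @param H,Z Measurement matrix and measurements.
#' @param estimates A [run_filter()] result (its `filtered` trajectory feeds
#'   the forward pass), or a matrix.
#' @param config A [refinement_config()].
#' @param engine Passed to [refine_gradients()].
#' @return List with the updated `model` and `loss` (epoch means `Lm`, `Lv`,
#'   `L` plus the per-step series).
#' @export
refine_epoch <- function(model, H, Z, estimates, config = refinement_config(),
                         engine = "cpp") {
  J_in <- if (is.list(estimates)) estimates$filtered else estimates
  gr <- refine_gradients(model, J_in, H, Z, gamma = config$gamma,
                         hinge = config$hinge, engine = engine)
  if (!config$update_self) {
    self <- model$connections$src == model$connections$dst
    gr$grad_c[self, ] <- 0
    gr$grad_a[self] <- 0
  }
  model <- update_parameters(model, gr, config$eta, nrow(as.matrix(Z)))
  loss <- list(Lm = mean(gr$Lm), Lv = mean(gr$Lv),
               L = mean(gr$Lm) + config$gamma * mean(gr$Lv),
               Lm_series = gr$Lm, Lv_series = gr$Lv)
  list(model = model, loss = loss)
}
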