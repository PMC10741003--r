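# Independent reference implementations used as oracles. These deliberately
# re-derive results through different code paths (dense linear algebra,
# direct formula evaluation, event queues) than the package internals.

# Dense textbook Kalman filter sharing the model's all-pass state prediction
# but doing every covariance operation with full dense matrices and no
# support projection. On models whose voxels are all mutual neighbors the
# sparse filter must agree with this to machine precision.
dense_kalman_oracle <- function(model, H, Z, config) {
  nv <- model$grid$n_voxels
  N <- 3L * nv
  ns <- nrow(H)
  nm <- nrow(Z)
  conn <- model$connections
  gains <- model$gains
  keep <- rowSums(abs(gains)) > 0
  conn <- conn[keep, , drop = FALSE]
  gains <- gains[keep, , drop = FALSE]
  nc <- nrow(conn)
  Cmat <- matrix(0, N, N)
  for (cc in seq_len(nc)) {
    Cmat[3 * (conn$dst[cc] - 1) + 1:3, 3 * (conn$src[cc] - 1) + 1:3] <-
      Cmat[3 * (conn$dst[cc] - 1) + 1:3, 3 * (conn$src[cc] - 1) + 1:3] +
      matrix(gains[cc, ], 3, 3)
  }
  P <- diag(config$p0_diag, N)
  Q <- diag(config$q_diag, N)
  R <- diag(config$r_diag, ns)
  u <- model$control$u[seq_len(nm)]
  Jc <- matrix(0, nm, N)
  yprev <- matrix(0, max(nc, 1), 3)
  out <- matrix(0, nm, N)
  for (n in seq_len(nm)) {
    jp <- model$b * u[n]
    for (cc in seq_len(nc)) {
      sc <- 3 * (conn$src[cc] - 1)
      m1 <- n - conn$k[cc]
      x1 <- if (m1 >= 1 && m1 < n) Jc[m1, sc + 1:3] else c(0, 0, 0)
      x2 <- if (m1 - 1 >= 1) Jc[m1 - 1, sc + 1:3] else c(0, 0, 0)
      y <- conn$a[cc] * (x1 - yprev[cc, ]) + x2
      yprev[cc, ] <- y
      dcol <- 3 * (conn$dst[cc] - 1)
      jp[dcol + 1:3] <- jp[dcol + 1:3] + matrix(gains[cc, ], 3, 3) %*% y
    }
    P <- Cmat %*% P %*% t(Cmat) + Q
    S <- H %*% P %*% t(H) + R
    K <- P %*% t(H) %*% solve(S)
    jc <- jp + K %*% (Z[n, ] - H %*% jp)
    P <- (diag(N) - K %*% H) %*% P
    Jc[n, ] <- jc
    out[n, ] <- jc
  }
  out
}

# Event-driven re-implementation of the wavefront initialization: a queue of
# (activation time, voxel) events processed in time order with the same
# tie-breaking (ascending parent index), recording sigma and parent.
wavefront_oracle <- function(grid, types, velocities, fs,
                             connectivity = type_connectivity()) {
  nv <- grid$n_voxels
  sa <- which(types == "sinoatrial_node")
  root <- sa[1]
  sigma <- rep(NA_real_, nv)
  parent <- rep(NA_integer_, nv)
  sigma[root] <- 0
  done <- rep(FALSE, nv)
  repeat {
    pending <- which(!done & !is.na(sigma))
    if (length(pending) == 0) break
    t_now <- min(sigma[pending])
    front <- pending[sigma[pending] == t_now]   # all voxels at this time
    for (o in sort(front)) {
      for (i in neighbors(grid, o)) {
        if (!is.na(sigma[i])) next
        if (!connectivity[types[o], types[i]]) next
        d_mm <- sqrt(sum((grid$positions[i, ] - grid$positions[o, ])^2))
        tau <- max(1, d_mm / 1000 / velocities[types[i]] * fs)
        sigma[i] <- sigma[o] + tau / fs * 1000
        parent[i] <- o
      }
      done[o] <- TRUE
    }
  }
  list(sigma_ms = sigma, parent = parent)
}

# Minimum-norm least-squares via MASS::ginv (independent pseudoinverse).
ginv_estimate <- function(H, Z) {
  t(MASS::ginv(H) %*% t(Z))
}

# Random small model for gradient tests: a pair2 fixture with perturbed
# gains (including unestablished slots) and fractional coefficients.
random_small_model <- function(seed) {
  set.seed(seed)
  fx <- make_fixture("pair2")
  m <- fx$model
  m$gains <- m$gains + matrix(rnorm(length(m$gains), sd = 0.3), nrow(m$gains))
  m$connections$a <- pmin(1, pmax(0.05, m$connections$a - runif(nrow(m$connections), 0, 0.5)))
  list(model = m, H = fx$H)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}

# The scaled-down rendition of the simulated study used by the end-to-end
# acceptance checks: the package's reduced profile with its defaults.
reduced_study_config <- function() mcg_config("reduced")
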