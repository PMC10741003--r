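#' Kalman filter configuration
#'
#' Noise covariances for the sparse Kalman state estimator. All three
#' matrices are diagonal: `Q = q_diag I` (process noise, normalized current
#' units squared), `R = r_diag I` (measurement noise, squared measurement
#' units -- pT^2 in the shipped experiment) and `P(0) = p0_diag I` (initial
#' state variance).
#'
#' @param q_diag Process-noise variance.
#' @param r_diag Measurement-noise variance; the natural choice is the
#'   square of the per-sample sensor noise standard deviation.
#' @param p0_diag Initial state variance.
#' @param feed `"corrected"` feeds the all-pass delay lines with the
#'   corrected estimates j(n|n) so measurement information propagates into
#'   future predictions; `"predicted"` feeds j(n|n-1) instead.
#' @return A `kalman_config` list.
#' @export
kalman_config <- function(q_diag = 1e-4, r_diag = 1, p0_diag = 1e-2,
                          feed = c("corrected", "predicted")) {
  feed <- match.arg(feed)
  if (any(c(q_diag, r_diag, p0_diag) < 0, na.rm = TRUE))
    stop("variances must be >= 0")
  structure(list(q_diag = q_diag, r_diag = r_diag, p0_diag = p0_diag,
                 feed = feed), class = "kalman_config")
}

#' State-level covariance support mask
#'
#' The sparse filter keeps covariance entries only for state pairs whose
#' voxels are 26-neighbors (or identical). Returns the mask as a logical
#' 3Nv x 3Nv matrix (for the plain-R path) and as a voxel-level CSR
#' structure (for the C++ path), together with the 2-hop support the
#' covariance prediction needs.
#'
#' @param grid A [build_grid()] object.
#' @param adjacency Optional precomputed [adjacency_list()].
#' @return List: `mask` (3Nv x 3Nv logical), `supp_ptr`/`supp_idx` and
#'   `supp2_ptr`/`supp2_idx` (0-based CSR pointers, 1-based voxel indices).
#' @export
covariance_support <- function(grid, adjacency = NULL) {
  if (is.null(adjacency)) adjacency <- adjacency_list(grid)
  nv <- grid$n_voxels
  supp <- lapply(seq_len(nv), function(v) sort(c(v, adjacency[[v]])))
  supp2 <- lapply(seq_len(nv), function(v)
    sort(unique(c(v, unlist(adjacency[supp[[v]]])))))
  mask <- matrix(FALSE, 3 * nv, 3 * nv)
  for (v in seq_len(nv)) {
    rows <- 3 * (v - 1) + 1:3
    cols <- as.vector(outer(1:3, 3 * (supp[[v]] - 1), `+`))
    mask[rows, cols] <- TRUE
  }
  list(
    mask = mask,
    supp_ptr = as.integer(c(0, cumsum(lengths(supp)))),
    supp_idx = as.integer(unlist(supp)),
    supp2_ptr = as.integer(c(0, cumsum(lengths(supp2)))),
    supp2_idx = as.integer(unlist(supp2))
  )
}

#' Sparse covariance prediction
#'
#' One covariance prediction step restricted to the neighbor support:
#' `P(n|n-1) = C P C' + Q` evaluated only on masked entries (everything off
#' the support is treated as -- and stays -- zero), then re-symmetrized.
#' Plain-R reference used on small systems and in tests; [run_filter()] uses
#' the equivalent compiled path.
#'
#' @param P Covariance (dense storage, zero off support).
#' @param Q Process-noise matrix (same layout).
#' @param C State-transition gain matrix (3Nv x 3Nv, zero outside allowed
#'   connections).
#' @param mask Logical support mask from [covariance_support()].
#' @return Predicted covariance, zero off support.
#' @export
predict_covariance <- function(P, Q, C, mask) {
  out <- C %*% P %*% t(C) + Q
  out[!mask] <- 0
  (out + t(out)) / 2
}

#' Kalman gain and innovation covariance
#'
#' `S = H P H' + R`, `K = P H' S^-1`, with `P` supported on the neighbor
#' mask. Errors out (naming the smallest eigenvalue) when `S` is singular.
#'
#' @param P Covariance (zero off support).
#' @param H Measurement matrix.
#' @param R Measurement-noise matrix.
#' @return List with `K` (3Nv x Ns) and `S` (Ns x Ns).
#' @export
gain_and_innovation <- function(P, H, R) {
  S <- H %*% P %*% t(H) + R
  S <- (S + t(S)) / 2
  ev <- tryCatch(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values),
                 error = function(e) NA_real_)
  Si <- tryCatch(solve(S), error = function(e)
    stop(sprintf("innovation covariance S is singular (smallest eigenvalue %g)",
                 ev)))
  list(K = P %*% t(H) %*% Si, S = S)
}

#' State correction
#'
#' `j(n|n) = j(n|n-1) + K (z - z_hat)`.
#'
#' @param j_pred Predicted state vector.
#' @param K Kalman gain.
#' @param z Measurement vector.
#' @param z_pred Predicted measurement vector.
#' @return Corrected state vector.
#' @export
correct_state <- function(j_pred, K, z, z_pred) {
  as.numeric(j_pred + K %*% (z - z_pred))
}

#' Sparse covariance correction
#'
#' `P(n|n) = (I - K H) P(n|n-1)` projected back onto the neighbor support,
#' re-symmetrized, with the diagonal floored at zero.
#'
#' @param P Predicted covariance (zero off support).
#' @param K Kalman gain.
#' @param H Measurement matrix.
#' @param mask Logical support mask.
#' @return Corrected covariance, zero off support.
#' @export
correct_covariance <- function(P, K, H, mask) {
  out <- P - K %*% (H %*% P)
  out[!mask] <- 0
  out <- (out + t(out)) / 2
  diag(out)[diag(out) < 0] <- 0
  out
}

#' Gain matrix of a model as a dense state-transition operator
#'
#' Entry block `(dst, src)` holds the connection's 3x3 gains; used by the
#' covariance recursion, which treats the gains as the one-step transition.
#'
#' @param model A [state_space_model].
#' @return 3Nv x 3Nv matrix.
#' @export
transition_gains <- function(model) {
  nv <- model$grid$n_voxels
  C <- matrix(0, 3 * nv, 3 * nv)
  conn <- model$connections
  for (cc in seq_len(nrow(conn))) {
    rows <- 3 * (conn$dst[cc] - 1) + 1:3
    cols <- 3 * (conn$src[cc] - 1) + 1:3
    C[rows, cols] <- C[rows, cols] + matrix(model$gains[cc, ], 3, 3)
  }
  C
}

#' Run the sparse Kalman filter
#'
#' Loops state prediction (all-pass propagation model), covariance
#' prediction, gain computation, state correction and covariance correction
#' over all time steps. The covariance recursion is restricted to the
#' 26-neighbor support; `S` (Ns x Ns) is factorized densely. Initial state
#' is zero with `P(0) = p0_diag I`; all-pass memories start at zero.
#'
#' @param model A [state_space_model].
#' @param H Measurement matrix matching the model's state layout.
#' @param Z Nm x Ns measurements (same units as `H`'s output).
#' @param config A [kalman_config()].
#' @param engine `"cpp"` or `"r"` (reference implementation built from the
#'   exported step operations; small systems only).
#' @param support Optional precomputed [covariance_support()].
#' @return List with `filtered` (Nm x 3Nv, j(n|n)), `predicted`
#'   (j(n|n-1)), `innovations` (Nm x Ns), `z_hat` and `P_diag` (final).
#' @export
run_filter <- function(model, H, Z, config = kalman_config(),
                       engine = c("cpp", "r"), support = NULL) {
  engine <- match.arg(engine)
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(H)) stop("Z channels do not match H rows")
  if (ncol(H) != n_states(model)) stop("H columns do not match model states")
  if (is.null(support)) support <- covariance_support(model$grid)
  active <- rowSums(abs(model$gains)) > 0
  conn <- model$connections[active, , drop = FALSE]
  gains <- model$gains[active, , drop = FALSE]
  k_eff <- effective_k(conn$k, model$convention)
  u <- control_at(model, nrow(Z))
  if (engine == "cpp") {
    res <- cpp_kalman(conn$src, conn$dst, k_eff, conn$a, gains, model$b, u,
                      H, Z, config$q_diag, config$r_diag, config$p0_diag,
                      model$grid$n_voxels,
                      support$supp_ptr, support$supp_idx,
                      support$supp2_ptr, support$supp2_idx,
                      identical(config$feed, "corrected"))
    res$filtered <- unname(res$filtered)
    res$predicted <- unname(res$predicted)
    res
  } else {
    r_run_filter(model, conn, gains, k_eff, u, H, Z, config, support$mask)
  }
}

# Reference loop assembled from the exported step operations.
r_run_filter <- function(model, conn, gains, k_eff, u, H, Z, config, mask) {
  nv <- model$grid$n_voxels
  N <- 3L * nv
  ns <- nrow(H)
  nm <- nrow(Z)
  nc <- nrow(conn)
  Cmat <- transition_gains(model)
  Q <- diag(config$q_diag, N)
  R <- diag(config$r_diag, ns)
  P <- diag(config$p0_diag, N)
  P[!mask] <- 0
  Jc <- matrix(0, nm, N); Jp <- matrix(0, nm, N)
  innov <- matrix(0, nm, ns); Zh <- matrix(0, nm, ns)
  y_prev <- matrix(0, max(nc, 1), 3)
  src_col <- 3L * (conn$src - 1L)
  feed_corrected <- identical(config$feed, "corrected")
  for (n in seq_len(nm)) {
    feed <- if (feed_corrected) Jc else Jp
    jp <- model$b * u[n]
    if (nc > 0) {
      for (cc in seq_len(nc)) {
        n1 <- n - k_eff[cc]
        x1 <- if (n1 >= 1) feed[n1, src_col[cc] + 1:3] else c(0, 0, 0)
        x2 <- if (n1 - 1 >= 1) feed[n1 - 1, src_col[cc] + 1:3] else c(0, 0, 0)
        y <- conn$a[cc] * (x1 - y_prev[cc, ]) + x2
        y_prev[cc, ] <- y
        d <- 3L * (conn$dst[cc] - 1L)
        jp[d + 1:3] <- jp[d + 1:3] + matrix(gains[cc, ], 3, 3) %*% y
      }
    }
    P <- predict_covariance(P, Q, Cmat, mask)
    ki <- gain_and_innovation(P, H, R)
    zh <- as.numeric(H %*% jp)
    jc <- correct_state(jp, ki$K, Z[n, ], zh)
    P <- correct_covariance(P, ki$K, H, mask)
    Jp[n, ] <- jp; Jc[n, ] <- jc
    Zh[n, ] <- zh; innov[n, ] <- Z[n, ] - zh
  }
  list(filtered = Jc, predicted = Jp, innovations = innov, z_hat = Zh,
       P_diag = diag(P))
}
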