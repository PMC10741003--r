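test_that("masked covariance operations match dense formulas on full support", {
  set.seed(5)
  N <- 6                              # 2 voxels: support covers all pairs
  mask <- matrix(TRUE, N, N)
  A <- matrix(rnorm(N * N), N)
  P <- crossprod(A) / N
  Cm <- matrix(rnorm(N * N, sd = 0.3), N)
  Q <- diag(0.01, N)
  expect_equal(predict_covariance(P, Q, Cm, mask),
               Cm %*% P %*% t(Cm) + Q, tolerance = 1e-12)
  # trivial cases
  expect_equal(predict_covariance(P, Q, 0 * Cm, mask), Q)
  expect_equal(predict_covariance(P, Q, diag(N), mask), P + Q)

  H <- matrix(rnorm(2 * N), 2, N)
  R <- diag(0.5, 2)
  ki <- gain_and_innovation(P, H, R)
  expect_equal(ki$S, H %*% P %*% t(H) + R, tolerance = 1e-12)
  expect_equal(ki$K, P %*% t(H) %*% solve(ki$S), tolerance = 1e-12)
  # P = 0 gives S = R and K = 0
  k0 <- gain_and_innovation(0 * P, H, R)
  expect_equal(k0$S, R)
  expect_equal(k0$K, matrix(0, N, 2))
  # huge R drives the gain to zero
  kinf <- gain_and_innovation(P, H, diag(1e12, 2))
  expect_lt(max(abs(kinf$K)), 1e-10)
  # singular S errors out naming an eigenvalue
  expect_error(gain_and_innovation(0 * P, H, 0 * R), "singular")

  expect_equal(correct_covariance(P, ki$K, H, mask),
               (diag(N) - ki$K %*% H) %*% P, tolerance = 1e-12)
  expect_equal(correct_covariance(P, 0 * ki$K, H, mask), P)
  expect_equal(correct_covariance(P, ki$K, 0 * H, mask), P)
})

test_that("state correction is the textbook update", {
  expect_equal(correct_state(1, matrix(0.5), 1.2, 1.0), 1.1)
  j <- rnorm(6); K <- matrix(rnorm(12), 6, 2); z <- rnorm(2); zp <- rnorm(2)
  expect_equal(correct_state(j, K, z, zp), as.numeric(j + K %*% (z - zp)))
  expect_equal(correct_state(j, K, z, z), j)
  expect_equal(correct_state(j, 0 * K, z, zp), j)
})

test_that("sparse filter equals an independent dense Kalman on pair2", {
  fx <- make_fixture("pair2")
  Zn <- add_noise(fx$Z_clean, ensd_fT = 40, fs = fx$fs, seed = 21)
  kc <- kalman_config(q_diag = 1e-3, r_diag = noise_sigma_pT(40, fx$fs)^2,
                      p0_diag = 1e-2)
  res <- run_filter(fx$model, fx$H, Zn, kc)
  oracle <- dense_kalman_oracle(fx$model, fx$H, Zn, kc)
  expect_lt(max(abs(res$filtered - oracle)), 1e-8)
  # compiled and plain-R paths agree
  res_r <- run_filter(fx$model, fx$H, Zn, kc, engine = "r")
  expect_lt(max(abs(res$filtered - res_r$filtered)), 1e-10)
  expect_lt(max(abs(res$P_diag - res_r$P_diag)), 1e-12)
})

test_that("noiseless self-generated data yields vanishing innovations", {
  fx <- make_fixture("chain3")
  kc <- kalman_config(q_diag = 1e-4, r_diag = 1e-6, p0_diag = 1e-2)
  res <- run_filter(fx$model, fx$H, fx$Z_clean, kc)
  burn <- 10
  expect_lt(max(abs(res$innovations[-(1:burn), ])),
            0.01 * max(abs(fx$Z_clean)))
})

test_that("with no uncertainty the filter reduces to the open-loop rollout", {
  fx <- make_fixture("sheet5x5", n_steps = 200)
  Zn <- add_noise(fx$Z_clean[1:200, ], 40, fx$fs, seed = 2)
  res <- run_filter(fx$model, fx$H, Zn,
                    kalman_config(q_diag = 0, r_diag = 1, p0_diag = 0))
  expect_equal(res$filtered, simulate_model(fx$model, 200), tolerance = 1e-12)
})

test_that("covariance support never grows and diag stays nonnegative", {
  fx <- make_fixture("sheet5x5", n_steps = 120)
  g <- fx$grid
  sup <- covariance_support(g)
  # mask structure: voxel pair in mask iff neighbors or identical
  for (v in c(1, 7, 13, 25)) {
    in_mask <- which(sup$mask[3 * (v - 1) + 1, c(TRUE, FALSE, FALSE)])
    expect_equal(in_mask, sort(c(v, neighbors(g, v))))
  }
  Zn <- add_noise(fx$Z_clean[1:120, ], 40, fx$fs, seed = 5)
  res <- run_filter(fx$model, fx$H, Zn, kalman_config(
    q_diag = 1e-3, r_diag = 1, p0_diag = 1e-2), engine = "r")
  expect_true(all(res$P_diag >= 0))
})

test_that("innovations shrink as measurement trust grows under model mismatch", {
  fx <- make_fixture("pair2")
  wrong <- fx$model
  live <- which(rowSums(abs(wrong$gains)) > 0 &
                wrong$connections$src != wrong$connections$dst)[1]
  wrong$gains[live, ] <- 0.5 * wrong$gains[live, ]
  rms <- sapply(c(1e6, 1e3, 1), function(r) {
    res <- run_filter(wrong, fx$H, fx$Z_clean,
                      kalman_config(q_diag = 1e-3, r_diag = r,
                                    p0_diag = 1e-2))
    sqrt(mean(res$innovations^2))
  })
  expect_true(all(diff(rms) < 0))
})
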