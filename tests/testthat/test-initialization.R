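test_that("pairwise delays follow distance over receiver velocity times fs", {
  g <- build_grid(c(2, 2, 1), 2.5)
  types <- c("atrium", "atrium", "atrium", "atrioventricular_node")
  # axial pair, receiver atrium at 1.1 m/s
  expect_equal(initial_delays(g, types, 1, 2, fs = 2000), 4.5455,
               tolerance = 1e-4)
  # diagonal pair: 2.5*sqrt(2) mm, receiver atrium
  expect_equal(initial_delays(g, types, 2, 3, fs = 2000),
               0.0025 * sqrt(2) / 1.1 * 2000, tolerance = 1e-12)
  expect_equal(initial_delays(g, types, 2, 3, fs = 2000), 6.4282,
               tolerance = 1e-4)
  # slow AV receiver
  expect_equal(initial_delays(g, types, 2, 4, fs = 2000),
               0.0025 / 0.012 * 2000, tolerance = 1e-12)
  expect_equal(initial_delays(g, types, 2, 4, fs = 2000), 416.67,
               tolerance = 1e-4)
  # sub-sample delays clamp to 1 with a warning
  expect_warning(
    tau <- initial_delays(g, c("his_purkinje", "his_purkinje", "atrium", "atrium"),
                          1, 2, fs = 500),
    "clamped")
  expect_equal(tau, 1)
  expect_error(initial_delays(g, types, 1, 2,
                              velocities = c(atrium = 0), fs = 2000))
})

test_that("chain3 wavefront reproduces the analytic activation cascade", {
  fx <- make_fixture("chain3")
  act <- fx$model$activation
  expect_equal(act$sigma_ms, c(0, 2.2727, 4.5455), tolerance = 1e-4)
  expect_equal(act$delta[1, ], c(1, 0, 0))
  expect_equal(act$delta[2, ], c(0, 1, 0))       # step along +y, unit L1
  expect_equal(act$parent, c(NA, 1L, 2L))
})

test_that("direction and gain arithmetic follows the wavefront rules", {
  # diagonal step: delta has unit L1 norm with equal components
  g <- build_grid(c(2, 2, 1), 2.5)
  types <- c("sinoatrial_node", "atrium", "atrium", "atrium")
  model <- build_model(g, types, fs = 2000, n_steps = 200,
                       control_params = list(rise_ms = 2, plateau_ms = 20,
                                             repol_ms = 10))
  act <- model$activation
  expect_equal(rowSums(abs(act$delta)), rep(1, 4))
  # child of the root along +x: delta=(1,0,0); C = delta_i outer sign(delta_o)
  conn <- model$connections
  r12 <- which(conn$src == 1 & conn$dst == 2)
  expect_equal(matrix(model$gains[r12, ], 3, 3),
               outer(c(1, 0, 0), c(1, 0, 0)))
  # diagonal child (voxel 4 at +x+y) connected from the root at equal time
  r14 <- which(conn$src == 1 & conn$dst == 4)
  expect_equal(matrix(model$gains[r14, ], 3, 3),
               outer(c(0.5, 0.5, 0), c(1, 0, 0)))
  # sign(0) = 0: columns for zero components of the parent direction vanish
  expect_true(all(matrix(model$gains[r14, ], 3, 3)[, 2:3] == 0))
})

test_that("wavefront matches the event-queue oracle on random sheets", {
  vel <- default_velocities()
  for (seed in 1:3) {
    set.seed(seed)
    g <- build_grid(c(4, 4, 1), 2.5)
    types <- sample(c("atrium", "ventricle", "his_purkinje"), 16, replace = TRUE)
    types[sample(16, 1)] <- "sinoatrial_node"
    model <- suppressWarnings(
      build_model(g, types, fs = 2000, n_steps = 120,
                  control_params = list(rise_ms = 2, plateau_ms = 10,
                                        repol_ms = 5)))
    oracle <- suppressWarnings(
      wavefront_oracle(g, types, vel, fs = 2000))
    expect_equal(model$activation$sigma_ms, oracle$sigma_ms, tolerance = 1e-9)
    expect_equal(model$activation$parent, oracle$parent)
  }
})

test_that("activation times are non-decreasing along the connection tree", {
  cfg <- mcg_config("reduced")
  geo <- build_geometry(cfg)
  types <- assign_default_types(geo$grid, cfg$layout)
  model <- suppressWarnings(
    build_model(geo$grid, types, cfg$fs, cfg$n_steps,
                control_params = cfg$control))
  act <- model$activation
  kids <- which(!is.na(act$parent))
  expect_true(all(act$sigma_ms[kids] > act$sigma_ms[act$parent[kids]]))
  # each connected voxel has exactly one parent; pathological ones none
  expect_true(all(is.na(act$sigma_ms[types == "pathological"])))
  expect_true(all(!is.na(act$sigma_ms[types != "pathological"])))
})

test_that("control vector drives exactly the sinoatrial x component", {
  g <- build_grid(c(2, 1, 1), 2.5)
  b <- control_vector(g, c("atrium", "sinoatrial_node"))
  expect_equal(sum(b), 1)
  expect_equal(which(b == 1), 4L)    # x component of voxel 2
  expect_error(control_vector(g, c("ventricle", "ventricle")), "sinoatrial")
})

test_that("model building is deterministic and single-voxel models are drive-only", {
  g <- build_grid(c(1, 1, 1), 2.5)
  m <- build_model(g, "sinoatrial_node", fs = 2000, n_steps = 150,
                   control_params = list(rise_ms = 2, plateau_ms = 20,
                                         repol_ms = 10))
  expect_equal(sum(m$connections$src != m$connections$dst), 0)
  expect_equal(which(m$b == 1), 1L)

  fx1 <- make_fixture("sheet5x5")
  fx2 <- make_fixture("sheet5x5")
  expect_identical(fx1$model$gains, fx2$model$gains)
  expect_identical(fx1$model$connections, fx2$model$connections)
  expect_identical(fx1$J, fx2$J)
})
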