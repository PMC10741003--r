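single_voxel_setup <- function(orientation) {
  grid <- build_grid(c(1, 1, 1), 2.5, origin = c(-1.25, -1.25, -1.25))
  sensors <- build_sensor_array(c(1, 1, 1), c(0, 0, 0), c(0, 0, 200),
                                triaxial = FALSE, orientation = orientation)
  list(grid = grid, sensors = sensors)
}

test_that("Biot-Savart entry matches the hand-evaluated SI value", {
  s <- single_voxel_setup(c(0, 1, 0))
  H <- measurement_matrix(s$grid, s$sensors, scale = 1,
                          current_unit = "A/mm^2", field_unit = "T")
  # mu0/4pi * 1e6 * V / r^2 for a unit x current seen by a y sensor above
  expect_equal(H[1, 1], -3.90625e-8, tolerance = 1e-10 / 3.90625e-8)
  expect_equal(H[1, 3], 0)           # z current: j x r_hat has no y part
})

test_that("field obeys orthogonality, 1/r^2 decay, and scale linearity", {
  s <- single_voxel_setup(c(0, 0, 1))
  Hz <- measurement_matrix(s$grid, s$sensors, scale = 1,
                           current_unit = "A/mm^2", field_unit = "T")
  expect_equal(Hz[1, 1], 0)          # o parallel to r_hat: o . (j x r_hat) = 0

  s2 <- single_voxel_setup(c(0, 1, 0))
  H200 <- measurement_matrix(s2$grid, s2$sensors, scale = 1,
                             current_unit = "A/mm^2", field_unit = "T")
  far <- build_sensor_array(c(1, 1, 1), c(0, 0, 0), c(0, 0, 400),
                            triaxial = FALSE, orientation = c(0, 1, 0))
  H400 <- measurement_matrix(s2$grid, far, scale = 1,
                             current_unit = "A/mm^2", field_unit = "T")
  expect_equal(H400[1, 1] * 4, H200[1, 1], tolerance = 1e-12)

  H7 <- measurement_matrix(s2$grid, s2$sensors, scale = 7,
                           current_unit = "A/mm^2", field_unit = "T")
  expect_equal(H7, 7 * H200, tolerance = 1e-14)
  HpT <- measurement_matrix(s2$grid, s2$sensors, scale = 1,
                            current_unit = "A/mm^2", field_unit = "pT")
  expect_equal(HpT, 1e12 * H200, tolerance = 1e-14)
})

test_that("opposite currents at mirrored positions cancel on the symmetry plane", {
  grid <- build_grid(c(2, 1, 1), 2.5, origin = c(-2.5, -1.25, -1.25))
  # sensor on the x = 0 plane, oriented along y
  sensors <- build_sensor_array(c(1, 1, 1), c(0, 0, 0), c(0, 0, 150),
                                triaxial = FALSE, orientation = c(0, 1, 0))
  H <- measurement_matrix(grid, sensors)
  j <- c(1, 0, 0, -1, 0, 0)          # equal and opposite x currents
  expect_equal(as.numeric(predict_measurements(H, matrix(j, 1))), 0,
               tolerance = 1e-25)
})

test_that("measurement prediction is linear and shape-checked", {
  fx <- make_fixture("pair2")
  J <- fx$J
  expect_equal(predict_measurements(fx$H, 0 * J), 0 * fx$Z_clean)
  expect_equal(predict_measurements(fx$H, 2.5 * J), 2.5 * fx$Z_clean)
  expect_error(predict_measurements(fx$H, J[, 1:3]), "columns")
})

test_that("sensor-voxel coincidence is rejected", {
  grid <- build_grid(c(1, 1, 1), 2.5)
  sensors <- build_sensor_array(c(1, 1, 1), c(0, 0, 0), c(1.25, 1.25, 1.25),
                                triaxial = FALSE)
  expect_error(measurement_matrix(grid, sensors), "coincides")
})

test_that("pseudoinverse reproduces orthogonal, random, and in-range cases", {
  # orthonormal square H: pseudoinverse estimate equals H^T z
  th <- 0.3
  Hq <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  Z <- matrix(rnorm(10), 5, 2)
  expect_equal(pseudoinverse_estimate(Hq, Z), Z %*% Hq, tolerance = 1e-12)

  # random underdetermined H against the independent MASS::ginv oracle
  set.seed(11)
  H <- matrix(rnorm(21), 3, 7)
  Z2 <- matrix(rnorm(12), 4, 3)
  expect_equal(pseudoinverse_estimate(H, Z2), ginv_estimate(H, Z2),
               tolerance = 1e-10)

  # noiseless in-range measurements: residual vanishes
  Jtrue <- matrix(rnorm(14), 2, 7)
  Zr <- Jtrue %*% t(H)
  Jhat <- pseudoinverse_estimate(H, Zr)
  expect_lt(max(abs(Zr - Jhat %*% t(H))), 1e-10 * max(abs(Zr)))

  # minimum-norm property: any least-squares solution has larger 2-norm
  j0 <- as.numeric(pseudoinverse_estimate(H, Zr[1, , drop = FALSE]))
  ns_basis <- svd(H, nv = 7)$v[, 4:7]
  for (i in 1:4) {
    alt <- j0 + 0.1 * ns_basis[, i]
    expect_lt(sum(j0^2), sum(alt^2))
    # the perturbation stays a least-squares minimizer
    expect_equal(as.numeric(H %*% alt), Zr[1, ], tolerance = 1e-10)
  }

  # overdetermined full-rank noiseless: exact recovery
  H3 <- matrix(rnorm(30), 10, 3)
  J3 <- matrix(rnorm(6), 2, 3)
  expect_equal(pseudoinverse_estimate(H3, J3 %*% t(H3)), J3, tolerance = 1e-10)
})
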