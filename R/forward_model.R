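#' Biot-Savart measurement (lead-field) matrix
#'
#' Maps the concatenated per-voxel current densities
#' `j = (j_1x, j_1y, j_1z, j_2x, ...)` to the sensor readings `z = H j` by
#' superposition of the Biot-Savart law over voxels: the entry for channel
#' `i`, voxel `k`, component `c` is
#' `scale * (mu0 / 4 pi) * o_i . (e_c x r_hat) / |r|^2 * V`,
#' with `r = p_sensor - p_voxel`, evaluated in SI units internally
#' (`mu0 = 4 pi 1e-7` T m/A).
#'
#' The numeric value of a current density depends on its unit;
#' `current_unit = "A/mm^2"` applies the 1e6 conversion to A/m^2, while
#' `"A/m^2"` (the default, used by the shipped experiment for its normalized
#' current amplitudes) applies none. `field_unit` selects Tesla or picoTesla
#' output.
#'
#' @param grid A [build_grid()] object (positions in mm).
#' @param sensors A [build_sensor_array()] object (positions in mm).
#' @param scale Dimensionless global gain folded into H (the study's
#'   one-layer amplitude calibration factor; 1 for the bare physical map).
#' @param current_unit Unit the current-density numbers are expressed in.
#' @param field_unit Unit of the returned field values.
#' @param min_distance_mm Sensor-voxel distances below this are an error
#'   (Biot-Savart singularity).
#' @return Ns x 3Nv matrix; column block `3(k-1)+1 .. 3k` belongs to voxel k.
#' @export
measurement_matrix <- function(grid, sensors, scale = 1,
                               current_unit = c("A/m^2", "A/mm^2"),
                               field_unit = c("T", "pT"),
                               min_distance_mm = 1) {
  current_unit <- match.arg(current_unit)
  field_unit <- match.arg(field_unit)
  ps <- sensors$positions / 1000       # m
  pv <- grid$positions / 1000          # m
  os <- sensors$orientations
  vol <- grid$volume * 1e-9            # mm^3 -> m^3
  ns <- nrow(ps); nv <- nrow(pv)
  unit_fac <- if (current_unit == "A/mm^2") 1e6 else 1
  out_fac <- if (field_unit == "pT") 1e12 else 1
  mu0_4pi <- 1e-7

  H <- matrix(0, ns, 3L * nv)
  for (i in seq_len(ns)) {
    r <- matrix(ps[i, ], nv, 3, byrow = TRUE) - pv      # Nv x 3
    d2 <- rowSums(r^2)
    if (any(d2 < (min_distance_mm / 1000)^2))
      stop("sensor coincides with (or is closer than `min_distance_mm` to) a voxel center")
    d <- sqrt(d2)
    rh <- r / d
    o <- os[i, ]
    # o . (e_c x r_hat) = (r_hat x o)_c  (scalar triple product rotation)
    cxr <- cbind(rh[, 2] * o[3] - rh[, 3] * o[2],
                 rh[, 3] * o[1] - rh[, 1] * o[3],
                 rh[, 1] * o[2] - rh[, 2] * o[1])
    w <- scale * mu0_4pi * vol * unit_fac * out_fac / d2
    H[i, ] <- as.vector(t(cxr * w))
  }
  H
}

#' Predict sensor measurements from a current-density trajectory
#'
#' Applies `z(n) = H j(n)` for every time step.
#'
#' @param H Measurement matrix (Ns x 3Nv), see [measurement_matrix()].
#' @param J Nm x 3Nv matrix; row n holds all current densities at step n.
#' @return Nm x Ns matrix of predicted readings.
#' @export
predict_measurements <- function(H, J) {
  J <- as.matrix(J)
  if (ncol(J) != ncol(H))
    stop(sprintf("J has %d columns but H expects %d", ncol(J), ncol(H)))
  J %*% t(H)
}

#' Minimum-norm pseudoinverse estimate
#'
#' The baseline solution of the ill-posed inverse problem: per time step the
#' Moore-Penrose minimum-norm least-squares estimate `j = H^+ z`, computed
#' through a truncated SVD. Singular values below
#' `svd_tolerance * max(singular value)` are discarded.
#'
#' @param H Measurement matrix.
#' @param Z Nm x Ns measurement matrix (rows are time steps).
#' @param svd_tolerance Relative truncation threshold.
#' @return Nm x 3Nv matrix of estimated current densities.
#' @export
pseudoinverse_estimate <- function(H, Z, svd_tolerance = 1e-10) {
  Z <- as.matrix(Z)
  if (ncol(Z) != nrow(H))
    stop(sprintf("Z has %d channels but H has %d rows", ncol(Z), nrow(H)))
  sv <- svd(H)
  keep <- sv$d > svd_tolerance * sv$d[1]
  # H^+ = V D^-1 U^T on the retained subspace; J^T = H^+ Z^T
  Hp <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  Z %*% t(Hp)
}
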