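#' Build a regular magnetometer array
#'
#' Sensor sites lie on a regular lattice spanning `extent` and centered on
#' `center`; along an axis with `k > 1` sites the spacing is
#' `extent / (k - 1)` (sites at both faces), a single site sits at the
#' center. With `triaxial = TRUE` each site contributes three channels with
#' orientations (1,0,0), (0,1,0), (0,0,1); otherwise one channel per site
#' with the given `orientation`.
#'
#' @param grid_counts Integer triple: number of sites along x, y, z.
#' @param extent 3-vector, mm: spanned region.
#' @param center 3-vector, mm: center of the region.
#' @param triaxial One channel per axis per site?
#' @param orientation Unit 3-vector used when `triaxial = FALSE`.
#' @return A `sensor_array` object with `positions` (Ns x 3, mm) and
#'   `orientations` (Ns x 3, unit vectors), plus `n_channels`.
#' @export
build_sensor_array <- function(grid_counts, extent, center,
                               triaxial = TRUE, orientation = c(0, 0, 1)) {
  grid_counts <- as.integer(grid_counts)
  if (length(grid_counts) != 3L || any(grid_counts < 1L))
    stop("`grid_counts` must be three integers >= 1")
  ax <- function(k, span, mid) {
    if (k == 1L) mid else seq(mid - span / 2, mid + span / 2, length.out = k)
  }
  sites <- as.matrix(expand.grid(
    x = ax(grid_counts[1], extent[1], center[1]),
    y = ax(grid_counts[2], extent[2], center[2]),
    z = ax(grid_counts[3], extent[3], center[3])
  ))
  if (triaxial) {
    positions <- sites[rep(seq_len(nrow(sites)), each = 3L), , drop = FALSE]
    orientations <- matrix(rep(t(diag(3)), nrow(sites)), ncol = 3, byrow = TRUE)
  } else {
    orientation <- orientation / sqrt(sum(orientation^2))
    positions <- sites
    orientations <- matrix(orientation, nrow(sites), 3, byrow = TRUE)
  }
  dimnames(positions) <- list(NULL, c("x", "y", "z"))
  dimnames(orientations) <- list(NULL, c("x", "y", "z"))
  structure(list(positions = positions, orientations = orientations,
                 n_channels = nrow(positions)),
            class = "sensor_array")
}

#' @export
print.sensor_array <- function(x, ...) {
  cat(sprintf("<sensor_array> %d channels\n", x$n_channels))
  invisible(x)
}
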