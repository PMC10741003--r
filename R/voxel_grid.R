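#' Electrophysiological voxel types
#'
#' The six tissue classes used by the propagation model, together with their
#' default conduction velocities. `pathological` voxels conduct nothing: they
#' are never connected to their neighbors and never excited.
#'
#' @return Character vector of the six type names, in canonical order.
#' @export
voxel_types <- function() {
  c("sinoatrial_node", "atrium", "atrioventricular_node",
    "his_purkinje", "ventricle", "pathological")
}

#' Default conduction velocity table
#'
#' Velocities in m/s per voxel type: 1.1 m/s for sinoatrial node, atrium and
#' ventricle, 0.012 m/s for the atrioventricular node (the slow junction that
#' produces the PR delay) and 4.5 m/s for the His-Purkinje system.
#' `pathological` tissue does not conduct; its entry is `NA` and is never used.
#'
#' @return Named numeric vector (m/s), names as in [voxel_types()].
#' @export
default_velocities <- function() {
  c(sinoatrial_node = 1.1, atrium = 1.1, atrioventricular_node = 0.012,
    his_purkinje = 4.5, ventricle = 1.1, pathological = NA_real_)
}

#' Build a regular voxel grid
#'
#' Voxel centers lie on a regular lattice: voxel `(ix, iy, iz)` (1-based) has
#' center `origin + (c(ix, iy, iz) - 0.5) * voxel_size`. The linear voxel
#' index runs x fastest, then y, then z, i.e.
#' `v = ix + (iy - 1) * nx + (iz - 1) * nx * ny`.
#'
#' @param dims Integer triple `(nx, ny, nz)`, each >= 1.
#' @param voxel_size Edge length of the cubic voxels in mm.
#' @param origin 3-vector, mm; corner of the grid volume.
#' @return A `voxel_grid` object with elements `dims`, `voxel_size`, `origin`,
#'   `positions` (Nv x 3 matrix of centers, mm), `volume` (mm^3) and `n_voxels`.
#' @export
build_grid <- function(dims, voxel_size, origin = c(0, 0, 0)) {
  dims <- as.integer(dims)
  if (length(dims) != 3L || any(is.na(dims)) || any(dims < 1L))
    stop("`dims` must be three integers >= 1")
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0)
    stop("`voxel_size` must be a positive scalar (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("`origin` must be a finite 3-vector (mm)")
  nv <- prod(dims)
  idx <- grid_indices(dims)
  positions <- sweep((idx - 0.5) * voxel_size, 2, origin, `+`)
  colnames(positions) <- c("x", "y", "z")
  structure(list(
    dims = dims, voxel_size = voxel_size, origin = as.numeric(origin),
    positions = positions, volume = voxel_size^3, n_voxels = nv
  ), class = "voxel_grid")
}

# Nv x 3 matrix of 1-based lattice indices, x fastest.
grid_indices <- function(dims) {
  cbind(
    ix = rep_len(seq_len(dims[1]), prod(dims)),
    iy = rep(rep(seq_len(dims[2]), each = dims[1]), times = dims[3]),
    iz = rep(seq_len(dims[3]), each = dims[1] * dims[2])
  )
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("<voxel_grid> %d x %d x %d voxels of %.3g mm (Nv = %d)\n",
              x$dims[1], x$dims[2], x$dims[3], x$voxel_size, x$n_voxels))
  invisible(x)
}

#' 26-neighborhood of a voxel
#'
#' All voxels whose lattice offset from `v` lies in `{-1,0,1}^3` minus the
#' origin, clipped at the grid boundary. The result is sorted ascending, so
#' the relation is deterministic and symmetric.
#'
#' @param grid A [build_grid()] object.
#' @param v Voxel index (1-based).
#' @return Integer vector of neighbor indices (possibly empty).
#' @export
neighbors <- function(grid, v) {
  nv <- grid$n_voxels
  if (length(v) != 1L || is.na(v) || v < 1L || v > nv)
    stop("voxel index out of range")
  d <- grid$dims
  i0 <- linear_to_lattice(v, d)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, , drop = FALSE]
  cand <- sweep(off, 2, i0, `+`)
  keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
          cand[, 2] >= 1 & cand[, 2] <= d[2] &
          cand[, 3] >= 1 & cand[, 3] <= d[3]
  cand <- cand[keep, , drop = FALSE]
  sort(lattice_to_linear(cand, d))
}

linear_to_lattice <- function(v, dims) {
  v0 <- v - 1L
  ix <- v0 %% dims[1]
  iy <- (v0 %/% dims[1]) %% dims[2]
  iz <- v0 %/% (dims[1] * dims[2])
  c(ix, iy, iz) + 1L
}

lattice_to_linear <- function(idx, dims) {
  idx <- matrix(as.integer(idx), ncol = 3)
  idx[, 1] + (idx[, 2] - 1L) * dims[1] + (idx[, 3] - 1L) * dims[1] * dims[2]
}

#' Full adjacency list of a grid
#'
#' @param grid A [build_grid()] object.
#' @return List of length Nv; element `v` holds `neighbors(grid, v)`.
#' @export
adjacency_list <- function(grid) {
  lapply(seq_len(grid$n_voxels), function(v) neighbors(grid, v))
}
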