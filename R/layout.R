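#' Default one-layer heart sheet layout
#'
#' Region extents for the simulated "unrolled" heart sheet, expressed as
#' fractions of the grid dimensions so the same layout can be rendered at any
#' resolution. The sheet has the atria at the top (high y), the ventricles
#' below, a one-voxel-thick atrioventricular (AV) node block on the boundary
#' row, a T-shaped His-Purkinje tree (septal trunk plus an apical branch row)
#' and a small sinoatrial (SA) node block inside the atria. The optional
#' pathological patch -- a non-conducting region standing in for
#' arrhythmogenic tissue -- sits in the right ventricle (viewer's left).
#'
#' All bounds are inclusive fractional coordinates in `[0, 1]`; they are
#' converted to voxel index ranges with `round()` when the layout is applied.
#'
#' @param with_patch Include the pathological patch (the "ground truth"
#'   layout)? With `FALSE` the healthy "initial model" layout is produced.
#' @return A plain list of layout parameters, suitable for serialization.
#' @export
default_layout <- function(with_patch = TRUE) {
  list(
    atria_y = c(0.70, 1.00),
    sa_x = c(0.12, 0.20), sa_y = c(0.86, 0.93),
    av_x = c(0.46, 0.54),                    # one row thick, just below atria
    his_branch_y = 0.10,                     # apical branch row(s); may be a vector
    his_branch_x = c(0.15, 0.85),
    patch = if (with_patch) list(x = c(0.15, 0.32), y = c(0.30, 0.46)) else NULL
  )
}

frac_to_rows <- function(frac, n) {
  lo <- max(1L, round(frac[1] * n))
  hi <- min(n, round(frac[length(frac)] * n))
  if (hi < lo) lo <- hi
  lo:hi
}

#' Assign voxel types on a one-layer sheet
#'
#' Renders a [default_layout()] (or a modified copy of one) onto a one-layer
#' grid. Every voxel receives exactly one type; the pathological patch, when
#' present, only overwrites ventricular voxels (a patch reaching outside the
#' ventricle region is clipped with a warning).
#'
#' @param grid A [build_grid()] object with `dims[3] == 1`.
#' @param layout Layout parameter list, see [default_layout()].
#' @return Character vector of length Nv with values from [voxel_types()].
#' @export
assign_default_types <- function(grid, layout = default_layout()) {
  if (grid$dims[3] != 1L)
    stop("the default layout is defined for one-layer grids (nz = 1)")
  nx <- grid$dims[1]; ny <- grid$dims[2]
  idx <- grid_indices(grid$dims)
  ix <- idx[, 1]; iy <- idx[, 2]
  types <- rep("ventricle", grid$n_voxels)

  atria_rows <- frac_to_rows(layout$atria_y, ny)
  types[iy %in% atria_rows] <- "atrium"

  av_row <- min(atria_rows) - 1L
  if (av_row < 1L) stop("layout leaves no room for the AV node row")
  av_cols <- frac_to_rows(layout$av_x, nx)
  types[iy == av_row & ix %in% av_cols] <- "atrioventricular_node"

  branch_rows <- pmax(2L, round(layout$his_branch_y * ny))
  trunk_col <- as.integer(ceiling(nx / 2))
  trunk_rows <- min(branch_rows):(av_row - 1L)
  types[ix == trunk_col & iy %in% trunk_rows] <- "his_purkinje"
  branch_cols <- frac_to_rows(layout$his_branch_x, nx)
  types[iy %in% branch_rows & ix %in% branch_cols] <- "his_purkinje"

  sa_cols <- frac_to_rows(layout$sa_x, nx)
  sa_rows <- frac_to_rows(layout$sa_y, ny)
  sa <- ix %in% sa_cols & iy %in% sa_rows
  if (!any(sa)) stop("layout produces no sinoatrial voxel")
  types[sa] <- "sinoatrial_node"

  if (!is.null(layout$patch)) {
    p_cols <- frac_to_rows(layout$patch$x, nx)
    p_rows <- frac_to_rows(layout$patch$y, ny)
    p <- ix %in% p_cols & iy %in% p_rows
    if (any(p & types != "ventricle")) {
      warning("pathological patch clipped to the ventricle region")
      p <- p & types == "ventricle"
    }
    types[p] <- "pathological"
  }
  types
}

#' Directed connectivity between voxel types
#'
#' The allowed propagation steps between neighboring voxels, as a directed
#' predicate on (source type, target type). The default relation is:
#' SA -> SA, SA -> atrium, atrium -> atrium, atrium -> AV, AV -> His,
#' His -> His, His -> ventricle, ventricle -> ventricle. Pathological voxels
#' have no connections in either direction, so they are never excited.
#' A direct atrium -> ventricle step is not allowed: propagation must pass
#' through the AV node and the His-Purkinje system.
#'
#' @param extra Optional character matrix / data.frame with columns
#'   `from`, `to` of additional allowed pairs (config override).
#' @return A 6 x 6 logical matrix `allowed[from, to]` with dimnames from
#'   [voxel_types()].
#' @export
type_connectivity <- function(extra = NULL) {
  tv <- voxel_types()
  allowed <- matrix(FALSE, 6, 6, dimnames = list(from = tv, to = tv))
  pairs <- rbind(
    c("sinoatrial_node", "sinoatrial_node"),
    c("sinoatrial_node", "atrium"),
    c("atrium", "atrium"),
    c("atrium", "atrioventricular_node"),
    c("atrioventricular_node", "his_purkinje"),
    c("his_purkinje", "his_purkinje"),
    c("his_purkinje", "ventricle"),
    c("ventricle", "ventricle")
  )
  if (!is.null(extra)) pairs <- rbind(pairs, as.matrix(extra))
  for (r in seq_len(nrow(pairs))) allowed[pairs[r, 1], pairs[r, 2]] <- TRUE
  allowed["pathological", ] <- FALSE
  allowed[, "pathological"] <- FALSE
  allowed
}
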