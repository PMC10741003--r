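#' Per-voxel activity map
#'
#' For each voxel, the maximum over time of the L1 norm of its 3-vector
#' current density -- the quantity the threshold segmentation operates on.
#' In the control-normalized unit system healthy voxels peak near 1 and
#' non-conducting voxels stay near 0.
#'
#' @param J Nm x 3Nv current-density trajectory.
#' @return Numeric vector of length Nv (>= 0).
#' @export
activity_map <- function(J) {
  J <- as.matrix(J)
  nv <- ncol(J) / 3L
  if (nrow(J) == 0) return(numeric(nv))
  l1 <- abs(J[, seq(1, 3 * nv, by = 3), drop = FALSE]) +
        abs(J[, seq(2, 3 * nv, by = 3), drop = FALSE]) +
        abs(J[, seq(3, 3 * nv, by = 3), drop = FALSE])
  apply(l1, 2, max)
}

#' Threshold segmentation of an activity map
#'
#' A voxel is classified `pathological` when its activity is strictly below
#' the threshold, `healthy` otherwise (ties are healthy).
#'
#' @param map Activity map from [activity_map()].
#' @param threshold Segmentation threshold (>= 0), normalized units;
#'   0 classifies everything healthy.
#' @return Character vector of labels (`"healthy"` / `"pathological"`).
#' @export
segment <- function(map, threshold) {
  if (threshold < 0) stop("threshold must be >= 0")
  ifelse(map < threshold, "pathological", "healthy")
}

#' Score a segmentation against ground truth
#'
#' Confusion counts and DICE / recall / precision with `pathological` as the
#' positive class. With no positive truth voxels the three metrics are
#' undefined and reported as `NaN` with a warning.
#'
#' @param labels Predicted labels (`"healthy"` / `"pathological"`).
#' @param truth True labels, same length and coding.
#' @param threshold Optional threshold to record in the report.
#' @return A `segmentation_report` list: `tp`, `fp`, `tn`, `fn`, `dice`,
#'   `recall`, `precision`, `threshold`.
#' @export
score_segmentation <- function(labels, truth, threshold = NA_real_) {
  if (length(labels) != length(truth)) stop("label vectors differ in length")
  pos <- truth == "pathological"
  pred <- labels == "pathological"
  tp <- sum(pred & pos); fp <- sum(pred & !pos)
  fn <- sum(!pred & pos); tn <- sum(!pred & !pos)
  if (tp + fn == 0) {
    warning("no pathological voxels in truth: metrics undefined")
    dice <- recall <- precision <- NaN
  } else {
    dice <- 2 * tp / (2 * tp + fp + fn)
    recall <- tp / (tp + fn)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NaN
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, dice = dice,
                 recall = recall, precision = precision,
                 threshold = threshold),
            class = "segmentation_report")
}

#' @export
print.segmentation_report <- function(x, ...) {
  cat(sprintf(
    "<segmentation_report> threshold %.3g | DICE %.3f recall %.3f precision %.3f (TP %d FP %d TN %d FN %d)\n",
    x$threshold, x$dice, x$recall, x$precision, x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Sweep the segmentation threshold
#'
#' Evaluates the DICE score on a regular threshold grid and returns the full
#' curve together with the maximizing threshold (ties broken toward the
#' lowest threshold).
#'
#' @param map Activity map.
#' @param truth True labels.
#' @param lo,hi Grid range (inclusive), `lo < hi`.
#' @param step Grid spacing.
#' @return List: `best_threshold`, `best_dice`, `curve` (data frame with
#'   `threshold`, `dice`), `best_report`.
#' @export
threshold_sweep <- function(map, truth, lo = 0.6, hi = 1.0, step = 0.01) {
  if (lo >= hi) stop("need lo < hi")
  grid <- seq(lo, hi, by = step)
  dice <- vapply(grid, function(th)
    score_segmentation(segment(map, th), truth, th)$dice, numeric(1))
  best <- which.max(dice)        # first maximum = lowest threshold on ties
  list(best_threshold = grid[best], best_dice = dice[best],
       curve = data.frame(threshold = grid, dice = dice),
       best_report = score_segmentation(segment(map, grid[best]), truth,
                                        grid[best]))
}
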