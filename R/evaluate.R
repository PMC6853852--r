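boundary_rows <- function(b) {
  if (inherits(b, "oct_boundary")) b$rows else as.numeric(b)
}

#' Mean absolute deviation between two boundaries
#'
#' Symmetric nearest-point distance between the two boundary curves, read as
#' 2D pixel point sets `(row_i, col_i)`:
#' `0.5 * (mean_i d(gt_i, SEG) + mean_j d(seg_j, GT))`
#' with Euclidean distances in pixel units. Zero iff the boundaries
#' coincide; symmetric in its arguments.
#'
#' @param seg,gt Boundaries (`oct_boundary` or numeric per-column row
#'   vectors of equal length).
#' @return Non-negative scalar, in pixels.
#' @examples
#' boundary_mad(rep(10, 6), rep(13, 6))  # 3
#' @export
boundary_mad <- function(seg, gt) {
  a <- boundary_rows(seg)
  b <- boundary_rows(gt)
  if (length(a) == 0L || length(b) == 0L)
    stop("undefined metric: empty boundary point set")
  ca <- seq_along(a)
  cb <- seq_along(b)
  d2 <- outer(a, b, "-")^2 + outer(ca, cb, "-")^2
  d <- sqrt(d2)
  0.5 * (mean(apply(d, 2L, min)) + mean(apply(d, 1L, min)))
}

#' Root mean squared error between two boundaries
#'
#' Per-column row differences: `sqrt(mean((seg_i - gt_i)^2))`, in pixels.
#'
#' @inheritParams boundary_mad
#' @return Non-negative scalar, in pixels.
#' @export
boundary_rmse <- function(seg, gt) {
  a <- boundary_rows(seg)
  b <- boundary_rows(gt)
  if (length(a) != length(b))
    stop("boundaries must have the same number of columns")
  sqrt(mean((a - b)^2))
}

#' Dice overlap coefficient of two binary masks
#'
#' `2 |GT & SEG| / (|GT| + |SEG|)`: 1 for identical non-empty masks, 0 for
#' disjoint ones.
#'
#' @param seg,gt Same-shape logical (or 0/1) matrices.
#' @return Scalar in `[0, 1]`.
#' @export
dice_coefficient <- function(seg, gt) {
  seg <- as.logical(seg)
  gt <- as.logical(gt)
  if (length(seg) != length(gt)) stop("masks must have the same shape")
  ns <- sum(seg)
  ng <- sum(gt)
  if (ns + ng == 0L) stop("undefined metric: both masks are empty")
  2 * sum(seg & gt) / (ns + ng)
}

#' Pixel-wise confusion metrics of a segmented region
#'
#' Counts true/false positives/negatives of `seg` against `gt` and returns
#' `accuracy = (TP + TN) / (TP + FP + FN + TN)`,
#' `sensitivity = TP / (TP + FN)` (true positive rate) and
#' `error_rate = FP / (FP + TN)` (false positive rate). A degenerate
#' denominator raises an error naming the affected ratio.
#'
#' @inheritParams dice_coefficient
#' @return Named numeric vector `accuracy`, `sensitivity`, `error_rate`.
#' @examples
#' gt <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
#' confusion_metrics(gt, gt)
#' @export
confusion_metrics <- function(seg, gt) {
  seg <- as.logical(seg)
  gt <- as.logical(gt)
  if (length(seg) != length(gt)) stop("masks must have the same shape")
  tp <- sum(seg & gt)
  tn <- sum(!seg & !gt)
  fp <- sum(seg & !gt)
  fn <- sum(!seg & gt)
  if (tp + fn == 0L) stop("undefined metric: sensitivity has TP + FN = 0")
  if (fp + tn == 0L) stop("undefined metric: error rate has FP + TN = 0")
  c(accuracy = (tp + tn) / (tp + fp + fn + tn),
    sensitivity = tp / (tp + fn),
    error_rate = fp / (fp + tn))
}

#' Evaluate a segmentation against ground-truth boundaries
#'
#' Computes per-boundary MAD and RMSE, per-layer Dice, and the retinal nerve
#' fibre layer thickness (RNFLT, the band between ILM and NFL-GCL) accuracy,
#' sensitivity, error rate and Dice — the band most relevant to glaucoma
#' diagnosis. Both inputs must be in the same coordinate frame; the
#' segmentation's boundaries are exported in original (pre-crop) coordinates.
#'
#' @param seg An `oct_segmentation` or `W x 8` boundary-row matrix.
#' @param gt Ground truth `W x 8` boundary-row matrix (same frame).
#' @param height Full image height of that frame.
#' @return An `oct_eval` list: `boundaries` (data.frame with `mad`, `rmse`
#'   per boundary), `layer_dice` (named vector, 7 layers), and `rnflt`
#'   (accuracy, sensitivity, error_rate, dice).
#' @export
evaluate_segmentation <- function(seg, gt, height) {
  segm <- if (inherits(seg, "oct_segmentation"))
    boundary_matrix(seg, original_coords = TRUE) else as.matrix(seg)
  gtm <- as.matrix(gt)
  if (!all(dim(segm) == dim(gtm)))
    stop("segmentation and ground truth must cover the same columns and boundaries")
  labs <- boundary_labels()
  bdf <- data.frame(
    boundary = labs,
    mad = vapply(seq_len(8L), function(k) boundary_mad(segm[, k], gtm[, k]),
                 numeric(1)),
    rmse = vapply(seq_len(8L), function(k) boundary_rmse(segm[, k], gtm[, k]),
                  numeric(1)),
    row.names = NULL
  )
  sm <- layer_masks(segm, height = height)
  gm <- layer_masks(gtm, height = height)
  ld <- vapply(layer_labels(),
               function(l) dice_coefficient(sm[[l]], gm[[l]]), numeric(1))
  rn <- confusion_metrics(sm[["NFL"]], gm[["NFL"]])
  rn <- c(rn, dice = dice_coefficient(sm[["NFL"]], gm[["NFL"]]))
  structure(list(boundaries = bdf, layer_dice = ld, rnflt = rn),
            class = "oct_eval")
}

#' @export
print.oct_eval <- function(x, ...) {
  cat("<oct_eval>\n")
  print(x$boundaries, row.names = FALSE)
  cat("layer Dice:\n")
  print(round(x$layer_dice, 4))
  cat("RNFLT:\n")
  print(round(x$rnflt, 4))
  invisible(x)
}
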