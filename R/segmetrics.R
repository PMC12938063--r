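#' Pixel-wise confusion counts between two masks
#'
#' @param pred,truth Binary matrices of the same shape.
#' @return Named list `TP`, `FP`, `FN`, `TN` (pixel counts).
#' @export
confusion <- function(pred, truth) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) stop_aaawall("mask shape mismatch")
  p <- pred > 0.5; t <- truth > 0.5
  list(TP = sum(p & t), FP = sum(p & !t), FN = sum(!p & t), TN = sum(!p & !t))
}

#' Overlap metrics from confusion counts
#'
#' Computes accuracy, sensitivity, precision, specificity, Dice (DSC),
#' IoU and Matthews correlation. Degenerate denominators follow the
#' common convention: a ratio whose defining sets are all empty is 1
#' (perfect agreement on "nothing"), and 0 when exactly one side is
#' empty.
#'
#' @param counts List with `TP`, `FP`, `FN`, `TN` (from [confusion()]).
#' @return A `seg_report` list of the counts and derived fractions.
#' @export
overlap_metrics <- function(counts) {
  TP <- counts$TP; FP <- counts$FP; FN <- counts$FN; TN <- counts$TN
  N <- TP + FP + FN + TN
  if (N == 0) stop_aaawall("empty masks: no pixels")
  ratio <- function(num, den) if (den == 0) { if (num == 0) 1 else 0 } else num / den
  dsc <- if (2 * TP + FP + FN == 0) 1 else 2 * TP / (2 * TP + FP + FN)
  iou <- if (TP + FP + FN == 0) 1 else TP / (TP + FP + FN)
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  mcc <- if (mcc_den == 0) 0 else (TP * TN - FP * FN) / mcc_den
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 accuracy = (TP + TN) / N,
                 sensitivity = ratio(TP, TP + FN),
                 precision = ratio(TP, TP + FP),
                 specificity = ratio(TN, TN + FP),
                 dsc = dsc, iou = iou, mcc = mcc),
            class = "seg_report")
}

# boundary pixels: foreground with at least one 4-neighbour background
# pixel (image border counts as background); returns (x, y) coordinates
boundary_pixels <- function(mask) {
  H <- nrow(mask); W <- ncol(mask)
  pad <- matrix(0L, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- mask
  core <- pad[2:(H + 1), 2:(W + 1)]
  nb_min <- pmin(pad[1:H, 2:(W + 1)], pad[3:(H + 2), 2:(W + 1)],
                 pad[2:(H + 1), 1:W], pad[2:(H + 1), 3:(W + 2)])
  which(core == 1 & nb_min == 0, arr.ind = TRUE)
}

# directed boundary distances from each point of a to its nearest point
# of b (rows of a and b are points already in mm)
directed_distances <- function(a, b) {
  vapply(seq_len(nrow(a)), function(i) {
    sqrt(min((b[, 1] - a[i, 1])^2 + (b[, 2] - a[i, 2])^2))
  }, numeric(1))
}

#' 95th-percentile Hausdorff boundary distance
#'
#' Pools the directed boundary-to-boundary distances in both directions
#' and takes the 95th percentile (linear interpolation), scaled to mm;
#' the pooled definition is symmetric in its arguments. Anisotropic
#' spacing is supported by a length-2 `pixel_size`.
#'
#' @param pred,truth Non-empty binary masks of the same shape.
#' @param pixel_size mm/pixel, scalar or per-axis length-2.
#' @param q Percentile (default 95; 100 gives the exact Hausdorff
#'   distance).
#' @return Distance in mm.
#' @export
hausdorff95 <- function(pred, truth, pixel_size = 1, q = 95) {
  assert_binary_mask(pred, "pred"); assert_binary_mask(truth, "truth")
  if (!all(dim(pred) == dim(truth))) stop_aaawall("mask shape mismatch")
  if (sum(pred) == 0 || sum(truth) == 0)
    stop_aaawall("Hausdorff distance undefined for an empty mask")
  ps <- rep_len(pixel_size, 2)
  bp <- boundary_pixels(pred); bt <- boundary_pixels(truth)
  bp <- cbind(bp[, 1] * ps[1], bp[, 2] * ps[2])
  bt <- cbind(bt[, 1] * ps[1], bt[, 2] * ps[2])
  pooled <- c(directed_distances(bp, bt), directed_distances(bt, bp))
  unname(quantile(pooled, q / 100, type = 7))
}

#' Evaluate a predicted mask stack against ground truth
#'
#' Per-slice confusion metrics and HD95, aggregated as mean and SD
#' across slices (2-D evaluation, matching a slice-wise segmentation
#' model).
#'
#' @param pred,truth Lists of binary masks.
#' @param pixel_size mm/pixel for the Hausdorff distance.
#' @return List with `per_slice` (data.frame) and `aggregate`
#'   (mean/sd per metric).
#' @export
evaluate_masks <- function(pred, truth, pixel_size = 1) {
  if (length(pred) != length(truth)) stop_aaawall("stack length mismatch")
  rows <- lapply(seq_along(pred), function(i) {
    m <- overlap_metrics(confusion(pred[[i]], truth[[i]]))
    hd <- if (sum(pred[[i]]) > 0 && sum(truth[[i]]) > 0)
      hausdorff95(pred[[i]], truth[[i]], pixel_size) else NA_real_
    data.frame(slice = i, accuracy = m$accuracy, sensitivity = m$sensitivity,
               precision = m$precision, specificity = m$specificity,
               dsc = m$dsc, iou = m$iou, mcc = m$mcc, hd95_mm = hd)
  })
  per_slice <- do.call(rbind, rows)
  metrics <- setdiff(names(per_slice), "slice")
  aggregate <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_slice[[m]], na.rm = TRUE), numeric(1)),
    sd = vapply(metrics, function(m) sd(per_slice[[m]], na.rm = TRUE), numeric(1)))
  list(per_slice = per_slice, aggregate = aggregate)
}
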