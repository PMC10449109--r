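#' Huber loss
#'
#' Elementwise smooth-L1 penalty with delta 1: `0.5 d^2` for `|d| <= 1` and
#' `|d| - 0.5` beyond, with `d = y - y_hat`; reduced by the mean over all
#' elements. Quadratic near zero, linear in the tails, continuous at the
#' branch point.
#'
#' @param y,y_hat Numeric arrays of identical shape.
#' @return Scalar mean loss.
#' @export
huber <- function(y, y_hat) {
  if (!identical(dim(y) %||% length(y), dim(y_hat) %||% length(y_hat))) {
    stop("shape mismatch")
  }
  d <- abs(y - y_hat)
  mean(ifelse(d <= 1, 0.5 * d^2, d - 0.5))
}

#' Weighted total detection loss
#'
#' Combines the three per-head Huber losses with weights 1 : 1/2 : 1/2:
#' `L_total = L_heatmap + 0.5 L_height + 0.5 L_width`.
#'
#' @param l_heatmap,l_height,l_width Scalars.
#' @return Scalar.
#' @export
total_loss <- function(l_heatmap, l_height, l_width) {
  l_heatmap + 0.5 * l_height + 0.5 * l_width
}

#' Mean squared reconstruction error
#'
#' Pixel-wise MSE between a reconstruction and its target, averaged over all
#' pixels and channels. By default every pixel contributes — the pre-training
#' objective reconstructs seen and unseen parts alike; pass the mask to
#' restrict the average to masked pixels only.
#'
#' @param recon,target Arrays of identical shape (H x W or H x W x 3).
#' @param mask Optional logical H x W matrix; if given, only TRUE pixels
#'   (all channels) enter the mean.
#' @return Scalar.
#' @export
mse_reconstruction <- function(recon, target, mask = NULL) {
  if (!identical(dim(recon), dim(target))) stop("shape mismatch")
  sq <- (recon - target)^2
  if (is.null(mask)) return(mean(sq))
  if (length(dim(sq)) == 3L) {
    mask <- array(rep(mask, dim(sq)[3]), dim = dim(sq))
  }
  mean(sq[mask])
}

#' Structural similarity from whole-image statistics
#'
#' Global SSIM: means, variances and covariance are computed over the entire
#' input (no sliding window), with stabilizers `(0.01 L)^2` and `(0.03 L)^2`
#' for dynamic range `L`. Variances use the population (1/N) convention.
#' For 3-channel inputs the score is computed per channel and averaged.
#'
#' @param x1,x2 Arrays of identical shape; H x W or H x W x 3.
#' @param L Dynamic range of the data (1 for [0,1] images).
#' @return Scalar SSIM, at most 1, equal to 1 iff the inputs are identical
#'   (non-degenerate case).
#' @export
ssim <- function(x1, x2, L = 1) {
  if (!identical(dim(x1), dim(x2))) stop("shape mismatch")
  stopifnot(L > 0)
  if (length(dim(x1)) == 3L) {
    return(mean(vapply(seq_len(dim(x1)[3]), function(c) {
      ssim(x1[, , c], x2[, , c], L)
    }, 0)))
  }
  c1 <- (0.01 * L)^2; c2 <- (0.03 * L)^2
  n <- length(x1)
  mu1 <- mean(x1); mu2 <- mean(x2)
  v1 <- sum((x1 - mu1)^2) / n
  v2 <- sum((x2 - mu2)^2) / n
  cov <- sum((x1 - mu1) * (x2 - mu2)) / n
  ((2 * mu1 * mu2 + c1) * (2 * cov + c2)) /
    ((mu1^2 + mu2^2 + c1) * (v1 + v2 + c2))
}

#' Mean intersection-over-union of thresholded heatmaps
#'
#' Both maps are binarized at the (strict) threshold; the IoU of each of the
#' two classes — background and centroid blobs — is computed from
#' true-positive, false-positive and false-negative pixel counts and the two
#' are averaged. A class absent from both maps contributes IoU 1.
#'
#' @param pred_heatmap,gt_heatmap H x W maps sharing a shape.
#' @param threshold Binarization threshold (default 0.75, matching the
#'   decoder).
#' @return Scalar in [0,1]; symmetric in its two arguments.
#' @export
miou <- function(pred_heatmap, gt_heatmap, threshold = 0.75) {
  if (!identical(dim(pred_heatmap), dim(gt_heatmap))) stop("shape mismatch")
  p <- pred_heatmap > threshold
  g <- gt_heatmap > threshold
  iou_class <- function(pc, gc) {
    inter <- sum(pc & gc)
    union <- sum(pc | gc)
    if (union == 0) 1 else inter / union
  }
  (iou_class(p, g) + iou_class(!p, !g)) / 2
}

#' Export detections as COCO results JSON
#'
#' Writes detection results in the standard COCO results dialect (list of
#' `{image_id, category_id, bbox, score}` entries) alongside a matching
#' ground-truth file via [export_coco_gt()], so any COCO evaluator can score
#' AP from the pair.
#'
#' @param detections_list List of detection data.frames (one per image) as
#'   returned by [decode_detections()].
#' @param path Output JSON path for the results file.
#' @return The path, invisibly.
#' @export
export_coco_results <- function(detections_list, path) {
  res <- list()
  for (i in seq_along(detections_list)) {
    d <- detections_list[[i]]
    if (is.null(d) || nrow(d) == 0L) next
    for (j in seq_len(nrow(d))) {
      res[[length(res) + 1L]] <- list(
        image_id = i, category_id = 1L,
        bbox = c(d$x_topleft[j], d$y_topleft[j], d$width[j], d$height[j]),
        score = d$score[j])
    }
  }
  jsonlite::write_json(res, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Intersection-over-union of two boxes
#'
#' Boxes are `c(x, y, w, h)` with the top-left corner first.
#'
#' @param a,b Numeric length-4 vectors.
#' @return IoU in [0,1].
#' @export
box_iou <- function(a, b) {
  x1 <- max(a[1], b[1]); y1 <- max(a[2], b[2])
  x2 <- min(a[1] + a[3], b[1] + b[3]); y2 <- min(a[2] + a[4], b[2] + b[4])
  inter <- max(0, x2 - x1) * max(0, y2 - y1)
  inter / (a[3] * a[4] + b[3] * b[4] - inter)
}
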