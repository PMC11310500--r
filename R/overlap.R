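#' Smallest box enclosing the positive voxels of both masks
#'
#' The union bounding box is the evaluation region for the confusion counts:
#' restricting to it leaves TP/FP/FN untouched (every positive voxel of either
#' mask lies inside) while making TN — and hence TNR and RI — informative
#' instead of saturating near 1 on a whole-CT background.
#'
#' @param gt,test [BinaryMask] objects on the same grid.
#' @return a [BoxRegion] (1-based inclusive voxel index bounds).
#' @export
boundingBoxUnion <- function(gt, test) {
  stopIfGridMismatch(gt, test)
  pos <- gt@voxels | test@voxels
  if (!any(pos))
    stop("degenerate input: both masks are empty", call. = FALSE)
  idx <- which(pos, arr.ind = TRUE)
  new("BoxRegion", lo = as.integer(apply(idx, 2, min)),
      hi = as.integer(apply(idx, 2, max)))
}

#' Confusion-matrix cardinalities inside a region
#'
#' Counts TP, FP, FN, TN over the voxels of \code{region} only. The region
#' must contain every positive voxel of both masks (guaranteed when it comes
#' from [boundingBoxUnion()], possibly enlarged).
#'
#' @param gt,test [BinaryMask] objects on the same grid.
#' @param region a [BoxRegion]; defaults to the union bounding box.
#' @return a [ConfusionCounts].
#' @export
confusionCounts <- function(gt, test, region = boundingBoxUnion(gt, test)) {
  stopIfGridMismatch(gt, test)
  d <- dim(gt@voxels)
  if (any(region@hi > d))
    stop("region exceeds the voxel grid", call. = FALSE)
  sub <- function(m) m@voxels[region@lo[1]:region@hi[1],
                              region@lo[2]:region@hi[2],
                              region@lo[3]:region@hi[3], drop = FALSE]
  g <- sub(gt); t_ <- sub(test)
  if (sum(g) != sum(gt@voxels) || sum(t_) != sum(test@voxels))
    stop("contract error: region excludes positive voxels of a mask",
         call. = FALSE)
  tp <- sum(g & t_)
  fp <- sum(!g & t_)
  fn <- sum(g & !t_)
  tn <- sum(!g & !t_)
  new("ConfusionCounts", tp = as.numeric(tp), fp = as.numeric(fp),
      fn = as.numeric(fn), tn = as.numeric(tn), region = region)
}

#' A BoxRegion covering a whole grid
#'
#' Convenience for computing whole-volume confusion counts, e.g. to see the
#' background-saturation effect the union bounding box avoids.
#'
#' @param x an ImageVolume or BinaryMask.
#' @return a [BoxRegion] spanning all voxels of \code{x}.
#' @export
fullRegion <- function(x) {
  new("BoxRegion", lo = c(1L, 1L, 1L), hi = as.integer(dim(x)))
}

#' The six overlap metrics from confusion counts
#'
#' DSC = 2TP/(2TP+FP+FN), JAC = TP/(TP+FP+FN), TPR = TP/(TP+FN),
#' TNR = TN/(TN+FP), PPV = TP/(TP+FP), RI = (TP+TN)/(TP+TN+FP+FN).
#' Any 0/0 ratio is NaN.
#'
#' @param counts a [ConfusionCounts].
#' @return an [OverlapMetrics].
#' @export
overlapMetrics <- function(counts) {
  tp <- counts@tp; fp <- counts@fp; fn <- counts@fn; tn <- counts@tn
  ratio <- function(num, den) if (den == 0) NaN else num / den
  new("OverlapMetrics",
      dsc = ratio(2 * tp, 2 * tp + fp + fn),
      jac = ratio(tp, tp + fp + fn),
      tpr = ratio(tp, tp + fn),
      tnr = ratio(tn, tn + fp),
      ppv = ratio(tp, tp + fp),
      ri  = ratio(tp + tn, tp + tn + fp + fn))
}
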