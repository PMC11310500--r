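#' Extract the surface point set of a mask
#'
#' Surface voxels are positive voxels with at least one face-adjacent
#' (6-connectivity) neighbor that is outside the mask or outside the grid.
#' Points are the voxel centers in mm. This voxel-center surface convention
#' keeps every distance computation exactly reproducible by brute force; it
#' can differ from a marching-cubes mesh surface by up to one voxel.
#'
#' @param mask a non-empty [BinaryMask].
#' @return a [SurfacePointSet].
#' @export
extractSurface <- function(mask) {
  m <- mask@voxels
  if (!any(m))
    stop("degenerate input: mask is empty", call. = FALSE)
  d <- dim(m)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  shifted <- function(dx, dy, dz)
    pad[(2:(d[1] + 1)) + dx, (2:(d[2] + 1)) + dy, (2:(d[3] + 1)) + dz,
        drop = FALSE]
  interior <- shifted(1, 0, 0) & shifted(-1, 0, 0) &
              shifted(0, 1, 0) & shifted(0, -1, 0) &
              shifted(0, 0, 1) & shifted(0, 0, -1)
  boundary <- m & !interior
  idx <- which(boundary, arr.ind = TRUE)
  pts <- voxelCenter(mask, idx)
  dimnames(pts) <- NULL
  new("SurfacePointSet", points = pts, organ = mask@organ, role = mask@role)
}

## Internal: for each row of A (n x 3, mm), the Euclidean distance to its
## nearest row of B. Blocked so the full distance matrix never materializes;
## arithmetic order matches the exhaustive double loop bit for bit.
nnDistImpl <- function(A, B, chunk = 1024L) {
  n <- nrow(A)
  out <- numeric(n)
  for (s in seq.int(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    d2 <- outer(A[rows, 1], B[, 1], "-")^2 +
          outer(A[rows, 2], B[, 2], "-")^2 +
          outer(A[rows, 3], B[, 3], "-")^2
    j <- max.col(-d2, ties.method = "first")
    out[rows] <- sqrt(d2[cbind(seq_along(rows), j)])
  }
  out
}

#' Nearest-neighbor distance vector d(A, B)
#'
#' For every point of \code{src}, the minimum Euclidean distance (mm) to any
#' point of \code{dst}. \code{max()} of the result is the directed Hausdorff
#' distance h(src, dst).
#'
#' @param src,dst [SurfacePointSet] objects (or n x 3 matrices of mm points).
#' @return numeric vector, one nonnegative distance per src point.
#' @export
nnDistances <- function(src, dst) {
  A <- if (is(src, "SurfacePointSet")) src@points else as.matrix(src)
  B <- if (is(dst, "SurfacePointSet")) dst@points else as.matrix(dst)
  if (nrow(A) < 1L || nrow(B) < 1L)
    stop("degenerate input: empty point set", call. = FALSE)
  nnDistImpl(A, B)
}

#' The seven Hausdorff-family distance metrics
#'
#' Let v be the pooled vector \code{c(d(A,B), d(B,A))} of nearest-neighbor
#' distances with A the ground-truth surface and B the test surface. Then
#' HD_max = max(v) (the classical Hausdorff distance), HD_min = min(v),
#' HD_mean = mean(v), HD_median = median(v), HD_std = population SD of v,
#' HD_95 = 95th percentile of v (linear interpolation between order
#' statistics), and MDA = mean(d(A,B)) — one direction only, ground truth to
#' test.
#'
#' @param gtSurface,testSurface non-empty [SurfacePointSet] objects.
#' @return a [DistanceMetrics], all values in mm.
#' @export
distanceMetrics <- function(gtSurface, testSurface) {
  dAB <- nnDistances(gtSurface, testSurface)
  dBA <- nnDistances(testSurface, gtSurface)
  v <- c(dAB, dBA)
  new("DistanceMetrics",
      hdStd = sqrt(mean((v - mean(v))^2)),
      hdMin = min(v),
      hdMedian = stats::median(v),
      hdMean = mean(v),
      mda = mean(dAB),
      hd95 = unname(stats::quantile(v, 0.95, type = 7)),
      hdMax = max(v))
}

#' All 13 metrics for one ground-truth/test mask pair
#'
#' Convenience wrapper: union bounding box, confusion counts, overlap metrics
#' and surface distance metrics in one call.
#'
#' @param gt,test [BinaryMask] objects on the same grid.
#' @return named numeric vector of the 13 metrics (see [metricNames()]).
#'   If either mask is empty, the distance metrics (and the overlap metrics
#'   whose ratios are 0/0) are NaN.
#' @export
compareMasks <- function(gt, test) {
  counts <- confusionCounts(gt, test)
  ov <- metricVector(overlapMetrics(counts))
  dist <- if (any(gt@voxels) && any(test@voxels)) {
    metricVector(distanceMetrics(extractSurface(gt), extractSurface(test)))
  } else {
    stats::setNames(rep(NaN, 7L), metricNames("distance"))
  }
  c(ov, dist)
}
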