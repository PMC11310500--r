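#' @import methods
NULL

## Central S4 classes. All voxel indexing is 1-based; the physical position of
## voxel (i,j,k) is origin + (index - 1) * spacing (voxel-center convention).

#' ImageVolume: a 3-D CT volume in Hounsfield units
#'
#' Holds the voxel array together with its physical geometry: per-axis voxel
#' spacing in mm and the world position of the center of voxel (1,1,1).
#'
#' @slot voxels 3-D numeric array of HU values.
#' @slot spacing numeric(3), mm per voxel along each axis; all positive.
#' @slot origin numeric(3), world coordinates (mm) of the first voxel center.
#'
#' @export
setClass("ImageVolume",
  representation(voxels = "array", spacing = "numeric", origin = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
        any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive finite values")
    if (length(object@origin) != 3L || any(!is.finite(object@origin)))
      msg <- c(msg, "origin must be 3 finite values")
    if (length(msg)) msg else TRUE
  })

#' BinaryMask: a binary organ segmentation on an ImageVolume grid
#'
#' @slot voxels 3-D logical array; TRUE marks voxels inside the organ.
#' @slot spacing numeric(3) mm, matching the parent image grid.
#' @slot origin numeric(3) mm, matching the parent image grid.
#' @slot organ organ label (see [organVocabulary()]).
#' @slot role either \code{"ground_truth"} or \code{"test"}.
#'
#' @export
setClass("BinaryMask",
  representation(voxels = "array", spacing = "numeric", origin = "numeric",
                 organ = "character", role = "character"),
  validity = function(object) {
    msg <- character()
    if (length(dim(object@voxels)) != 3L)
      msg <- c(msg, "voxels must be a 3-D array")
    if (!is.logical(object@voxels))
      msg <- c(msg, "voxels must be logical")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values")
    if (length(object@origin) != 3L)
      msg <- c(msg, "origin must have length 3")
    if (length(object@organ) != 1L)
      msg <- c(msg, "organ must be a single label")
    if (length(object@role) != 1L ||
        !object@role %in% c("ground_truth", "test"))
      msg <- c(msg, "role must be 'ground_truth' or 'test'")
    if (length(msg)) msg else TRUE
  })

#' BoxRegion: an axis-aligned box of voxel indices (1-based, inclusive)
#'
#' @slot lo integer(3) inclusive lower voxel index bounds.
#' @slot hi integer(3) inclusive upper voxel index bounds.
#'
#' @export
setClass("BoxRegion",
  representation(lo = "integer", hi = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@lo) != 3L || length(object@hi) != 3L)
      msg <- c(msg, "lo and hi must have length 3")
    else {
      if (any(object@lo < 1L)) msg <- c(msg, "indices are 1-based: lo >= 1")
      if (any(object@lo > object@hi)) msg <- c(msg, "lo must be <= hi componentwise")
    }
    if (length(msg)) msg else TRUE
  })

#' ConfusionCounts: voxel confusion-matrix cardinalities inside a box region
#'
#' TP/FP/FN/TN counted over the voxels of \code{region} only. Restricting the
#' count to the union bounding box leaves TP, FP and FN unchanged but keeps TN
#' from being dominated by the vast empty background of a whole CT.
#'
#' @slot tp,fp,fn,tn nonnegative counts.
#' @slot region the [BoxRegion] the counts were taken over.
#'
#' @export
setClass("ConfusionCounts",
  representation(tp = "numeric", fp = "numeric", fn = "numeric",
                 tn = "numeric", region = "BoxRegion"),
  validity = function(object) {
    counts <- c(object@tp, object@fp, object@fn, object@tn)
    msg <- character()
    if (any(counts < 0) || any(counts != round(counts)))
      msg <- c(msg, "counts must be nonnegative integers")
    nbox <- prod(object@region@hi - object@region@lo + 1)
    if (sum(counts) != nbox)
      msg <- c(msg, "tp + fp + fn + tn must equal the region voxel count")
    if (length(msg)) msg else TRUE
  })

#' OverlapMetrics: the six volumetric overlap scores
#'
#' Each value lies in [0, 1]; a ratio of 0/0 is reported as NaN rather than
#' being coerced to 0 or 1.
#'
#' @slot dsc Dice similarity coefficient, 2TP/(2TP+FP+FN).
#' @slot jac Jaccard index, TP/(TP+FP+FN) = DSC/(2-DSC).
#' @slot tpr true positive rate (sensitivity/recall), TP/(TP+FN).
#' @slot tnr true negative rate (specificity), TN/(TN+FP).
#' @slot ppv positive predictive value (precision), TP/(TP+FP).
#' @slot ri Rand index, (TP+TN)/(TP+TN+FP+FN).
#'
#' @export
setClass("OverlapMetrics",
  representation(dsc = "numeric", jac = "numeric", tpr = "numeric",
                 tnr = "numeric", ppv = "numeric", ri = "numeric"),
  validity = function(object) {
    v <- c(object@dsc, object@jac, object@tpr, object@tnr, object@ppv, object@ri)
    ok <- is.nan(v) | (v >= 0 & v <= 1)
    if (all(ok)) TRUE else "defined metric values must lie in [0, 1]"
  })

#' SurfacePointSet: boundary voxel centers of a mask, in mm
#'
#' Points are the world coordinates of mask voxels that have at least one
#' face-adjacent (6-connectivity) neighbor outside the mask or outside the grid.
#'
#' @slot points n x 3 numeric matrix of positions in mm.
#' @slot organ organ label.
#' @slot role \code{"ground_truth"} or \code{"test"}.
#'
#' @export
setClass("SurfacePointSet",
  representation(points = "matrix", organ = "character", role = "character"),
  validity = function(object) {
    msg <- character()
    if (!is.numeric(object@points) || ncol(object@points) != 3L)
      msg <- c(msg, "points must be a numeric n x 3 matrix")
    if (nrow(object@points) < 1L)
      msg <- c(msg, "surface point set must be non-empty")
    if (length(msg)) msg else TRUE
  })

#' DistanceMetrics: the seven Hausdorff-family surface distance statistics (mm)
#'
#' All but MDA are statistics of the pooled nearest-neighbor distance vector
#' \code{c(d(A,B), d(B,A))}; MDA is \code{mean(d(A,B))} with A the ground-truth
#' surface.
#'
#' @slot hdStd,hdMin,hdMedian,hdMean,mda,hd95,hdMax nonnegative mm values.
#'
#' @export
setClass("DistanceMetrics",
  representation(hdStd = "numeric", hdMin = "numeric", hdMedian = "numeric",
                 hdMean = "numeric", mda = "numeric", hd95 = "numeric",
                 hdMax = "numeric"),
  validity = function(object) {
    v <- c(object@hdStd, object@hdMin, object@hdMedian, object@hdMean,
           object@mda, object@hd95, object@hdMax)
    msg <- character()
    if (any(!is.finite(v)) || any(v < 0))
      msg <- c(msg, "all distance metrics must be finite and >= 0")
    tol <- 1e-9
    if (!length(msg)) {
      if (object@hdMin > object@hdMedian + tol ||
          object@hdMedian > object@hd95 + tol ||
          object@hd95 > object@hdMax + tol ||
          object@hdMin > object@hdMean + tol ||
          object@hdMean > object@hdMax + tol ||
          object@mda > object@hdMax + tol)
        msg <- c(msg, "distance metric ordering invariant violated")
    }
    if (length(msg)) msg else TRUE
  })

#' HUSample: Hounsfield-unit values extracted at mask-positive voxels
#'
#' @slot values numeric vector of HU values, one per positive voxel.
#' @slot organ organ label.
#' @slot patientId patient identifier.
#'
#' @export
setClass("HUSample",
  representation(values = "numeric", organ = "character",
                 patientId = "character"),
  validity = function(object) {
    if (length(object@values) < 1L) "HU sample must be non-empty" else TRUE
  })

#' KDEGrid: a uniform grid of HU evaluation points shared by KDE curves
#'
#' @slot points strictly increasing HU values with uniform step.
#' @slot step grid step, HU.
#'
#' @export
setClass("KDEGrid",
  representation(points = "numeric", step = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@points) < 2L)
      msg <- c(msg, "grid needs at least 2 points")
    else {
      d <- diff(object@points)
      if (any(d <= 0)) msg <- c(msg, "grid points must be strictly increasing")
      if (max(abs(d - object@step)) > 1e-8 * max(1, abs(object@step)))
        msg <- c(msg, "grid spacing must be uniform and equal to step")
    }
    if (length(msg)) msg else TRUE
  })

#' KDECurve: a Gaussian-kernel density estimate evaluated on a KDEGrid
#'
#' @slot grid the [KDEGrid] support.
#' @slot density nonnegative density values, one per grid point.
#' @slot bandwidth kernel bandwidth used, HU.
#' @slot nSamples number of HU samples the curve was fitted to.
#'
#' @export
setClass("KDECurve",
  representation(grid = "KDEGrid", density = "numeric", bandwidth = "numeric",
                 nSamples = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@density) != length(object@grid@points))
      msg <- c(msg, "density length must match the grid")
    if (any(object@density < 0))
      msg <- c(msg, "density must be nonnegative")
    if (length(object@bandwidth) != 1L || object@bandwidth <= 0)
      msg <- c(msg, "bandwidth must be a single positive value")
    if (length(msg)) msg else TRUE
  })

#' BaselineKDE: per-organ reference density with plus/minus 2 SD bounds
#'
#' Pointwise mean and sample SD over a reference cohort of per-patient KDE
#' curves; \code{lower = max(mean - 2*sd, 0)} and \code{upper = mean + 2*sd}.
#'
#' @slot organ organ label.
#' @slot grid shared [KDEGrid].
#' @slot meanDensity pointwise mean of the reference curves.
#' @slot sdDensity pointwise sample SD (n-1 denominator).
#' @slot lower,upper the two-sigma envelope.
#' @slot nReference number of reference curves.
#' @slot bandwidthRule how bandwidths were chosen (e.g. "scott").
#'
#' @export
setClass("BaselineKDE",
  representation(organ = "character", grid = "KDEGrid",
                 meanDensity = "numeric", sdDensity = "numeric",
                 lower = "numeric", upper = "numeric",
                 nReference = "integer", bandwidthRule = "character"),
  validity = function(object) {
    n <- length(object@grid@points)
    msg <- character()
    if (length(object@meanDensity) != n || length(object@sdDensity) != n ||
        length(object@lower) != n || length(object@upper) != n)
      msg <- c(msg, "all density vectors must match the grid length")
    else {
      tol <- 1e-9
      if (any(object@sdDensity < 0))
        msg <- c(msg, "sdDensity must be nonnegative")
      if (max(abs(object@lower -
                  pmax(object@meanDensity - 2 * object@sdDensity, 0))) > tol)
        msg <- c(msg, "lower must equal max(mean - 2*sd, 0)")
      if (max(abs(object@upper -
                  (object@meanDensity + 2 * object@sdDensity))) > tol)
        msg <- c(msg, "upper must equal mean + 2*sd")
    }
    if (object@nReference < 2L)
      msg <- c(msg, "a baseline needs at least 2 reference curves")
    if (length(msg)) msg else TRUE
  })

#' PhantomSpec: recipe for a synthetic CT phantom
#'
#' Organs are geometric primitives (sphere, ellipsoid, tube) filled with
#' Gaussian HU noise around an organ-typical mean, embedded in a Gaussian
#' background.
#'
#' @slot gridShape integer(3) voxel grid dimensions.
#' @slot spacing numeric(3) mm.
#' @slot origin numeric(3) mm.
#' @slot backgroundMean,backgroundSD background HU distribution.
#' @slot organs data.frame with columns organ, primitive, cx, cy, cz (mm),
#'   rx, ry, rz (mm), huMean, huSD.
#' @slot allowOverlap if TRUE, later organ rows take precedence where
#'   primitives overlap; if FALSE overlap is an error.
#'
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", spacing = "numeric",
                 origin = "numeric", backgroundMean = "numeric",
                 backgroundSD = "numeric", organs = "data.frame",
                 allowOverlap = "logical"),
  validity = function(object) {
    msg <- character()
    req <- c("organ", "primitive", "cx", "cy", "cz", "rx", "ry", "rz",
             "huMean", "huSD")
    if (!all(req %in% names(object@organs)))
      msg <- c(msg, paste("organs must have columns:", paste(req, collapse = ", ")))
    else {
      if (any(object@organs$rx <= 0 | object@organs$ry <= 0 |
              object@organs$rz <= 0))
        msg <- c(msg, "organ radii must be positive")
      if (any(object@organs$huMean < -1024 | object@organs$huMean > 3000))
        msg <- c(msg, "organ HU means must lie in [-1024, 3000]")
      if (!all(object@organs$primitive %in% c("sphere", "ellipsoid", "tube")))
        msg <- c(msg, "primitive must be sphere, ellipsoid or tube")
    }
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive values")
    if (length(msg)) msg else TRUE
  })

## show methods ---------------------------------------------------------------

setMethod("show", "ImageVolume", function(object) {
  d <- dim(object@voxels)
  cat("ImageVolume:", paste(d, collapse = " x "), "voxels,",
      "spacing", paste(format(object@spacing), collapse = " x "), "mm\n")
  cat("  HU range: [", round(min(object@voxels), 1), ",",
      round(max(object@voxels), 1), "]\n")
})

setMethod("show", "BinaryMask", function(object) {
  cat("BinaryMask:", object@organ, sprintf("(%s),", object@role),
      sum(object@voxels), "positive voxels on a",
      paste(dim(object@voxels), collapse = " x "), "grid\n")
})

setMethod("show", "OverlapMetrics", function(object) {
  v <- c(DSC = object@dsc, JAC = object@jac, TPR = object@tpr,
         TNR = object@tnr, PPV = object@ppv, RI = object@ri)
  cat("OverlapMetrics:\n")
  print(round(v, 4))
})

setMethod("show", "DistanceMetrics", function(object) {
  v <- c(HD_std = object@hdStd, HD_min = object@hdMin,
         HD_median = object@hdMedian, HD_mean = object@hdMean,
         MDA = object@mda, HD_95 = object@hd95, HD_max = object@hdMax)
  cat("DistanceMetrics (mm):\n")
  print(round(v, 4))
})

setMethod("show", "BaselineKDE", function(object) {
  cat("BaselineKDE:", object@organ, "- grid [",
      min(object@grid@points), ",", max(object@grid@points), "] HU, step",
      object@grid@step, ",", object@nReference, "reference curves\n")
})

setMethod("show", "KDECurve", function(object) {
  cat("KDECurve:", length(object@grid@points), "grid points, bandwidth",
      round(object@bandwidth, 3), "HU, n =", object@nSamples, "\n")
})
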