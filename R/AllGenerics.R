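#' Accessors for contourQA objects
#'
#' @param x an object of one of the package's S4 classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' @rdname accessors
#' @export
setGeneric("spacing", function(x) standardGeneric("spacing"))

#' @rdname accessors
#' @export
setGeneric("origin", function(x) standardGeneric("origin"))

#' @rdname accessors
#' @export
setGeneric("organ", function(x) standardGeneric("organ"))

#' @rdname accessors
#' @export
setGeneric("maskRole", function(x) standardGeneric("maskRole"))

#' @rdname accessors
#' @export
setGeneric("surfacePoints", function(x) standardGeneric("surfacePoints"))

#' @rdname accessors
#' @export
setGeneric("gridPoints", function(x) standardGeneric("gridPoints"))

#' @rdname accessors
#' @export
setGeneric("gridStep", function(x) standardGeneric("gridStep"))

#' @rdname accessors
#' @export
setGeneric("densityValues", function(x) standardGeneric("densityValues"))

#' @rdname accessors
#' @export
setGeneric("bandwidth", function(x) standardGeneric("bandwidth"))

#' @rdname accessors
#' @export
setGeneric("huValues", function(x) standardGeneric("huValues"))

#' @rdname accessors
#' @export
setGeneric("meanDensity", function(x) standardGeneric("meanDensity"))

#' @rdname accessors
#' @export
setGeneric("sdDensity", function(x) standardGeneric("sdDensity"))

#' @rdname accessors
#' @export
setGeneric("lowerBound", function(x) standardGeneric("lowerBound"))

#' @rdname accessors
#' @export
setGeneric("upperBound", function(x) standardGeneric("upperBound"))

#' @rdname accessors
#' @export
setGeneric("nReference", function(x) standardGeneric("nReference"))

#' Coerce metric objects to a named numeric vector
#'
#' @param x an [OverlapMetrics] or [DistanceMetrics] object.
#' @return named numeric vector using the standard metric names
#'   (DSC, JAC, ... / HD_std, ..., HD_max).
#' @export
setGeneric("metricVector", function(x) standardGeneric("metricVector"))

#' @rdname accessors
#' @export
setMethod("voxels", "ImageVolume", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("voxels", "BinaryMask", function(x) x@voxels)
#' @rdname accessors
#' @export
setMethod("spacing", "ImageVolume", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("spacing", "BinaryMask", function(x) x@spacing)
#' @rdname accessors
#' @export
setMethod("origin", "ImageVolume", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("origin", "BinaryMask", function(x) x@origin)
#' @rdname accessors
#' @export
setMethod("organ", "BinaryMask", function(x) x@organ)
#' @rdname accessors
#' @export
setMethod("organ", "HUSample", function(x) x@organ)
#' @rdname accessors
#' @export
setMethod("organ", "SurfacePointSet", function(x) x@organ)
#' @rdname accessors
#' @export
setMethod("organ", "BaselineKDE", function(x) x@organ)
#' @rdname accessors
#' @export
setMethod("maskRole", "BinaryMask", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("maskRole", "SurfacePointSet", function(x) x@role)
#' @rdname accessors
#' @export
setMethod("surfacePoints", "SurfacePointSet", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("gridPoints", "KDEGrid", function(x) x@points)
#' @rdname accessors
#' @export
setMethod("gridPoints", "KDECurve", function(x) x@grid@points)
#' @rdname accessors
#' @export
setMethod("gridPoints", "BaselineKDE", function(x) x@grid@points)
#' @rdname accessors
#' @export
setMethod("gridStep", "KDEGrid", function(x) x@step)
#' @rdname accessors
#' @export
setMethod("gridStep", "KDECurve", function(x) x@grid@step)
#' @rdname accessors
#' @export
setMethod("densityValues", "KDECurve", function(x) x@density)
#' @rdname accessors
#' @export
setMethod("bandwidth", "KDECurve", function(x) x@bandwidth)
#' @rdname accessors
#' @export
setMethod("huValues", "HUSample", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("meanDensity", "BaselineKDE", function(x) x@meanDensity)
#' @rdname accessors
#' @export
setMethod("sdDensity", "BaselineKDE", function(x) x@sdDensity)
#' @rdname accessors
#' @export
setMethod("lowerBound", "BaselineKDE", function(x) x@lower)
#' @rdname accessors
#' @export
setMethod("upperBound", "BaselineKDE", function(x) x@upper)
#' @rdname accessors
#' @export
setMethod("nReference", "BaselineKDE", function(x) x@nReference)

#' @rdname metricVector
#' @export
setMethod("metricVector", "OverlapMetrics", function(x)
  c(DSC = x@dsc, JAC = x@jac, TPR = x@tpr, TNR = x@tnr, RI = x@ri, PPV = x@ppv))

#' @rdname metricVector
#' @export
setMethod("metricVector", "DistanceMetrics", function(x)
  c(HD_std = x@hdStd, HD_min = x@hdMin, HD_median = x@hdMedian,
    HD_mean = x@hdMean, MDA = x@mda, HD_95 = x@hd95, HD_max = x@hdMax))

#' @rdname accessors
#' @export
setMethod("dim", "ImageVolume", function(x) dim(x@voxels))
#' @rdname accessors
#' @export
setMethod("dim", "BinaryMask", function(x) dim(x@voxels))
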