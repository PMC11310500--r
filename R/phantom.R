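#' Construct a PhantomSpec
#'
#' @param gridShape integer(3) voxel grid dimensions.
#' @param spacing numeric(3) voxel spacing, mm.
#' @param origin numeric(3) world origin, mm.
#' @param backgroundMean,backgroundSD Gaussian background HU distribution.
#' @param organs data.frame with columns organ, primitive (sphere | ellipsoid
#'   | tube), cx, cy, cz (center, mm), rx, ry, rz (radii, mm; equal for a
#'   sphere), huMean, huSD.
#' @param allowOverlap if TRUE overlapping primitives are resolved by row
#'   order (later rows win); if FALSE overlap is an error.
#' @return a [PhantomSpec].
#' @export
phantomSpec <- function(gridShape, spacing = c(1, 1, 1.5),
                        origin = c(0, 0, 0), backgroundMean = -100,
                        backgroundSD = 20, organs, allowOverlap = FALSE) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      spacing = as.numeric(spacing), origin = as.numeric(origin),
      backgroundMean = backgroundMean, backgroundSD = backgroundSD,
      organs = organs, allowOverlap = allowOverlap)
}

#' A default desk-scale phantom
#'
#' A 64 x 64 x 48 grid at 1 x 1 x 1.5 mm (CT-like anisotropic slices) holding
#' four well-separated organs with tissue-typical HU: a lung (about -700 HU,
#' high variance), a kidney and a brain (soft tissue, 20-40 HU, low variance)
#' and an eye, embedded in a fat-like background (about -100 HU). Organ HU
#' means differ from the background by several SDs, which is what makes the
#' density-based QA sensitive to boundary errors.
#'
#' @return a [PhantomSpec].
#' @export
defaultPhantomSpec <- function() {
  organs <- data.frame(
    organ = c("lung_L", "kidney_L", "brain", "eye_L"),
    primitive = c("sphere", "ellipsoid", "sphere", "sphere"),
    cx = c(16, 46, 32, 50),
    cy = c(16, 16, 46, 46),
    cz = c(20, 20, 36, 54),
    rx = c(11, 8, 12, 5),
    ry = c(11, 6, 12, 5),
    rz = c(11, 10, 12, 5),
    huMean = c(-700, 30, 35, 20),
    huSD = c(60, 15, 10, 10),
    stringsAsFactors = FALSE)
  phantomSpec(gridShape = c(64L, 64L, 48L), spacing = c(1, 1, 1.5),
              organs = organs)
}

## Internal: rasterize one primitive row into a logical array.
## Voxel-center-inside test: ((p - c)/r)^2 summed <= 1 for sphere/ellipsoid;
## a tube is an elliptical cylinder along z with half-length rz.
rasterizePrimitive <- function(row, gridShape, spacing, origin) {
  xs <- origin[1] + (seq_len(gridShape[1]) - 1) * spacing[1]
  ys <- origin[2] + (seq_len(gridShape[2]) - 1) * spacing[2]
  zs <- origin[3] + (seq_len(gridShape[3]) - 1) * spacing[3]
  ux <- ((xs - row$cx) / row$rx)^2
  uy <- ((ys - row$cy) / row$ry)^2
  uz <- ((zs - row$cz) / row$rz)^2
  if (row$primitive == "tube") {
    inPlane <- outer(ux, uy, "+") <= 1
    m <- array(FALSE, gridShape)
    for (k in which(abs(zs - row$cz) <= row$rz)) m[, , k] <- inPlane
    m
  } else {
    outer(outer(ux, uy, "+"), uz, "+") <= 1
  }
}

#' Generate a synthetic CT phantom
#'
#' Background voxels are drawn from the background Gaussian, then each organ
#' primitive is rasterized (voxel-center-inside test) and filled with draws
#' from its own HU Gaussian. The ground-truth mask of each organ is exactly
#' its rasterized primitive. Identical (spec, seed) pairs give bit-identical
#' output.
#'
#' @param spec a [PhantomSpec].
#' @param seed integer RNG seed.
#' @return list with \code{image} (an [ImageVolume]) and \code{masks}
#'   (named list of ground-truth [BinaryMask]s).
#' @export
generatePhantom <- function(spec, seed = 1L) {
  set.seed(seed)
  d <- spec@gridShape
  img <- array(stats::rnorm(prod(d), spec@backgroundMean, spec@backgroundSD),
               dim = d)
  masks <- list()
  occupied <- array(FALSE, d)
  for (i in seq_len(nrow(spec@organs))) {
    row <- spec@organs[i, ]
    m <- rasterizePrimitive(row, d, spec@spacing, spec@origin)
    if (!spec@allowOverlap && any(m & occupied))
      stop("overlapping organ primitives (set allowOverlap = TRUE to resolve ",
           "by row order)", call. = FALSE)
    occupied <- occupied | m
    img[m] <- stats::rnorm(sum(m), row$huMean, row$huSD)
    masks[[row$organ]] <- suppressWarnings(
      binaryMask(m, organ = row$organ, role = "ground_truth",
                 spacing = spec@spacing, origin = spec@origin))
  }
  list(image = imageVolume(img, spacing = spec@spacing,
                           origin = spec@origin),
       masks = masks)
}
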