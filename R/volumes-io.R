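#' Construct an ImageVolume
#'
#' @param voxels 3-D numeric array of HU values.
#' @param spacing numeric(3) voxel spacing in mm.
#' @param origin numeric(3) world position (mm) of the first voxel center.
#' @return an [ImageVolume].
#' @export
imageVolume <- function(voxels, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(voxels) <- "double"
  new("ImageVolume", voxels = voxels, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a BinaryMask
#'
#' Unknown organ labels produce a warning (the vocabulary is closed at the CLI
#' boundary but open programmatically, so the QA tool generalizes).
#'
#' @param voxels 3-D logical (or 0/1 numeric) array.
#' @param geometry an [ImageVolume] (or [BinaryMask]) supplying the grid, or
#'   NULL to pass spacing/origin directly.
#' @param organ organ label.
#' @param role \code{"ground_truth"} or \code{"test"}.
#' @param spacing,origin grid geometry, used when \code{geometry} is NULL.
#' @return a [BinaryMask].
#' @export
binaryMask <- function(voxels, geometry = NULL, organ, role = "ground_truth",
                       spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (!is.null(geometry)) {
    if (!identical(dim(voxels), dim(geometry)))
      stop("geometry error: mask shape ", paste(dim(voxels), collapse = "x"),
           " does not match grid shape ", paste(dim(geometry), collapse = "x"),
           call. = FALSE)
    spacing <- spacing(geometry)
    origin <- origin(geometry)
  }
  checkOrgan(organ, strict = FALSE)
  v <- array(as.logical(voxels), dim = dim(voxels))
  new("BinaryMask", voxels = v, spacing = as.numeric(spacing),
      origin = as.numeric(origin), organ = organ, role = role)
}

#' Do two volumes/masks share a voxel grid?
#'
#' Same shape, spacing and origin (within 1e-6 mm).
#'
#' @param a,b ImageVolume or BinaryMask objects.
#' @return logical.
#' @export
sameGrid <- function(a, b) {
  identical(dim(a), dim(b)) &&
    max(abs(spacing(a) - spacing(b))) < 1e-6 &&
    max(abs(origin(a) - origin(b))) < 1e-6
}

stopIfGridMismatch <- function(a, b) {
  if (!sameGrid(a, b))
    stop("geometry error: objects do not share a voxel grid", call. = FALSE)
  invisible(TRUE)
}

#' Physical position of voxel centers
#'
#' Voxel (i,j,k) (1-based) sits at \code{origin + (index - 1) * spacing}.
#'
#' @param x an ImageVolume or BinaryMask.
#' @param index n x 3 matrix (or length-3 vector) of 1-based voxel indices.
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxelCenter <- function(x, index) {
  if (is.null(dim(index))) index <- matrix(index, ncol = 3)
  sweep(sweep(index - 1, 2, spacing(x), "*"), 2, origin(x), "+")
}

## Internal: diagonal xform matrix encoding spacing + origin.
makeXform <- function(spacing, origin) {
  m <- diag(c(spacing, 1))
  m[1:3, 4] <- origin
  structure(m, code = 2L)
}

#' Read a 3-D NIfTI volume
#'
#' @param path path to a .nii or .nii.gz file.
#' @return an [ImageVolume] with voxels, spacing and origin from the header.
#' @export
readVolume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a 3-D volume, got ", length(d),
         " dimensions in ", path, call. = FALSE)
  sp <- RNifti::pixdim(img)
  if (length(sp) != 3L || any(sp <= 0))
    stop("format error: non-positive voxel spacing in ", path, call. = FALSE)
  xf <- RNifti::xform(img)
  imageVolume(array(as.numeric(img), dim = d), spacing = sp,
              origin = xf[1:3, 4])
}

#' Write an ImageVolume as NIfTI
#'
#' @param volume an [ImageVolume].
#' @param path destination .nii or .nii.gz path.
#' @return the path, invisibly.
#' @export
writeVolume <- function(volume, path) {
  img <- RNifti::asNifti(volume@voxels)
  RNifti::pixdim(img) <- volume@spacing
  m <- makeXform(volume@spacing, volume@origin)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary organ mask from NIfTI
#'
#' Voxel values are thresholded at 0.5. The mask must share the stated
#' geometry exactly; no resampling is performed.
#'
#' @param path path to a .nii or .nii.gz file.
#' @param geometry the [ImageVolume] grid the mask must live on, or NULL to
#'   take the geometry from the mask file itself.
#' @param organ organ label; must be in [organVocabulary()] when
#'   \code{strictOrgan} is TRUE.
#' @param role \code{"ground_truth"} or \code{"test"}.
#' @param strictOrgan reject unknown organ labels (default TRUE, the CLI
#'   behavior); FALSE downgrades to a warning.
#' @return a [BinaryMask].
#' @export
readMask <- function(path, geometry = NULL, organ, role = "ground_truth",
                     strictOrgan = TRUE) {
  checkOrgan(organ, strict = strictOrgan)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("format error: expected a 3-D mask, got ", length(d),
         " dimensions in ", path, call. = FALSE)
  if (!is.null(geometry) && !identical(d, dim(geometry)))
    stop("geometry error: mask shape ", paste(d, collapse = "x"),
         " does not match geometry shape ",
         paste(dim(geometry), collapse = "x"), call. = FALSE)
  v <- array(as.numeric(img) > 0.5, dim = d)
  if (is.null(geometry)) {
    sp <- RNifti::pixdim(img)
    xf <- RNifti::xform(img)
    suppressWarnings(binaryMask(v, organ = organ, role = role, spacing = sp,
                                origin = xf[1:3, 4]))
  } else {
    suppressWarnings(binaryMask(v, geometry = geometry, organ = organ,
                                role = role))
  }
}

#' Write a BinaryMask as NIfTI (uint8 0/1)
#'
#' @param mask a [BinaryMask].
#' @param path destination path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
  a <- array(as.integer(mask@voxels), dim = dim(mask@voxels))
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- mask@spacing
  m <- makeXform(mask@spacing, mask@origin)
  RNifti::qform(img) <- m
  RNifti::sform(img) <- m
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

## Internal: parse <patient>_<organ>_<role>.nii[.gz] filenames.
parseMaskFilename <- function(path) {
  base <- sub("\\.nii(\\.gz)?$", "", basename(path))
  role <- if (grepl("_ground_truth$", base)) "ground_truth"
          else if (grepl("_test$", base)) "test"
          else return(NULL)
  rest <- sub("_(ground_truth|test)$", "", base)
  org <- organVocabulary()[vapply(organVocabulary(), function(o)
    grepl(paste0("_", o, "$"), rest), logical(1))]
  if (length(org) != 1L) return(NULL)
  pid <- sub(paste0("_", org, "$"), "", rest)
  list(patient = pid, organ = org, role = role)
}
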