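## Segmentation-error perturbations for synthetic masks: the error modes an
## auto-segmenter typically makes (systematic over/under-estimation, global
## misplacement, ragged boundaries).

## Internal: integer offsets of a voxel ball of radius r (voxels).
ballOffsets <- function(r) {
  r <- as.integer(floor(r))
  if (r < 1L) return(matrix(0L, nrow = 1, ncol = 3))
  g <- -r:r
  off <- as.matrix(expand.grid(dx = g, dy = g, dz = g))
  off[rowSums(off^2) <= r^2, , drop = FALSE]
}

## Internal: shift a logical array by integer voxels, filling with FALSE.
shiftArray <- function(m, by) {
  d <- dim(m)
  out <- array(FALSE, d)
  src <- dst <- vector("list", 3)
  for (a in 1:3) {
    b <- by[a]
    if (abs(b) >= d[a]) return(out)
    if (b >= 0) { dst[[a]] <- (1 + b):d[a]; src[[a]] <- 1:(d[a] - b) }
    else { dst[[a]] <- 1:(d[a] + b); src[[a]] <- (1 - b):d[a] }
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
  out
}

## Internal: morphological dilation with a voxel ball.
dilateBall <- function(m, r) {
  offs <- ballOffsets(r)
  acc <- m
  for (i in seq_len(nrow(offs))) {
    off <- offs[i, ]
    if (all(off == 0)) next
    acc <- acc | shiftArray(m, off)
  }
  acc
}

erodeBall <- function(m, r) !dilateBall(!m, r)

#' Perturb a binary mask with a segmentation-error model
#'
#' Kinds:
#' \describe{
#'   \item{dilate / erode}{morphological operation with a voxel ball of radius
#'     \code{magnitude} (systematic over-/under-segmentation).}
#'   \item{translate}{rigid shift by \code{magnitude} mm along
#'     \code{direction}, rounded to whole voxels per axis.}
#'   \item{boundary_noise}{each surface voxel of the mask is dropped, and each
#'     face-adjacent exterior voxel added, independently with probability
#'     \code{magnitude} (a rate in [0, 1]).}
#'   \item{mislabel_shift}{translate by \code{magnitude} mm in a seeded
#'     uniformly random direction.}
#' }
#' Deterministic for fixed (mask, kind, magnitude, seed, direction);
#' \code{magnitude = 0} is the identity for every kind.
#'
#' @param mask a non-empty [BinaryMask].
#' @param kind perturbation kind (see above).
#' @param magnitude voxels for dilate/erode, mm for translate/mislabel_shift,
#'   a flip rate in [0,1] for boundary_noise.
#' @param seed integer seed for the stochastic kinds.
#' @param direction numeric(3) direction for \code{translate} (normalized
#'   internally; default +x).
#' @return the perturbed [BinaryMask] with role \code{"test"}.
#' @export
perturbMask <- function(mask,
                        kind = c("dilate", "erode", "translate",
                                 "boundary_noise", "mislabel_shift"),
                        magnitude, seed = 0L, direction = c(1, 0, 0)) {
  kind <- match.arg(kind)
  if (magnitude < 0) stop("magnitude must be >= 0", call. = FALSE)
  m <- mask@voxels
  if (!any(m)) stop("degenerate input: mask is empty", call. = FALSE)
  out <- if (magnitude == 0) m else switch(kind,
    dilate = dilateBall(m, magnitude),
    erode = erodeBall(m, magnitude),
    translate = {
      u <- direction / sqrt(sum(direction^2))
      shiftArray(m, as.integer(round(magnitude * u / mask@spacing)))
    },
    boundary_noise = {
      if (magnitude > 1) stop("boundary_noise rate must be in [0, 1]",
                              call. = FALSE)
      set.seed(seed)
      inner <- m & !erodeBall(m, 1)       # surface voxels of the mask
      outerRing <- dilateBall(m, 1) & !m  # face/ball-adjacent exterior
      drop <- which(inner)
      add <- which(outerRing)
      res <- m
      res[drop[stats::runif(length(drop)) < magnitude]] <- FALSE
      res[add[stats::runif(length(add)) < magnitude]] <- TRUE
      res
    },
    mislabel_shift = {
      set.seed(seed)
      u <- stats::rnorm(3)
      u <- u / sqrt(sum(u^2))
      shiftArray(m, as.integer(round(magnitude * u / mask@spacing)))
    })
  if (!any(out))
    stop("degenerate output: perturbation emptied the mask", call. = FALSE)
  suppressWarnings(binaryMask(out, organ = mask@organ, role = "test",
                              spacing = mask@spacing, origin = mask@origin))
}
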