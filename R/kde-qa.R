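#' Construct an HUSample
#'
#' @param values numeric HU values.
#' @param organ organ label.
#' @param patientId patient identifier.
#' @return an [HUSample].
#' @export
huSample <- function(values, organ = "unknown", patientId = "unknown") {
  new("HUSample", values = as.numeric(values), organ = organ,
      patientId = patientId)
}

#' Extract HU values under a mask
#'
#' Pulls the image intensities at every mask-positive voxel. The resulting
#' sample is what the QA tool summarizes into a density, making the comparison
#' independent of organ size.
#'
#' @param image an [ImageVolume].
#' @param mask a non-empty [BinaryMask] on the same grid.
#' @param patientId patient identifier carried into the sample.
#' @return an [HUSample] with one value per positive voxel.
#' @export
extractHU <- function(image, mask, patientId = "unknown") {
  stopIfGridMismatch(image, mask)
  if (!any(mask@voxels))
    stop("degenerate input: mask is empty", call. = FALSE)
  huSample(image@voxels[mask@voxels], organ = mask@organ,
           patientId = patientId)
}

#' Construct a uniform KDE evaluation grid
#'
#' The default grid spans the full diagnostic CT range, -1024 to 1600 HU in
#' 2 HU steps, so every organ's density lives on one shared support and curves
#' can be averaged and compared pointwise.
#'
#' @param min,max HU range (inclusive; max is trimmed to a whole number of
#'   steps).
#' @param step grid step in HU.
#' @return a [KDEGrid].
#' @export
kdeGrid <- function(min = -1024, max = 1600, step = 2) {
  n <- floor((max - min) / step + 1e-9) + 1
  pts <- min + (seq_len(n) - 1) * step
  new("KDEGrid", points = pts, step = step)
}

#' Fit a Gaussian-kernel density estimate on a grid
#'
#' density(h) = mean_i dnorm((h - x_i)/bw) / bw. The automatic bandwidth is
#' Scott's rule, sd(x) * n^(-1/5). A zero-variance sample cannot use Scott's
#' rule; the bandwidth falls back to max(1 HU, grid step) with a warning.
#' If the grid does not cover the sample range plus/minus 4 bandwidths, mass
#' falls off the support and the unit-integral property degrades; a warning is
#' issued.
#'
#' @param sample an [HUSample].
#' @param grid a [KDEGrid].
#' @param bandwidth "auto" (Scott's rule) or a positive HU value.
#' @return a [KDECurve].
#' @export
fitKDE <- function(sample, grid = kdeGrid(), bandwidth = "auto") {
  x <- sample@values
  n <- length(x)
  if (identical(bandwidth, "auto")) {
    s <- if (n > 1) stats::sd(x) else 0
    if (!is.finite(s) || s <= 0) {
      bw <- max(1, grid@step)
      warning("zero sample variance: falling back to bandwidth ", bw, " HU",
              call. = FALSE)
    } else {
      bw <- s * n^(-1 / 5)
    }
  } else {
    bw <- as.numeric(bandwidth)
    if (!is.finite(bw) || bw <= 0)
      stop("bandwidth must be positive", call. = FALSE)
  }
  g <- grid@points
  if (min(x) - 4 * bw < g[1] - grid@step / 2 ||
      max(x) + 4 * bw > g[length(g)] + grid@step / 2)
    warning("grid does not cover the sample range +/- 4 bandwidths; ",
            "density mass falls outside the support", call. = FALSE)
  ## evaluate in grid blocks to cap the n x grid matrix size
  dens <- numeric(length(g))
  blk <- max(1L, as.integer(2^22 / n))
  for (s0 in seq.int(1L, length(g), by = blk)) {
    e0 <- min(s0 + blk - 1L, length(g))
    gg <- g[s0:e0]
    dens[s0:e0] <- colMeans(stats::dnorm(outer(x, gg, "-") / bw)) / bw
  }
  new("KDECurve", grid = grid, density = dens, bandwidth = bw,
      nSamples = as.integer(n))
}

#' Trapezoidal integral of a KDE curve over its grid
#'
#' @param curve a [KDECurve].
#' @return the integral; close to 1 when the grid covers the sample support.
#' @export
kdeIntegral <- function(curve) {
  y <- curve@density
  sum((y[-1] + y[-length(y)]) / 2) * curve@grid@step
}

#' Build a per-organ baseline from reference KDE curves
#'
#' Pointwise mean and sample SD (n-1 denominator) across the reference
#' curves; the two-sigma envelope is lower = max(mean - 2 SD, 0) and
#' upper = mean + 2 SD, expected to cover about 95% of same-population
#' densities at each HU value.
#'
#' @param curves list of at least two [KDECurve]s on the identical grid.
#' @param organ organ label.
#' @param bandwidthRule free-text note on how bandwidths were chosen.
#' @return a [BaselineKDE].
#' @export
buildBaseline <- function(curves, organ, bandwidthRule = "scott") {
  if (length(curves) < 2L)
    stop("degenerate input: need at least 2 reference curves", call. = FALSE)
  g0 <- curves[[1]]@grid
  for (k in curves) {
    if (!isTRUE(all.equal(k@grid@points, g0@points, tolerance = 1e-10)))
      stop("geometry error: reference curves are not on one grid",
           call. = FALSE)
  }
  dens <- do.call(rbind, lapply(curves, function(k) k@density))
  mu <- colMeans(dens)
  sdv <- sqrt(colSums(sweep(dens, 2, mu)^2) / (nrow(dens) - 1))
  new("BaselineKDE", organ = organ, grid = g0, meanDensity = mu,
      sdDensity = sdv, lower = pmax(mu - 2 * sdv, 0), upper = mu + 2 * sdv,
      nReference = length(curves), bandwidthRule = bandwidthRule)
}

#' Agreement value of a test KDE against a baseline
#'
#' The fraction of grid points at which the test density lies inside the
#' baseline's two-sigma envelope (bounds inclusive):
#' sum_i [lower_i <= KDE_T(i) <= upper_i] / length(KDE_T).
#'
#' With \code{support = "full"} the denominator is the whole grid, so long
#' zero-density tails where bounds and test are all ~0 count as agreeing;
#' \code{support = "restricted"} limits the comparison to grid points where
#' the baseline mean density exceeds 1e-6, which removes that inflation.
#'
#' @param test a [KDECurve] on the baseline's grid.
#' @param baseline a [BaselineKDE].
#' @param support "full" (whole-grid denominator, the default) or
#'   "restricted".
#' @return agreement value in [0, 1].
#' @export
agreementValue <- function(test, baseline, support = c("full", "restricted")) {
  support <- match.arg(support)
  if (!isTRUE(all.equal(test@grid@points, baseline@grid@points,
                        tolerance = 1e-10)))
    stop("geometry error: test curve and baseline are on different grids",
         call. = FALSE)
  idx <- if (support == "restricted") baseline@meanDensity > 1e-6
         else rep(TRUE, length(baseline@meanDensity))
  if (!any(idx)) return(NaN)
  d <- test@density[idx]
  mean(baseline@lower[idx] <= d & d <= baseline@upper[idx])
}

#' QA a set of organ contours against per-organ baselines
#'
#' For each mask: extract the HU sample, fit its KDE on the organ baseline's
#' grid, compute the agreement value and issue a verdict. An organ with no
#' baseline is reported with verdict \code{"no_baseline"} rather than raising.
#'
#' @param image the [ImageVolume] the masks live on.
#' @param masks list of [BinaryMask] objects.
#' @param baselines named list of [BaselineKDE] objects (names = organ labels).
#' @param threshold pass/review threshold on the agreement value; the default
#'   1.0 is the strict clinical choice (anything below 100% agreement is
#'   flagged for review) and can be relaxed.
#' @param patientId patient identifier for the report rows.
#' @param method method label for the report rows.
#' @param support passed to [agreementValue()].
#' @return data.frame with columns patient_id, organ, method, agreement,
#'   threshold, verdict (pass / review / no_baseline).
#' @export
qaContourSet <- function(image, masks, baselines, threshold = 1.0,
                         patientId = "unknown", method = "unknown",
                         support = "full") {
  rows <- lapply(masks, function(m) {
    org <- m@organ
    if (is.null(baselines[[org]]))
      return(data.frame(patient_id = patientId, organ = org, method = method,
                        agreement = NaN, threshold = threshold,
                        verdict = "no_baseline", stringsAsFactors = FALSE))
    bl <- baselines[[org]]
    samp <- extractHU(image, m, patientId = patientId)
    curve <- fitKDE(samp, grid = bl@grid)
    a <- agreementValue(curve, bl, support = support)
    data.frame(patient_id = patientId, organ = org, method = method,
               agreement = a, threshold = threshold,
               verdict = if (a >= threshold) "pass" else "review",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
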