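#' Simulate a synthetic patient cohort on disk
#'
#' Writes, per patient, a phantom CT (one seed-derived realization of the
#' spec), its ground-truth masks, and one perturbed mask set per named method.
#' Patient-to-patient anatomical variation is modelled by one uniform radius
#' scale factor per patient (\code{1 +/- sizeJitter}), mimicking the wide size
#' range of a pediatric cohort. All randomness derives from \code{seed} via a
#' per-patient offset (\code{seed + patient index}), so runs are reproducible
#' and files byte-identical across reruns.
#'
#' Directory layout (consumed by [compareContourSets()],
#' [buildBaselineFromCohort()] and [qaFromFiles()]):
#' \preformatted{
#'   out-dir/images/<pid>_ct.nii.gz
#'   out-dir/ground_truth/<pid>_<organ>_ground_truth.nii.gz
#'   out-dir/<method>/<pid>_<organ>_test.nii.gz
#'   out-dir/manifest.json
#' }
#'
#' @param spec a [PhantomSpec].
#' @param nPatients number of patients (>= 1).
#' @param sizeJitter radius jitter fraction; each patient's organ radii are
#'   scaled by one draw from Uniform(1 - sizeJitter, 1 + sizeJitter).
#' @param perturbations named list: method label -> list(kind, magnitude, and
#'   optionally direction) passed to [perturbMask()]; an empty-magnitude or
#'   zero-magnitude entry reproduces the ground truth.
#' @param seed master integer seed.
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly (list with spec echo, seed, patient ids and
#'   jitter factors).
#' @export
simulateCohort <- function(spec, nPatients, sizeJitter = 0.1,
                           perturbations = list(), seed = 1L, outDir) {
  if (nPatients < 1L) stop("nPatients must be >= 1", call. = FALSE)
  if (sizeJitter < 0 || sizeJitter >= 1)
    stop("sizeJitter must be in [0, 1)", call. = FALSE)
  dir.create(file.path(outDir, "images"), recursive = TRUE,
             showWarnings = FALSE)
  dir.create(file.path(outDir, "ground_truth"), showWarnings = FALSE)
  for (meth in names(perturbations))
    dir.create(file.path(outDir, meth), showWarnings = FALSE)
  pids <- sprintf("p%03d", seq_len(nPatients))
  jitters <- numeric(nPatients)
  for (p in seq_len(nPatients)) {
    pseed <- seed + p
    set.seed(pseed)
    u <- stats::runif(1, 1 - sizeJitter, 1 + sizeJitter)
    jitters[p] <- u
    specP <- spec
    specP@organs$rx <- spec@organs$rx * u
    specP@organs$ry <- spec@organs$ry * u
    specP@organs$rz <- spec@organs$rz * u
    if (any(specP@organs$rx <= 0))
      stop("spec error: jitter produced non-positive radii", call. = FALSE)
    ph <- generatePhantom(specP, seed = pseed)
    writeVolume(ph$image, file.path(outDir, "images",
                                    paste0(pids[p], "_ct.nii.gz")))
    for (org in names(ph$masks)) {
      gt <- ph$masks[[org]]
      writeMask(gt, file.path(outDir, "ground_truth",
                              sprintf("%s_%s_ground_truth.nii.gz",
                                      pids[p], org)))
      for (meth in names(perturbations)) {
        pt <- perturbations[[meth]]
        tm <- if (is.null(pt$magnitude) || pt$magnitude == 0) {
          suppressWarnings(binaryMask(gt@voxels, organ = org, role = "test",
                                      spacing = gt@spacing,
                                      origin = gt@origin))
        } else {
          perturbMask(gt, kind = pt$kind, magnitude = pt$magnitude,
                      seed = pseed + match(org, names(ph$masks)),
                      direction = if (is.null(pt$direction)) c(1, 0, 0)
                                  else pt$direction)
        }
        writeMask(tm, file.path(outDir, meth,
                                sprintf("%s_%s_test.nii.gz", pids[p], org)))
      }
    }
  }
  manifest <- list(seed = seed, n_patients = nPatients,
                   size_jitter = sizeJitter, patient_ids = pids,
                   jitter_factors = jitters,
                   organs = spec@organs$organ,
                   methods = names(perturbations))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Matched-population agreement simulation
#'
#' Simulates the consistency check behind the QA tool's two-sigma rule: a
#' cohort of patients whose organ HU samples are i.i.d. draws from one fixed
#' organ distribution, split into a reference group (baseline: pointwise mean
#' and +/- 2 sample SD of the per-patient KDEs) and a held-out group whose
#' ground-truth KDEs are scored against that baseline. Under the two-sigma
#' rule the mean agreement, and the pooled pointwise coverage of the bounds,
#' are both expected near 0.95.
#'
#' @param nPatients patients per replicate (reference + held-out).
#' @param nReference reference group size (the remainder is held out).
#' @param sampleSize HU values per patient (organ voxel count).
#' @param huMean,huSD the organ HU distribution (normal).
#' @param gridStep KDE grid step, HU; the grid spans huMean +/- 4 huSD.
#' @param seeds integer vector of replicate seeds (one split per seed).
#' @param support passed to [agreementValue()].
#' @return list: \code{meanAgreement} (mean over held-out patients and seeds),
#'   \code{coverage} (pooled pointwise fraction inside the bounds, in [0,1]),
#'   \code{perSeedAgreement}, \code{perSeedCoverage}.
#' @export
matchedCohortAgreement <- function(nPatients = 100L, nReference = 80L,
                                   sampleSize = 5000L, huMean = 40,
                                   huSD = 10, gridStep = 1,
                                   seeds = 1:20, support = "full") {
  stopifnot(nReference < nPatients, nReference >= 2)
  grid <- kdeGrid(huMean - 4 * huSD, huMean + 4 * huSD, gridStep)
  perSeedA <- perSeedC <- numeric(length(seeds))
  for (si in seq_along(seeds)) {
    set.seed(seeds[si])
    curves <- lapply(seq_len(nPatients), function(p) {
      x <- stats::rnorm(sampleSize, huMean, huSD)
      ## a few sample tails may poke past the fixed +/- 4 SD support;
      ## the lost mass is negligible for the pointwise comparison
      suppressWarnings(fitKDE(huSample(x), grid = grid))
    })
    refIdx <- sample(nPatients, nReference)
    baseline <- buildBaseline(curves[refIdx], organ = "simulated")
    held <- curves[setdiff(seq_len(nPatients), refIdx)]
    agr <- vapply(held, agreementValue, numeric(1), baseline = baseline,
                  support = support)
    inside <- vapply(held, function(k) {
      d <- k@density
      c(sum(baseline@lower <= d & d <= baseline@upper), length(d))
    }, numeric(2))
    perSeedA[si] <- mean(agr)
    perSeedC[si] <- sum(inside[1, ]) / sum(inside[2, ])
  }
  list(meanAgreement = mean(perSeedA), coverage = mean(perSeedC),
       perSeedAgreement = perSeedA, perSeedCoverage = perSeedC)
}
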