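## Directory-level drivers tying the metric and QA machinery to the on-disk
## cohort layout (<patient>_<organ>_<role>.nii.gz; see simulateCohort()).

## Internal: list mask files of a role in a directory, keyed by patient/organ.
listMaskFiles <- function(dir, role) {
  files <- list.files(dir, pattern = "\\.nii(\\.gz)?$", full.names = TRUE)
  parsed <- lapply(files, parseMaskFilename)
  keep <- vapply(parsed, function(p) !is.null(p) && p$role == role, logical(1))
  files <- files[keep]
  parsed <- parsed[keep]
  data.frame(path = files,
             patient = vapply(parsed, `[[`, character(1), "patient"),
             organ = vapply(parsed, `[[`, character(1), "organ"),
             stringsAsFactors = FALSE)
}

#' Compare two directories of contours into a metric table
#'
#' Pairs ground-truth and test masks by (patient, organ) parsed from the
#' filenames, computes all 13 metrics per pair, and returns a long metric
#' table (see [metricTable()]). Pairs missing on either side are skipped with
#' a message.
#'
#' @param gtDir directory of \code{<pid>_<organ>_ground_truth.nii[.gz]} files.
#' @param testDir directory of \code{<pid>_<organ>_test.nii[.gz]} files.
#' @param method method label recorded in the table.
#' @return a metric table data.frame.
#' @export
compareContourSets <- function(gtDir, testDir, method = "test") {
  gt <- listMaskFiles(gtDir, "ground_truth")
  te <- listMaskFiles(testDir, "test")
  pairs <- merge(gt, te, by = c("patient", "organ"),
                 suffixes = c(".gt", ".test"))
  if (!nrow(pairs)) stop("no (patient, organ) pairs found", call. = FALSE)
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    g <- readMask(pairs$path.gt[i], organ = pairs$organ[i],
                  role = "ground_truth")
    t_ <- readMask(pairs$path.test[i], organ = pairs$organ[i], role = "test")
    v <- compareMasks(g, t_)
    data.frame(patient_id = pairs$patient[i], organ = pairs$organ[i],
               method = method, metric = names(v), value = unname(v),
               stringsAsFactors = FALSE)
  })
  metricTable(do.call(rbind, rows))
}

#' Build per-organ baselines from a cohort directory
#'
#' Reads every patient's CT and ground-truth masks, extracts the HU sample of
#' each organ, fits per-patient KDEs on one shared grid, and averages them
#' into per-organ [BaselineKDE] models.
#'
#' @param cohortDir directory containing \code{images/} and
#'   \code{ground_truth/} subdirectories in the [simulateCohort()] layout.
#' @param grid shared [KDEGrid] (default [kdeGrid()]: -1024..1600 HU, step 2).
#' @param bandwidth passed to [fitKDE()].
#' @return named list of [BaselineKDE] objects, one per organ with >= 2
#'   patients.
#' @export
buildBaselineFromCohort <- function(cohortDir, grid = kdeGrid(),
                                    bandwidth = "auto") {
  masks <- listMaskFiles(file.path(cohortDir, "ground_truth"), "ground_truth")
  if (!nrow(masks)) stop("no ground-truth masks found", call. = FALSE)
  curves <- list()
  for (pid in unique(masks$patient)) {
    img <- readVolume(file.path(cohortDir, "images",
                                paste0(pid, "_ct.nii.gz")))
    sub <- masks[masks$patient == pid, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      m <- readMask(sub$path[i], geometry = img, organ = sub$organ[i])
      samp <- extractHU(img, m, patientId = pid)
      curves[[sub$organ[i]]] <- c(curves[[sub$organ[i]]],
                                  list(fitKDE(samp, grid = grid,
                                              bandwidth = bandwidth)))
    }
  }
  curves <- curves[vapply(curves, length, integer(1)) >= 2L]
  out <- lapply(names(curves), function(org)
    buildBaseline(curves[[org]], organ = org,
                  bandwidthRule = if (identical(bandwidth, "auto")) "scott"
                                  else "fixed"))
  names(out) <- names(curves)
  out
}

#' QA one patient's contour set from files
#'
#' @param imagePath NIfTI CT path.
#' @param masksDir directory of this patient's organ masks (role parsed from
#'   filenames; both roles accepted).
#' @param baselines a baselines JSON path (see [writeBaselines()]) or a named
#'   list of [BaselineKDE]s.
#' @param threshold agreement threshold (default 1.0).
#' @param method method label for the report.
#' @param support passed to [agreementValue()].
#' @return QA report data.frame (see [qaContourSet()]).
#' @export
qaFromFiles <- function(imagePath, masksDir, baselines, threshold = 1.0,
                        method = "unknown", support = "full") {
  img <- readVolume(imagePath)
  if (is.character(baselines)) baselines <- readBaselines(baselines)
  files <- rbind(listMaskFiles(masksDir, "ground_truth"),
                 listMaskFiles(masksDir, "test"))
  if (!nrow(files)) stop("no masks found in ", masksDir, call. = FALSE)
  rows <- lapply(unique(files$patient), function(pid) {
    sub <- files[files$patient == pid, , drop = FALSE]
    masks <- lapply(seq_len(nrow(sub)), function(i)
      readMask(sub$path[i], geometry = img, organ = sub$organ[i]))
    qaContourSet(img, masks, baselines, threshold = threshold,
                 patientId = pid, method = method, support = support)
  })
  do.call(rbind, rows)
}
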