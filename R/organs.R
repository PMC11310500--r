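#' The closed organ vocabulary
#'
#' The 16 organs at risk covered by the evaluation suite. Labels are plain
#' strings so the QA machinery generalizes to other structures, but the CLI
#' and strict readers reject labels outside this set.
#'
#' @return character vector of 16 organ labels.
#' @export
organVocabulary <- function() {
  c("brain", "brainstem", "chiasm", "cochlea_L", "cochlea_R", "esophagus",
    "eye_L", "eye_R", "lens_L", "lens_R", "lung_L", "lung_R",
    "kidney_L", "kidney_R", "optic_nerve_L", "optic_nerve_R")
}

## Internal: check an organ label; strict -> error, otherwise warn once.
checkOrgan <- function(organ, strict = FALSE) {
  if (!organ %in% organVocabulary()) {
    msg <- sprintf("organ '%s' is not in the 16-organ vocabulary", organ)
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(organ)
}

#' The 13 metric names
#'
#' Six overlap metrics and seven surface-distance metrics, in the canonical
#' column order of the metric table.
#'
#' @param family one of "all", "overlap", "distance".
#' @return character vector of metric names.
#' @export
metricNames <- function(family = c("all", "overlap", "distance")) {
  family <- match.arg(family)
  overlap <- c("DSC", "JAC", "TPR", "TNR", "RI", "PPV")
  distance <- c("HD_std", "HD_min", "HD_median", "HD_mean", "MDA",
                "HD_95", "HD_max")
  switch(family, all = c(overlap, distance), overlap = overlap,
         distance = distance)
}
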