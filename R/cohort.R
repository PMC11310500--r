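## Cohort-level aggregation of the 13-metric table and paired significance
## testing between two segmentation methods. NaN metric values (undefined
## ratios, empty masks) are skipped in every mean, SD and test, and the number
## of contributing values is reported alongside.

naSkip <- function(x) x[!is.na(x)]

summarizeCells <- function(table, method, rowVar) {
  sub <- table[table$method == method, , drop = FALSE]
  if (!nrow(sub))
    stop("empty result: no records for method '", method, "'", call. = FALSE)
  keys <- unique(sub[, c(rowVar, "metric")])
  res <- lapply(seq_len(nrow(keys)), function(i) {
    v <- naSkip(sub$value[sub[[rowVar]] == keys[[rowVar]][i] &
                          sub$metric == keys$metric[i]])
    data.frame(keys[i, , drop = FALSE],
               mean = if (length(v)) mean(v) else NaN,
               sd = if (length(v) > 1) stats::sd(v) else NaN,
               n = length(v), stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, res)
}

#' Per-organ summary of a metric table
#'
#' NaN-skipping mean and sample SD of every metric for one method, across the
#' cohort's patients, one row per (organ, metric) with the contributing count.
#'
#' @param table a metric table (see [metricTable()]).
#' @param method method label to summarize.
#' @return data.frame with columns organ, metric, mean, sd, n.
#' @export
summarizeByOrgan <- function(table, method) {
  validateMetricTable(table)
  summarizeCells(table, method, "organ")
}

#' Per-patient summary of a metric table
#'
#' Metrics averaged across organs within each patient, giving one value per
#' (patient, metric): how well a method contoured an entire patient.
#'
#' @inheritParams summarizeByOrgan
#' @return data.frame with columns patient_id, metric, mean, sd, n.
#' @export
summarizeByPatient <- function(table, method) {
  validateMetricTable(table)
  summarizeCells(table, method, "patient_id")
}

#' Signed method-difference matrix
#'
#' Cell (organ, metric) = mean(method2) - mean(method1) over the cohort.
#' For overlap metrics a positive cell favors method2 (higher is better);
#' for distance metrics a negative cell favors method2 (lower is better).
#'
#' @param table a metric table.
#' @param method1,method2 method labels.
#' @param family "overlap" or "distance".
#' @return numeric matrix, rows = organs, cols = metrics of the family.
#' @export
differenceMatrix <- function(table, method1, method2,
                             family = c("overlap", "distance")) {
  family <- match.arg(family)
  mets <- metricNames(family)
  s1 <- summarizeByOrgan(table, method1)
  s2 <- summarizeByOrgan(table, method2)
  organs <- sort(unique(c(s1$organ, s2$organ)))
  out <- matrix(NaN, nrow = length(organs), ncol = length(mets),
                dimnames = list(organs, mets))
  for (og in organs) for (m in mets) {
    a <- s1$mean[s1$organ == og & s1$metric == m]
    b <- s2$mean[s2$organ == og & s2$metric == m]
    if (length(a) == 1 && length(b) == 1) out[og, m] <- b - a
  }
  out
}

## Internal: is a higher value of this metric better?
higherIsBetter <- function(metric) metric %in% metricNames("overlap")

#' Paired t-test between two methods for one organ and metric
#'
#' Two-sided paired t-test on per-patient differences (method2 - method1),
#' complete pairs only. With fewer than 2 complete pairs the p-value is NaN
#' and the winner is "no_difference". Zero-variance nonzero differences get
#' p = 0 by convention, with the winner decided by the better mean (higher for
#' overlap metrics, lower for distance metrics); all-zero differences are
#' "no_difference".
#'
#' @param table a metric table.
#' @param method1,method2 method labels.
#' @param organ organ label.
#' @param metric metric name.
#' @param alpha two-sided significance level (default 0.05).
#' @return data.frame row: organ, metric, n_pairs, t_statistic, p_value,
#'   winner (a method label or "no_difference").
#' @export
pairedTest <- function(table, method1, method2, organ, metric, alpha = 0.05) {
  validateMetricTable(table)
  sub <- table[table$organ == organ & table$metric == metric, , drop = FALSE]
  a <- sub[sub$method == method1, c("patient_id", "value")]
  b <- sub[sub$method == method2, c("patient_id", "value")]
  m <- merge(a, b, by = "patient_id", suffixes = c(".1", ".2"))
  m <- m[!is.na(m$value.1) & !is.na(m$value.2), , drop = FALSE]
  n <- nrow(m)
  mk <- function(t, p, winner)
    data.frame(organ = organ, metric = metric, n_pairs = n, t_statistic = t,
               p_value = p, winner = winner, stringsAsFactors = FALSE)
  if (n < 2L) return(mk(NaN, NaN, "no_difference"))
  d <- m$value.2 - m$value.1
  better <- if (xor(mean(d) > 0, !higherIsBetter(metric))) method2 else method1
  ## same degeneracy threshold t.test uses for "essentially constant" data
  if (stats::sd(d) / sqrt(n) <= 10 * .Machine$double.eps * abs(mean(d))) {
    if (mean(d) == 0) return(mk(NaN, NaN, "no_difference"))
    return(mk(sign(mean(d)) * Inf, 0, better))
  }
  tt <- stats::t.test(m$value.2, m$value.1, paired = TRUE)
  winner <- if (tt$p.value < alpha) better else "no_difference"
  mk(unname(tt$statistic), tt$p.value, winner)
}

#' Win/tie/loss tally over all organ-metric cells
#'
#' Runs [pairedTest()] for every (organ, metric) cell present for both methods
#' and counts how often method2 wins, method1 wins, or no significant
#' difference is found, using the metric-family sign convention (higher
#' overlap / lower distance is better).
#'
#' @inheritParams pairedTest
#' @return list with the per-cell results data.frame and counts
#'   (method2_wins, method1_wins, no_difference, n_cells).
#' @export
winLossTally <- function(table, method1, method2, alpha = 0.05) {
  validateMetricTable(table)
  sub <- table[table$method %in% c(method1, method2), , drop = FALSE]
  cells <- unique(sub[, c("organ", "metric")])
  res <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i)
    pairedTest(table, method1, method2, cells$organ[i], cells$metric[i],
               alpha = alpha)))
  list(cells = res,
       method2_wins = sum(res$winner == method2),
       method1_wins = sum(res$winner == method1),
       no_difference = sum(res$winner == "no_difference"),
       n_cells = nrow(res))
}

#' Write a difference matrix in long form
#'
#' @param mat matrix from [differenceMatrix()].
#' @param path CSV destination (columns organ, metric, value).
#' @return the path, invisibly.
#' @export
writeDifferenceMatrix <- function(mat, path) {
  long <- data.frame(organ = rep(rownames(mat), times = ncol(mat)),
                     metric = rep(colnames(mat), each = nrow(mat)),
                     value = as.vector(mat), stringsAsFactors = FALSE)
  utils::write.table(long, path, sep = ",", row.names = FALSE, na = "")
  invisible(path)
}
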