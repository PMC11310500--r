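mkTable <- function(...) metricTable(data.frame(..., stringsAsFactors = FALSE))

test_that("per-organ summaries use NaN-skipping means and sample SDs", {
  tab <- mkTable(patient_id = c("p1", "p2", "p1", "p2", "p3"),
                 organ = "brain", method = "atlas",
                 metric = c("DSC", "DSC", "HD_max", "HD_max", "HD_max"),
                 value = c(0.6, 0.8, 0.5, NaN, 0.7))
  s <- summarizeByOrgan(tab, "atlas")
  dsc <- s[s$metric == "DSC", ]
  expect_equal(dsc$mean, 0.7)
  expect_equal(dsc$sd, sqrt(0.02), tolerance = 1e-12)  # two-point closed form
  expect_equal(dsc$n, 2L)
  hd <- s[s$metric == "HD_max", ]
  expect_equal(hd$mean, 0.6)   # NaN skipped
  expect_equal(hd$n, 2L)

  one <- mkTable(patient_id = "p1", organ = "brain", method = "atlas",
                 metric = "DSC", value = 0.7)
  s1 <- summarizeByOrgan(one, "atlas")
  expect_equal(s1$mean, 0.7)
  expect_true(is.na(s1$sd))
  expect_error(summarizeByOrgan(one, "nn"), "empty result")
})

test_that("per-patient summaries average across organs", {
  tab <- mkTable(patient_id = "p1",
                 organ = c("brain", "lung_L", "kidney_L"),
                 method = "nn", metric = "DSC", value = c(0.6, 0.8, NaN))
  s <- summarizeByPatient(tab, "nn")
  expect_equal(s$mean, 0.7)
  expect_equal(s$n, 2L)

  allNaN <- mkTable(patient_id = "p1", organ = c("brain", "lung_L"),
                    method = "nn", metric = "TNR", value = c(NaN, NaN))
  expect_true(is.nan(summarizeByPatient(allNaN, "nn")$mean))
})

test_that("difference matrices subtract means and are antisymmetric", {
  tab <- mkTable(patient_id = rep(c("p1", "p2"), 4),
                 organ = "brain",
                 method = rep(c("atlas", "nn"), each = 2, times = 2),
                 metric = rep(c("DSC", "HD_mean"), each = 4),
                 value = c(0.64, 0.68, 0.71, 0.75, 6, 8, 2, 3))
  ov <- differenceMatrix(tab, "atlas", "nn", "overlap")
  expect_equal(ov["brain", "DSC"], 0.73 - 0.66, tolerance = 1e-12)
  di <- differenceMatrix(tab, "atlas", "nn", "distance")
  expect_equal(di["brain", "HD_mean"], 2.5 - 7)   # negative favors method2
  rev <- differenceMatrix(tab, "nn", "atlas", "overlap")
  expect_equal(rev, -ov)
  same <- differenceMatrix(tab, "atlas", "atlas", "overlap")
  expect_equal(same["brain", "DSC"], 0)
  expect_error(differenceMatrix(tab, "atlas", "nn", "texture"))
})

test_that("paired t-tests match the closed form and handle degeneracies", {
  a <- c(0.5, 0.6, 0.7, 0.8); b <- c(0.6, 0.7, 0.8, 0.9)
  tab <- mkTable(patient_id = rep(sprintf("p%d", 1:4), 2),
                 organ = "brain",
                 method = rep(c("atlas", "nn"), each = 4),
                 metric = "DSC", value = c(a, b))
  res <- pairedTest(tab, "atlas", "nn", "brain", "DSC")
  expect_equal(res$n_pairs, 4L)
  # a constant +0.1 shift: zero-variance differences, p = 0 by convention
  expect_true(is.infinite(res$t_statistic) && res$t_statistic > 0)
  expect_equal(res$p_value, 0)
  expect_equal(res$winner, "nn")

  jit <- c(0.58, 0.72, 0.79, 0.93)
  tab2 <- mkTable(patient_id = rep(sprintf("p%d", 1:4), 2),
                  organ = "brain", method = rep(c("atlas", "nn"), each = 4),
                  metric = "DSC", value = c(a, jit))
  res2 <- pairedTest(tab2, "atlas", "nn", "brain", "DSC")
  d2 <- jit - a
  expect_equal(res2$t_statistic, mean(d2) / (sd(d2) / sqrt(4)),
               tolerance = 1e-12)
  expect_equal(res2$p_value,
               unname(t.test(jit, a, paired = TRUE)$p.value))

  ident <- mkTable(patient_id = rep(sprintf("p%d", 1:3), 2),
                   organ = "brain", method = rep(c("atlas", "nn"), each = 3),
                   metric = "DSC", value = rep(c(0.5, 0.6, 0.7), 2))
  resI <- pairedTest(ident, "atlas", "nn", "brain", "DSC")
  expect_equal(resI$winner, "no_difference")

  # distance metric: lower is better, so a negative shift means method2 wins
  tab3 <- mkTable(patient_id = rep(sprintf("p%d", 1:3), 2),
                  organ = "brain", method = rep(c("atlas", "nn"), each = 3),
                  metric = "HD_mean", value = c(5, 6, 7, 4, 5, 6))
  res3 <- pairedTest(tab3, "atlas", "nn", "brain", "HD_mean")
  expect_equal(res3$winner, "nn")
  expect_equal(res3$p_value, 0)

  few <- mkTable(patient_id = c("p1", "p1"), organ = "brain",
                 method = c("atlas", "nn"), metric = "DSC",
                 value = c(0.5, 0.6))
  resF <- pairedTest(few, "atlas", "nn", "brain", "DSC")
  expect_true(is.nan(resF$p_value))
  expect_equal(resF$winner, "no_difference")
})

test_that("p-values are swap-invariant and winners flip", {
  set.seed(8)
  a <- runif(10, 0.5, 0.7); b <- a + rnorm(10, 0.05, 0.02)
  tab <- mkTable(patient_id = rep(sprintf("p%02d", 1:10), 2),
                 organ = "eye_L", method = rep(c("m1", "m2"), each = 10),
                 metric = "JAC", value = c(a, b))
  r12 <- pairedTest(tab, "m1", "m2", "eye_L", "JAC")
  r21 <- pairedTest(tab, "m2", "m1", "eye_L", "JAC")
  expect_equal(r12$p_value, r21$p_value)
  expect_equal(r12$winner, r21$winner)  # the better method wins either way
})

test_that("the cell-level win/tie tally reproduces a constructed advantage", {
  set.seed(15)
  organs <- organVocabulary()
  mets <- metricNames("all")
  cells <- expand.grid(organ = organs, metric = mets,
                       stringsAsFactors = FALSE)
  betterCells <- seq_len(40)   # method2 strictly better on 40 of 208 cells
  rows <- list()
  for (ci in seq_len(nrow(cells))) {
    og <- cells$organ[ci]; mt <- cells$metric[ci]
    base <- runif(6, 0.4, 0.6)
    shift <- if (ci %in% betterCells) {
      if (mt %in% metricNames("overlap")) 0.2 else -0.2
    } else 0
    rows[[ci]] <- data.frame(
      patient_id = rep(sprintf("p%d", 1:6), 2), organ = og,
      method = rep(c("m1", "m2"), each = 6), metric = mt,
      value = c(base, base + shift), stringsAsFactors = FALSE)
  }
  tab <- metricTable(do.call(rbind, rows))
  tally <- winLossTally(tab, "m1", "m2")
  expect_equal(tally$n_cells, 16L * 13L)
  expect_equal(tally$method2_wins, 40L)
  expect_equal(tally$method1_wins, 0L)
  expect_equal(tally$no_difference, 208L - 40L)
})
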