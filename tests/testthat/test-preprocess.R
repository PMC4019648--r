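test_that("subject correction matches closed-form least squares on a 2-subject toy", {
  # subject B = subject A + 1.0 at every shared condition
  times <- c(30, 60, 120)
  y0 <- c(5, 6, 7)                      # offset-free per-condition values
  ann <- data.frame(
    sample_id = sprintf("s%d", 1:8),
    dose = c(0, 0, rep(1, 6)),
    time_min = c(0, 0, times, times),
    subject_id = c("A", "B", rep("A", 3), rep("B", 3)),
    status = "ok")
  vals <- rbind(gene1 = c(4, 5, y0, y0 + 1.0))
  vals <- rbind(vals, gene2 = 2 * vals[1, ])   # second gene, scaled
  colnames(vals) <- ann$sample_id
  grid <- DesignGrid(vals, ann)
  corr <- exprValues(correctSubjectEffects(grid))
  # corrected values for A and B agree at shared conditions
  expect_equal(corr[, 3:5], corr[, 6:8], ignore_attr = TRUE)
  # grand mean preserved per gene
  expect_equal(rowMeans(corr), rowMeans(vals), tolerance = 1e-12)
})

test_that("subject correction is idempotent and exact for sum-to-zero offsets", {
  set.seed(11)
  times <- c(30, 60, 120, 240)
  # condition-only truth: both subjects see the same value per condition
  condTruth <- matrix(rnorm(5 * 5, 8, 1), nrow = 5,
                      dimnames = list(paste0("g", 1:5), NULL))
  condIdx <- c(1, 1, 2:5, 2:5)          # t0, then the 4 times per subject
  ann <- data.frame(
    sample_id = sprintf("s%02d", 1:10),
    dose = c(0, 0, rep(2, 8)),
    time_min = c(0, 0, times, times),
    subject_id = c("A", "B", rep("A", 4), rep("B", 4)),
    status = "ok")
  truth <- condTruth[, condIdx]
  colnames(truth) <- ann$sample_id
  offsets <- c(A = -0.7, B = 0.7)       # balanced, sum to zero
  observed <- truth + rep(offsets[ann$subject_id], each = 5)
  grid <- DesignGrid(observed, ann)
  corr1 <- correctSubjectEffects(grid)
  expect_equal(exprValues(corr1), truth, tolerance = 1e-12)
  corr2 <- correctSubjectEffects(corr1)
  expect_equal(exprValues(corr2), exprValues(corr1), tolerance = 1e-12)
})

test_that("subject correction edge cases: one subject, zero-variance gene", {
  grid <- makeTinyGrid(nGenes = 3)      # no subjects annotated
  expect_identical(exprValues(correctSubjectEffects(grid)),
                   exprValues(grid))
  # zero-variance gene stays unchanged under two subjects
  ann <- data.frame(sample_id = paste0("s", 1:4), dose = c(0, 0, 1, 1),
                    time_min = c(0, 0, 30, 30),
                    subject_id = c("A", "B", "A", "B"), status = "ok")
  vals <- rbind(flat = rep(3, 4), var = c(1, 2, 3, 4))
  colnames(vals) <- ann$sample_id
  out <- exprValues(correctSubjectEffects(DesignGrid(vals, ann)))
  expect_equal(out["flat", ], setNames(rep(3, 4), paste0("s", 1:4)))
})

test_that("ratio grids compute the declared baselines", {
  # baseline 5.0, cell 6.5 -> ratio 1.5; identical cell -> 0
  ann <- data.frame(sample_id = c("b", "c1", "c2", "u"),
                    dose = c(0, 1, 1, 0), time_min = c(0, 30, 60, 30),
                    subject_id = NA, status = "ok")
  vals <- rbind(g1 = c(5, 6.5, 5, 5.2), g2 = c(7, 7, 6, 7))
  colnames(vals) <- ann$sample_id
  grid <- DesignGrid(vals, ann)
  rg <- computeRatioGrid(grid, "global_t0")
  ri <- cellInfo(rg)
  expect_equal(ratioValues(rg)[, ri$dose == 1 & ri$time == 30],
               c(g1 = 1.5, g2 = 0))
  # time-matched: cell (1, 30) vs untreated sample at 30 min
  suppressWarnings(tm <- computeRatioGrid(grid, "time_matched_dose0"))
  ti <- cellInfo(tm)
  expect_equal(ratioValues(tm)[, ti$dose == 1 & ti$time == 30],
               c(g1 = 6.5 - 5.2, g2 = 0))
  # untreated grid restricted to dose 0, time > 0
  ug <- computeRatioGrid(grid, "untreated_vs_t0")
  expect_equal(cellInfo(ug)$dose, 0)
  expect_equal(cellInfo(ug)$time, 30)
  # missing time-matched baseline -> cell omitted with a warning, not fatal
  expect_warning(computeRatioGrid(grid, "time_matched_dose0"), "omitted")
})

test_that("ratio grids are translation-invariant per gene", {
  grid <- makeTinyGrid(nGenes = 6, doses = c(0, 1, 4), times = c(30, 120))
  shifted <- grid
  SummarizedExperiment::assay(shifted, "log2expr") <-
    exprValues(grid) + seq_len(6)       # gene-wise constants
  for (kind in c("global_t0", "time_matched_dose0", "untreated_vs_t0")) {
    expect_equal(ratioValues(computeRatioGrid(grid, kind)),
                 ratioValues(computeRatioGrid(shifted, kind)),
                 tolerance = 1e-12)
  }
})

test_that("in-vivo treated cells use their own subject's pre-exposure baseline", {
  sim <- simulateDesignGrid(syntheticSpec(
    doses = c(0, 90, 180), times = c(60, 180), nGenes = 8, noiseSd = 0,
    layout = "invivo_paired",
    subjectOffsets = c(m_d0_a = 0, m_d0_b = 0, m_d90_a = 2, m_d90_b = -2,
                       m_d180_a = 0, m_d180_b = 0),
    seed = 3))
  rg <- computeRatioGrid(sim$grid, "global_t0")
  # subject offsets cancel against the subject's own baseline: at zero
  # noise and no planted signal all ratios are exactly 0
  expect_equal(max(abs(ratioValues(rg))), 0)
})

test_that("yield summaries flag rRNA/mRNA divergence", {
  y <- data.frame(sample_id = c("t0", "a", "b"), dose = 0,
                  time_min = c(0, 720, 2880),
                  total_rna_ng = c(100, 300, 600),
                  arna_ug = c(2, 6, 12))
  out <- summarizeYields(y)
  expect_equal(out$rel_total, c(1, 3, 6))
  expect_equal(out$rel_mrna, c(1, 3, 6))
  expect_false(attr(out, "anyFlag"))    # 6x total, 6x mRNA: ratio steady
  y$arna_ug <- c(2, 6, 2)               # total 6x, mRNA 1x at last point
  out2 <- summarizeYields(y)
  expect_true(out2$ratio_flag[3])
  expect_error(summarizeYields(y[-1, ]), "t = 0")
})
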