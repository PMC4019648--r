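.mkRatioForTimes <- function(genes, doses, times, f) {
  # build a time_matched_dose0 RatioGrid whose cell (d, t) holds f(gene, d, t)
  cells <- expand.grid(dose = doses[doses > 0], time = times)
  vals <- matrix(0, nrow = length(genes), ncol = nrow(cells),
                 dimnames = list(genes, paste0("d", cells$dose, "_t", cells$time)))
  for (i in seq_len(nrow(cells)))
    vals[, i] <- vapply(genes, f, numeric(1), cells$dose[i], cells$time[i])
  makeRatioGrid(vals, cells$dose, cells$time)
}

test_that("dose-response correlations match hand-computed Pearson values", {
  rg <- .mkRatioForTimes("g1", doses = c(0, 1, 2, 3), times = 30,
                         f = function(g, d, t) c(0, 1, 1, 2)[d + 1])
  ct <- doseResponseCorrelations(rg, GeneSet("s", "g1"), minPoints = 4)
  expect_equal(ct@r["g1", "30"], 3 / sqrt(10), tolerance = 1e-12)
  expect_true(ct@relevant["g1", "30"])            # 0.949 > 0.8
  # exactly linear -> r = 1; symmetric triple -> r = 0
  rg2 <- .mkRatioForTimes(c("lin", "sym"), doses = c(0, 1, 2), times = 30,
                          f = function(g, d, t)
                            if (g == "lin") 0.7 * d else c(0, 1, 0)[d + 1])
  ct2 <- doseResponseCorrelations(rg2, GeneSet("s", c("lin", "sym")),
                                  minPoints = 3)
  expect_equal(ct2@r["lin", "30"], 1, tolerance = 1e-12)
  expect_equal(ct2@r["sym", "30"], 0, tolerance = 1e-12)
  expect_false(ct2@relevant["sym", "30"])
})

test_that("correlations are affine-invariant and catch anti-correlation", {
  rg <- .mkRatioForTimes("g1", doses = c(0, 2, 5, 9), times = c(30, 60),
                         f = function(g, d, t) -0.4 * d)
  ct <- doseResponseCorrelations(rg, GeneSet("s", "g1"))
  expect_equal(unname(ct@r["g1", ]), c(-1, -1), tolerance = 1e-12)
  expect_true(all(ct@relevant["g1", ]))           # absolute-value rule
  # rescaling dose units and ratio units preserves |r| (sign flips with
  # a negative ratio-unit factor; the dose-0 anchor at ratio 0 is fixed)
  rg2 <- rg
  rg2@cellDose <- rg@cellDose * 37.2
  rg2@values <- rg@values * -0.01
  ct2 <- doseResponseCorrelations(rg2, GeneSet("s", "g1"))
  expect_equal(ct2@r, -ct@r, tolerance = 1e-12)
})

test_that("cells with too few dose points are absent", {
  rg <- .mkRatioForTimes("g1", doses = c(0, 1, 2), times = 30,
                         f = function(g, d, t) d)
  ct <- doseResponseCorrelations(rg, GeneSet("s", "g1"), minPoints = 4)
  expect_true(is.na(ct@r["g1", "30"]))            # only 3 dose points
  ct3 <- doseResponseCorrelations(rg, GeneSet("s", "g1"), minPoints = 3)
  expect_equal(ct3@r["g1", "30"], 1)
  # genes absent from the filtered data are omitted
  ct4 <- doseResponseCorrelations(rg, GeneSet("s", c("g1", "gone")),
                                  minPoints = 3)
  expect_equal(rownames(ct4@r), "g1")
  expect_error(doseResponseCorrelations(rg, GeneSet("s", "gone")),
               "no genes")
})

test_that("table assembly drops irrelevant genes, flags sweet columns, orders rows", {
  r <- rbind(early = c(0.95, 0.2, NA),
             late = c(0.1, 0.5, -0.9),
             weak = c(0.79, 0.5, 0.3),
             earlyWeak = c(0.85, NA, 0.2))
  colnames(r) <- c("60", "360", "720")
  rel <- !is.na(r) & abs(r) > 0.8
  ct <- new("CorrelationTable", setName = "s", r = r, relevant = rel,
            sweetTimes = numeric(0), threshold = 0.8)
  sw <- matrix(FALSE, 2, 3, dimnames = list(c("1", "2.25"),
                                            c("60", "360", "720")))
  sw["2.25", "360"] <- TRUE
  diag <- new("EnrichmentDiagram", setName = "s",
              pRaw = sw * 0.01, pAdj = sw * 0.01, pMin = 0, pMax = 0.2,
              colorValue = sw * 0, sweetMask = sw, nGenesUsed = 4L,
              meta = list())
  out <- assembleTable(ct, diag)
  expect_equal(rownames(out@r), c("early", "earlyWeak", "late"))
  expect_false("weak" %in% rownames(out@r))       # max |r| 0.79 dropped
  expect_equal(out@sweetTimes, 360)
  # tidy + display writers
  tidy <- tidyCorrelations(out)
  expect_true(all(tidy$sweet_column == (tidy$time_min == 360)))
  path <- tempfile()
  writeCorrelationTable(out, path)
  lines <- readLines(path)
  expect_match(lines[2], "6 h\\*")                # 360 min flagged
  expect_equal(length(lines), 2 + 3)
  # empty sweet mask: table still emitted
  diag@sweetMask <- sw & FALSE
  out2 <- assembleTable(ct, diag)
  expect_equal(length(out2@sweetTimes), 0)
  expect_error(assembleTable(ct, classifySweetSpots(
    new("EnrichmentDiagram", setName = "other", pRaw = sw * 0.01,
        pAdj = sw * 0.01, pMin = 0, pMax = 0.2, colorValue = sw * 0,
        sweetMask = sw, nGenesUsed = 2L, meta = list()))),
    "different sets")
})

test_that("a planted dose-linear set is recovered exactly at zero noise", {
  sim <- simulateDesignGrid(syntheticSpec(
    doses = c(0, 1, 2, 4, 8), times = c(30, 60, 120), nGenes = 60,
    noiseSd = 0,
    plantedModules = list(plantedModule(
      10, data.frame(dose = rep(c(1, 2, 4, 8), 2),
                     time = rep(c(60, 120), each = 4)),
      amplitude = 2, doseShape = "linear", name = "lin")),
    seed = 2))
  rg <- computeRatioGrid(sim$grid, "time_matched_dose0")
  ct <- doseResponseCorrelations(rg, GeneSet("lin", sim$truth$moduleGenes$lin))
  out <- assembleTable(ct, NULL)
  expect_setequal(rownames(out@r), sim$truth$moduleGenes$lin)
  # relevant exactly at the planted times 60 and 120, not at 30
  expect_true(all(out@relevant[, c("60", "120")]))
  expect_true(all(!out@relevant[, "30"]))
})
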