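test_that("rank test equals exhaustive subset enumeration on small universes", {
  # worked instance: 6 distinct |ratios|, set = the two top-ranked genes
  st <- setNames(c(2.5, -2.0, 1.0, -0.5, 0.3, 0.1), paste0("g", 1:6))
  p <- geneSetEnrichmentTest(st, c("g1", "g2"))
  expect_equal(p, 1 / 15)
  # randomized instances incl. ties, all alternatives, N <= 10, k <= 4
  set.seed(71)
  for (i in 1:40) {
    N <- sample(5:10, 1); k <- sample(2:min(4, N - 1), 1)
    stats <- round(rnorm(N), sample(c(1, 2), 1))    # rounding induces ties
    names(stats) <- paste0("g", seq_len(N))
    inSet <- seq_len(N) %in% sample(N, k)
    for (alt in c("mixed", "up", "down")) {
      if (length(unique(.altStat <- switch(alt, mixed = abs(stats),
                                           up = stats, down = -stats))) == 1)
        next
      p <- geneSetEnrichmentTest(stats, inSet,
                                 enrichmentConfig(alternative = alt))
      expect_equal(p, bruteRankSumP(stats, inSet, alt), tolerance = 1e-12,
                   label = paste("instance", i, alt))
    }
  }
})

test_that("permutation method converges to the exhaustive mean-statistic value", {
  st <- setNames(c(2.5, -2.0, 1.0, -0.5, 0.3, 0.1), paste0("g", 1:6))
  inSet <- c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  exact <- bruteMeanStatP(st, inSet)
  B <- 9999
  p <- geneSetEnrichmentTest(st, inSet,
    enrichmentConfig(method = "permutation", nPermutations = B, seed = 123))
  expect_lt(abs(p - exact), 3 * sqrt(exact * (1 - exact) / B) + 1 / (B + 1))
})

test_that("rank test agrees with an independent implementation on large data", {
  skip_if_not_installed("limma")
  set.seed(9)
  stats <- rnorm(500)
  idx <- sample(500, 30)
  ours <- geneSetEnrichmentTest(setNames(stats, paste0("g", 1:500)),
                                seq_len(500) %in% idx)
  ref <- limma::geneSetTest(idx, stats, alternative = "mixed",
                            ranks.only = TRUE)
  expect_equal(ours, ref, tolerance = 0.005)
})

test_that("degenerate enrichment inputs are handled per contract", {
  st <- setNames(rep(1, 6), paste0("g", 1:6))
  expect_warning(p <- geneSetEnrichmentTest(st, c("g1", "g2")), "constant")
  expect_equal(p, 1)
  st2 <- setNames(rnorm(6), paste0("g", 1:6))
  expect_error(geneSetEnrichmentTest(st2, "g1"), "fewer than 2")
  expect_error(geneSetEnrichmentTest(st2, paste0("g", 1:6)), "proper subset")
  expect_error(enrichmentConfig(method = "permutation", nPermutations = 10),
               ">= 99")
})

test_that("Benjamini-Hochberg matches closed forms and the stats oracle", {
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(benjaminiHochberg(0.2), 0.2)
  expect_equal(benjaminiHochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(31)
  for (i in 1:10) {
    p <- runif(sample(2:40, 1))^2
    adj <- benjaminiHochberg(p)
    expect_equal(adj, p.adjust(p, "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    # order invariance
    o <- sample(length(p))
    expect_equal(benjaminiHochberg(p[o]), adj[o], tolerance = 1e-15)
    # monotone: larger raw p never gets a smaller adjusted p
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
})

test_that("the adaptive colour key and sweet-spot rules follow the two branches", {
  mkDiag <- function(padj) {
    m <- matrix(padj, nrow = 2, dimnames = list(c("1", "2"), c("30", "60")))
    new("EnrichmentDiagram", setName = "s", pRaw = m, pAdj = m,
        pMin = min(m, na.rm = TRUE), pMax = 0.01, colorValue = m * NA,
        sweetMask = matrix(NA, 2, 2, dimnames = dimnames(m)),
        nGenesUsed = 25L, meta = list())
  }
  cfg <- enrichmentConfig(pmax = 0.01, redBandFraction = 0.25)
  d <- classifySweetSpots(mkDiag(c(0.001, 0.0035, 0.5, 0.9)), cfg)
  cv <- colorValues(d)
  expect_equal(cv[1, 1], 0)                       # the pmin cell is fully red
  expect_equal(cv[2, 1], 0.25)                    # (0.0035 - 0.001) / 0.01
  expect_true(sweetMask(d)[1, 1])
  expect_true(sweetMask(d)[2, 1])                 # boundary inclusive
  expect_false(sweetMask(d)[1, 2])
  # fallback branch: pmin above 0.3 -> fixed 0.3..0.5 scale, never sweet
  d2 <- classifySweetSpots(mkDiag(c(1, 1, 1, 1)), cfg)
  expect_true(all(colorValues(d2) == 1))
  expect_false(any(sweetMask(d2)))
  d3 <- classifySweetSpots(mkDiag(c(0.35, 0.4, 0.45, 0.6)), cfg)
  expect_equal(colorValues(d3)[1, 1], 0.25)       # (0.35 - 0.3) / 0.2
  expect_false(any(sweetMask(d3)))
})

test_that("lowering a cell's adjusted p never removes it from the sweet mask", {
  cfg <- enrichmentConfig(pmax = 0.05)
  set.seed(13)
  for (i in 1:20) {
    padj <- sort(runif(6))
    m <- matrix(padj, nrow = 2, dimnames = list(c("1", "2"), c("10", "20", "30")))
    base <- new("EnrichmentDiagram", setName = "s", pRaw = m, pAdj = m,
                pMin = min(m), pMax = 0.05, colorValue = m * NA,
                sweetMask = matrix(NA, 2, 3, dimnames = dimnames(m)),
                nGenesUsed = 10L, meta = list())
    before <- sweetMask(classifySweetSpots(base, cfg))
    cell <- sample(6, 1)
    m2 <- m; m2[cell] <- m[cell] * runif(1)
    low <- base; low@pAdj <- m2; low@pRaw <- pmin(low@pRaw, m2)
    after <- sweetMask(classifySweetSpots(low, cfg))
    expect_true(all(!before[cell] | after[cell]))
  }
})

test_that("enrichment over the design space localizes a planted activation", {
  sim <- simulateDesignGrid(syntheticSpec(
    doses = c(0, 1, 2, 4), times = c(30, 60, 120), nGenes = 400,
    noiseSd = 0.4,
    plantedModules = list(plantedModule(30, data.frame(dose = 2, time = 60),
                                        amplitude = 2, name = "mod")),
    seed = 17))
  rg <- computeRatioGrid(sim$grid, "time_matched_dose0")
  sets <- GeneSetCollection(list(
    GeneSet("mod", sim$truth$moduleGenes$mod),
    GeneSet("absent", c("nope1", "nope2"))))
  expect_warning(diags <- enrichDesignSpace(rg, sets), "skipping")
  expect_equal(attr(diags, "skipped"), "absent")
  d <- diags$mod
  expect_true(all(pAdjusted(d) >= pRaw(d), na.rm = TRUE))
  amin <- which(pAdjusted(d) == min(pAdjusted(d), na.rm = TRUE), arr.ind = TRUE)
  expect_equal(rownames(pAdjusted(d))[amin[1, 1]], "2")
  expect_equal(colnames(pAdjusted(d))[amin[1, 2]], "60")
  d <- classifySweetSpots(d, enrichmentConfig())
  expect_true(sweetMask(d)["2", "60"])
})

test_that("random-set diagnostics are seed-deterministic", {
  sim <- simulateDesignGrid(syntheticSpec(
    doses = c(0, 1, 2), times = c(30, 60), nGenes = 150, noiseSd = 0.5,
    seed = 33))
  rg <- computeRatioGrid(sim$grid, "time_matched_dose0")
  s1 <- randomSetDiagnostic(rg, size = 15, nSets = 20, seed = 4)
  s2 <- randomSetDiagnostic(rg, size = 15, nSets = 20, seed = 4)
  expect_identical(s1, s2)
  expect_true(all(s1$pmin >= 0 & s1$pmin <= 1))
  expect_warning(randomSetDiagnostic(rg, size = 149, nSets = 2, seed = 1),
                 "degenerate")
})
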