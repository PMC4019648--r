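# Fixtures built in code and independent oracles used across the suite.

# A tiny deterministic DesignGrid: nGenes x (doses x times grid + t0
# baseline), all values from a seeded Normal(8, 1).
makeTinyGrid <- function(nGenes = 10, doses = c(0, 1, 2),
                         times = c(30, 60), seed = 42,
                         subjects = FALSE) {
  set.seed(seed)
  cells <- expand.grid(time = times, dose = doses)[, c("dose", "time")]
  ann <- rbind(data.frame(dose = 0, time = 0), cells)
  n <- nrow(ann)
  ann$sample_id <- sprintf("s%02d", seq_len(n))
  ann$subject_id <- if (subjects) rep(c("A", "B"), length.out = n) else NA
  ann$status <- "ok"
  mat <- matrix(rnorm(nGenes * n, 8, 1), nrow = nGenes,
                dimnames = list(sprintf("g%02d", seq_len(nGenes)),
                                ann$sample_id))
  DesignGrid(mat, data.frame(sample_id = ann$sample_id, dose = ann$dose,
                             time_min = ann$time, subject_id = ann$subject_id,
                             status = ann$status))
}

# Brute-force oracle for the competitive rank test: enumerate every
# same-size gene subset and count those whose rank-sum reaches the
# observed set's rank-sum. Kept independent of the package's DP/normal
# code paths.
bruteRankSumP <- function(statistics, inSet, alternative = "mixed") {
  s <- switch(alternative, mixed = abs(statistics), up = statistics,
              down = -statistics)
  r <- rank(s, ties.method = "average")
  k <- sum(inSet)
  obs <- sum(r[inSet])
  subs <- utils::combn(length(s), k)
  hits <- sum(colSums(matrix(r[subs], nrow = k)) >= obs - 1e-9)
  hits / ncol(subs)
}

# Brute-force oracle on the mean raw statistic (the permutation method's
# test statistic).
bruteMeanStatP <- function(statistics, inSet, alternative = "mixed") {
  s <- switch(alternative, mixed = abs(statistics), up = statistics,
              down = -statistics)
  k <- sum(inSet)
  obs <- mean(s[inSet])
  subs <- utils::combn(length(s), k)
  hits <- sum(colMeans(matrix(s[subs], nrow = k)) >= obs - 1e-12)
  hits / ncol(subs)
}

# Write a GMT file from a named list of character vectors.
writeTmpGMT <- function(sets, descriptions = NULL) {
  path <- tempfile(fileext = ".gmt")
  if (is.null(descriptions)) descriptions <- rep("test", length(sets))
  writeLines(vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1)), path)
  path
}

# Ratio grid built directly from explicit per-cell ratio vectors,
# bypassing computeRatioGrid (for unit tests of downstream stages).
makeRatioGrid <- function(values, cellDose, cellTime,
                          baselineKind = "time_matched_dose0") {
  new("RatioGrid", values = values, cellDose = cellDose, cellTime = cellTime,
      baselineKind = baselineKind)
}
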