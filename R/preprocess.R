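# Subject-effect correction, baseline ratio grids and RNA-yield QC.

#' Correct per-subject (e.g. individual mouse) offsets
#'
#' For each gene a fixed-effect least-squares model with an intercept and
#' sum-to-zero subject offsets is fitted over that gene's ok samples; the
#' returned expression is the observed value minus the fitted subject
#' offset, re-centred so the per-gene grand mean over ok samples is
#' preserved exactly. With single-replicate cells there is no information to
#' estimate variance components, so a point correction replaces a mixed
#' model; in the balanced case the two coincide. With fewer than two
#' annotated subjects the grid is returned unchanged (no offsets are
#' estimable; they are defined as zero).
#'
#' @param grid a [DesignGrid-class] with `subject_id` annotations.
#' @return a corrected [DesignGrid-class] (failed samples untouched).
#' @export
correctSubjectEffects <- function(grid) {
  cd <- SummarizedExperiment::colData(grid)
  ok <- cd$status == "ok" & !is.na(cd$subject_id)
  subj <- cd$subject_id[ok]
  if (length(unique(subj)) < 2) return(grid)
  counts <- table(subj)
  if (any(counts == 1))
    warning("subject(s) with a single sample: ",
            paste(names(counts)[counts == 1], collapse = ", "),
            " (offset confounded with that sample's condition)")
  mat <- exprValues(grid)
  V <- mat[, ok, drop = FALSE]
  # per-gene subject means: genes x subjects
  grp <- factor(subj)
  sums <- V %*% stats::model.matrix(~ grp - 1)
  means <- sweep(sums, 2, as.numeric(table(grp)), "/")
  mu <- rowMeans(means)                      # unweighted mean of subject means
  offsets <- means - mu                      # sum-to-zero across subjects
  corr <- V - offsets[, as.integer(grp), drop = FALSE]
  # restore per-gene grand mean over ok samples (exact, incl. unbalanced case)
  corr <- corr + (rowMeans(V) - rowMeans(corr))
  mat[, ok] <- corr
  out <- grid
  SummarizedExperiment::assay(out, "log2expr") <- mat
  out
}

#' Compute a log2 ratio grid against a declared baseline
#'
#' Per design-space cell, the per-gene log2 ratio is the cell's log2
#' expression minus the baseline's. When several baseline samples qualify,
#' their per-gene mean (geometric mean on the raw scale) is used. When a
#' cell holds several ok samples (e.g. two subjects), their per-sample
#' ratios are averaged. Cells whose baseline is missing are omitted with a
#' warning, not an error.
#'
#' Baselines:
#' * `global_t0`: the (dose 0, time 0) sample; per subject when subjects are
#'   annotated (each sample is compared against its own subject's
#'   pre-exposure sample).
#' * `time_matched_dose0`: the dose-0 sample(s) at the cell's own time, so
#'   fold changes reflect dose response rather than time drift; cells are
#'   the dose > 0 points.
#' * `untreated_vs_t0`: restricts cells to dose 0, time > 0 against the t0
#'   baseline — the input of the background drift filter.
#'
#' @param grid a [DesignGrid-class].
#' @param baselineKind one of `"global_t0"`, `"time_matched_dose0"`,
#'   `"untreated_vs_t0"`.
#' @return a [RatioGrid-class].
#' @export
computeRatioGrid <- function(grid,
                             baselineKind = c("global_t0",
                                              "time_matched_dose0",
                                              "untreated_vs_t0")) {
  baselineKind <- match.arg(baselineKind)
  cd <- SummarizedExperiment::colData(grid)
  ok <- which(cd$status == "ok")
  mat <- exprValues(grid)[, ok, drop = FALSE]
  dose <- cd$dose[ok]; time <- cd$time_min[ok]
  subject <- cd$subject_id[ok]
  hasSubjects <- any(!is.na(subject)) && length(unique(subject[!is.na(subject)])) > 1

  isT0 <- dose == 0 & time == 0
  if (baselineKind %in% c("global_t0", "untreated_vs_t0") && !any(isT0))
    stop("no ok (dose = 0, time = 0) baseline sample")

  cellSel <- switch(baselineKind,
    global_t0 = !(isT0),
    time_matched_dose0 = dose > 0,
    untreated_vs_t0 = dose == 0 & time > 0)

  key <- paste(dose, time, sep = "@")
  cells <- unique(key[cellSel])
  # deterministic order: by dose then time
  cd2 <- do.call(rbind, strsplit(cells, "@", fixed = TRUE))
  cDose <- as.numeric(cd2[, 1]); cTime <- as.numeric(cd2[, 2])
  o <- order(cDose, cTime)
  cells <- cells[o]; cDose <- cDose[o]; cTime <- cTime[o]

  perSubjectT0 <- NULL
  if (hasSubjects) {
    t0idx <- which(isT0)
    perSubjectT0 <- split(t0idx, subject[t0idx])
  }

  ratioCols <- list(); keepDose <- numeric(); keepTime <- numeric()
  for (i in seq_along(cells)) {
    sidx <- which(key == cells[i] & cellSel)
    perSample <- list()
    for (s in sidx) {
      if (baselineKind == "time_matched_dose0") {
        bidx <- which(dose == 0 & time == time[s])
      } else if (hasSubjects && !is.na(subject[s]) &&
                 !is.null(perSubjectT0[[subject[s]]])) {
        bidx <- perSubjectT0[[subject[s]]]
      } else if (hasSubjects && !is.na(subject[s])) {
        bidx <- integer(0)                 # subject without its own baseline
      } else {
        bidx <- which(isT0)
      }
      if (!length(bidx)) next
      base <- if (length(bidx) > 1) rowMeans(mat[, bidx, drop = FALSE])
              else mat[, bidx]
      perSample[[length(perSample) + 1L]] <- mat[, s] - base
    }
    if (!length(perSample)) {
      warning("cell (dose ", cDose[i], ", time ", cTime[i],
              " min) omitted: no qualifying baseline sample")
      next
    }
    ratioCols[[length(ratioCols) + 1L]] <-
      if (length(perSample) > 1) rowMeans(do.call(cbind, perSample))
      else perSample[[1]]
    keepDose <- c(keepDose, cDose[i]); keepTime <- c(keepTime, cTime[i])
  }
  if (!length(ratioCols)) stop("no ratio cells could be computed")
  values <- do.call(cbind, ratioCols)
  colnames(values) <- paste0("d", keepDose, "_t", keepTime)
  rownames(values) <- rownames(exprValues(grid))
  new("RatioGrid", values = values, cellDose = keepDose, cellTime = keepTime,
      baselineKind = baselineKind)
}

#' Subset a RatioGrid to a set of genes
#'
#' @param ratios a [RatioGrid-class].
#' @param genes gene ids to keep (order preserved from the grid).
#' @return a [RatioGrid-class].
#' @export
subsetGenes <- function(ratios, genes) {
  keep <- rownames(ratios@values) %in% genes
  new("RatioGrid", values = ratios@values[keep, , drop = FALSE],
      cellDose = ratios@cellDose, cellTime = ratios@cellTime,
      baselineKind = ratios@baselineKind)
}

#' Read a yield table
#'
#' TSV with columns `sample_id`, `dose`, `time_min`, `total_rna_ng` (total
#' RNA yield) and `arna_ug` (aRNA after linear amplification from equal
#' input mass, used as an mRNA-level proxy).
#'
#' @param path path to the TSV.
#' @return a data.frame.
#' @export
readYieldTable <- function(path) read.delim(path, stringsAsFactors = FALSE)

#' Relative RNA yields and rRNA/mRNA-ratio divergence flag
#'
#' Adds relative yield columns (each sample's yield divided by the t = 0
#' reference sample's yield, so the reference is exactly 1) for total RNA
#' and the mRNA proxy, plus a per-sample flag raised when the two
#' trajectories diverge by more than `foldThreshold` in either direction —
#' an approximation of an rRNA/mRNA-ratio shift that would hamper analysis.
#'
#' @param yields data.frame with columns `sample_id`, `dose`, `time_min`,
#'   `total_rna_ng`, `arna_ug`.
#' @param foldThreshold divergence fold threshold (default 2).
#' @return the input with `rel_total`, `rel_mrna` and `ratio_flag` columns;
#'   attribute `"anyFlag"` is TRUE if any sample is flagged.
#' @export
summarizeYields <- function(yields, foldThreshold = 2) {
  ref <- which(yields$time_min == 0 & yields$dose == 0)
  if (!length(ref)) stop("yield table has no t = 0 reference row")
  refTotal <- mean(yields$total_rna_ng[ref])
  refMrna <- mean(yields$arna_ug[ref])
  yields$rel_total <- yields$total_rna_ng / refTotal
  yields$rel_mrna <- yields$arna_ug / refMrna
  div <- yields$rel_total / yields$rel_mrna
  yields$ratio_flag <- div > foldThreshold | div < 1 / foldThreshold
  attr(yields, "anyFlag") <- any(yields$ratio_flag)
  yields
}
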