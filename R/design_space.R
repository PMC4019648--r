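# DEG-count maps, non-specific-response restriction, background-drift filter.

.cellMatrix <- function(values, cellDose, cellTime, fill = NA_real_) {
  doses <- sort(unique(cellDose)); times <- sort(unique(cellTime))
  m <- matrix(fill, nrow = length(doses), ncol = length(times),
              dimnames = list(as.character(doses), as.character(times)))
  m[cbind(match(cellDose, doses), match(cellTime, times))] <- values
  m
}

#' Count differentially expressed genes per design-space cell
#'
#' A gene is counted as a DEG in a cell when its |log2 ratio| is strictly
#' greater than `cutoff` (directionless: up- and down-regulation both
#' count). No replication-based statistics are involved — this is the
#' fold-change screen of an unreplicated range-finding design.
#'
#' @param ratios a [RatioGrid-class].
#' @param cutoff |log2 FC| cutoff, must be > 0 (default 1, i.e. 2-fold).
#' @return a [DegMap-class] (doses x times matrix; `NA` = missing cell).
#' @export
countDegs <- function(ratios, cutoff = 1) {
  stopifnot(cutoff > 0)
  counts <- colSums(abs(ratios@values) > cutoff)
  new("DegMap",
      counts = .cellMatrix(counts, ratios@cellDose, ratios@cellTime),
      cutoff = cutoff, baselineKind = ratios@baselineKind,
      nGenes = nrow(ratios@values))
}

#' Restrict the design space by flagging non-specific cells
#'
#' Cells whose DEG count reaches `threshold` (greater-or-equal convention)
#' are marked non-specific: a transcriptome-wide stress response makes them
#' uninformative for a specific mechanism. A `threshold` below 1 is read as
#' a fraction of the gene total (e.g. 0.10 of 24302 genes resolves to
#' 2430).
#'
#' @param degmap a [DegMap-class].
#' @param threshold DEG count (default 2000) or fraction in (0, 1).
#' @return a [RestrictionMask-class].
#' @export
restrictDesignSpace <- function(degmap, threshold = 2000) {
  stopifnot(threshold > 0)
  resolved <- if (threshold < 1) threshold * degmap@nGenes else threshold
  ns <- degmap@counts >= resolved
  nUse <- sum(!ns, na.rm = TRUE); nTot <- sum(!is.na(ns))
  message("design space: ", nUse, "/", nTot, " cells usable (threshold ",
          resolved, " DEGs)")
  new("RestrictionMask", nonspecific = ns, threshold = resolved,
      thresholdSpec = threshold)
}

#' Remove genes drifting in untreated samples
#'
#' Genes whose |log2 ratio| exceeds `cutoff` in at least one untreated
#' (dose 0, time > 0) cell relative to the t0 baseline change without the
#' perturbation (growth, circadian and other background processes); their
#' differential expression elsewhere in the design space cannot be
#' attributed to the exposure, so they are removed from the whole data set
#' before enrichment and correlation screening.
#'
#' @param ratiosUntreated a [RatioGrid-class] with baseline
#'   `untreated_vs_t0`.
#' @param cutoff |log2 FC| cutoff (default 1).
#' @return a [BackgroundFilterResult-class].
#' @export
filterBackgroundGenes <- function(ratiosUntreated, cutoff = 1) {
  if (baselineKind(ratiosUntreated) != "untreated_vs_t0")
    stop("background filter needs a RatioGrid with baseline 'untreated_vs_t0'")
  if (ncol(ratiosUntreated@values) == 0)
    stop("no untreated cells: background filter undefined")
  drifting <- rowSums(abs(ratiosUntreated@values) > cutoff) > 0
  genes <- rownames(ratiosUntreated@values)
  message("background filter: removing ", sum(drifting), "/", length(genes),
          " genes drifting in untreated samples")
  new("BackgroundFilterResult",
      removedGenes = genes[drifting],
      keptGenes = genes[!drifting],
      cutoff = cutoff)
}
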