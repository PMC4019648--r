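# Per-time-point Pearson dose-response correlation screening.

#' Dose-response correlations for a gene set
#'
#' For each gene of the set present in the (filtered) data and each time
#' point, computes the Pearson correlation between dose and log2 ratio
#' across the doses available at that time. Because ratios are taken
#' against the time-matched dose-0 sample, dose 0 participates as an
#' anchor with ratio identically 0 (switchable via `includeZeroAnchor`).
#' Correlations are computed on the natural dose scale. |r| strictly
#' greater than `threshold` (default 0.8) is marked relevant; a strong
#' (anti-)correlation indicates a direct dose-expression relation at that
#' time.
#'
#' @param ratios a [RatioGrid-class] with baseline `time_matched_dose0`.
#' @param set a [GeneSet-class].
#' @param minPoints minimum dose points per correlation (>= 3; default 4);
#'   times with fewer doses yield `NA`.
#' @param includeZeroAnchor include the (dose 0, ratio 0) anchor point
#'   (default TRUE).
#' @param threshold relevance threshold on |r| (default 0.8, strict).
#' @return a [CorrelationTable-class] holding the full r matrix (genes x
#'   times) and the relevance marks; `sweetTimes` is empty until
#'   [assembleTable()].
#' @export
doseResponseCorrelations <- function(ratios, set, minPoints = 4,
                                     includeZeroAnchor = TRUE,
                                     threshold = 0.8) {
  if (baselineKind(ratios) != "time_matched_dose0")
    stop("dose-response screening needs a time_matched_dose0 RatioGrid")
  stopifnot(minPoints >= 3)
  genes <- set@genes[set@genes %in% rownames(ratios@values)]
  if (!length(genes))
    stop("no genes of set ", sQuote(set@name), " present in the filtered data")
  times <- sort(unique(ratios@cellTime))
  r <- matrix(NA_real_, nrow = length(genes), ncol = length(times),
              dimnames = list(genes, as.character(times)))
  for (ti in seq_along(times)) {
    sel <- which(ratios@cellTime == times[ti])
    d <- ratios@cellDose[sel]
    o <- order(d)
    d <- d[o]; sel <- sel[o]
    vals <- ratios@values[genes, sel, drop = FALSE]
    if (includeZeroAnchor && !0 %in% d) {
      d <- c(0, d)
      vals <- cbind(0, vals)
    }
    if (length(d) < minPoints) next
    if (sd(d) == 0) next
    rr <- suppressWarnings(apply(vals, 1, function(y)
      if (sd(y) == 0) NA_real_ else cor(d, y)))
    r[, ti] <- rr
  }
  relevant <- !is.na(r) & abs(r) > threshold
  new("CorrelationTable", setName = set@name, r = r, relevant = relevant,
      sweetTimes = numeric(0), threshold = threshold)
}

#' Assemble the presentation table for a gene set
#'
#' Drops genes without any relevant correlation at any time point, flags
#' the time columns whose enrichment-diagram column contains a sweet spot
#' at any dose, and orders the remaining genes by their earliest relevant
#' time, then by descending |r| at that time — grouping early, middle and
#' late responders.
#'
#' @param corr a [CorrelationTable-class].
#' @param diagram the [EnrichmentDiagram-class] of the same set (classified);
#'   pass `NULL` to skip sweet-column flagging.
#' @return the assembled [CorrelationTable-class].
#' @export
assembleTable <- function(corr, diagram = NULL) {
  sweetTimes <- numeric(0)
  if (!is.null(diagram)) {
    if (diagram@setName != corr@setName)
      stop("diagram and table refer to different sets")
    sw <- diagram@sweetMask
    if (!all(is.na(sw))) {
      anySweet <- apply(sw, 2, function(col) any(col, na.rm = TRUE))
      sweetTimes <- as.numeric(colnames(sw)[anySweet])
    }
  }
  keep <- rowSums(corr@relevant) > 0
  r <- corr@r[keep, , drop = FALSE]
  rel <- corr@relevant[keep, , drop = FALSE]
  if (nrow(r)) {
    firstRel <- apply(rel, 1, function(x) which(x)[1])
    strength <- vapply(seq_len(nrow(r)), function(i)
      abs(r[i, firstRel[i]]), numeric(1))
    o <- order(firstRel, -strength)
    r <- r[o, , drop = FALSE]
    rel <- rel[o, , drop = FALSE]
  }
  new("CorrelationTable", setName = corr@setName, r = r, relevant = rel,
      sweetTimes = sweetTimes, threshold = corr@threshold)
}

#' Write a correlation table in the per-time-point display layout
#'
#' Gene rows, time columns (displayed in hours), correlations printed only
#' where relevant (|r| above the threshold); a header comment line flags
#' the sweet-spot time columns. The full matrix is available via
#' [tidyCorrelations()].
#'
#' @param corr an assembled [CorrelationTable-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCorrelationTable <- function(corr, path) {
  times <- as.numeric(colnames(corr@r))
  hdr <- sprintf("%g h%s", times / 60,
                 ifelse(times %in% corr@sweetTimes, "*", ""))
  disp <- matrix("", nrow = nrow(corr@r), ncol = ncol(corr@r))
  sel <- corr@relevant
  disp[sel] <- sprintf("%.2f", corr@r[sel])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# gene set: ", corr@setName,
                    "; * marks sweet-spot time columns"), con)
  writeLines(paste(c("gene", hdr), collapse = "\t"), con)
  if (nrow(disp))
    writeLines(paste(rownames(corr@r),
                     apply(disp, 1, paste, collapse = "\t"), sep = "\t"), con)
  invisible(path)
}

#' Tidy (long) form of a correlation table
#'
#' @param corr a [CorrelationTable-class].
#' @return data.frame (set, gene, time_min, r, relevant, sweet_column) with
#'   every computed correlation, including non-relevant ones.
#' @export
tidyCorrelations <- function(corr) {
  if (!nrow(corr@r))
    return(data.frame(set = character(), gene = character(),
                      time_min = numeric(), r = numeric(),
                      relevant = logical(), sweet_column = logical()))
  times <- as.numeric(colnames(corr@r))
  out <- data.frame(
    set = corr@setName,
    gene = rep(rownames(corr@r), times = ncol(corr@r)),
    time_min = rep(times, each = nrow(corr@r)),
    r = as.vector(corr@r),
    relevant = as.vector(corr@relevant),
    stringsAsFactors = FALSE
  )
  out$sweet_column <- out$time_min %in% corr@sweetTimes
  out[!is.na(out$r), , drop = FALSE]
}
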