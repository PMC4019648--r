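# Pipeline orchestration: the five-step range-finding protocol.

#' Pipeline configuration
#'
#' All thresholds are echoed into the output metadata for provenance.
#'
#' @param degCutoff |log2 FC| cutoff for DEG counting (default 1).
#' @param backgroundCutoff |log2 FC| cutoff of the background drift filter
#'   (default 1).
#' @param restrictionThreshold DEG count (or fraction < 1 of all genes) at
#'   or above which a cell is non-specific (default 2000).
#' @param correlationThreshold relevance threshold on |r| (default 0.8).
#' @param minPoints minimum dose points per correlation (default 4).
#' @param enrichment an [enrichmentConfig()].
#' @param seed integer seed for any stochastic stage.
#' @return a list of class `RunConfig`.
#' @export
runConfig <- function(degCutoff = 1, backgroundCutoff = 1,
                      restrictionThreshold = 2000,
                      correlationThreshold = 0.8, minPoints = 4,
                      enrichment = enrichmentConfig(), seed = 1) {
  structure(list(degCutoff = degCutoff, backgroundCutoff = backgroundCutoff,
                 restrictionThreshold = restrictionThreshold,
                 correlationThreshold = correlationThreshold,
                 minPoints = minPoints, enrichment = enrichment,
                 seed = as.integer(seed)),
            class = "RunConfig")
}

#' Serialize a cell matrix (DegMap / mask / diagram layer) as tidy TSV rows
#' @noRd
.tidyCells <- function(m, value = "value") {
  df <- data.frame(
    dose = rep(as.numeric(rownames(m)), times = ncol(m)),
    time_min = rep(as.numeric(colnames(m)), each = nrow(m)),
    v = as.vector(m))
  names(df)[3] <- value
  df <- df[!is.na(df[[value]]), , drop = FALSE]
  df[order(df$dose, df$time_min), , drop = FALSE]
}

#' Tidy serialization of an enrichment diagram
#'
#' @param diagram a classified [EnrichmentDiagram-class].
#' @return data.frame (set, dose, time_min, p_raw, p_adj, color_value,
#'   sweet) over the diagram's computed cells.
#' @export
tidyDiagram <- function(diagram) {
  m <- diagram@pRaw
  sel <- !is.na(m)
  idx <- which(sel, arr.ind = TRUE)
  out <- data.frame(
    set = diagram@setName,
    dose = as.numeric(rownames(m)[idx[, 1]]),
    time_min = as.numeric(colnames(m)[idx[, 2]]),
    p_raw = diagram@pRaw[sel],
    p_adj = diagram@pAdj[sel],
    color_value = diagram@colorValue[sel],
    sweet = diagram@sweetMask[sel],
    stringsAsFactors = FALSE)
  out[order(out$dose, out$time_min), , drop = FALSE]
}

.writeTidy <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full range-finding pipeline
#'
#' Executes the protocol end to end: per-subject correction (when subjects
#' are annotated), the untreated-vs-t0 ratio grid and background drift
#' filter, the time-matched ratio grid on the kept genes, DEG counting and
#' design-space restriction, competitive enrichment with BH correction and
#' sweet-spot classification per gene set, and per-set dose-response
#' correlation tables. All stage outputs are written as plain TSV files
#' under `outDir` (so partial pipelines are resumable and diffable) plus a
#' machine-readable `summary.tsv` and human-readable `report.txt`.
#'
#' @param grid a [DesignGrid-class].
#' @param sets a [GeneSetCollection-class]; may be empty (DEG/restriction
#'   outputs only, with a warning).
#' @param config a [runConfig()].
#' @param outDir output directory (created if missing); `NULL` writes
#'   nothing.
#' @return invisibly, a list: `filter`, `degmap`, `mask`, `diagrams`,
#'   `tables`, `summary` (data.frame: set, n_genes_used, pmin, n_sweet,
#'   sweet_cells, table_rows).
#' @export
runPipeline <- function(grid, sets = GeneSetCollection(list()),
                        config = runConfig(), outDir = NULL) {
  t0 <- Sys.time()
  log_ <- function(...) message("[rangefindr] ", ...)

  cd <- SummarizedExperiment::colData(grid)
  nSubj <- length(unique(cd$subject_id[!is.na(cd$subject_id)]))
  if (nSubj >= 2) {
    log_("stage subject-correction: ", nSubj, " subjects")
    grid <- correctSubjectEffects(grid)
  }

  log_("stage background-filter")
  untreated <- computeRatioGrid(grid, "untreated_vs_t0")
  filt <- filterBackgroundGenes(untreated, config$backgroundCutoff)

  log_("stage ratio-grid (time-matched, ", length(filt@keptGenes),
       " genes kept)")
  ratios <- computeRatioGrid(grid, "time_matched_dose0")
  ratios <- subsetGenes(ratios, filt@keptGenes)

  log_("stage degmap + restriction")
  degmap <- countDegs(ratios, config$degCutoff)
  mask <- restrictDesignSpace(degmap, config$restrictionThreshold)

  diagrams <- list(); tables <- list()
  if (length(geneSets(sets)) == 0) {
    warning("no gene sets supplied: writing DEG/restriction outputs only")
  } else {
    log_("stage enrichment (", length(geneSets(sets)), " sets)")
    enrCfg <- config$enrichment
    if (is.null(enrCfg$seed)) enrCfg$seed <- config$seed
    diagrams <- enrichDesignSpace(ratios, sets, mask, enrCfg)
    diagrams <- lapply(diagrams, classifySweetSpots, config = enrCfg)
    log_("stage correlations")
    for (nm in names(diagrams)) {
      set <- sets[[nm]]
      tbl <- tryCatch({
        ct <- doseResponseCorrelations(ratios, set,
                                       minPoints = config$minPoints,
                                       threshold = config$correlationThreshold)
        assembleTable(ct, diagrams[[nm]])
      }, error = function(e) {
        warning("correlation table for ", sQuote(nm), " failed: ",
                conditionMessage(e))
        NULL
      })
      if (!is.null(tbl)) tables[[nm]] <- tbl
    }
  }

  sumRows <- lapply(names(diagrams), function(nm) {
    d <- diagrams[[nm]]
    sw <- which(d@sweetMask, arr.ind = TRUE)
    cells <- if (nrow(sw))
      paste(paste0(rownames(d@sweetMask)[sw[, 1]], "@",
                   colnames(d@sweetMask)[sw[, 2]]), collapse = ";")
    else ""
    data.frame(set = nm, n_genes_used = d@nGenesUsed,
               pmin = d@pMin, n_sweet = nrow(sw), sweet_cells = cells,
               table_rows = if (!is.null(tables[[nm]])) nrow(tables[[nm]]@r)
                            else NA_integer_,
               stringsAsFactors = FALSE)
  })
  summary <- if (length(sumRows)) do.call(rbind, sumRows) else
    data.frame(set = character(), n_genes_used = integer(), pmin = numeric(),
               n_sweet = integer(), sweet_cells = character(),
               table_rows = integer())

  result <- list(filter = filt, degmap = degmap, mask = mask,
                 diagrams = diagrams, tables = tables, summary = summary,
                 config = config)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writeLines(c("# background drift filter",
                 paste0("# cutoff\t", filt@cutoff),
                 paste0("removed\t", filt@removedGenes)),
               file.path(outDir, "background_filter.tsv"))
    .writeTidy(.tidyCells(degCounts(degmap), "deg_count"),
               file.path(outDir, "degmap.tsv"))
    maskDf <- .tidyCells(mask@nonspecific * 1, "nonspecific")
    .writeTidy(maskDf, file.path(outDir, "restriction.tsv"))
    if (length(diagrams)) {
      allDiag <- do.call(rbind, lapply(diagrams, tidyDiagram))
      .writeTidy(allDiag, file.path(outDir, "diagrams.tsv"))
      allCorr <- do.call(rbind, lapply(tables, tidyCorrelations))
      if (!is.null(allCorr) && nrow(allCorr))
        .writeTidy(allCorr, file.path(outDir, "correlations.tsv"))
      for (nm in names(tables))
        writeCorrelationTable(tables[[nm]],
          file.path(outDir, paste0("table_", gsub("[^A-Za-z0-9_.-]", "_", nm),
                                   ".tsv")))
    }
    .writeTidy(summary, file.path(outDir, "summary.tsv"))
    rep <- c(
      "range-finding pipeline report",
      "=============================",
      paste0("genes in: ", length(filt@removedGenes) + length(filt@keptGenes),
             "; removed by background filter: ", length(filt@removedGenes)),
      paste0("design-space cells: ", sum(!is.na(degCounts(degmap))),
             "; non-specific: ", sum(mask@nonspecific, na.rm = TRUE),
             " (threshold ", mask@threshold, " DEGs)"),
      paste0("gene sets tested: ", length(diagrams),
             "; skipped: ", length(attr(diagrams, "skipped"))),
      "",
      "thresholds: ",
      paste0("  deg cutoff |log2FC| > ", config$degCutoff),
      paste0("  background cutoff |log2FC| > ", config$backgroundCutoff),
      paste0("  restriction >= ", mask@threshold, " DEGs"),
      paste0("  correlation relevance |r| > ", config$correlationThreshold),
      paste0("  enrichment: ", config$enrichment$method, ", alternative ",
             config$enrichment$alternative, ", pmax ", config$enrichment$pmax,
             ", red band ", config$enrichment$redBandFraction),
      paste0("  seed ", config$seed),
      "",
      "per-set results:")
    if (nrow(summary)) {
      rep <- c(rep, apply(summary, 1, function(r)
        paste0("  ", r[["set"]], ": pmin=", format(as.numeric(r[["pmin"]]),
                                                   digits = 4),
               ", sweet cells [dose@min]: ",
               if (nzchar(r[["sweet_cells"]])) r[["sweet_cells"]] else "none")))
    } else rep <- c(rep, "  (no gene sets)")
    writeLines(rep, file.path(outDir, "report.txt"))
  }
  log_("done in ", format(round(difftime(Sys.time(), t0, units = "secs"), 1)))
  invisible(result)
}
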