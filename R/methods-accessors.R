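# Accessor and show methods for the package classes.

#' @rdname DesignGrid-class
#' @export
setMethod("exprValues", "DesignGrid", function(x)
  SummarizedExperiment::assay(x, "log2expr"))

#' @rdname DesignGrid-class
#' @export
setMethod("sampleInfo", "DesignGrid", function(x) {
  cd <- SummarizedExperiment::colData(x)
  data.frame(sample_id = rownames(cd), dose = cd$dose, time_min = cd$time_min,
             subject_id = cd$subject_id, status = cd$status,
             stringsAsFactors = FALSE, row.names = NULL)
})

#' @rdname DesignGrid-class
#' @export
setMethod("geneIds", "DesignGrid", function(x) rownames(x))

#' @rdname DesignGrid-class
#' @export
setMethod("doseLevels", "DesignGrid", function(x)
  sort(unique(SummarizedExperiment::colData(x)$dose)))

#' @rdname DesignGrid-class
#' @export
setMethod("timeLevels", "DesignGrid", function(x)
  sort(unique(SummarizedExperiment::colData(x)$time_min)))

#' @rdname DesignGrid-class
#' @export
setMethod("okSamples", "DesignGrid", function(x)
  x[, SummarizedExperiment::colData(x)$status == "ok"])

setMethod("show", "DesignGrid", function(object) {
  cd <- SummarizedExperiment::colData(object)
  nFail <- sum(cd$status == "failed")
  cat("DesignGrid:", nrow(object), "genes x", ncol(object), "samples",
      if (nFail) paste0("(", nFail, " failed)") else "", "\n")
  cat("  doses:", paste(doseLevels(object), collapse = ", "), "\n")
  cat("  times (min):", paste(timeLevels(object), collapse = ", "), "\n")
  subj <- unique(cd$subject_id[!is.na(cd$subject_id)])
  if (length(subj)) cat("  subjects:", length(subj), "\n")
  invisible(NULL)
})

#' @rdname RatioGrid-class
#' @export
setMethod("ratioValues", "RatioGrid", function(x) x@values)

#' @rdname RatioGrid-class
#' @export
setMethod("cellInfo", "RatioGrid", function(x)
  data.frame(cell = colnames(x@values), dose = x@cellDose, time_min = x@cellTime,
             stringsAsFactors = FALSE, row.names = NULL))

#' @rdname RatioGrid-class
#' @export
setMethod("baselineKind", "RatioGrid", function(x) x@baselineKind)

#' @rdname RatioGrid-class
#' @export
setMethod("geneIds", "RatioGrid", function(x) rownames(x@values))

setMethod("show", "RatioGrid", function(object) {
  cat("RatioGrid (baseline:", object@baselineKind, "):",
      nrow(object@values), "genes x", ncol(object@values), "cells\n")
  invisible(NULL)
})

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSets", "GeneSetCollection", function(x) x@sets)

#' @rdname GeneSetCollection-class
#' @export
setMethod("geneSetNames", "GeneSetCollection", function(x)
  vapply(x@sets, function(s) s@name, character(1)))

setMethod("length", "GeneSetCollection", function(x) length(x@sets))

setMethod("[[", "GeneSetCollection", function(x, i, ...) {
  if (is.character(i)) i <- match(i, geneSetNames(x))
  x@sets[[i]]
})

setMethod("show", "GeneSetCollection", function(object) {
  cat("GeneSetCollection with", length(object@sets), "sets\n")
  sz <- vapply(object@sets, function(s) length(s@genes), integer(1))
  if (length(sz)) cat("  sizes:", min(sz), "-", max(sz), "\n")
  invisible(NULL)
})

setMethod("show", "GeneSet", function(object) {
  cat("GeneSet", sQuote(object@name), "with", length(object@genes), "genes",
      if (object@smallSet) "[small: unstable under filtering]" else "", "\n")
  invisible(NULL)
})

#' @rdname DegMap-class
#' @export
setMethod("degCounts", "DegMap", function(x) x@counts)

setMethod("show", "DegMap", function(object) {
  cat("DegMap (|log2 FC| >", object@cutoff, ", baseline",
      object@baselineKind, ") over", object@nGenes, "genes\n")
  print(object@counts)
  invisible(NULL)
})

#' @rdname RestrictionMask-class
#' @export
setMethod("usableCells", "RestrictionMask", function(x) !x@nonspecific)

setMethod("show", "RestrictionMask", function(object) {
  ns <- sum(object@nonspecific, na.rm = TRUE)
  tot <- sum(!is.na(object@nonspecific))
  cat("RestrictionMask: ", ns, "/", tot, " cells non-specific (threshold ",
      object@threshold, " DEGs)\n", sep = "")
  invisible(NULL)
})

#' @rdname EnrichmentDiagram-class
#' @export
setMethod("pRaw", "EnrichmentDiagram", function(x) x@pRaw)

#' @rdname EnrichmentDiagram-class
#' @export
setMethod("pAdjusted", "EnrichmentDiagram", function(x) x@pAdj)

#' @rdname EnrichmentDiagram-class
#' @export
setMethod("sweetMask", "EnrichmentDiagram", function(x) x@sweetMask)

#' @rdname EnrichmentDiagram-class
#' @export
setMethod("colorValues", "EnrichmentDiagram", function(x) x@colorValue)

setMethod("show", "EnrichmentDiagram", function(object) {
  cat("EnrichmentDiagram for set", sQuote(object@setName),
      "(", object@nGenesUsed, "genes used)\n")
  cat("  pmin =", format(object@pMin, digits = 4), "\n")
  sw <- object@sweetMask
  if (!all(is.na(sw))) {
    idx <- which(sw, arr.ind = TRUE)
    if (nrow(idx)) {
      cells <- paste0("(", rownames(sw)[idx[, 1]], " J/m2, ",
                      colnames(sw)[idx[, 2]], " min)")
      cat("  sweet spots:", paste(cells, collapse = ", "), "\n")
    } else cat("  sweet spots: none\n")
  } else cat("  not yet classified\n")
  invisible(NULL)
})

setMethod("show", "CorrelationTable", function(object) {
  cat("CorrelationTable for set", sQuote(object@setName), ":",
      nrow(object@r), "genes x", ncol(object@r), "time points\n")
  cat("  relevant cells (|r| >", object@threshold, "):",
      sum(object@relevant, na.rm = TRUE), "\n")
  if (length(object@sweetTimes))
    cat("  sweet-spot time columns (min):",
        paste(object@sweetTimes, collapse = ", "), "\n")
  invisible(NULL)
})
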