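#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats cor pnorm rnorm sd setNames
#' @importFrom utils combn read.delim write.table head
NULL

.BASELINE_KINDS <- c("global_t0", "time_matched_dose0", "untreated_vs_t0")

#' DesignGrid: a dose x time range-finding experiment
#'
#' A `DesignGrid` holds a genes x samples matrix of normalized log2
#' expression together with per-sample design-space coordinates (UV dose,
#' recovery time in minutes, optional subject, ok/failed status). It extends
#' [SummarizedExperiment::SummarizedExperiment] with a single assay named
#' `"log2expr"`; the colData must carry `dose`, `time_min`, `subject_id` and
#' `status`. Failed samples carry no usable expression values and are
#' excluded from every downstream computation.
#'
#' @slot ... inherited from `SummarizedExperiment`.
#' @seealso [readDesignGrid()], [simulateDesignGrid()]
#' @export
setClass("DesignGrid", contains = "SummarizedExperiment")

setValidity("DesignGrid", function(object) {
  msg <- character()
  if (!"log2expr" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2expr' is required")
  cd <- SummarizedExperiment::colData(object)
  need <- c("dose", "time_min", "subject_id", "status")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("colData misses column(s): ", paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "gene identifiers must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample identifiers must be unique")
  if (!length(msg)) {
    if (!all(cd$status %in% c("ok", "failed")))
      msg <- c(msg, "status must be 'ok' or 'failed'")
    if (any(cd$dose < 0, na.rm = TRUE) || any(cd$time_min < 0, na.rm = TRUE))
      msg <- c(msg, "dose and time_min must be non-negative")
    ok <- cd$status == "ok"
    if (any(ok) && !all(is.finite(SummarizedExperiment::assay(object, "log2expr")[, ok, drop = FALSE])))
      msg <- c(msg, "expression values must be finite for ok samples")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a DesignGrid
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids), log2 scale.
#' @param sampleInfo data.frame with one row per sample and columns
#'   `sample_id`, `dose`, `time_min`, optionally `subject_id` and `status`
#'   (`"ok"`/`"failed"`; default ok). Rows are matched to the columns of
#'   `values` by `sample_id`; a mismatch is an error.
#' @return a [DesignGrid-class] object.
#' @export
DesignGrid <- function(values, sampleInfo) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have gene ids as rownames")
  if (is.null(colnames(values))) stop("values must have sample ids as colnames")
  sampleInfo <- as.data.frame(sampleInfo)
  if (!"sample_id" %in% colnames(sampleInfo)) stop("sampleInfo needs a sample_id column")
  if (anyDuplicated(sampleInfo$sample_id)) stop("duplicate sample_id in annotation")
  if (anyDuplicated(rownames(values))) stop("duplicate gene id in expression matrix")
  unmatched <- setdiff(colnames(values), sampleInfo$sample_id)
  if (length(unmatched))
    stop("expression column(s) absent from annotation: ", paste(unmatched, collapse = ", "))
  extra <- setdiff(sampleInfo$sample_id, colnames(values))
  if (length(extra))
    stop("annotation row(s) without expression column: ", paste(extra, collapse = ", "))
  sampleInfo <- sampleInfo[match(colnames(values), sampleInfo$sample_id), , drop = FALSE]
  if (is.null(sampleInfo$subject_id)) sampleInfo$subject_id <- NA_character_
  if (is.null(sampleInfo$status)) sampleInfo$status <- "ok"
  cd <- S4Vectors::DataFrame(
    dose = as.numeric(sampleInfo$dose),
    time_min = as.numeric(sampleInfo$time_min),
    subject_id = as.character(sampleInfo$subject_id),
    status = as.character(sampleInfo$status),
    row.names = sampleInfo$sample_id
  )
  bad <- cd$status == "ok" & !apply(is.finite(values), 2, all)
  if (any(bad))
    stop("non-finite/non-numeric expression for ok sample(s): ",
         paste(rownames(cd)[bad], collapse = ", "))
  new("DesignGrid",
      SummarizedExperiment::SummarizedExperiment(
        assays = list(log2expr = values), colData = cd))
}

#' RatioGrid: per-cell log2 fold changes against a declared baseline
#'
#' Columns are design-space cells (one per retained `(dose, time)`
#' combination), rows are genes; entries are log2 ratios against the baseline
#' declared by `baselineKind`:
#' * `global_t0` — the (dose 0, time 0) sample(s), per subject when subjects
#'   are annotated;
#' * `time_matched_dose0` — the dose-0 sample(s) at the cell's own time;
#' * `untreated_vs_t0` — dose-0, time > 0 samples against the t0 baseline
#'   (the grid used by the background drift filter).
#'
#' @slot values numeric matrix, genes x cells, finite.
#' @slot cellDose,cellTime numeric vectors parallel to the columns.
#' @slot baselineKind one of `"global_t0"`, `"time_matched_dose0"`,
#'   `"untreated_vs_t0"`.
#' @export
setClass("RatioGrid", representation(
  values = "matrix",
  cellDose = "numeric",
  cellTime = "numeric",
  baselineKind = "character"
))

setValidity("RatioGrid", function(object) {
  msg <- character()
  if (!object@baselineKind %in% .BASELINE_KINDS)
    msg <- c(msg, "unknown baselineKind")
  if (length(object@cellDose) != ncol(object@values) ||
      length(object@cellTime) != ncol(object@values))
    msg <- c(msg, "cellDose/cellTime must parallel the columns of values")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "ratios must be finite")
  if (length(msg)) msg else TRUE
})

#' GeneSet: a named set of gene identifiers
#'
#' @slot name set name (unique within a collection).
#' @slot genes character vector of unique gene ids (non-empty).
#' @slot source free-text provenance (e.g. the GMT description field).
#' @slot smallSet TRUE when the set held fewer than `minStableSize` genes
#'   after intersection with the data; such sets are unstable under
#'   filtering and results should be read with caution.
#' @export
setClass("GeneSet", representation(
  name = "character", genes = "character", source = "character",
  smallSet = "logical"
))

setValidity("GeneSet", function(object) {
  msg <- character()
  if (length(object@genes) == 0) msg <- c(msg, "gene set is empty")
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate genes in set")
  if (length(msg)) msg else TRUE
})

#' @rdname GeneSet-class
#' @param name,genes,source,smallSet see slots.
#' @export
GeneSet <- function(name, genes, source = "", smallSet = FALSE) {
  new("GeneSet", name = as.character(name), genes = unique(as.character(genes)),
      source = as.character(source), smallSet = smallSet)
}

#' GeneSetCollection: an ordered list of gene sets with unique names
#'
#' @slot sets list of [GeneSet-class] objects, file order preserved.
#' @export
setClass("GeneSetCollection", representation(sets = "list"))

setValidity("GeneSetCollection", function(object) {
  nm <- vapply(object@sets, function(s) s@name, character(1))
  if (anyDuplicated(nm)) return("duplicate gene set names")
  TRUE
})

#' @rdname GeneSetCollection-class
#' @param sets list of [GeneSet-class] objects.
#' @export
GeneSetCollection <- function(sets) new("GeneSetCollection", sets = sets)

#' DegMap: per-cell counts of genes past a fold-change cutoff
#'
#' @slot counts numeric matrix, doses in rows, times in columns (dimnames are
#'   the numeric levels as strings); `NA` marks missing cells.
#' @slot cutoff the |log2 FC| cutoff used (strictly-greater convention).
#' @slot baselineKind baseline of the underlying [RatioGrid-class].
#' @slot nGenes number of genes the counts were computed over.
#' @export
setClass("DegMap", representation(
  counts = "matrix", cutoff = "numeric", baselineKind = "character",
  nGenes = "integer"
))

setValidity("DegMap", function(object) {
  cnt <- object@counts
  if (any(cnt < 0 | cnt > object@nGenes, na.rm = TRUE))
    return("counts must lie in [0, nGenes]")
  TRUE
})

#' RestrictionMask: usable vs non-specific design-space cells
#'
#' A cell is non-specific iff its DEG count is greater than or equal to the
#' resolved threshold; such cells are excluded from enrichment.
#'
#' @slot nonspecific logical matrix aligned with the [DegMap-class] counts
#'   (`NA` for missing cells).
#' @slot threshold resolved DEG-count threshold.
#' @slot thresholdSpec the threshold as requested (count, or fraction < 1).
#' @export
setClass("RestrictionMask", representation(
  nonspecific = "matrix", threshold = "numeric", thresholdSpec = "numeric"
))

#' BackgroundFilterResult: genes drifting in untreated samples
#'
#' @slot removedGenes genes with |log2 FC| > cutoff in at least one untreated
#'   (dose 0, time > 0) cell relative to t0.
#' @slot keptGenes the complementary ordered gene list.
#' @slot cutoff the |log2 FC| cutoff used.
#' @export
setClass("BackgroundFilterResult", representation(
  removedGenes = "character", keptGenes = "character", cutoff = "numeric"
))

#' EnrichmentDiagram: a per-gene-set p-value map over the design space
#'
#' Holds raw and BH-adjusted competitive enrichment p-values per usable
#' design-space cell, the adaptive colour values (0 = red, 1 = grey) and the
#' sweet-spot mask once [classifySweetSpots()] has run.
#'
#' @slot setName gene set name.
#' @slot pRaw,pAdj numeric matrices (doses x times; `NA` = missing or
#'   restricted cell).
#' @slot pMin lowest adjusted p in the diagram.
#' @slot pMax colour-scale span used by the adaptive key.
#' @slot colorValue numeric matrix in `[0, 1]` (NA until classified).
#' @slot sweetMask logical matrix; `TRUE` = red cell = sweet spot.
#' @slot nGenesUsed set size after intersection with the data.
#' @slot meta list of provenance (alternative, method, thresholds...).
#' @export
setClass("EnrichmentDiagram", representation(
  setName = "character", pRaw = "matrix", pAdj = "matrix",
  pMin = "numeric", pMax = "numeric", colorValue = "matrix",
  sweetMask = "matrix", nGenesUsed = "integer", meta = "list"
))

setValidity("EnrichmentDiagram", function(object) {
  msg <- character()
  pr <- object@pRaw; pa <- object@pAdj
  if (any(pr < 0 | pr > 1, na.rm = TRUE) || any(pa < 0 | pa > 1, na.rm = TRUE))
    msg <- c(msg, "p-values must lie in [0, 1]")
  if (any(pa < pr - 1e-12, na.rm = TRUE))
    msg <- c(msg, "adjusted p-values must be >= raw p-values cellwise")
  if (length(msg)) msg else TRUE
})

#' CorrelationTable: per-gene, per-time dose-response correlations
#'
#' @slot setName gene set name.
#' @slot r numeric matrix genes x times of Pearson correlations between dose
#'   and log2 ratio (`NA` where fewer than `minPoints` doses were available).
#' @slot relevant logical matrix, `TRUE` where |r| exceeds the relevance
#'   threshold (strictly).
#' @slot sweetTimes times (minutes) whose diagram column holds a sweet spot
#'   at any dose.
#' @slot threshold the relevance threshold on |r|.
#' @export
setClass("CorrelationTable", representation(
  setName = "character", r = "matrix", relevant = "matrix",
  sweetTimes = "numeric", threshold = "numeric"
))

setValidity("CorrelationTable", function(object) {
  if (any(abs(object@r) > 1 + 1e-12, na.rm = TRUE))
    return("correlations must lie in [-1, 1]")
  TRUE
})
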