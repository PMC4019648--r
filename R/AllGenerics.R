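#' @rdname DesignGrid-class
#' @param x a package object.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname DesignGrid-class
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname DesignGrid-class
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname DesignGrid-class
#' @export
setGeneric("doseLevels", function(x) standardGeneric("doseLevels"))

#' @rdname DesignGrid-class
#' @export
setGeneric("timeLevels", function(x) standardGeneric("timeLevels"))

#' @rdname DesignGrid-class
#' @export
setGeneric("okSamples", function(x) standardGeneric("okSamples"))

#' @rdname RatioGrid-class
#' @param x a package object.
#' @export
setGeneric("ratioValues", function(x) standardGeneric("ratioValues"))

#' @rdname RatioGrid-class
#' @export
setGeneric("cellInfo", function(x) standardGeneric("cellInfo"))

#' @rdname RatioGrid-class
#' @export
setGeneric("baselineKind", function(x) standardGeneric("baselineKind"))

#' @rdname GeneSetCollection-class
#' @param x a package object.
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))

#' @rdname GeneSetCollection-class
#' @export
setGeneric("geneSetNames", function(x) standardGeneric("geneSetNames"))

#' @rdname EnrichmentDiagram-class
#' @param x a package object.
#' @export
setGeneric("pRaw", function(x) standardGeneric("pRaw"))

#' @rdname EnrichmentDiagram-class
#' @export
setGeneric("pAdjusted", function(x) standardGeneric("pAdjusted"))

#' @rdname EnrichmentDiagram-class
#' @export
setGeneric("sweetMask", function(x) standardGeneric("sweetMask"))

#' @rdname EnrichmentDiagram-class
#' @export
setGeneric("colorValues", function(x) standardGeneric("colorValues"))

#' @rdname DegMap-class
#' @param x a package object.
#' @export
setGeneric("degCounts", function(x) standardGeneric("degCounts"))

#' @rdname RestrictionMask-class
#' @param x a package object.
#' @export
setGeneric("usableCells", function(x) standardGeneric("usableCells"))
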