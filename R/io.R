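# Readers and writers for expression grids, sample annotations and gene sets.

#' Read a DesignGrid from an expression TSV and an annotation TSV
#'
#' The expression file has gene ids in the first column and one column per
#' sample (header row of sample ids), values on log2 scale. The annotation
#' file has one row per sample with columns `sample_id`, `dose`, `time_min`,
#' optional `subject_id` and `status` (`ok`/`failed`). Every expression
#' column must have an annotation row and vice versa. Failed samples may
#' carry empty/NA expression values.
#'
#' @param exprPath path to the expression TSV.
#' @param annotPath path to the annotation TSV.
#' @return a [DesignGrid-class].
#' @export
readDesignGrid <- function(exprPath, annotPath) {
  expr <- read.delim(exprPath, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(expr) < 2) stop("expression table needs a gene column plus samples")
  gene <- as.character(expr[[1]])
  mat <- as.matrix(expr[, -1, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- gene
  annot <- read.delim(annotPath, stringsAsFactors = FALSE)
  DesignGrid(mat, annot)
}

#' Write a DesignGrid to an expression TSV and an annotation TSV
#'
#' Values are written with 17 significant digits so a read round-trip is
#' bit-exact.
#'
#' @param grid a [DesignGrid-class].
#' @param exprPath,annotPath output paths.
#' @return invisibly, the two paths.
#' @export
writeDesignGrid <- function(grid, exprPath, annotPath) {
  mat <- exprValues(grid)
  df <- data.frame(gene_id = rownames(mat), .formatNum(mat),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  si <- sampleInfo(grid)
  si$dose <- .formatNum(si$dose)
  si$time_min <- .formatNum(si$time_min)
  write.table(si, annotPath, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(c(exprPath, annotPath))
}

.formatNum <- function(x) {
  if (is.matrix(x)) {
    out <- matrix(sprintf("%.17g", x), nrow = nrow(x), dimnames = dimnames(x))
    out[is.na(x)] <- ""
    out
  } else {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- ""
    out
  }
}

#' Read a gene-set collection from a GMT file
#'
#' Standard GMT dialect: one set per line, `name TAB description TAB gene
#' ids...`. File order is preserved; duplicate gene ids within a set are
#' counted once. A duplicated set name or an empty set is an error.
#'
#' @param path path to the GMT file.
#' @param minStableSize sets smaller than this after reading are flagged as
#'   small (results for such sets are unstable under gene filtering).
#' @return a [GeneSetCollection-class].
#' @export
readGMT <- function(path, minStableSize = 20) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 2)
      stop("malformed GMT line (need name, description, genes): ",
           substr(ln, 1, 50))
    genes <- unique(parts[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("empty gene set: ", parts[1])
    GeneSet(parts[1], genes, source = parts[2],
            smallSet = length(genes) < minStableSize)
  })
  nm <- vapply(sets, function(s) s@name, character(1))
  if (anyDuplicated(nm))
    stop("duplicate gene set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  GeneSetCollection(sets)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [GeneSetCollection-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeGMT <- function(collection, path) {
  lines <- vapply(geneSets(collection), function(s)
    paste(c(s@name, s@source, s@genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersect a gene set with the genes present in the data
#'
#' Restricts a set to the genes of a grid (or to an explicit gene universe).
#' An empty intersection is an error naming the set; an intersection below
#' `minStableSize` flags the set as small.
#'
#' @param set a [GeneSet-class].
#' @param grid a [DesignGrid-class], [RatioGrid-class], or character vector
#'   of gene ids.
#' @param minStableSize instability threshold on the resulting size
#'   (default 20).
#' @return the restricted [GeneSet-class]; the original size is retained in
#'   an attribute-free manner via the unchanged `source` field.
#' @export
intersectWithData <- function(set, grid, minStableSize = 20) {
  universe <- if (is.character(grid)) grid else geneIds(grid)
  keep <- set@genes[set@genes %in% universe]
  if (!length(keep))
    stop("gene set ", sQuote(set@name), " has no genes in the data")
  small <- length(keep) < minStableSize
  if (small && !set@smallSet)
    warning("gene set ", sQuote(set@name), " has only ", length(keep),
            " genes after intersection with the data (< ", minStableSize,
            "): results may be unstable")
  GeneSet(set@name, keep, source = set@source, smallSet = small)
}
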