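# Competitive gene-set enrichment over the design space, BH correction,
# adaptive colour key and sweet-spot classification.

#' Enrichment configuration
#'
#' @param alternative `"mixed"` tests whether set genes sit among the large
#'   |log2 ratios| regardless of direction (the default: a set is
#'   interesting when its genes move, up or down); `"up"` / `"down"` are
#'   one-directional on the signed statistic.
#' @param method `"rank"`: a competitive Wilcoxon rank-sum (mean-rank) test,
#'   one-sided toward set enrichment, exact for small gene universes and
#'   normal-approximated (with tie correction and continuity correction)
#'   otherwise. `"permutation"`: a seeded gene-permutation test comparing
#'   the set's mean statistic against random same-size gene subsets, with
#'   the add-one estimator so p is never zero.
#' @param nPermutations number of random subsets for the permutation method
#'   (default 9999; at least 99).
#' @param seed optional integer seed applied before the permutation draw.
#' @param pmax colour-scale span of the adaptive key: the scale runs from
#'   pmin (red) to pmin + pmax (grey). Presets from the two case studies:
#'   0.2 (in-vitro, the conservative default) and 0.01 (in-vivo); see
#'   [pmaxPreset()].
#' @param redBandFraction fraction of the active colour scale counted as
#'   "red", i.e. as sweet spot (default 0.25).
#' @param fallbackFloor,fallbackCeiling when the lowest adjusted p exceeds
#'   `fallbackFloor` (0.3) the colouring falls back to a fixed
#'   `fallbackFloor` (red) to `fallbackCeiling` (0.5, grey) scale and no
#'   sweet spots are declared — the red anchor is unoccupied.
#' @param bhScope `"diagram"` adjusts p-values across the usable cells of
#'   each gene set's own diagram (the diagram is the visual unit);
#'   `"global"` adjusts across all sets and cells jointly.
#' @param exactLimit gene universes up to this size use the exact rank-sum
#'   permutation distribution (default 60).
#' @return a list of class `EnrichmentConfig`.
#' @export
enrichmentConfig <- function(alternative = c("mixed", "up", "down"),
                             method = c("rank", "permutation"),
                             nPermutations = 9999,
                             seed = NULL,
                             pmax = 0.2,
                             redBandFraction = 0.25,
                             fallbackFloor = 0.3,
                             fallbackCeiling = 0.5,
                             bhScope = c("diagram", "global"),
                             exactLimit = 60) {
  method <- match.arg(method)
  if (method == "permutation" && nPermutations < 99)
    stop("nPermutations must be >= 99 for the permutation method")
  stopifnot(pmax > 0, redBandFraction > 0, redBandFraction < 1,
            fallbackCeiling > fallbackFloor)
  structure(list(
    alternative = match.arg(alternative), method = method,
    nPermutations = as.integer(nPermutations), seed = seed, pmax = pmax,
    redBandFraction = redBandFraction, fallbackFloor = fallbackFloor,
    fallbackCeiling = fallbackCeiling, bhScope = match.arg(bhScope),
    exactLimit = as.integer(exactLimit)
  ), class = "EnrichmentConfig")
}

#' Colour-scale span presets from the two case studies
#'
#' @param which `"invitro"` (0.2) or `"invivo"` (0.01).
#' @return the pmax value.
#' @export
pmaxPreset <- function(which = c("invitro", "invivo")) {
  switch(match.arg(which), invitro = 0.2, invivo = 0.01)
}

.transformStats <- function(statistics, alternative) {
  switch(alternative,
         mixed = abs(statistics),
         up = statistics,
         down = -statistics)
}

# Exact one-sided p for the set rank-sum: fraction of all size-k subsets of
# the (doubled, hence integer) midranks whose sum is >= the observed sum.
# Dynamic-programming count over subset sums; counts held as doubles.
.exactRankSumP <- function(ranks2, k, obs2) {
  S <- sum(ranks2)
  f <- matrix(0, nrow = k + 1, ncol = S + 1)
  f[1, 1] <- 1
  seen <- 0L
  for (v in ranks2) {
    seen <- seen + 1L
    for (j in min(k, seen):1) {
      if (v > 0)
        f[j + 1, (v + 1):(S + 1)] <- f[j + 1, (v + 1):(S + 1)] +
          f[j, 1:(S + 1 - v)]
    }
  }
  tail <- f[k + 1, seq.int(obs2 + 1, S + 1)]
  sum(tail) / choose(length(ranks2), k)
}

#' Competitive gene-set enrichment test on one design-space cell
#'
#' Tests whether the genes of a set carry larger statistics (per-gene log2
#' ratios of one cell; absolute values under the default `mixed`
#' alternative) than the remaining genes, with genes as the unit of
#' randomization. The test assumes set genes are on average no more
#' correlated than random genes; with inter-gene correlation p-values run
#' low, which is acceptable for screening where ranges, not exact p-values,
#' are sought.
#'
#' @param statistics named numeric vector of per-gene statistics (a
#'   [RatioGrid-class] column).
#' @param set a [GeneSet-class], a character vector of gene ids, or an
#'   integer/logical index into `statistics`.
#' @param config an [enrichmentConfig()].
#' @return a single p-value.
#' @export
geneSetEnrichmentTest <- function(statistics, set,
                                  config = enrichmentConfig()) {
  if (is(set, "GeneSet")) set <- set@genes
  if (is.character(set)) {
    if (is.null(names(statistics)))
      stop("statistics must be named when the set is given as gene ids")
    inSet <- names(statistics) %in% set
  } else if (is.logical(set)) {
    inSet <- set
  } else {
    inSet <- seq_along(statistics) %in% set
  }
  N <- length(statistics); k <- sum(inSet)
  if (k < 2) stop("gene set has fewer than 2 genes in the statistic vector")
  if (k >= N) stop("gene set must be a proper subset of the genes")
  s <- .transformStats(statistics, config$alternative)
  if (all(s == s[1])) {
    warning("constant statistic vector: p = 1")
    return(1)
  }
  if (config$method == "rank") {
    r <- rank(s, ties.method = "average")
    W <- sum(r[inSet])
    if (N <= config$exactLimit) {
      ranks2 <- as.integer(round(2 * r))
      return(.exactRankSumP(ranks2, k, as.integer(round(2 * W))))
    }
    n2 <- N - k
    mu <- k * (N + 1) / 2
    ties <- table(r)
    tieCorr <- sum(ties^3 - ties) / (N * (N - 1))
    sigma2 <- k * n2 / 12 * ((N + 1) - tieCorr)
    if (sigma2 <= 0) {
      warning("degenerate rank variance: p = 1")
      return(1)
    }
    return(pnorm((W - 0.5 - mu) / sqrt(sigma2), lower.tail = FALSE))
  }
  # gene-permutation on the mean statistic, add-one estimator
  if (!is.null(config$seed)) set.seed(config$seed)
  obs <- mean(s[inSet])
  B <- config$nPermutations
  hits <- 0L
  for (b in seq_len(B)) {
    if (mean(s[sample.int(N, k)]) >= obs) hits <- hits + 1L
  }
  (1 + hits) / (1 + B)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Standard step-up adjustment: sorted ascending, `p[i] * m / i` with a
#' cumulative minimum from the largest p downwards, capped at 1 and
#' returned in the input order.
#'
#' @param p numeric vector of p-values in \[0, 1\] (no NAs).
#' @return adjusted p-values, same length and order.
#' @export
benjaminiHochberg <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no NAs")
  m <- length(p)
  if (m <= 1) return(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(p[o] * m / seq.int(m, 1)))[ro]
}

.alignMask <- function(mask, cellDose, cellTime) {
  if (is.null(mask)) return(rep(TRUE, length(cellDose)))
  ns <- mask@nonspecific
  i <- match(as.character(cellDose), rownames(ns))
  j <- match(as.character(cellTime), colnames(ns))
  flag <- ns[cbind(i, j)]
  is.na(flag) | !flag            # cells unknown to the mask stay usable
}

#' Enrich every gene set over the usable design space
#'
#' Runs [geneSetEnrichmentTest()] on each usable cell of a time-matched
#' ratio grid for each gene set (after intersection with the data), then
#' applies Benjamini-Hochberg correction within each set's diagram (or
#' globally, per `config$bhScope`). Sets that fail (e.g. fewer than 2 genes
#' in the data) are skipped with a warning and reported in the
#' `"skipped"` attribute; remaining sets are processed.
#'
#' @param ratios a [RatioGrid-class], normally with baseline
#'   `time_matched_dose0` and the background filter already applied.
#' @param sets a [GeneSetCollection-class] (or list of [GeneSet-class]).
#' @param mask optional [RestrictionMask-class]; non-specific cells are not
#'   tested.
#' @param config an [enrichmentConfig()].
#' @return named list of [EnrichmentDiagram-class] (not yet classified; see
#'   [classifySweetSpots()]).
#' @export
enrichDesignSpace <- function(ratios, sets, mask = NULL,
                              config = enrichmentConfig()) {
  if (is(sets, "GeneSetCollection")) sets <- geneSets(sets)
  if (is(sets, "GeneSet")) sets <- list(sets)
  usable <- .alignMask(mask, ratios@cellDose, ratios@cellTime)
  if (!any(usable)) stop("no usable cells in the design space")
  if (config$method == "permutation" && !is.null(config$seed))
    set.seed(config$seed)
  cellConfig <- config; cellConfig$seed <- NULL
  genes <- rownames(ratios@values)
  diagrams <- list(); skipped <- character()
  for (set in sets) {
    p <- tryCatch({
      keep <- set@genes[set@genes %in% genes]
      if (length(keep) < 2)
        stop("fewer than 2 genes of set ", sQuote(set@name), " in the data")
      idx <- genes %in% keep
      vapply(which(usable), function(ci)
        geneSetEnrichmentTest(ratios@values[, ci], idx, cellConfig),
        numeric(1))
    }, error = function(e) {
      warning("skipping gene set ", sQuote(set@name), ": ",
              conditionMessage(e))
      NULL
    })
    if (is.null(p)) { skipped <- c(skipped, set@name); next }
    pAdj <- if (config$bhScope == "diagram") benjaminiHochberg(p) else p
    pRawM <- .cellMatrix(replace(rep(NA_real_, length(usable)), usable, p),
                         ratios@cellDose, ratios@cellTime)
    pAdjM <- .cellMatrix(replace(rep(NA_real_, length(usable)), usable, pAdj),
                         ratios@cellDose, ratios@cellTime)
    nUsed <- sum(genes %in% set@genes)
    diagrams[[set@name]] <- new("EnrichmentDiagram",
      setName = set@name, pRaw = pRawM, pAdj = pAdjM,
      pMin = min(pAdj), pMax = config$pmax,
      colorValue = pAdjM * NA, sweetMask = matrix(NA, nrow(pAdjM), ncol(pAdjM),
                                                  dimnames = dimnames(pAdjM)),
      nGenesUsed = as.integer(nUsed),
      meta = list(alternative = config$alternative, method = config$method,
                  nPermutations = if (config$method == "permutation")
                    config$nPermutations else NA_integer_,
                  bhScope = config$bhScope, smallSet = nUsed < 20))
  }
  if (config$bhScope == "global" && length(diagrams)) {
    allP <- unlist(lapply(diagrams, function(d) d@pRaw[!is.na(d@pRaw)]))
    adj <- benjaminiHochberg(allP)
    off <- 0L
    for (nm in names(diagrams)) {
      d <- diagrams[[nm]]
      sel <- !is.na(d@pRaw)
      n <- sum(sel)
      d@pAdj[sel] <- adj[off + seq_len(n)]
      d@pMin <- min(d@pAdj, na.rm = TRUE)
      off <- off + n
      diagrams[[nm]] <- d
    }
  }
  attr(diagrams, "skipped") <- skipped
  diagrams
}

#' Classify sweet spots with the adaptive colour key
#'
#' Maps adjusted p-values to colour values in \[0, 1\] (0 = red, 1 = grey).
#' If the lowest adjusted p-value (pmin) exceeds `fallbackFloor` (0.3) the
#' scale runs from 0.3 (red) to `fallbackCeiling` (0.5, grey) and no sweet
#' spots are declared: the red anchor is unoccupied and the fixed scale
#' shows a non-finding. Otherwise the scale runs from pmin (red) to
#' pmin + pmax (grey) and cells whose colour value is within
#' `redBandFraction` of the red end are classified as sweet spots.
#'
#' @param diagram an [EnrichmentDiagram-class] with adjusted p-values.
#' @param config an [enrichmentConfig()] (supplies pmax, redBandFraction
#'   and the fallback scale; the diagram's stored pMax is updated from it).
#' @return the diagram with `colorValue`, `sweetMask` and `pMax` filled in.
#' @export
classifySweetSpots <- function(diagram, config = enrichmentConfig()) {
  pa <- diagram@pAdj
  pmin_ <- min(pa, na.rm = TRUE)
  if (pmin_ > config$fallbackFloor) {
    colorv <- (pa - config$fallbackFloor) /
      (config$fallbackCeiling - config$fallbackFloor)
    colorv <- pmin(pmax(colorv, 0), 1)
    sweet <- matrix(FALSE, nrow(pa), ncol(pa), dimnames = dimnames(pa))
    sweet[is.na(pa)] <- NA
  } else {
    colorv <- (pa - pmin_) / config$pmax
    colorv <- pmin(pmax(colorv, 0), 1)
    sweet <- colorv <= config$redBandFraction
  }
  diagram@colorValue <- colorv
  diagram@sweetMask <- sweet
  diagram@pMin <- pmin_
  diagram@pMax <- config$pmax
  diagram@meta$redBandFraction <- config$redBandFraction
  diagram
}

#' Random-set diagnostic: are sweet-spot patterns likely by chance?
#'
#' Runs randomly composed gene sets of a given size through enrichment and
#' classification, and reports the distribution of per-diagram lowest
#' adjusted p-values and the fraction of random diagrams showing any sweet
#' spot. On data without real signal that fraction approximates the
#' visual false-positive rate of the red band; on real data a planted or
#' biological pattern should stand far outside this reference
#' distribution.
#'
#' @param ratios a [RatioGrid-class].
#' @param mask optional [RestrictionMask-class].
#' @param size genes per random set (>= 2).
#' @param nSets number of random sets (default 100).
#' @param seed integer seed (draws are reproducible given the seed).
#' @param config an [enrichmentConfig()].
#' @return data.frame (set, pmin, nSweet) with attributes
#'   `"fractionWithSweet"` and `"pminSummary"`.
#' @export
randomSetDiagnostic <- function(ratios, mask = NULL, size, nSets = 100,
                                seed = NULL, config = enrichmentConfig()) {
  stopifnot(size >= 2)
  genes <- rownames(ratios@values)
  if (size >= length(genes) - 1)
    warning("random set size ", size, " nearly exhausts the ",
            length(genes), "-gene universe: test is degenerate")
  if (!is.null(seed)) set.seed(seed)
  sets <- lapply(seq_len(nSets), function(i)
    GeneSet(sprintf("random_%04d", i), sample(genes, size),
            source = "random diagnostic"))
  diagrams <- enrichDesignSpace(ratios, GeneSetCollection(sets), mask, config)
  diagrams <- lapply(diagrams, classifySweetSpots, config = config)
  out <- data.frame(
    set = names(diagrams),
    pmin = vapply(diagrams, function(d) d@pMin, numeric(1)),
    nSweet = vapply(diagrams, function(d) sum(d@sweetMask, na.rm = TRUE),
                    integer(1)),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "fractionWithSweet") <- mean(out$nSweet > 0)
  attr(out, "pminSummary") <- summary(out$pmin)
  out
}
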