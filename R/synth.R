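# Synthetic range-finding experiments with known ground truth.

#' Describe a planted gene-set activation
#'
#' @param size number of genes in the module.
#' @param activeCells data.frame with columns `dose`, `time` (minutes): the
#'   design-space cells where the module responds.
#' @param amplitude log2-unit effect size at the strongest active dose.
#' @param doseShape `"linear"` (effect proportional to dose), `"saturating"`
#'   (dose / (dose + K), K = median active dose) or `"threshold"` (full
#'   effect at or above the lowest active dose). Shapes are normalized so
#'   the maximum active dose receives exactly `amplitude`.
#' @param name module (gene set) name.
#' @return a list describing the module.
#' @export
plantedModule <- function(size, activeCells, amplitude = 1.5,
                          doseShape = c("linear", "saturating", "threshold"),
                          name = "planted") {
  stopifnot(size >= 2, nrow(activeCells) >= 1,
            all(c("dose", "time") %in% colnames(activeCells)))
  list(size = as.integer(size), activeCells = activeCells,
       amplitude = amplitude, doseShape = match.arg(doseShape), name = name)
}

#' Specify a synthetic range-finding experiment
#'
#' @param doses dose levels (first must be 0: the untreated row).
#' @param times recovery times in minutes (all > 0; the generator adds the
#'   required t = 0 baseline sample(s) itself).
#' @param nGenes number of genes.
#' @param noiseSd Gaussian noise SD in log2 units (applied to every value).
#' @param layout `"invitro_single"`: one sample per (dose, time) cell plus a
#'   single t0 control. `"invivo_paired"`: two subjects per dose, sampled
#'   alternately over the time course, each with its own pre-exposure
#'   baseline sample at (dose 0, time 0).
#' @param plantedModules list of [plantedModule()] descriptions.
#' @param driftGenes list(count, amplitude, timeShape) describing background
#'   genes that change over time in all samples including dose 0 (growth /
#'   circadian drift); `timeShape` is `"linear"` or `"step"` (step switches
#'   on at the median recovery time).
#' @param subjectOffsetsSd SD of per-subject additive offsets (log2 units;
#'   `invivo_paired` only). Explicit offsets can be supplied via
#'   `subjectOffsets` as a named vector instead.
#' @param subjectOffsets optional named numeric vector of fixed per-subject
#'   offsets (overrides `subjectOffsetsSd`).
#' @param stressCells data.frame (`dose`, `time`) of cells with a
#'   transcriptome-wide non-specific response.
#' @param stressFraction fraction of all genes perturbed at stress cells
#'   (default 0.10, the non-specific-response scale).
#' @param stressAmplitude log2 shift (random sign) of stressed genes
#'   (default 2.5).
#' @param seed integer seed.
#' @return a list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(doses, times, nGenes = 2000, noiseSd = 0.25,
                          layout = c("invitro_single", "invivo_paired"),
                          plantedModules = list(),
                          driftGenes = list(count = 0, amplitude = 2,
                                            timeShape = "linear"),
                          subjectOffsetsSd = 0.3,
                          subjectOffsets = NULL,
                          stressCells = NULL,
                          stressFraction = 0.10,
                          stressAmplitude = 2.5,
                          seed = 1) {
  layout <- match.arg(layout)
  doses <- sort(unique(as.numeric(doses)))
  times <- sort(unique(as.numeric(times)))
  if (doses[1] != 0) stop("doses must include 0 (the untreated row)")
  if (any(times <= 0)) stop("times are recovery times and must be > 0")
  totalPlanted <- sum(vapply(plantedModules, `[[`, integer(1), "size")) +
    driftGenes$count
  if (totalPlanted > nGenes)
    stop("planted module and drift genes exceed nGenes")
  for (m in plantedModules) {
    bad <- !(m$activeCells$dose %in% doses) | !(m$activeCells$time %in% times)
    if (any(bad))
      stop("module ", m$name, ": active cell(s) outside the dose x time grid")
  }
  structure(list(doses = doses, times = times, nGenes = as.integer(nGenes),
                 noiseSd = noiseSd, layout = layout,
                 plantedModules = plantedModules, driftGenes = driftGenes,
                 subjectOffsetsSd = subjectOffsetsSd,
                 subjectOffsets = subjectOffsets,
                 stressCells = stressCells, stressFraction = stressFraction,
                 stressAmplitude = stressAmplitude, seed = as.integer(seed)),
            class = "SyntheticSpec")
}

.doseShapeFun <- function(shape, activeDoses) {
  dmax <- max(activeDoses)
  switch(shape,
    linear = function(d) d / dmax,
    saturating = {
      K <- stats::median(activeDoses)
      norm <- dmax / (dmax + K)
      function(d) (d / (d + K)) / norm
    },
    threshold = {
      dmin <- min(activeDoses)
      function(d) as.numeric(d >= dmin)
    })
}

.timeShapeFun <- function(shape, times) {
  switch(shape,
    linear = function(t) t / max(times),
    step = {
      tstep <- stats::median(times)
      function(t) as.numeric(t >= tstep)
    },
    stop("unknown timeShape: ", shape))
}

.layoutSamples <- function(spec) {
  if (spec$layout == "invitro_single") {
    treat <- expand.grid(time = spec$times, dose = spec$doses)[, c("dose", "time")]
    df <- rbind(data.frame(dose = 0, time = 0), treat)
    df$subject_id <- NA_character_
    df$baseline <- df$time == 0
  } else {
    rows <- list(); i <- 0L
    for (d in spec$doses) {
      subj <- paste0("m_d", d, "_", c("a", "b"))
      for (s in subj) {
        i <- i + 1L
        rows[[i]] <- data.frame(dose = 0, time = 0, subject_id = s,
                                baseline = TRUE)
      }
      for (ti in seq_along(spec$times)) {
        i <- i + 1L
        rows[[i]] <- data.frame(dose = d, time = spec$times[ti],
                                subject_id = subj[1 + (ti + 1) %% 2],
                                baseline = FALSE)
      }
    }
    df <- do.call(rbind, rows)
  }
  df$sample_id <- sprintf("s%03d", seq_len(nrow(df)))
  df
}

#' Generate a synthetic DesignGrid with its ground-truth record
#'
#' Baseline log2 expression per gene is Normal(8, 2); planted modules add
#' `amplitude * doseShape(dose)` at their active cells; drift genes add
#' `amplitude * timeShape(time)` in every sample including dose 0; the
#' in-vivo layout adds per-subject offsets (also to each subject's own
#' baseline, as a real between-animal effect would); stress cells shift a
#' `stressFraction` of all genes by `stressAmplitude` with random signs;
#' Gaussian noise with `noiseSd` tops everything. All randomness is
#' governed by `spec$seed`.
#'
#' The returned truth record is sufficient to compute every downstream
#' expectation at zero noise (DEG counts, the background-filter gene list,
#' restricted cells, sweet-spot locations) without re-simulation.
#'
#' @param spec a [syntheticSpec()].
#' @return list with elements `grid` ([DesignGrid-class]) and `truth`.
#' @export
simulateDesignGrid <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  genes <- sprintf("g%05d", seq_len(spec$nGenes))
  samples <- .layoutSamples(spec)
  n <- nrow(samples)

  # assign planted gene identities: modules first, then drift genes
  cursor <- 0L
  moduleGenes <- list()
  for (m in spec$plantedModules) {
    moduleGenes[[m$name]] <- genes[cursor + seq_len(m$size)]
    cursor <- cursor + m$size
  }
  driftIds <- if (spec$driftGenes$count > 0)
    genes[cursor + seq_len(spec$driftGenes$count)] else character(0)

  mu <- rnorm(spec$nGenes, mean = 8, sd = 2)
  mat <- matrix(mu, nrow = spec$nGenes, ncol = n,
                dimnames = list(genes, samples$sample_id))

  for (m in spec$plantedModules) {
    shapeFun <- .doseShapeFun(m$doseShape, m$activeCells$dose)
    gi <- match(moduleGenes[[m$name]], genes)
    for (ci in seq_len(nrow(m$activeCells))) {
      sel <- samples$dose == m$activeCells$dose[ci] &
        samples$time == m$activeCells$time[ci]
      if (any(sel))
        mat[gi, sel] <- mat[gi, sel] +
          m$amplitude * shapeFun(m$activeCells$dose[ci])
    }
  }

  if (length(driftIds)) {
    tf <- .timeShapeFun(spec$driftGenes$timeShape, spec$times)
    gi <- match(driftIds, genes)
    drift <- spec$driftGenes$amplitude * tf(samples$time)
    mat[gi, ] <- mat[gi, ] + rep(drift, each = length(gi))
  }

  subjectOffsets <- NULL
  if (spec$layout == "invivo_paired") {
    subj <- unique(samples$subject_id)
    subjectOffsets <- spec$subjectOffsets
    if (is.null(subjectOffsets)) {
      subjectOffsets <- setNames(rnorm(length(subj), 0, spec$subjectOffsetsSd),
                                 subj)
    }
    mat <- mat + rep(subjectOffsets[samples$subject_id], each = spec$nGenes)
  }

  stressGenes <- list()
  if (!is.null(spec$stressCells) && nrow(spec$stressCells)) {
    nStress <- round(spec$stressFraction * spec$nGenes)
    for (ci in seq_len(nrow(spec$stressCells))) {
      sg <- sample(genes, nStress)
      signs <- sample(c(-1, 1), nStress, replace = TRUE)
      sel <- samples$dose == spec$stressCells$dose[ci] &
        samples$time == spec$stressCells$time[ci]
      key <- paste0("d", spec$stressCells$dose[ci], "_t",
                    spec$stressCells$time[ci])
      stressGenes[[key]] <- sg
      if (any(sel))
        mat[match(sg, genes), sel] <- mat[match(sg, genes), sel] +
          signs * spec$stressAmplitude
    }
  }

  if (spec$noiseSd > 0)
    mat <- mat + matrix(rnorm(length(mat), 0, spec$noiseSd), nrow = nrow(mat))

  grid <- DesignGrid(mat, data.frame(
    sample_id = samples$sample_id, dose = samples$dose,
    time_min = samples$time, subject_id = samples$subject_id,
    status = "ok", stringsAsFactors = FALSE))

  truth <- list(
    moduleGenes = moduleGenes,
    moduleCells = lapply(spec$plantedModules, `[[`, "activeCells"),
    driftGenes = driftIds,
    stressCells = spec$stressCells,
    stressGenes = stressGenes,
    subjectOffsets = subjectOffsets,
    baselineMeans = setNames(mu, genes),
    spec = spec
  )
  names(truth$moduleCells) <- names(moduleGenes)
  list(grid = grid, truth = truth)
}

#' Mark random non-baseline samples as failed
#'
#' Emulates occasional sample failures of a real range-finding run. The
#' t = 0 baseline sample(s) are never failed (every downstream baseline
#' would be lost). Failed samples get `NA` expression and are excluded from
#' all computations.
#'
#' @param grid a [DesignGrid-class].
#' @param nFailed number of samples to fail.
#' @param seed integer seed.
#' @return the grid with `nFailed` additional failed samples.
#' @export
failureMask <- function(grid, nFailed, seed = 1) {
  if (nFailed == 0) return(grid)
  cd <- SummarizedExperiment::colData(grid)
  eligible <- which(cd$status == "ok" & cd$time_min > 0)
  if (nFailed >= length(eligible))
    stop("nFailed = ", nFailed, " leaves no ok non-baseline samples")
  set.seed(seed)
  fail <- sample(eligible, nFailed)
  cd$status[fail] <- "failed"
  mat <- exprValues(grid)
  mat[, fail] <- NA_real_
  out <- grid
  SummarizedExperiment::colData(out) <- cd
  SummarizedExperiment::assay(out, "log2expr") <- mat
  out
}

#' Preset: an in-vitro-like UV-C range-finding layout
#'
#' 6 UV-C doses (0, 0.25, 0.75, 2.25, 6.7, 20 J/m2) x 8 recovery times
#' (10 min to 48 h), one sample per cell plus a t0 control — 49 samples.
#'
#' @param nGenes,noiseSd,seed,... passed to [syntheticSpec()].
#' @return a `SyntheticSpec`.
#' @export
invitroSpec <- function(nGenes = 24302, noiseSd = 0.25, seed = 1, ...) {
  syntheticSpec(doses = c(0, 0.25, 0.75, 2.25, 6.7, 20),
                times = c(10, 30, 60, 180, 360, 720, 1440, 2880),
                nGenes = nGenes, noiseSd = noiseSd,
                layout = "invitro_single", seed = seed, ...)
}

#' Preset: an in-vivo-like UV-B range-finding layout
#'
#' 6 UV-B doses (0, 90, 180, 360, 450, 720 J/m2) x 7 recovery times (1 h to
#' 48 h), two subjects per dose sampled alternately, each with its own
#' pre-exposure baseline — 54 samples.
#'
#' @param nGenes,noiseSd,seed,... passed to [syntheticSpec()].
#' @return a `SyntheticSpec`.
#' @export
invivoSpec <- function(nGenes = 24302, noiseSd = 0.25, seed = 1, ...) {
  syntheticSpec(doses = c(0, 90, 180, 360, 450, 720),
                times = c(60, 180, 360, 540, 720, 1440, 2880),
                nGenes = nGenes, noiseSd = noiseSd,
                layout = "invivo_paired", seed = seed, ...)
}
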