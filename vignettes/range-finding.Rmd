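---
title: "Range finding in a dose x time design space: methods and choices"
author: "rangefindr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Range finding in a dose x time design space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangefindr)
```

## The setting

A range-finding experiment covers a wide grid of experimental conditions —
here two axes, perturbation dose and recovery time — with **one sample per
cell** and no replication. The goal is not inference about individual
genes (impossible without replicates) but a map: for a gene set
representing a cellular process, where in the grid do those genes move
most? That location (the *sweet spot*) is where a subsequent, replicated
experiment should be placed. `rangefindr` takes a normalized log2
expression matrix with per-sample (dose, time, subject, status)
annotations and produces per-set enrichment diagrams, a design-space
restriction mask, and per-gene dose-response tables.

All times are stored in minutes internally (display layers convert to
hours); doses are in whatever unit the experiment uses (J/m² in the UV
examples). Gene identifiers are opaque strings. Dose × time grids need not
be complete rectangles; missing cells are tolerated at every stage.
Samples flagged `failed` carry no usable values and are excluded from
every computation.

## Baselines and ratio grids

Three log2-ratio baselines are used, each for a different question:

* **global t0** (`global_t0`) — every cell against the (dose 0, time 0)
  control; per subject when subjects are annotated, so each animal is
  compared with its own pre-exposure biopsy and additive between-animal
  offsets cancel exactly.
* **time-matched dose 0** (`time_matched_dose0`) — each treated cell
  against the untreated sample at the same recovery time. This is the grid
  used for enrichment and correlation screening: it isolates *dose*
  response from time drift.
* **untreated vs t0** (`untreated_vs_t0`) — the dose-0 time course against
  t0; the input of the background drift filter.

When several baseline samples qualify, their per-gene mean (log2 scale,
i.e. geometric mean of intensities) is used; the choice is arbitrary but
deterministic and documented here because the source protocol leaves it
open. Missing baselines drop the affected cell with a warning rather than
failing the run: incomplete grids are a fact of pilot experiments.

## Subject correction

In-vivo designs nest samples in animals. With single-replicate cells there
is no information to estimate variance components, so instead of a mixed
model the package fits, per gene, a fixed-effect least-squares model with
an intercept and sum-to-zero subject offsets over that gene's ok samples,
and subtracts the fitted offsets. In a balanced design this equals the
mixed-model point correction; in unbalanced designs the per-gene grand
mean is restored exactly after offset removal, which also makes the
operation idempotent. Offsets for a subject observed once are estimable
but confounded with that sample's condition — the function warns. Whether
dose/time should enter as fixed effects alongside subject is left out
deliberately: with one sample per (subject, condition) the saturated model
is not estimable, and offsets-only matches the correction's intent.

The exact-recovery guarantee ("corrected equals offset-free truth") holds
when the planted offsets sum to zero across subjects; a common shift of
all subjects is indistinguishable from a change of baseline and is neither
removable nor harmful.

## The enrichment test

Per design-space cell, the statistic vector is the per-gene log2 ratio of
that cell. The default **rank method** is a competitive Wilcoxon rank-sum
test with genes as the randomization unit: with midranks $r_i$ of the
transformed statistics (absolute values under the default `mixed`
alternative; signed or negated under `up`/`down`), the observed set
rank-sum $W = \sum_{i \in S} r_i$ is referred to the distribution of
same-size gene subsets.

* For gene universes up to `exactLimit` (default 60) the reference
  distribution is computed **exactly** by dynamic programming over subset
  sums of the doubled midranks; the p-value is the fraction of all
  $\binom{N}{k}$ subsets whose rank-sum reaches $W$. This matches
  brute-force enumeration bit-for-bit and is what small curated sets on
  toy universes exercise.
* Above that, the normal approximation is used with the standard tie
  correction, $\sigma^2 = \frac{k(N-k)}{12}\left((N+1) -
  \sum_t (t^3-t)/(N(N-1))\right)$, and a 0.5 continuity correction,
  one-sided toward enrichment.

A **gene-permutation method** draws `nPermutations` (default 9,999) random
same-size subsets and compares mean statistics, with the add-one estimator
$(1 + \#\{\bar s_{perm} \ge \bar s_{obs}\})/(1 + B)$ so p is never zero.
It is seeded and converges to the exhaustive enumeration value.

The competitive test assumes set genes are, on average, no more correlated
than random genes. Real pathways violate this, making p-values
anti-conservative; for *screening* — ranking cells within a diagram — this
is acceptable, and exact p-values belong to the replicated follow-up
experiment. Sets with fewer than 20 genes after intersection with the
filtered data are flagged: removal of single genes by upstream filters
makes their results unstable. Constant statistic vectors (e.g. a
zero-noise cell without signal) return p = 1 with a warning.

## Multiple testing and the adaptive colour key

Raw p-values are Benjamini–Hochberg adjusted **within each gene set's
diagram** across its usable cells. The diagram is the visual unit and its
lowest corrected p-value anchors the colour scale, which argues for the
per-diagram family; a `bhScope = "global"` option adjusts across all sets
and cells jointly for users who prefer one family. This family choice is
the largest judgment call in the package and is recorded in every output's
metadata. (Note the BH step-up adjustment is order-invariant and monotone
but *not* idempotent — re-adjusting adjusted values inflates them — so
adjusted values are never fed back through the procedure.)

The colour key maps adjusted p-values to [0, 1] (0 = red, 1 = grey):

* if $p_{min} \le 0.3$: $c = \min(1, (p_{adj} - p_{min})/p_{max})$, with
  `pmax` the scale span — presets 0.2 (in-vitro case, the conservative
  default) and 0.01 (in-vivo case);
* if $p_{min} > 0.3$: a fixed scale from 0.3 (red) to 0.5 (grey), and **no
  sweet spots are declared** — the red anchor is unoccupied and the
  fallback exists to display non-findings.

"Red" is operationalized as the lowest `redBandFraction` (default 0.25) of
the active scale, boundary inclusive; the original definition is visual,
so the fraction is configurable and echoed in output metadata. Lowering a
cell's adjusted p can only keep or add it to the sweet mask, never remove
it. The `randomSetDiagnostic()` routine estimates how often randomly
composed sets of a given size produce sweet spots on the same data — the
reference against which a real pattern must stand out.

## DEG counting, restriction, drift filter

DEG calls are directionless fold-change threshold crossings, strictly
greater than the cutoff (default |log2 FC| > 1, i.e. 2-fold); the
restriction threshold is greater-or-equal (default 2,000 DEGs, or a
fraction < 1 resolved against the gene total, 10% ≈ 2,430 of 24,302).
The asymmetric boundary conventions ("more than 2-fold" vs "2,000 or
more") are deliberate and configurable. The drift filter removes genes
with |log2 FC| > cutoff in *any* untreated cell and runs before, and
independently of, the restriction; DEG maps downstream are computed on the
filtered gene list.

## Dose-response screening

Per gene and time point, Pearson r between dose (natural scale — the
example designs span 0.25–20 and 90–720 J/m² without log spacing) and
log2 ratio. Dose 0 enters as an anchor with ratio identically 0, since the
ratio is defined against dose 0 itself; `includeZeroAnchor = FALSE`
removes it. At least `minPoints` (default 4) dose points are required;
|r| > 0.8 (strict) is relevant; genes never relevant are dropped from the
display table; remaining genes are ordered by earliest relevant time, then
descending |r| — a presentation rule that groups early/middle/late
responders, not a statistical claim. The display table prints only
relevant cells (blanks elsewhere) while the tidy output keeps the full
matrix.

## The synthetic generator

`simulateDesignGrid()` emulates the two pilot layouts: in-vitro-like
(6 doses × 8 recovery times, one sample per cell plus a t0 control, 49
samples) and in-vivo-like (6 doses × 7 times, two subjects per dose
sampled alternately, each with a pre-exposure baseline, 54 samples).
Ground truth is planted on a Normal(8, 2) log2 baseline:

* **modules** — gene sets adding `amplitude × doseShape(dose)` at chosen
  cells, with linear, saturating (d/(d+K), K the median active dose) or
  threshold shapes, normalized so the strongest active dose receives
  exactly the stated amplitude;
* **drift genes** — time-shaped changes in *all* samples including dose 0
  (growth/circadian stand-ins), which the background filter must remove;
* **subject offsets** — additive per-animal effects, drawn or fixed;
* **stress cells** — a stated fraction of all genes (default 10%) shifted
  by ±2.5 log2 units, the non-specific-response zones the restriction must
  flag;
* Gaussian noise, default SD 0.25 log2 units. The default is calibrated to
  realistic two-colour array log-ratio noise: over 8 untreated samples it
  makes the drift filter remove a few percent of null genes, the order
  observed in practice; at 0.5 the filter would remove over a third of the
  transcriptome, which no real normalized data set shows. Individual
  analyses that stress-test recovery use their own stated sigma.

Gaussian noise on the log2 scale (not a count model) matches the
two-colour array origin of the protocol. The generator does **not**
emulate probe-level artifacts, dye bias, amplification chemistry,
inter-gene correlation within pathways, or heavy-tailed noise — so passing
tests demonstrate correctness of the *computations* and detectability
under idealized noise, not performance guarantees on any real platform.
The truth record returned alongside the grid suffices to predict every
zero-noise downstream result without re-simulation.

## Numerical choices and degenerate inputs

* Exact-vs-approximate switch for the rank test at 60 genes; dynamic
  programming counts held in doubles (exact well beyond the sizes where
  the exact path is used).
* Midranks for ties everywhere; tie-corrected variance in the
  approximation; continuity correction 0.5.
* Cells are ordered by (dose, time) throughout; outputs are written with
  17 significant digits so read/write round trips are bit-exact and
  repeated runs are byte-identical.
* Zero-variance genes pass through subject correction unchanged;
  zero-variance statistic vectors yield p = 1 with a warning; correlation
  of a constant ratio series is NA, never relevant.
* Empty set-data intersections are errors naming the set; inside
  `enrichDesignSpace()` such sets are skipped with a warning so one bad
  set cannot abort a 64-set screen.
* All stochastic steps (permutation test, random-set diagnostic,
  simulation, failure masking) take explicit seeds; the pipeline threads
  one seed through everything.

## Problem sizes used in the validation suite

The suite validates the rank test exactly on universes up to 10 genes
(against full enumeration), calibrates null p-values on 2,000 simulated
cells of 400 exchangeable genes, measures planted-module recovery on 100
seeded simulations of a 5 × 6 grid with 2,000 genes (30-gene module,
amplitude 1.5, noise SD 0.5), checks zero-noise exactness at the full
24,302-gene scale, and verifies byte-identical reruns of the complete
pipeline on the in-vivo-like preset at full scale. These sizes were chosen
as the smallest that exercise every code path at the study's realistic
dimensions.

## Limitations

* No inter-gene-correlation-aware or self-contained set tests: both need
  replicates the design deliberately lacks.
* No nonlinear dose-response modelling (4PL etc.) and no correlation
  p-values — relevance is by magnitude, as a screen.
* The restriction threshold (2,000 / ~10%) is a convention imported from
  stress-response literature, not estimated from the data.
* Sweet spots are *screening* outputs; they locate, they do not test.
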