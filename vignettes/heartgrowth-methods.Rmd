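---
title: "Models and methods behind heartgrowth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind heartgrowth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(heartgrowth)
```

This vignette documents the scientific models implemented in
`heartgrowth`, the parameters that matter, the design decisions taken
where the underlying observations leave the design open, and what the
synthetic-data tests do and do not demonstrate.

## The lineage model

The juvenile *Ciona* heart grows from the undifferentiated line (UL), a
band of compact cardiomyocyte progenitors: two distal clusters of 2–3
cells flanking a single-cell-wide midline row, attached to 10–24
myocytes at day 3. The simulator implements three division rules on
individually tracked cells:

* **Distal self-renewal.** A distal cell divides with per-day hazard
  `q_distal`; the parent remains distal and the daughter is inserted
  into the midline row adjacent to that cluster. Per-cluster distal
  counts are therefore invariant, matching the observation that distal
  numbers stay constant while the midline lengthens.
* **Midline bifurcation.** A midline cell divides with hazard
  `q_midline`; with probability `f_sym` both daughters stay midline
  (UL elongation), otherwise one daughter detaches as a myocardial
  precursor.
* **Precursor commitment.** Each precursor divides exactly once,
  `precursor_lag` hours after birth (default 12 h), into two
  differentiating myocytes. Myocytes are terminal; no cell death is
  modeled, because none is observed at these stages.

Time advances in synchronous rounds: `step_heart(state, params, dt)`
divides each eligible cell with probability `q · dt` (clipped at 1),
and the cohort simulators call it at a fixed internal resolution of 30
minutes, the shortest pulse length used experimentally. At these
hazards `q · dt ≤ 0.006`, so the discretization error is negligible.
Waiting times between divisions are therefore geometric at 30-minute
resolution; whenever an operation needs a cell's *scheduled* division
time (the pulse model does), it draws from exactly that law, which is
legitimate because the dynamics are memoryless.

Two bookkeeping conventions are configurable but inert: after an
asymmetric midline division the *anterior* daughter is retained in the
row by default (the observations do not resolve which daughter
detaches, and compartment counts do not depend on the choice), and
daughter fates are drawn independently rather than
sister-correlated (clonal data show both symmetric and asymmetric
sisters, but are too sparse to estimate a correlation).

### Calibration

The defaults are calibrated in two layers, because the reported daily
production rates and the reported pulse-labeling indices are not
jointly consistent under a single stationary cell-cycle model with the
stated compartment sizes — a tension the data themselves carry, not an
artifact of this implementation.

**Growth layer.** With `n_d ≈ 5` distal cells and `M(t)` midline
cells, the expected production rates are

* midline cells/day: `n_d · q_distal + M · q_midline · f_sym`
* myocytes/day: `2 · M · q_midline · (1 − f_sym)` (delayed by the
  precursor lag).

Solving against the observed anchors (1–2 midline and 4–5 myocytes per
day over days 3–15, with `M` growing from ≈ 6) gives the defaults
`q_distal = 0.25`, `q_midline = 0.18`, `f_sym = 0.15`. A 500-heart
cohort simulated at these values adds ≈ 1.65 midline cells and ≈ 4.4
myocytes per day.

**Labeling layer.** A cell is labeled by an EdU pulse when its S phase
— the interval `[T − g2m − s, T − g2m]` before its scheduled division
at `T` — overlaps the pulse window, thinned by a per-compartment factor
`s_window_scale`. S-phase length (6 h) and the S-to-division gap (2 h)
are generic animal-cell values, not measured in this system; any error
in them is absorbed by the scale factors. The closed-form overlap
probability under the geometric waiting-time law is
`(1 − q/48)^(k_lo − 1) − (1 − q/48)^(k_hi)` with
`k_lo = g2m/Δ` and `k_hi = (g2m + s + pulse)/Δ` at `Δ = 30` min;
setting `s_window_scale_distal = 0.895` and
`s_window_scale_midline = 0.336` makes the pooled expected indices
equal the observed 6.2% (distal) and 1.7% (midline). A consequence of
those printed indices is that ≈ 6% of hearts carry two or more labeled
UL cells after a 30-minute pulse (near-Poisson with mean ≈ 0.4 labels
per heart); the imaging data report fewer, another facet of the same
inconsistency, which the package exposes rather than hides.

### Estimators

`proliferative_index()` is the *pooled* labeled fraction (labeled cells
over all cells of a compartment across hearts), matching a cell-level
percentage; a per-heart-averaged variant would weight small hearts up.
`division_rate_estimate()` divides the mean of nonzero chase counts by
the mean of nonzero pulse counts and scales to 24 h
(`÷ chase_hours/24`); zero-count hearts are excluded from *both*
vectors — the published rule states zero-exclusion without specifying
the side, and the symmetric reading is the only one that leaves the
estimator's identity property intact (chase mean 1.5× pulse mean at a
36-h chase ⇒ exactly 1 division/day). `clone_census()` groups labeled
cells by their pulse-labeled founder; label inheritance is absolute, so
clones partition the labeled population. During a chase, cells divide
at their drawn schedules and the products receive fresh draws, so
labeled clones keep cycling at the model hazards; with the default
parameters most 72-h clones hold 1–4 cells (doublets of paired
distal+midline cells, midline pairs, and precursor-family clones), with
a tail of larger clones that the stochastic model necessarily produces.

## Synthetic data

`make_expression_pair()` emulates the data situation of a dissociated
heart dataset screened against a published blood atlas: well-separated
cell states with log-normal mean profiles (`meanlog 0`, `sdlog 1.2`),
negative-binomial counts (Gamma–Poisson with dispersion 0.25) drawn
conditionally on a fixed per-cell library size (1500–4000), two
biological replicates as shared per-gene log-mean shifts (SD 0.08),
and three kinds of planted truth:

* **shared states** — heart/blood pairs drawn from a common template
  (realized centroid correlation ≈ 0.99);
* **a margin-rescue pair** — a genuinely shared state whose heart
  profile is remixed from the blood profile's standardized direction
  and an orthogonalized remainder. Because the log1p/centroid transform
  adds seed-to-seed noise (± 0.013) that would swamp the 0.02-wide
  rescue band, the generator root-finds the mixing weight against the
  *realized* centroid correlation (RNG replayed per trial, so the
  search is deterministic given the seed), landing at the target 0.489.
  A 25-gene marker block boosted 150-fold in both profiles keeps the
  top-20 marker Jaccard between the pair at 0.4–0.7;
* **a rare mimic** — a 4-cell blood state copying the profile of an
  abundant heart state (cell count doubled), planting a large abundance
  discrepancy at high correlation.

True state labels and replicate ids ride along in the cell metadata for
scoring only; no pipeline stage reads them. The generator does not
model doublets, ambient RNA, or batch effects beyond the replicate
shift — so passing tests demonstrate that the procedures recover the
planted structure under clean separation, not that they are robust to
every artifact of real droplet data. No quantitative separation between
real heart and blood transcriptomes is available; the default
separation parameters are chosen for testability.

`make_assay_tables()` generates long-format per-animal count tables
(midline UL counts ~ NB around a mean of 12; per-region nuclei ~
Poisson(40) with binomial EdU positivity; binary morphology scores;
pre/post heart rates) with per-condition multiplicative effects and a
control arm in every trial.

## Atlas pipeline

The processing stages follow the standard single-cell recipe, with an
explicit stage flag (`raw → normalized → scaled`) so that each
operation rejects inputs at the wrong stage and raw counts are never
mutated:

* **QC** removes cells detecting fewer than 400 genes — strictly fewer,
  so a 400-gene cell is retained (the literal reading of the rule;
  configurable).
* **Normalization** scales each cell to a 1e4 target sum and applies
  natural `log1p`.
* **Regression/scaling** residualizes each gene on technical
  covariates — total counts and detected genes by default, the usual
  nuisance metrics, configurable — then standardizes to unit variance
  and clips values above 10 (upper clip only, as is conventional).
  Zero-variance genes become all-zero.
* **PCA** uses `prcomp`; dimensionality is chosen from the log
  variance-ratio curve, formalizing the elbow as the largest component
  whose drop to the next exceeds 5% of the total log-range. On data of
  planted rank *k* plus small noise this recovers exactly *k*.
* **Clustering** runs Louvain on an unweighted kNN graph of the
  informative components under a fixed seed. Package defaults follow
  common practice (resolution 1, 15 neighbors); for the planted
  six-state datasets used in the tests the documented analysis choice
  is resolution 0.5 with 30 neighbors, which recovers the planted
  partition exactly (adjusted Rand index 1.0) — resolution 1
  over-partitions homogeneous 100–220-cell blobs. If all embedding rows
  coincide, one cluster is returned rather than an arbitrary tie-broken
  graph partition.
* **Sub-clustering** restricts the *parent* PCA coordinates to one
  cluster's cells (no re-PCA, preserving the parent structure) and
  reruns Louvain at resolution 0.83.
* **Markers** are ranked per cluster by one-vs-rest Wilcoxon rank-sum
  on normalized values: exact p-values when both groups are under 50
  cells and the gene has no ties, otherwise a tie-corrected normal
  approximation; Benjamini–Hochberg adjustment per cluster. Ties in the
  statistic (genes separating a cluster completely) are broken by
  fold change. Detection fractions in/out of cluster support the
  auxiliary lists (top expressed; specific low-expressed markers).
* Replicates are analyzed by plain concatenation; no batch alignment is
  applied beyond the regression covariates.

UMAP is deliberately not computed: it would serve visualization only,
and no stage of the analysis depends on it.

## Contaminant matching

Cross-dataset cluster matching correlates per-cluster mean
log-normalized expression (centroids use normalized values, not scaled
residuals) over a stated gene set — by default the query's top-2000
highly variable genes, ranked by within-bin standardized dispersion.
A query cluster whose best reference correlation reaches the threshold
(≥ 0.5, boundary inclusive) is a contaminant. Two deterministic rules
replace what would otherwise be manual review:

* **Margin rescue**: a best correlation within 0.02 below the threshold
  still flags the cluster if the two clusters' top-20 marker Jaccard
  reaches 0.25.
* **Abundance guard**: a match is suppressed when the reference
  cluster's cell fraction is less than 5% of the query cluster's — a
  handful of reference cells should not eliminate an abundant query
  population. Disabling the guard can only add contaminant labels,
  never remove one.

`calibrate_threshold()` reproduces the replicate-based threshold
choice: the largest grid value (step 0.01) at which every cluster of
either replicate still has a partner in the other replicate — the
largest cutoff that keeps every state "represented in both
replicates". The grid rule is one formalization of that published
criterion; when coverage is impossible it falls back to the operative
0.5 with a flag. The calibrated value is invariant to cluster
relabeling and to duplicating every cell.

## Assay statistics

* **Normalized UL counts**: each animal's midline UL count is divided
  by the trial's *control-arm mean* — the published description
  ("normalizing by the counts for an animal in the control condition")
  is ambiguous between one designated animal and the arm mean; the mean
  is used for robustness and the choice is configurable. Trial means
  are compared by a plain two-sample t-test (equal variances, matching
  spreadsheet-style analysis; Welch is available), two-sided throughout
  since no direction was prespecified.
* **EdU percentages** support both groupings used across figures:
  per-heart labeled fractions (`100·EdU+/nuclei`, zero-nuclei hearts
  excluded with a warning) and per-trial percentages of animals with
  any labeled cell in a region.
* **Crispant morphology**: abnormal counts are pooled over trials per
  group and tested with a two-sided Fisher's exact test on the 2×2
  table.
* **Paired heart rate**: per-animal post−pre differences with a paired
  t-test; all-identical differences are flagged as zero-variance rather
  than producing a spurious statistic (p = 1 when the shift is zero, NA
  otherwise).

No multiple-testing correction is applied across assays, matching the
original analyses.

## Problem sizes and reproducibility

The test suite and the acceptance script use the study-scale problem
sizes directly: 500-heart cohorts over days 3–15 for the growth
anchors, 110-heart cohorts for the pulse indices (their tolerance is
three binomial standard errors of the ~540/~640 pooled UL cells — at
that cohort size the indices are estimates, not constants), 1000-seed
sweeps for the cheap lineage invariants, and full-size (1500-gene,
~110-cells-per-state) expression pairs for the matching properties.
Every stochastic entry point takes or derives from a single seed;
generators called twice with the same spec and seed return
byte-identical objects, and the command-line wrapper writes a manifest
sufficient to re-run a command exactly.

## Limitations

The simulator has no spatial mechanics, pericardial lineage, or cell
death; the labeling model ignores dye dilution and imaging noise; the
expression generator's clean state separation makes the planted
recovery tests necessary-but-not-sufficient evidence for performance on
real data; and the two-layer calibration means the growth rates and the
labeling indices are matched to their respective observations
separately, not derived from a single consistent cell-cycle model — the
underlying counts do not admit one.
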