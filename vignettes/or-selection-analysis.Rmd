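---
title: "Phases of odorant receptor selection along the OSN lineage: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phases of odorant receptor selection along the OSN lineage: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orselect)
library(dplyr)
```

## The analysis in one paragraph

Mature olfactory sensory neurons (mOSNs) express exactly one odorant receptor
(OR) gene out of a repertoire of more than a thousand, arranged in 68 genomic
clusters in mouse. Single-cell RNA-seq of the olfactory epithelium shows that
this monogenic state is reached through a transient *multigenic* phase in
which a differentiating cell expresses several ORs at similar, moderate
levels. `orselect` takes a genes × cells count matrix, per-cell stage labels
and pseudotime, a gene annotation and an OR cluster map, and (i) ranks the OR
genes within each cell into a *winner* and *runners-up*, (ii) calls each
cell's activity state and counts its active OR clusters and chromosomes,
(iii) segments the lineage into silent / multigenic / monogenic phases,
(iv) tests whether jointly active ORs co-locate in genomic clusters with a
fixed-margin permutation null, (v) screens regulators for differential
expression at the two phase transitions, and (vi) scans enhancer sequences
for degenerate consensus motifs. A synthetic-data generator emulating the
seven-stage lineage makes the entire pipeline testable without any external
download.

## Normalization and thresholds

All decision thresholds in the package operate on **normalized counts**:
each cell is scaled so its library sums to a common target (the median
library by default). This is a deliberate simplification — variance-stabilising
regression (as used by Seurat's SCTransform) produces corrected counts whose
exact values depend on a fitted regularised model and are therefore hard to
reproduce from first principles. Library-size scaling keeps the three
count-scale rules of the analysis elementary and exactly reproducible:

* **gene retention**: keep genes whose best cell has *strictly more than*
  40 raw counts (`filter_genes()`); the strict inequality follows the rule's
  wording, so a maximum of exactly 40 is dropped;
* **activity**: an OR is active in a cell at ≥ 50 normalized counts
  (`ActivityThreshold`, inclusive);
* **detectability**: a regulator is screened only if ≥ 35 normalized counts
  in ≥ 15 cells (`detectable_genes()`, both bounds inclusive).

A natural-log view `log_normalized()` exists for plotting and fold-change
displays only; thresholds are never applied to it. Zeros are preserved by
scaling, and within-cell rank order is unchanged, so the winner/runner-up
ranking is identical on raw and normalized data.

## Ranking, states, and cluster counting

`rank_or_genes()` sorts a cell's OR genes by normalized value, descending.
Ties are broken lexicographically by gene id: at realistic expression levels
ties at the winner rank are vanishingly rare, and a deterministic rule keeps
every downstream result reproducible. The winner is the rank-1 gene *only if
it reaches the activity threshold*; runners-up (ranks 2–4) are reported
regardless of threshold because their sub-threshold decay after the
multigenic phase is itself the signal of interest.

States follow the active-OR count: 0 → `silent`, 1 → `monogenic_like`,
≥ 2 → `multigenic`. Active-cluster and active-chromosome counts
(`count_active()`, `or_cell_profiles()`) count distinct clusters /
chromosomes carrying at least one active OR. ORs that fall outside every
annotated cluster are counted as their own singleton cluster by default —
silently dropping an active OR would understate activity; the alternative
(`unclustered = "exclude"`) is available. The chain
`n_active_chromosomes ≤ n_active_clusters ≤ n_active_or` holds for every
cell by construction and is asserted in the tests.

Because the data are cross-sectional (each cell observed once), "winner" is
a per-cell notion; the package makes no claim that the winner observed in an
immature cell remains the winner at maturity.

## Phase segmentation

The canonical segmentation is by stage: {qGBC, GBC, Early.INP, Mid.INP} →
silent, {Late.INP} → multigenic, {iOSN, mOSN} → monogenic. This stage-level
split is also what the differential-expression screen uses to form its
groups, which keeps the two analyses consistent. Descriptively, multigenic
expression spills into the earliest iOSN cells; `segment_phases(mode =
"state")` therefore offers a per-cell, activity-state-based segmentation as
a secondary view. Cells labelled outside the seven lineage stages are an
error (with the offending ids listed), not a silent drop.

## The fixed-margin permutation test

The question: do ORs that are active *in the same cell* sit in the same
genomic cluster more often than chance would have it? The statistic
(`cocluster_statistic()`, `"frequency"` variant) is, for each cell with any
active OR, the fraction of its active clusters containing more than one
active OR, averaged over those cells. A second reading of the quantity — the
absolute number of ≥ 2-active clusters averaged over cells — is implemented
as the `"count"` variant and always reported in the diagnostics
(`glance()`), since the two readings answer slightly different questions;
the frequency variant is the default because it normalises away how many
clusters a cell activates.

The null holds **both margins** of the binary activity matrix fixed: how
many ORs each cell activates, and how many cells each OR is active in. The
sampler uses curveball trades: a trade picks two OR genes, pools the cells
unique to each, and redistributes them at random. Trades provably walk the
fiber of matrices with the given margins, and chained long runs converge to
the uniform distribution on it. Defaults: `n_trades = 5 × n_genes` per
permutation, one equal-length burn-in before the first draw, permutations
chained from the previous state. The tests verify uniformity directly by
exhaustively enumerating small fibers and χ²-testing 20,000 chained draws,
and verify the sampled p against exact fiber-enumeration p on a panel of
small matrices.

The p-value is the one-sided upper tail with the add-one correction,
`(1 + #{null ≥ observed}) / (1 + n_perm)`, so a finite run can never report
p = 0. Tie comparison uses a 1e-12 slack so that identical rational
statistics computed through different summation orders still count as ties.
`n_perm` defaults to 1000. With a fixed seed the result is bit-reproducible.

## Differential expression at phase transitions

`phase_de()` compares silent vs multigenic and multigenic vs monogenic cells
per gene with the Wilcoxon rank-sum test (exact for small tie-free samples,
tie-corrected normal approximation with continuity correction otherwise; a
gene with identical values everywhere gets p = 1). Multiplicity is
controlled by **Bonferroni** across the genes tested within a transition —
deliberately conservative for a screening step whose hits are followed up
individually. Significance additionally requires an average fold change of
at least 2. The fold change is computed on the normalized count scale with a
pseudocount of 1, `log2((mean_b + 1)/(mean_a + 1))`; conventions differ
between tools (log-scale means vs count-scale means change borderline
calls), so the scale is fixed here, documented, and configurable via
`pseudocount`/`min_fold`. Groups with fewer than 3 cells are refused — a
rank test on 2 observations carries no information.

## Motif scanning

`scan_sequence()` performs a strict consensus scan: every window on both
strands whose mismatch count against the IUPAC pattern is at most
`max_mismatch` (default 3) is a hit. All overlapping hits are reported — no
greedy masking, since "one occurrence per enhancer" is an empirical
observation about these sequences, not a scanner rule. Minus-strand hits are
reported at the forward-strand coordinate of the window start so positions
are comparable across strands; coordinates are 0-based. Semantics of
ambiguity codes: `N` in the *pattern* matches anything; `N` (or any
non-ACGT character) in the *subject* matches only pattern `N` — ambiguous
genome bases are treated conservatively rather than as free matches.
`scan_motif_set()` aggregates per-sequence presence (≥ 1 hit on either
strand) over a FASTA. The scanner is validated against a naive
window-by-window oracle, against Biostrings on N-free sequences, and by
strand-symmetry and mismatch-monotonicity properties.

## The synthetic generator: what it emulates, and what it does not

`synthetic_config()` fixes the study conditions: 295 cells over the seven
stages (50/38/26/20/34/95/32), 212 OR genes in 68 clusters on 19
chromosomes, skewed cluster sizes (a few large clusters, many small ones),
silent OR means through Mid.INP, multigenic onset at Late.INP, winner
escalation and runner-up decay through iOSN/mOSN, three regulator
time-course groups (trough at Late.INP / peak at Late.INP / rise in the
monogenic phase), negative-binomial counts and log-normal library factors.

Magnitudes are order-of-magnitude choices made once: active multigenic ORs
at a mean of 100 normalized counts (comfortably above the 50 threshold but
far below winners), winners escalating to 500 (iOSN) and 2000 (mOSN) with
runner-up means decaying ×0.1 per stage — consistent with winners sitting
one to two orders of magnitude above the runners-up. Dispersion defaults to
a negative-binomial size of 2 (strong overdispersion, typical of deep
plate-based scRNA-seq); `nb_dispersion = Inf` gives the Poisson limit used
in the mean-recovery tests. Library factors are log-normal with σ = 0.3.

Placement of a multigenic cell's active ORs is controlled by
`same_cluster_bias`: at 0 the active set is drawn uniformly from the whole
repertoire — under that null the conditional distribution of the activity
matrix given its margins is uniform on the fiber, which is exactly the
permutation test's null, so p-values are calibrated (verified by a
Kolmogorov–Smirnov check over 200 replicate datasets). At 1, all of a cell's
active ORs come from one focal cluster (size-weighted), the planted signal
used for the power check. The cluster-count draw (2–9 clusters × 1–3 ORs
each) sets each cell's activity *count*; the bias parameter alone governs
*where* those ORs sit.

What the generator does **not** model — and hence what passing tests do not
show about real data: no zero-inflation or dropout beyond negative-binomial
sampling (appropriate for deep SMART-seq-like libraries, not for shallow
droplet data); pseudotime is emitted noiselessly in stage order, so tests are
not entangled with trajectory-inference error; cells are independent (no
doublets, no contamination); no allelic resolution; no non-neuronal
lineages; OR sequence similarity and multi-mapping losses are not simulated.
Conclusions about threshold behaviour on real data should be drawn with
those gaps in mind.

## Experiment sizes used by the test suite

These are the package's own experiment designs, chosen to make the checks
sharp and the suite quick:

* permutation exactness: a fixed panel of 2×2…4×4 matrices spanning fiber
  sizes from 1 to several hundred, 2000 permutations each, compared to full
  fiber enumeration at 3 Monte-Carlo standard errors;
* sampler uniformity: χ² goodness-of-fit at α = 0.01 over 20,000 chained
  draws on three exhaustively enumerable fibers;
* null calibration: 200 replicate null datasets of 30 multigenic cells ×
  60 ORs in 10 clusters, 200 permutations each, KS test at α = 0.01;
* power: 100 replicates of the same size with `same_cluster_bias = 1`,
  requiring p < 0.05 in at least 90%;
* rank-sum oracle: 500 random tie-free cases with n + m ≤ 12 against
  exhaustive enumeration of all group splits;
* motif oracle: 100 random 1-kb sequences at mismatch budgets 0–3 against
  the naive scan;
* full-pipeline recovery: the default 295-cell configuration, requiring the
  exact 134/34/127 phase partition, ≥ 99% programmed-winner recovery in the
  monogenic-phase stages, and the chromosome ≤ cluster ≤ active-OR chain in
  every cell.

## Numerical and degenerate-input choices

* Ranking ties: lexicographic by gene id, everywhere.
* Pseudotime ties in `pseudotime_course()`: broken by cell id.
* Cells with an all-zero library stay all-zero after normalization.
* An empty gene-retention result is a warning plus an empty matrix, not an
  error (downstream code can decide).
* `cocluster_statistic()` on a matrix with no active cell is an error; a
  *shuffle* that loses the statistic (impossible under margin conservation,
  kept as a guard) records 0 with a warning rather than aborting a long run.
* Permutation tie comparison uses a 1e-12 slack (see above).
* All randomness flows from explicit seeds: the generator from
  `config$seed`, the permutation test from its `seed` argument.

## Known limitations

The package consumes stage labels and pseudotime; it does not infer them, so
errors in upstream clustering or trajectory fitting propagate. The
stage-level phase segmentation can disagree with pseudotime order for a few
cells near the Late.INP/iOSN boundary — with the canonical mode those cells
follow their stage. Exact reproduction of numbers derived from a specific
public dataset additionally depends on upstream processing choices
(variance-stabilising normalization, clustering seeds) that are outside this
package's scope.

## A worked run

```{r example, eval = FALSE}
cfg <- synthetic_config(seed = 42)
sim <- simulate_counts(cfg)
norm <- sim$counts |> filter_genes() |> normalize_counts()
seg  <- segment_phases(sim$cell_meta)
phase_counts(seg)

prof <- or_cell_profiles(sim$cell_meta, norm, sim$annotation)
plot_aggregate_or(dplyr::mutate(prof, phase = seg$phase))
plot_winner_runnerup(prof)

ors <- intersect(rownames(norm), sim$annotation$gene_id[sim$annotation$is_or])
ct <- cocluster_test(binarize_activity(norm, ors), sim$annotation,
                     n_perm = 1000, seed = 1)
autoplot(ct)

de <- phase_de(seg, norm, setdiff(detectable_genes(norm), ors))
plot_volcano(de)
```
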