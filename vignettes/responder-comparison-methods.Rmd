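---
title: "Methods: normalization, the composite differential filter, enrichment and networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: normalization, the composite differential filter, enrichment and networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(responderomics)
```

`responderomics` compares two responder groups ("good" vs "poor") across a
targeted mRNA panel and label-free FFPE proteomics. This vignette is the
package's account of its statistical choices: what each stage assumes, which
knobs matter, what the synthetic generator does and does not emulate, and
where the design was genuinely open.

## Panel normalization

Targeted panels carry a housekeeping set assumed constant across samples.
Within each sample, every abundance is divided by the geometric mean of the
retained housekeeping genes; the geometric mean is the right location
summary because panel signals are analyzed on the log2 scale, where it
becomes an arithmetic mean.

**Low-signal exclusion.** A housekeeping gene whose signal approaches the
assay floor is an unreliable denominator. `select_housekeeping()` excludes a
housekeeping gene when its median raw signal across samples falls below
`low_signal_quantile` (default 0.05, dimensionless fraction) of the typical
signal, operationalized as the median over samples of each sample's median
signal. Only the outcome of such an exclusion — not its rule — is commonly
reported in practice, so the rule here is the package's own, chosen to be
scale-free and robust (medians on both axes). A matrix whose housekeeping
genes all sit at equal signal excludes none; threshold 0 disables the rule.

**Scale factor.** After division, values are small ratios; a single global
factor restores an interpretable positive log2 range. The factor is the
*lowest multiple of* `step` (default 100,000) such that no log2 value falls
below 1 — i.e. the smallest `k·step ≥ 2/min(normalized values)`. One factor
serves the whole matrix, not one per sample, so between-sample contrasts are
untouched. Minimality is asserted on every synthetic run: the factor minus
one step must violate the bound (unless the factor is already the smallest
allowed multiple). The factor is computed after housekeeping exclusion,
since exclusion changes the denominator and hence the minimum.

## Proteomics normalization (IRON-style)

Label-free intensities carry sample-specific, intensity-dependent biases.
The package normalizes each sample against a data-chosen reference with a
rank-invariant procedure in the spirit of Iterative Rank-Order
Normalization:

1. **Reference selection.** `find_median_sample()` returns the sample
   maximizing the *sum* of pairwise Pearson correlations with all other
   samples (log2 scale, each correlation over features present in both
   members of the pair). Maximizing the sum rather than the median of
   correlations was an open choice; the sum is smooth in every pairwise
   term and makes the tie-break (earlier column order) exercise rarely.
2. **Rank-invariant set.** Sample and reference are ranked over shared
   present features; for up to `max_iter = 10` passes, the `prune_fraction
   = 0.05` of features with the largest absolute rank difference is removed
   and the survivors re-ranked, stopping early when the maximum rank
   difference stops shrinking. Survivors are features whose relative order
   the bias did not disturb — the safest anchors for a correction.
3. **Correction curve.** Over the rank-invariant set, the log2 offset
   (sample − reference) is fit as a running median (window `window = 21`
   features, odd so the median is an observed value) against mean log2
   intensity, linearly interpolated between anchors and held constant
   beyond the extremes. Each feature's correction is evaluated at its own
   mean intensity (the anchors' coordinate); evaluating at the sample's raw
   coordinate instead would shift the lookup by half the offset and leave a
   systematic residual proportional to the curve's slope times the offset.
   The median (not mean) makes the curve robust to the minority of truly
   differential features that survive pruning.

Missing values (`--proteomics` behavior): zeros in raw label-free output
mean "not observed", so raw 0 is treated as missing by default, and missing
cells are ignored during ranking and fitting and stay missing afterwards.

The contract, asserted in tests: self-normalization is the identity; a
constant log2 offset is removed exactly at rank-invariant features; a
smooth intensity-dependent bias is removed to within 0.05 log2 at interior
features; re-normalizing an already-normalized sample yields corrections
below 10⁻³ log2. The procedure captures the *contract* of the published
IRON tool — intensity-dependent correction anchored on rank-stable
features — without claiming bit-level agreement with that binary.

## The composite differential filter

Per feature, on the normalized log2 matrix, with group means `m_g, m_p`,
standard deviations `s_g, s_p` and present-value counts `n_g, n_p`:

* **Fold change:** `log2_ratio = m_g − m_p`, candidate requires
  `|log2_ratio| ≥ log2(fold_threshold)` (default 1.5-fold). Two-sided,
  because candidates in both directions are of interest.
* **Welch t-test:** two-sided, unequal variance, `p < alpha` (default
  0.05). No multiple-testing correction is applied inside the filter: the
  raw-p condition is one arm of a conjunction, and the conjunction (not the
  t-test alone) controls the candidate rate. On 5,000-feature synthetic
  nulls the passing fraction stays below alpha — the t arm alone bounds it.
* **Hellinger distance:** each group's log2 signals are summarized as a
  normal distribution (sample mean, sample sd) and the closed form for two
  normals is used; candidate requires `H > h_threshold` (default 0.25,
  dimensionless in [0,1]). With 9–14 observations per group a normal
  approximation is an interpretation, made deliberately: it is
  deterministic, sample-size-robust, and consistent with summarizing groups
  by their log2 means. Whether to compute it on raw or log2 signals was
  open; log2 matches the scale of every other arm. Sds are floored at
  `sd_floor` (default 10⁻⁶ × the matrix's median absolute log2 signal) so
  degenerate zero-variance features cannot produce NaN.
* **Support:** `min_per_group = 3` present values per group; variance needs
  two, and a third guards against singleton-driven artifacts. Features
  below the floor are reported with `passes = FALSE`, reason `"low_n"`.

The three conditions form a *conjunctive filter*; no weighted scalar score
is invented, since only the cutoffs, not weights, are ever specified for
such composite scores. Relabeling the groups negates every ratio, preserves
p and H, and swaps the two direction lists exactly — an invariant under
test. Bovine-contaminant and reverse-decoy rows are removed before testing.

The Mann–Whitney helper (`mann_whitney_exact()`) serves group comparisons
of externally supplied per-sample quantities (e.g. deconvolved immune-cell
fractions): exact enumeration when the combined n ≤ 20 and tie-free, else
the tie-corrected normal approximation; both branches agree within 0.01 at
n = 10 vs 10 in simulation.

## Enrichment with a pruned universe

A targeted immune panel observes an immune-biased gene space; testing its
candidates against full gene-set collections would inflate immune-set
enrichment mechanically. `prune_sets()` therefore intersects every set with
the observed-gene universe (proteomics, mRNA, or their union with
provenance) and uses the *pruned universe size* as the hypergeometric
background N. Sets below `min_pruned_size = 3` members after pruning are
dropped — single-gene "pathways" have no enrichment meaning. The test is
one-sided (over-representation), matching how such candidate lists are
read; Benjamini–Hochberg adjustment is reported alongside raw p as modern
hygiene, without replacing the raw quantity. The implementation (upper-tail
`phyper`) is checked against exact-fraction enumeration of every margin
combination with N ≤ 25 to 10⁻¹².

## Seed-node direct-interaction networks

Candidates become seed nodes in a user-supplied undirected edge list (SIF
2- or 3-column). `direct_subnetwork()` induces the subgraph on the seeds —
no intermediate connectors — dropping members with no edge to another seed
(configurable). `filter_min_connections()` keeps members with at least `k`
(default 3) connections *within the subnetwork*, in a single pass: degrees
are not re-evaluated after removal, so the filter is monotone in `k` and
independent of removal order. Counting database-wide degree instead was the
open alternative; within-subnetwork degree is implemented because the
filter's purpose is to focus the *extracted* cluster, and it requires no
property of the (possibly huge) background network. `augment_with_nodes()`
adds externally chosen symbols with their known edges to current members,
flagging additions with no known interactions. Edge direction and sign
(activation/inhibition) are out of scope; the relation label is carried
through for display.

## The synthetic generator

The generators emulate the study shape the pipeline targets, with defaults
fixed at those conditions: proteomics with 4,958 features over 10 poor / 9
good samples, log2-normal baselines (mean 20, sd 2.5 — typical label-free
intensity scale), within-group sd 0.5 log2, planted |effect| 1.5 log2 on a
4.5% subset (both directions, matching the candidate fraction such studies
report), 1% bovine and 1% reverse rows carrying no effect, and 10% missing
cells; the panel with 549 genes over 11 poor / 14 good samples, 15
housekeeping genes of which exactly one is generated 8 log2 units low to
exercise the exclusion rule, and no missing values (panel assays report a
value for every gene).

Missingness is logistic in log2 intensity (slope 1 log2 unit), with the
midpoint calibrated by root-finding so the expected missing fraction equals
`missing_rate` — low-intensity cells drop out preferentially, the dominant
missingness mechanism in label-free data. Panel signals are continuous
positive abundances rather than integer counts, because the pipeline
consumes normalized log2 signals and none of its statistics use countness.

Gene sets: one planted set drawing 60% of its 25 members from truly
affected features plus uniform decoy sets, all salted with out-of-universe
symbols to exercise pruning. Networks: a preferential-attachment background
with a designated subset of seeds wired as a path-power-3 cluster (each
cluster seed linked to up to three predecessors) — curated interaction
clusters are densely interconnected, and this keeps the ≥ 3-connection
stage meaningful — plus seeds attached only to background nodes, isolated
among seeds.

What the generator does **not** emulate: peptide-level identification,
shared-peptide ambiguity between protein groups, batch structure,
heavy-tailed or feature-correlated noise, assay saturation, and
biologically structured (co-regulated) effect patterns. Passing tests
therefore demonstrate the pipeline's correctness and calibration under
clean log-normal conditions, not robustness to every pathology of real
FFPE data.

## Numerical and formatting choices

* Problem sizes in the test and acceptance runs (5,000-feature nulls,
  full-default power runs, 1,200-feature determinism runs, N ≤ 25
  enumeration scans) were chosen to give stable estimates in under a minute
  per check on a single CPU.
* Result TSVs are written with fixed formatting — p-like columns in
  6-significant-digit scientific notation, other numerics in `%.6g` — and
  documented sort keys with C-locale radix ordering, so identical runs are
  bytewise identical across platforms and locales.
* Ties in `find_median_sample()` break to the earlier input column;
  component numbering orders by size, then smallest member symbol; record
  sorting breaks ties by feature id.
* Degenerate inputs have defined behavior: both-constant equal groups give
  t = 0, p = 1; both-constant different groups give p = 0 with a
  `degenerate` flag; empty candidate lists, empty networks and all-flagged
  matrices warn and return empty results rather than erroring mid-pipeline.
* The pipeline seed feeds every generator (proteomics, panel, gene sets,
  network use seed, seed+1, seed+2, seed+3), so one integer reproduces an
  entire run.

## Known limitations

* The Hellinger arm assumes near-normal log2 group distributions; heavy
  tails shrink its power.
* The IRON-style procedure is a self-contained implementation of the
  rank-invariant contract, not a reproduction of the published binary.
* Single-pass ≥ k filtering intentionally differs from iterative k-core
  decomposition; members can retain fewer than k edges after their
  neighbors are removed.
* Enrichment treats candidate choice as fixed; uncertainty in the filter is
  not propagated into the hypergeometric test.
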