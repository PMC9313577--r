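---
title: "Methods: subset phenotyping and subsample-normalized repertoire statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: subset phenotyping and subsample-normalized repertoire statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(repsubsets)
```

This vignette documents the statistical procedures implemented in
`repsubsets`, the assumptions behind them, the defaults and why they were
chosen, and what the synthetic-data generator does and does not emulate.

## The phenotyping model

Cells arrive as boolean marker calls — thresholding of fluorescence
intensities (gating, compensation, doublet and viability exclusion) is
assumed to have happened upstream and is out of scope. The **analysis
scheme** assigns each cell by the CD45RA × CCR7 quadrant and, inside the
CD45RA⁺CCR7⁺ quadrant only, by CD95:

| subset | CD45RA | CCR7 | CD95 |
|--------|--------|------|------|
| naive  | +      | +    | −    |
| SCM    | +      | +    | +    |
| CM     | −      | +    | (not consulted) |
| EM     | −      | −    | (not consulted) |
| EMRA   | +      | −    | (not consulted) |

Three design points deserve justification:

* **CD27/CD28 are descriptive, never discriminating.** They are
  heterogeneous on EM cells and implied by the quadrant for the other
  subsets; making them discriminating would create unclassifiable marker
  combinations that the five-subset model does not admit. The test suite
  verifies by enumeration that all 8 combinations of the discriminating
  markers map to exactly one subset, and that toggling CD27/CD28 never
  changes an assignment.
* **CD95 is consulted only inside the CD45RA⁺CCR7⁺ quadrant**, matching
  the gating practice of identifying SCM within the naive-like gate.
* The **sorting scheme** additionally requires CD62L concordant with CCR7
  (naive/SCM/CM are CD62L⁺, EM/EMRA CD62L⁻). How discordant cells were
  handled during physical sorting is not knowable from marker tables, so
  this package makes its own choice: they are returned as `NA`
  (unassigned), excluded from frequency denominators, and counted in a
  message — never silently dropped.

**RTE flagging** is `naive AND CD21+`. CD21 expression on memory cells is
biologically real but is a separate readout (`cd21_memory_fraction()`), so
it never contributes to RTE calls.

**The minimum-cell filter.** Subset frequencies from very small samples are
dominated by counting noise, so any (donor, tissue, compartment) group with
fewer than `min_cells` (default 100) classified cells is excluded from
`cohort_frequencies()` with a warning. For Ki67 the same threshold flags
`low_confidence` instead of dropping, because the cycling fraction of a
rare subset is still informative while deserving caution — dropping it
would silently bias turnover comparisons toward abundant subsets.

## Repertoire statistics

A repertoire is a set of unique clonotypes with template counts. Clonotype
**identity** defaults to `(cdr3_nt, v_gene, j_gene)` at gene-level
resolution (allele suffixes `*01` stripped on input): nucleotide-level
identity is what makes sharing of nonproductive rearrangements a
clonal-origin signal, and gene-level V/J is the common denominator of the
two supported table dialects. The key is configurable (`cdr3_aa`-based
identity is a coarser alternative). Rows sharing a key are merged by
summing counts, never rejected — exports routinely split one clonotype
across rows.

With clone sizes $n_i$ and $N = \sum_i n_i$:

$$D = \frac{\sum_i n_i (n_i - 1)}{N (N - 1)}, \qquad
  \text{clonality} = \sqrt{D}, \qquad
  J(A,B) = \frac{|A \cap B|}{|A \cup B|}.$$

$D$ is the probability that two cells drawn without replacement share a
clonotype; the test suite checks it exactly against a brute-force
enumeration of ordered cell pairs. Jaccard is computed on unique-key sets;
abundance is deliberately ignored.

### Subsample normalization

Both statistics depend on depth, so comparisons are made after repeatedly
subsampling every larger repertoire to $k$, the unique-clonotype count of
the smallest repertoire in the comparison, and averaging over iterations
(default `n_iter = 100000`; desk-scale examples and the demo use 1 000).
Three conventions are fixed and recorded in every result object:

* **The subsampling unit is unique clonotypes**, drawn uniformly without
  replacement, retaining template counts. Count-weighted (read-level)
  rarefaction is a different estimator and is intentionally not provided.
* **The smallest repertoire is used as-is**, not jackknifed; with $k = R$
  the resampled mean equals the point value with zero variance.
* **Sampling is without replacement**, the natural reading of subsampling
  a finite clonotype set to a smaller size.

### Randomness and symmetry

Every resampled result is deterministic given its `seed`. Substreams are
derived per (seed, repertoire label) with a 31-bit string hash, and each
repertoire's subsample stream is advanced only by its own draws. This has
two consequences worth stating: `resampled_jaccard(A, B, ...)` is exactly
symmetric in its arguments, and a repertoire's subsample sequence does not
depend on which other computations ran before it. The caller's global RNG
state is saved and restored around every operation.

Monte-Carlo accuracy follows the usual $1/\sqrt{n_{\text{iter}}}$ law,
verified empirically in the tests by comparing the spread of resampled
means at 100 vs 10 000 iterations across independent seeds, and by
checking the resampled mean against *exhaustive* subset enumeration for
small repertoires (all $\binom{10}{5} = 252$ clonality subsets; all
$\binom{6}{3}^2 = 400$ Jaccard subsample pairs) within three Monte-Carlo
standard errors.

### Degenerate inputs

Simpson's statistics are undefined for $N < 2$ and error; Jaccard errors on
an empty set; `k` outside $[1, R]$ errors naming the offending repertoire;
repertoires left empty by a frame filter are excluded from the overlap
matrix with a warning, and fewer than two survivors is an error. Unknown
reading frames are resolved by an explicit fallback rule (productive iff
CDR3 length is a multiple of 3 and the in-frame translation has no stop
codon) or routed to the nonproductive fraction with a warning — never
silently.

## Cohort statistics

Spearman correlation (midranks, asymptotic two-sided p), Kruskal–Wallis
(tie-corrected, $\chi^2$ approximation) and median/IQR (quantile type 7,
linear interpolation) delegate to the corresponding base-R routines; the
conventions are fixed here and recorded in the result objects because
rank-test p-value conventions (exact vs asymptotic) otherwise vary between
tools. No multiple-testing correction is applied by default — each trend is
reported at its nominal p — but `cohort_age_trends(adjust = TRUE)` adds
Benjamini–Hochberg adjusted p-values. CMV serostatus is carried as a
stratification column; no CMV-adjusted model is fitted.

## What the synthetic generator emulates

`generate_repertoire()` produces structurally valid CDR3 nucleotide
sequences (leading Cys codon, 10–16 codons, no stops in frame) with clone
sizes from a zipf law $P(n_i = c) \propto c^{-a}$ truncated at $10^4$.
Defaults were chosen once to mirror the scale asymmetries of sorted-subset
TCRα data: naive/SCM exponents of 3.0 give a template-per-clonotype ratio
near 1.3 (mostly singletons), EM's 2.3 gives a heavier tail and higher
clonality. Each clone independently carries a paired nonproductive
rearrangement (stop-codon-bearing or out-of-frame) with probability 0.15 —
a configurable plumbing rate; only the *sharing pattern* of nonproductive
sequences carries meaning in tests, not the rate itself.

`generate_subset_family()` plants pairwise sharing **by construction**:
for each subset pair a dedicated pool of `round(fraction × min(R_i, R_j))`
clonotypes (with identical CDR3/V/J and, where present, identical
nonproductive partners) is placed in both subsets. Overlap ground truth is
therefore noiseless, and any scatter in downstream overlap estimates is
attributable to the estimator's own subsampling — deliberately separating
estimator error from generator error. Pool sizes are checked for
feasibility (the pools committed to a subset cannot exceed its size) and
infeasible specifications error. The default family is
naive = 40 000, CM = 30 000, EM = 20 000, SCM = 500 unique productive
clonotypes with planted sharing CM–EM = 0.30 > SCM–CM = 0.15 >
SCM–EM = 0.08 > naive–memory = 0.01, so tests exercise the same
size asymmetries (two orders of magnitude) that subsample normalization
exists to handle.

`generate_cohort()` draws each cell's subset from an age-dependent mixture:
the naive fraction declines linearly from a tissue/compartment anchor at
age 40 (steeper in blood than lymph node; small and EM-dominated in ileum),
the remaining mass splits across SCM/CM/EM/EMRA with fixed tissue weights,
and a donor-level logit-normal perturbation (sd 0.3) adds realistic
between-donor scatter. Marker vectors are the subset's canonical profile
with independent per-marker flips at `marker_noise` (default 0.02, a
plausible thresholding error rate). Ki67 rates are subset-specific
(naive 0.01, SCM 0.08, CM 0.05, EM 0.03, EMRA 0.02) scaled by tissue
(higher in ileum and blood, lower in lymph node and spleen); naive-cell
CD21 declines with age and reaches zero after age 50 in the CD4
compartment while remaining low-positive in CD8; memory-cell CD21 is
tissue-specific with the spleen CD8 rate set at 0.227. Cohorts default to
12 donors aged 20–70 with 2 000 cells per (donor, tissue, compartment)
sample.

**What it does not emulate.** Sequences are placeholders: no V(D)J
recombination biology, thymic selection, gene-usage bias or sequencing
error. Marker noise is independent per marker, whereas real spillover is
correlated. Clone-size laws are a modeling choice, not an inference from
data. Passing tests therefore demonstrate that the *estimators and rules*
behave as specified under known ground truth — not that any biological
conclusion transfers to a particular real dataset.

## Problem sizes

The test suite and the acceptance script scale their simulations to run
comfortably on a single core: resampling-exactness checks use 10 000
iterations against exhaustive enumerations; the planted-structure
integration check runs 100 seeded family analyses at 1 000 iterations each
and 200 simulated 12-donor cohorts; the acceptance script uses one family
analysis, 20 ordering replicates and 50 power replicates. The statistical
conventions are identical at any scale; only Monte-Carlo precision changes,
and every tolerance used is derived from the corresponding Monte-Carlo or
binomial standard error rather than tuned.

## Known limitations

* Identity-key configuration cannot express allele-level resolution (the
  reader strips allele suffixes unconditionally).
* The Jaccard matrix uses a single common $k$ (the global minimum); per-pair
  minima would retain more information for very unbalanced families but
  would not be comparable across cells of the matrix.
* Frame fallback translation assumes the CDR3 string starts in frame;
  junction sequences with leading partial codons would need upstream
  trimming.
* The cohort generator's mixtures are linear in age; real subset dynamics
  may plateau or accelerate, so age-trend *shapes* (beyond monotonicity)
  should not be read into it.
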