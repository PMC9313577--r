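# repsubsets

Quantitative analysis of human T-cell differentiation across tissues, built
for immunologists working with (a) flow-cytometry-derived per-cell marker
calls and (b) bulk TCRα clonotype tables (AIRR-seq). The package covers two
linked questions: how the naive / stem cell memory (SCM) / central memory
(CM) / effector memory (EM) / EMRA subset composition of the CD4⁺ and CD8⁺
compartments changes with age and tissue, and how clonal the TCR repertoires
of those sorted subsets are and how much they share.

## What it computes

**Subset phenotyping.** Cells are classified from boolean marker calls by
the CD45RA × CCR7 quadrant, with CD95 splitting the CD45RA⁺CCR7⁺ quadrant
into naive (CD95⁻) and SCM (CD95⁺); CD45RA⁻CCR7⁺ is CM, CD45RA⁻CCR7⁻ EM,
CD45RA⁺CCR7⁻ EMRA. CD27/CD28 are carried but never discriminate. Recent
thymic emigrants (RTE) are CD21⁺ naive cells. Per-sample subset frequencies
(groups under 100 cells excluded), Ki67⁺ turnover fractions and memory-cell
CD21⁺ fractions feed Spearman age trends, Kruskal–Wallis tissue comparisons
and median/IQR summaries.

**Repertoire statistics.** For a repertoire with clone sizes *nᵢ* and
*N* = Σ*nᵢ* cells,

- Simpson's diversity  D = Σ nᵢ(nᵢ−1) / (N(N−1)), the probability two
  cells drawn without replacement share a clonotype;
- Simpson's clonality  √D  (0 fully polyclonal, 1 monoclonal);
- Jaccard overlap  J(A,B) = |A∩B| / |A∪B|  on unique-clonotype sets.

Because both statistics depend on sampling depth, repertoires in a
comparison are repeatedly subsampled (default 100 000 iterations) to the
number of unique clonotypes of the smallest repertoire, and the subsample
averages are compared. Productive and nonproductive rearrangements are
analyzed separately: nonproductive sequences are never expressed, so their
sharing between subsets marks common clonal origin rather than convergent
selection.

**Synthetic data.** A generator produces repertoire families with
heavy-tailed (zipf) clone sizes, exactly planted pairwise sharing, paired
nonproductive rearrangements, and donor cohorts with age-dependent subset
mixtures and subset/tissue-specific Ki67 and CD21 rates — ground truth for
every pipeline stage.

## Worked example

```r
library(repsubsets)

fam <- generate_subset_family(
  n_unique = c(naive = 4000, SCM = 500, CM = 3000, EM = 2000), seed = 1)
prods <- lapply(fam, function(r) partition_by_frame(r, fallback = TRUE)$productive)
k <- min(sapply(prods, function(r) r$R))

resampled_clonality(prods$EM, k = k, n_iter = 1000, seed = 1)
#> Simpson's clonality [sim1|CD4|EM|MLN]
#>   point value: 0.105766
#>   resampled (k=500, 1000 iter, seed 1): mean 0.181686, sd 0.0635

pairwise_overlap_matrix(fam, n_iter = 1000, seed = 1)
#> Pairwise Jaccard overlap (productive frame, k=500, 1000 iter, seed 1)
#>       naive    SCM     CM     EM
#> naive 1e+00 0.0006 0.0006 0.0006
#> SCM   6e-04 1.0000 0.0127 0.0102
#> CM    6e-04 0.0127 1.0000 0.0254
#> EM    6e-04 0.0102 0.0254 1.0000
```

The EM repertoire is the most clonal (mean subsampled clonality 0.18 at a
common depth of 500 unique clonotypes), and the overlap matrix recovers the
planted sharing structure: CM–EM sharing (0.025) exceeds SCM–CM (0.013),
with naive–memory overlap near zero — the values are small because
subsampling 500 clonotypes from repertoires of thousands dilutes the
absolute intersection, but the ordering is preserved.

```r
cells  <- generate_cohort(n_donors = 12, tissues = "blood",
                          compartments = "CD4", seed = 1)
cohort <- cohort_frequencies(cells)          # <100-cell groups excluded
tr <- cohort_age_trends(cohort)
tr[tr$subset == "naive", ]
#>   tissue compartment subset        rho      p_value  n
#> 1  blood         CD4  naive -0.8251748 0.0009513629 12

round(median_iqr(cohort$frequency[cohort$subset == "naive"]), 3)
#> median     q1     q3
#>  0.361  0.255  0.425
```

The naive CD4⁺ fraction in blood declines with donor age (Spearman
ρ = −0.83, p < 0.001 across 12 donors), with a cohort median of 36%.

A command-line wrapper with `simulate`, `convert`, `phenotype`, `trends`,
`diversity`, `overlap` and `demo` subcommands is installed at
`inst/cli/repsubsets`; `repsubsets demo --seed 1 --out-dir out` runs the
whole pipeline on synthetic data and writes tidy TSVs with provenance
headers.

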