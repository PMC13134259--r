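---
title: "Localizing disease gene sets to cell types: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localizing disease gene sets to cell types: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Genetic studies of congenital disorders such as CAKUT (congenital anomalies
of the kidney and urinary tract) produce curated sets of risk genes, but not
the cellular contexts in which those genes act. Single-cell RNA-seq resolves
that missing axis: if disease genes are coordinately overexpressed in a cell
population, that population is a candidate substrate of the disease.
`screlev` implements the full chain of analyses needed to make that claim
quantitatively: per-gene cell-type specificity screening, gene-set-level
Monte-Carlo relevance scoring against matched control gene sets, driver-gene
ranking, temporal classification across developmental stages, and
cross-organ overlap prioritization — plus a synthetic-data generator with
planted ground truth so every stage can be validated without external
atlases.

# Preprocessing

All statistics operate on a `CellExpressionDataset`: a cells × genes count
matrix with per-cell type annotations. `qc_filter()` removes cells with
fewer than `min_genes_per_cell` detected genes (default 200), then genes
detected in fewer than `min_cells_per_gene` cells (default 3); the passes
iterate to a fixed point so re-filtering is a no-op. The defaults mirror
common single-cell practice; no published value exists for the datasets this
pipeline is designed around, so both are explicit, logged parameters.
`normalize_log1p()` rescales each cell to `target_sum` counts (default
10,000) and applies the natural-log `log1p`:

$$x_{ig} = \log\!\left(1 + c_{ig}\,\frac{S}{\sum_g c_{ig}}\right), \qquad S = 10^4 .$$

Within a cell this map is monotone, so every rank-based statistic downstream
is unaffected by the choice of `target_sum`.

# Per-gene specificity screen

For each gene, `kruskal_wallis_specificity()` tests whether the distribution
of normalized expression differs between cell types (tie-corrected
Kruskal–Wallis; `stats::kruskal.test`), with Benjamini–Hochberg adjustment
across exactly the tested gene list. Numerical conventions:

* a gene identical in every cell has no rank information; we return
  $H = 0$, $p = 1$ rather than the 0/0 the tie correction would produce;
* cell types below `min_cells_per_type` (default 10) are excluded — rank
  tests on a handful of cells are dominated by ties;
* the *top-expressing* type is the argmax of mean normalized expression,
  ties broken by detection rate, then lexicographically (ties are logged).

`top_type_enrichment()` compares how often each type is top-expressing
across the gene set with the expectation under the dataset's cell-type
abundances (chi-squared goodness of fit). Cells with expected count below 1
are pooled into an `"other"` category before the test — the classical
validity rule; observed/expected ratios are reported unpooled.

# Matched-control relevance scoring

The raw disease score of cell $i$ is the unweighted mean of its normalized
expression over the mapped disease genes. Significance comes from $K$
control gene sets (default 1,000) in which each disease gene is replaced by
a random gene from the same *expression bin* — and, in the dual-matched
mode, the same (expression bin, length bin) pair:

* expression bins are equal-occupancy quantile bins of mean normalized
  expression over all cells (default 20);
* length bins (default 5) use a user-supplied table or union-exon lengths
  from a GFF (`gene_lengths_from_gff()`); union-exon length tracks transcript
  detectability better than genomic span;
* bins under `min_bin_occupancy` (default 10) genes are merged into the
  nearest expression-bin neighbor so sampling stays well defined on small
  universes;
* disease genes themselves are excluded from control pools by default
  (`exclude_seed_genes`), and draws within a control set are without
  replacement while a bin's pool allows.

Per cell, the $K$ control scores standardize the raw score,
$z_i = (\mathrm{raw}_i - \mu_K)/\sigma_K$, and give a Monte-Carlo p-value
$(1 + \#\{k : \mathrm{raw}_{ik} \ge \mathrm{raw}_i\})/(K+1)$. Every
empirical p emitted anywhere in the package has this $(r+1)/(K+1)$ form, so
the attainable floor is $1/(K+1)$ — with $K = 1000$, $0.000999001$. The
observed score is accumulated through the same sparse matrix product as the
control scores, so exact ties survive floating-point arithmetic (a control
set equal to the disease set yields $p = 1$ exactly).

At the type level, `celltype_association()` aggregates the standardized
scores by their mean within each type and applies the identical aggregation
to each control set, yielding a $K$-point null per type from which the
one-sided (enrichment) empirical p and the z-score
$(observed - \bar{null})/sd(null)$ are computed. The type mean is a
deliberate, swappable choice: the underlying scoring framework does not pin
an aggregation, and the mean makes the null exactly exchangeable with the
observed statistic. Raw empirical p-values are reported per type without
multiplicity adjustment — with $K$ controls their granularity is coarse and
a BH pass over a handful of types is easy to apply downstream if wanted.

`celltype_heterogeneity()` asks a different question: does a type *mix*
strongly scoring and unremarkable cells? The statistic is the within-type
variance of the standardized score, with the same control-set Monte-Carlo
null. A homogeneous enriched type can be significant here too (its score
variance is genuinely inflated relative to matched controls); the test is
informative in *contrast* with the association result, as the planted
mixed-type simulation in the test suite shows.

# Driver genes, temporal classes, organ overlap

`gene_score_correlation()` ranks all genes by the Pearson correlation of
their normalized expression with the standardized disease score
(Spearman offered for heavy tails). Correlating against the standardized
rather than raw score makes the ranking invariant to control-set location
and scale. Constant genes are excluded and listed.

`classify_temporal()` takes per-stage ranking tables (earliest first),
re-ranks within the shared gene universe, and labels a gene `early_peak` if
it is in the top `r_early` at the first stage and worsens by at least
`drop_frac` of the universe by the last, `late_rise` for the mirror, else
`stable`. The two dynamic criteria are mutually exclusive by construction.
The defaults (`r_early = 5`, `drop_frac = 0.10`) encode a strict "top-5 then
substantial fall" reading; both knobs are exposed because any such published
screen is qualitative about "substantial".

Two rank bases are supported, and the choice matters. The
correlation basis inherits a subtle artifact: a disease-set gene contributes
$1/|set|$ of the score it is being correlated against, so even at a stage
where its biological signal is gone it retains a self-correlation floor and
rarely falls to a random rank. The specificity basis (per-stage
Kruskal–Wallis statistic) has no such term — a gene with no type effect at a
stage gets a genuinely uninformed rank. For recovering planted fold
schedules, the specificity basis is therefore the sharper instrument, and it
is what the package's own validation uses; the correlation basis remains the
default for mirroring score-driven analyses.

`top_k_genes()` and `overlap_analysis()` implement the cross-organ
prioritization: intersect each organ's top-K list (default K = 100) with the
disease set, and partition hits into organ-specific candidates and genes
shared by every organ. Because "the organ's ranking score" is ambiguous in
published practice, the per-organ ranking feeding `top_k_genes()` must be
chosen explicitly (correlation-based or specificity-based); neither is
asserted as canonical.

# The synthetic generator

`generate_dataset()` draws counts from a negative binomial — the standard
overdispersed model for scRNA-seq counts — with

$$c_{ig} \sim \mathrm{NB}\!\left(\mu = s_i\, b_g\, f_{g,\,type(i)},\ \text{size} = \theta\right),$$

log-normal per-gene baselines $b_g$, log-normal per-cell size factors $s_i$
(sd 0.3, so library-size normalization is non-trivial), and
$f = \texttt{program\_fold}$ exactly for planted (gene, type) pairs. Gene
lengths are log-normal; under `length_model = "expression_correlated"` their
ranks couple to the baselines through a Gaussian copula with one knob `rho`,
giving a controllable length–expression confounder for exercising the
dual-matched null. `generate_stage_series()` strings per-stage configs over
a shared gene universe so early-peak (fold schedule 8, 2, 1) and late-rise
(1, 2, 8) genes can be planted.

What the generator does *not* emulate: doublets, ambient RNA, batch
structure, trajectories, zero inflation beyond NB, or realistic gene–gene
correlation. Passing tests therefore demonstrate that the statistics do what
they claim under a clean overdispersed-count world with known truth — not
that any particular biological dataset satisfies those assumptions.

# Problem sizes and validation conditions

The package's own validation (test suite and `scripts/acceptance.R`) uses
these study conditions, chosen as the smallest scales at which the
statistical claims are meaningful:

* *null calibration*: 2,000 genes, 5 types × 400 cells, $K = 200$ controls,
  100 replicate random 50-gene "disease" sets; the fraction of association
  p-values ≤ 0.05 must sit in the exact-binomial 99% envelope around 0.05;
* *recovery*: 20 planted genes at fold 4 in a 200-cell type (1,000 genes,
  4 types), $K = 200$, 20 replicates; the planted type must attain the
  $1/(K+1)$ floor in ≥ 95% of replicates;
* *confounder control*: `rho = 0.8` length–expression coupling, a 40-gene
  longest-gene null "disease" set, 20 replicates; dual matching must not
  yield a larger mean $|z|$ than expression-only matching;
* *temporal recovery*: 25 early + 25 late genes, folds (8, 2, 1)/(1, 2, 8),
  2,000 genes, 4 types × 100 cells, specificity-rank basis with
  `baseline_log_sd = 0.5` (so recovery is not confounded with the detection
  limit of near-zero-expression genes), ≥ 90% correct labels over 20
  replicates.

# Known limitations

* The cell score is an unweighted mean over the gene set; inverse-variance
  gene weighting (as in the original disease-relevance scoring literature)
  is not implemented, though every Monte-Carlo property stated above is
  weighting-agnostic.
* The heterogeneity statistic (within-type variance against the control
  null) is one reasonable dispersion test among several; it is a declared
  stand-in, not a reimplementation of any published test.
* Control sampling conditions on bins computed from the full dataset; very
  small gene universes (< ~200 genes) force aggressive bin merging and the
  matched null degrades toward an unmatched one.
* Reading is limited to Matrix Market bundles plus TSV annotations; matrices
  exchanged from other ecosystems should be exported to MTX first.
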