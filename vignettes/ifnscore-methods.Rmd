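---
title: "Methods: interferon signature scoring across heterogeneous cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: interferon signature scoring across heterogeneous cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ifnscore)
```

## The problem and the model

Interferon (IFN)-inducible transcription is a hallmark of several
autoimmune skin diseases. Comparing its strength across cohorts is hard
because public expression datasets differ in platform, probe design, gene
coverage, and lab protocol. `ifnscore` addresses this with a deliberately
simple cross-platform model: every dataset is reduced to per-gene **linear
fold changes against its own internal healthy controls**, and all
downstream statistics (disease modules, signatures, scores, module maps,
correlations) operate on that shared currency. Dataset- and platform-level
multiplicative biases cancel in the fold ratio; what remains comparable
across studies is the *pattern and magnitude of regulation relative to
health*, not absolute expression.

Two estimated objects sit at the core:

1. **The core IFN signature.** Pooled in vitro IFN stimulation experiments
   (different cell types, IFN types, labs) are placed in log2 space and
   per-gene mean-centered *within each study*, removing study-specific
   baselines while preserving the pre/post contrast. The centered studies
   are concatenated and tested pre vs post with a SAM-style permutation
   analysis; significant genes induced at least 2-fold on average (equal
   per-study weights on the post/pre ratio of linear class means) and
   measurable on all platforms form the signature, ordered by mean fold.
2. **The IFN score.** Each sample's score is the **median, in linear
   space, of its fold changes over the top-25 signature genes**. The
   median makes the score robust to missing genes and single-gene
   artifacts; linear space keeps it interpretable as a fold change
   ("this sample's IFN genes run at 20× the healthy level").

### SAM-style differential expression

For gene *g*, `sam_fdr` computes `d_g = (m2 − m1) / (s_g + s0)` with `s_g`
the pooled equal-variance standard error of the mean difference over the
samples observed for that gene. The fudge factor `s0` damps the otherwise
explosive `d` of low-variance genes; `choose_s0` evaluates candidates at
the 0, 5, …, 100 percentiles of the `s_g` distribution and picks the one
minimizing the coefficient of variation of `mad(d)` across `s_g` bins, so
the spread of `d` is roughly constant in `s_g`. Significance is assessed by
relabelling samples (exhaustively when the number of distinct assignments
is within the permutation budget): at a symmetric threshold *t*, the
expected number of false calls is the median over permutations of
`#{|d*| ≥ t}`, scaled by π₀ estimated from the fraction of observed `d`
inside the central 50% of the permuted distribution. The smallest *t* whose
estimated FDR does not exceed the target defines the significant set
(threshold ties inclusive); per-gene q-values are the minimum estimated FDR
over admissible thresholds, monotonized in |d|. The comparison uses
`fdr(t) ≤ target` so that a vacuous target of 1 calls every gene with a
defined statistic, which keeps the threshold sweep's semantics total.

Genes with missing values are analysed over their observed samples (a gene
needs at least two observations per class in a permutation to contribute
a permuted statistic); nothing is imputed at this stage.

## Tunable parameters

| Parameter | Default | Units / meaning |
|---|---|---|
| `background_ratio` | 1.5 | minimum foreground/background signal ratio, either channel (inclusive) |
| `adequacy_fraction` | 0.8 | fraction of arrays in which a probe must be adequate |
| `span` (LOWESS) | 0.4 | smoother fraction for the M-vs-A dye-bias fit |
| `fdr` | 0.05 | permutation-FDR target; 0.043 is the stricter documented alternative used in parts of the original analyses |
| `min_fold` | 2 | minimum mean linear fold change (module and signature filters, module-map changed genes) |
| `n_perm` | 1000 (200 in pipeline runs) | label permutations |
| `top n` | 25 | scoring genes, descending in vitro mean fold, ties by identifier |
| `min_coverage` | 0.6 | fraction of scoring genes that must be observed for an unflagged score |
| `alpha`, `min_arrays` | 0.05, 4 | module-map call level (BH-adjusted) and reporting rule |
| `min_set_size`, `max_set_fraction` | 5, 0.5 | gene-set size guards for enrichment tests |

Where the upstream literature states a value (1.5× background, 80%
adequacy, LOWESS span 0.4, 2-fold, p ≤ 0.05, ≥ 4 arrays, top 25, median in
linear space) the default is that value; the remaining defaults (coverage
flagging, set-size guards, permutation count) are the package's own and are
exposed as arguments.

## Design choices where the ground was open

* **Space discipline.** Every matrix carries an explicit space
  (`linear`/`log2`); fold-change computations always happen in linear
  space, probe averaging is arithmetic in linear space, SAM runs on log2
  values. This is the main silent-corruption risk in mixed pipelines, so
  it is enforced by constructors rather than convention.
* **Control mean.** "Mean expression value of all control samples" is
  implemented as the arithmetic mean in linear space. When some control
  values are missing, the mean is taken over the observed controls; a gene
  is dropped only when no control value is observed or the mean is
  non-positive. Nothing is imputed, and retained genes keep the exact
  mean-fold-1 property over their observed controls.
* **Fold for the signature filter.** The "average fold" is the mean of
  per-study post/pre ratios of linear class means with equal study
  weights, so small studies are not swamped by large ones; a pooled-ratio
  alternative would weight by sample count.
* **Multiple testing in module maps.** Benjamini–Hochberg within each
  array × direction; induced and repressed gene sets are tested
  separately, and if a set passes both directions on one array the smaller
  adjusted p wins, keeping calls unambiguous.
* **Enrichment universe.** Genes present on the harmonized matrix, not the
  full annotation universe — testing against genes a platform cannot see
  would inflate enrichment.
* **Clustering semantics.** Average linkage operates on *similarities*
  (uncentered correlation by default, i.e. cosine similarity — the
  Cluster-3.0 "correlation (uncentered)" metric). Cluster–cluster
  similarity is the mean over all cross pairs (exact UPGMA, verified
  against a direct-averaging oracle); exported heights are 1 − similarity
  for TreeView compatibility. Ties are broken by the lexicographically
  smallest pair of smallest member leaf indices, which makes trees
  invariant to input row order.
* **Exact Spearman p-values.** For n ≤ 10 the two-sided p-value is exact:
  doubled average ranks are integers, so the permutation distribution of
  the rank inner product is tabulated exactly by dynamic programming over
  assignment bitmasks (equivalent to enumerating all n! permutations, and
  tested against explicit enumeration). Above n = 10 the usual
  t-approximation is used. Ties receive average ranks.
* **SVD imputation.** Missing entries start at row means and are
  iteratively replaced by the rank-k truncated-SVD reconstruction until
  the relative change of the imputed entries falls below `tol = 1e-5`
  (`max_iter = 100`; non-convergence warns and returns the last iterate).
  The default rank is the number of components capturing ≥ 90% of the
  variance of the complete rows, capped at 10, since the appropriate rank
  is data-dependent and rarely known. Observed entries are never touched.
* **PCA.** Samples are observations, genes variables; columns are centered
  and not scaled (the named base-R function's defaults); both flags are
  exposed. Log2 fold values are the default input.
* **Pipeline orchestration.** `run_pipeline` validates its configuration
  against a schema (unknown keys are errors), derives one seed per stage
  from the master seed, and writes a run manifest with parameters and md5
  checksums of every output, so identical configurations are byte-for-byte
  reproducible. An enabled stage whose upstream is off fails naming the
  dependency. The package is driven from R; the pipeline function plus the
  exported stage functions are the interface.

## What the synthetic cohorts emulate — and what they do not

`simulate_disease_cohort` generates, per dataset: per-gene platform
baselines (log2 ~ N(7, 1)); a latent per-sample IFN activity — log-normal
with median 2 and log-scale σ 0.75 for cases, exactly 0 for controls —
driving the planted signature genes at `signature_slope` (default 1.0)
log2 units per activity unit; planted disease modules applied to cases
only (defaults: 100 genes at 2.5-fold up, 50 genes at 0.4-fold down);
i.i.d. Gaussian gene-level noise (log2 sd 0.5); a probe layer with 1–3
probes per gene, constant per-probe affinity offsets (sd 0.3) and probe
noise (sd 0.1); 2% of probes annotated to two genes (exercising the
multi-gene exclusion); and 2% missing values completely at random. The
default platform coverage is 1.0 — genome-wide platforms — with partial,
per-platform random coverage available as a parameter to exercise the
comparison-matrix intersection. Reference problem sizes throughout the
validation suite: 3 datasets × (10 cases + 10 controls) × 3000 genes, 120
signature genes; stimulation studies 4 × (4 pre + 4 post) × 3000 genes
with per-study effects uniform in 1.5–3 log2 units; SAM with 100–200
permutations; 20 seeds for null-calibration averages.

The heavy-tailed activity distribution reproduces the qualitative shape of
real per-sample IFN scores (a long right tail over a baseline near 1). The
generator does *not* emulate: correlated noise between genes (real
co-expression makes effective sample sizes smaller than nominal),
intensity-dependent variance, batch effects within a dataset, dye-bias
curvature beyond what the LOWESS stage sees in its own tests, cell-type
composition shifts, or platform-specific probe affinity biases that
normalization cannot cancel. Passing the recovery tests therefore shows
the chain is *correct and calibrated under its stated model*, not that
real cohorts will yield these recall rates; on real data the binding
constraints are usually cohort size and cross-platform gene coverage.

Latent activities for controls are exactly 0, so rank ties among controls
cap the achievable score–activity Spearman correlation below 1 (at
10 controls + 10 cases per dataset the ceiling is ≈ 0.94 even for perfect
recovery); the validation threshold of 0.9 sits under that ceiling by
design.

## Numerical and degenerate-input conventions

* Even-count medians (possible when scoring genes are missing) are the
  arithmetic mean of the two central values.
* `sam_statistic` with zero pooled variance and `s0 = 0` reports the gene
  as missing with a warning rather than returning ±Inf; a degenerate
  (all-equal) standard-error distribution makes `choose_s0` return 0.
* Zero-norm vectors make the uncentered correlation undefined (missing
  with warning); array pairs sharing fewer than 3 genes get missing
  correlation entries; constant vectors make Spearman undefined.
* Hypergeometric tests validate their count consistency and use the exact
  upper tail; `k = 0` gives p = 1.
* All simulators require an explicit seed and are bit-reproducible under
  it; SEM of a single observation is reported as missing, not 0.

## Known limitations

* The SAM variant is the unpaired two-class equal-variance form; paired,
  multiclass and survival modes are out of scope, as are moderated-t
  (empirical Bayes) alternatives.
* Signature derivation treats studies as exchangeable after
  mean-centering; systematic cell-type-specific response differences are
  averaged over, not modelled.
* The module map tests marginal per-array enrichment; it does not model
  inter-gene correlation within sets, so its null calibration (verified in
  the tests) assumes approximately independent changed-gene draws.
* Affymetrix CEL processing, GEO fetching, and identifier translation are
  intentionally outside the package: data enter at the normalized-matrix
  level with identifiers already in a shared namespace, and cross-namespace
  merges are an error rather than a guess.
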