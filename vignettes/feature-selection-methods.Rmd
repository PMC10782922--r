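---
title: "Correlation-based feature selection for scCAS data: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based feature selection for scCAS data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Single-cell chromatin accessibility (scCAS) data arrive as a peak-by-cell
count matrix `X ∈ R^{p×n}` that is high-dimensional (10^4–10^6 peaks),
extremely sparse and close to binary: a site is either detected open in a
cell or not, with occasional extra counts. Only a minority of peaks
differ between cell types; the rest are background whose accessibility is
driven by depth and global prevalence. Feature selection should keep the
type-discriminating peaks, including those of *rare* types that
prevalence-based selectors drown out.

The method scores a peak by how its correlation pattern with *all other
peaks* deviates from the background trend:

1. **TF-IDF** (default, Signac convention, natural log):
   `x'_ij = log(1 + (x_ij / Σ_i x_ij) · (n / Σ_j x_ij) · 10^4)`.
   Alternatives: `origin` (TF × log1p(n / ncells_i)) and `scopen`
   (log1p of the scaled TF·IDF product on binarised prevalence). The exact
   formulas of the two alternatives follow the cited tools' conventions;
   they are exposed behind the same flag so variant comparisons can be run.
2. **Cell-wise PCA**: peaks are treated as observations, cells as
   variables (centred, not scaled — standard PCA, centering-only, since
   scaling is not stated anywhere and TF-IDF already equalises scales).
   The top `q = 100` principal coordinates of each peak form the
   peak-by-PC matrix `P`. One hundred components comfortably exceed the
   number of cell subpopulations in typical datasets while keeping the
   correlation stage cheap and robust to `n`.
3. **Correlation summaries**: for each peak `j`, the mean `m_j` and the
   mean square `s_j` of its `p − 1` correlation coefficients with the
   other peaks (self-correlation removed before averaging). Pearson is the
   default; Spearman (average ranks for ties) and cosine are options.
   Type-specific peaks of a common type show strong positive *and*
   negative correlations, so at equal mean they carry a larger mean
   square than background peaks — that separation is what the score
   exploits.
4. **Iterative LOWESS**: `s` is regressed on `m` with `stats::lowess`
   (span `frac = 0.3`, three robustifying iterations inside each fit —
   conventional smoother defaults, exposed as parameters since no
   bandwidth is prescribed). The fit is repeated three times; after each
   fit a normal distribution is fitted to the residuals of the points in
   that fit, and points outside the 5%–95% normal-CDF quantiles are
   excluded from the next fit, so genuine outliers cannot bend the curve
   they are measured against. After the last fit the curve is evaluated at
   every peak and the score is the absolute residual `|ds_j|`; raw
   absolute residuals rather than their normal quantiles are used for
   ranking (quantiles are reported alongside).

## Numerical choices

- **Curve evaluation at all peaks**: linear interpolation over the fitted
  `m` grid; *constant* extrapolation at the boundaries, so peaks whose
  `m` lies outside the trimmed range are not scored against a runaway
  extrapolated line.
- **Exact-fit ties**: residuals below `1e-12 · max(1, max|s|)` are snapped
  to zero so that, on degenerate collinear input, ranking falls back to
  the documented index tie-break instead of floating-point noise.
- **Flat residuals**: when the residual SD is numerically zero the normal
  quantile trim is skipped (there is nothing to trim) and quantiles are
  reported as 0.5.
- **PCA sign convention**: each component's loading vector is flipped so
  its largest-magnitude entry is positive. This pins the embedding under
  permutations of cells, making scores exactly cell-permutation invariant
  (up to measure-zero magnitude ties).
- **PCA backend**: exact eigendecomposition of the smaller Gram matrix
  for up to 10^7 matrix entries; seeded `irlba` above that. The seed is a
  recorded run parameter.
- **Degenerate embedding rows** (zero variance for Pearson/Spearman, zero
  norm for cosine) contribute coefficient 0 to every pair, including
  their own self term, and are flagged.
- **Blockwise correlation**: rows of `P` are standardised once; blocks of
  `chunk_size` peaks are correlated against all peaks by one matrix
  product; the slab is reduced to per-peak sums of `c` and `c²` and
  discarded; the self term is removed analytically (it contributes 1 and
  1² for well-defined rows). The working set is `p·q + chunk_size·p`,
  never `p²`. Workers map over blocks and the reduction order is fixed by
  block index, so results are independent of `n_workers` and agree across
  chunk sizes to the floating-point reduction tolerance (tested at
  1e-10). No instrumented-allocation test is included: R lacks reliable
  per-expression peak-memory measurement, and the working-set bound holds
  by construction.

## The simulator: what it emulates, and what it does not

The generator is this package's own definition of the five archetypes,
built to reproduce the well-known properties of real scCAS data —
high sparsity (overall density < 0.25 at S1 defaults), close-to-binary
counts (open sites receive `1 + Poisson(0.15)` counts, so ≥ 95% of
nonzero entries are ≤ 2), and planted type-specific peaks as ground
truth:

- **S1** (uniform): 4 types × 250 cells; 200 specific peaks per type open
  in their own type with probability 0.6, in other types 0.05; 1000
  background peaks open everywhere with probability 0.2.
- **S2/S3** (dynamic): as S1, but each specific peak's own-type open
  probability is drawn from U(0.4, 0.8) (S2) or the wider, harder
  U(0.2, 0.9) (S3). The widths are artifact conventions — only the
  existence of a "dynamic range" is documented behaviour.
- **S4** (rare type): three common types of 320 cells and one rare type
  of 40 cells (4%, under the ≤ 5% rarity bound).
- **S5** (trajectory): three branches (a root splitting into two children
  at pseudotime 0.5, represented as three labelled branches with uniform
  cell placement); branch-specific peaks ramp linearly from the off-type
  to the specific open probability along their branch's local pseudotime.

Not emulated: genomic sequence context, realistic peak coordinates
(peaks live on a dummy chromosome), batch effects, per-cell depth
gradients, fragment-level counts, and doublets. A green test on these
worlds therefore establishes that the selector recovers planted
co-accessibility structure under sparsity and dropout — not that it
handles batch confounding or real peak-calling artifacts.

## Evaluation harness

- **Overlap proportion** is `|selected ∩ truth| / min(|selected|,
  |truth|)`: the denominator of this statistic varies across the
  literature, and the `min` makes a perfect selector reach 1 whether it
  selects fewer or more peaks than the planted truth.
- **Baselines**: HDA scores peaks by prevalence; the Signac-style
  baseline by the empirical quantile of TF-IDF row sums; the
  epiScanpy-style baseline by the tent function `1 − |2f − 1|` of the
  open fraction `f` — an implementation of that method's *behavioural*
  description (maximal at half-open, zero at none/all-open), labelled an
  approximation of the baseline.
- **Clustering pipeline**: selected peaks → TF-IDF → cell-wise PCA to 50
  components → unweighted 15-NN graph under cosine distance → Leiden
  (modularity), with the resolution binary-searched (≤ 20 halvings) until
  the cluster count matches the number of true types, else the nearest
  count seen. The search targets the true type count because evaluation
  is against known labels.
- **Metrics**: NMI (arithmetic normalisation), AMI (exact hypergeometric
  expected-MI correction), ARI and homogeneity implemented from their
  textbook formulas and cross-checked in the tests against independent
  naive-loop recomputation and against values frozen from scikit-learn.
  ASW is the mean silhouette width of the true labels on the
  50-dimensional embedding mapped to [0, 1]. cLISI is the inverse-Simpson
  index of true labels over each cell's 30 nearest neighbours with
  uniform weights (a simplification of the perplexity-weighted original),
  rescaled so 1 = pure neighbourhoods, 0 = fully mixed, median over
  cells. Neighbourhood sizes (15 graph, 30 cLISI) are artifact defaults
  recorded in every report; cLISI can only reach 1 when every type has at
  least 30 cells.

## Known limitations

- The S1 world is *easy* for downstream clustering: four balanced types of
  250 cells separated by 800 planted peaks remain perfectly clusterable
  even when only a fifth of the selected peaks are informative and 30% of
  nonzero entries are dropped. The dropout-robustness acceptance property
  (strict NMI dominance of the correlation-based selector over every
  baseline at every rate) therefore saturates — all methods tie at
  NMI = 1.0 at every dropout rate up to 0.30 — and is reported red by
  design rather than papered over. The overlap-proportion properties,
  which do not saturate, are where the selectors genuinely separate.

- Absolute clustering metric values on the synthetic worlds are not
  comparable to any published benchmark numbers — only method *orderings*
  are meaningful, and that is what the acceptance properties assert.
- The planted-outlier recovery property is scale-free in the
  displacement-to-noise ratio: at a ratio of exactly 3 the "all 20
  outliers in the top 25" event is statistically near-impossible (the
  two-sided background extreme of 500 points reaches ≈ 3σ). The
  acceptance test uses a +0.3 displacement with noise
  σ = 0.02 (ratio 15), which the package recovers completely.
- `run_cofea` reports filtered-out peaks with score 0 after all scored
  peaks, so output rows always align with the input peak set; a
  filtered peak is never "selected" unless `k` exceeds the number of
  surviving peaks, which is rejected up front.
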