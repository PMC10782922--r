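# cofea

Correlation-based feature selection for single-cell chromatin accessibility
(scCAS / scATAC-seq) data, with simulators and a clustering-based evaluation
harness.

## The problem

A peak-by-cell scATAC-seq count matrix `X ∈ R^{p×n}` is extremely sparse,
high-dimensional and close to binary. Most peaks carry no cell-type signal,
and the common practice of keeping the most prevalent peaks (or the most
"variable" ones, judged peak by peak) systematically favours large cell
populations and misses rare ones. `cofea` instead asks how each peak
*co-varies with every other peak*: peaks specific to a cell type correlate
strongly (positively and negatively) with the other peaks of that type,
while background peaks do not.

## The method

1. **TF-IDF** normalisation (Signac-style by default):
   `x'_ij = log(1 + (x_ij / Σ_i x_ij) · (n / Σ_j x_ij) · 10^4)`.
2. **Cell-wise PCA**: peaks are the observations, cells the variables,
   giving a peak-by-PC embedding `P ∈ R^{p×q}` (default `q = 100`).
3. **Inter-peak correlation summaries**: for each peak `j`, the mean `m_j`
   and mean square `s_j` of its `p−1` Pearson correlations (Spearman and
   cosine also available) with all other peaks, computed block-by-block so
   the `p×p` matrix is never stored.
4. **Iterative LOWESS scoring**: a LOWESS curve of `s` on `m` captures the
   background trend; it is fitted three times, each time dropping points in
   the outer 5% normal-quantile tails of the residuals so outliers cannot
   bend the curve. Each peak's significance score is its absolute residual
   `|ds_j|` from the last fit; the top `k` scores are the informative peaks.

## Worked example

```r
library(cofea)

sim <- simulate_sccas(simulation_spec("S1", seed = 1))
sim$counts
#> CountMatrix: 1800 peaks x 1000 cells (density 0.194), 4 cell types

st <- run_cofea(sim$counts, k = 800)
head(st, 3)
#>   peak_index            peak_id      score rank selected
#> 1        651 chrS:650000-650500 0.09016804    1     TRUE
#> 2        639 chrS:638000-638500 0.08901623    2     TRUE
#> 3        730 chrS:729000-729500 0.08815384    3     TRUE

# fraction of the 800 planted type-specific peaks recovered
overlap_proportion(selected_peaks(st), seq_along(sim$truth_specific))
#> [1] 0.81
overlap_proportion(selected_peaks(baseline_hda(sim$counts, 800)),
                   seq_along(sim$truth_specific))
#> [1] 0.21875

rep <- cluster_and_score(sim$counts, selected_peaks(st), seed = 1)
c(nmi = rep$nmi, ari = rep$ari, clisi = rep$clisi)
#>   nmi   ari clisi
#>     1     1     1
```

The selected peaks recover 81% of the planted cell type-specific peaks
(prevalence-based selection recovers 22%), and clustering cells on the
selected peaks reproduces the four planted types perfectly (NMI = ARI = 1).

## Command line

```sh
Rscript inst/cli/cofea.R simulate --archetype S1 --seed 0 --out-dir sim/
Rscript inst/cli/cofea.R select --mtx sim/matrix.mtx --bed sim/peaks.bed \
    --barcodes sim/barcodes.tsv --n-features 800 --out scores.tsv
Rscript inst/cli/cofea.R evaluate --sim-dir sim/ --methods cofea,hda \
    --n-features 800 --out report.tsv
```

Every output gets a `.manifest.json` beside it with the resolved
configuration and input digests.

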