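# sctfa

Per-cell **transcription factor (TF) activity inference** from single-cell
RNA-seq by prior-structured Bayesian factor analysis.

A TF's regulatory activity is not the same thing as its mRNA level: many
master regulators are lowly or sporadically captured in scRNA-seq, while
their target programs are clearly engaged. `sctfa` estimates a latent
activity for every TF in every cell by decomposing the log-normalized
expression matrix

```
Y  ≈  W Z ,        Y: genes × cells,  W: genes × TFs,  Z: TFs × cells
```

where the loading matrix `W` is *structured by ChIP-seq evidence*: entry
`W[n, k]` gets a wide prior `N(0, 1/δ_k)` when gene *n* carries a binding
site of TF *k* in its promoter window, and a near-zero prior `N(0, 0.001)`
otherwise. The per-factor precision `δ_k ~ Gamma(10⁻³, 10⁻³)` is learned
(automatic relevance determination), so prior target genes that are not
actually regulated in the profiled cells are switched off by the data.
Activities are bounded, `Z[k, m] ~ Beta(0.5, 0.5)`, and residual noise is
Gaussian with per-gene scale `ε_n ~ Gamma(1, 1)`. The posterior is
approximated by mean-field automatic-differentiation variational inference
(ADVI): factorized Gaussians on unconstrained transforms, stochastic
gradient ascent on the ELBO, convergence when the mean relative ELBO change
drops below 0.01, and reported matrices are means of 300 posterior draws.

Around the model, the package provides the complete workflow:

* **Preprocessing** — `log_normalize()` (library-size scaling ×10,000,
  `log1p`), `select_variable_genes()` (mean > 0.1 and variance/mean > 1 on
  the log scale), `select_tfs()` (variably expressed, ChIP-seq available,
  ≥ 10 prior targets among the variable genes, with a user-include
  override).
* **Prior construction** — `promoter_regions()` (strand-aware
  [−2000, +200] windows around TSS), `assign_targets()` (≥ 1-base
  peak–promoter overlap via GenomicRanges), optional
  `filter_targets_by_accessibility()` for ATAC-style filtering, and
  `build_prior_matrix()` for the binary gene × TF mask.
* **Downstream analysis** — `rank_targets()` (posterior-weight target
  ranking), `marker_tfs()` (random-forest importance per cell type),
  `diffusion_distances()` + `louvain_cluster()` (top-20%-edge graph
  clustering in activity space), `partition_metrics()` (RI / ARI / NMI),
  `jaccard_index()`, and a CRISPRi-style `perturbation_auroc()` benchmark.
* **Synthetic ground truth** — `simulate_ground_truth()`,
  `simulate_counts()`, `simulate_perturbation()` generate datasets with
  known `W`, `Z`, labels and knockdowns so every claim is testable without
  external downloads.
* **Pipeline runner** — `run_pipeline()` plus a thin CLI wrapper
  (`inst/cli/sctfa`) chain the stages over plain files with a checksum
  manifest and a resolved-config echo.

## Worked example

```r
library(sctfa)

truth <- simulate_ground_truth(synthetic_scenario(seed = 1))
fit   <- fit_tfa(truth$Y, truth$mask, model_config(seed = 1))
fit
#> <tfa_fit> 200 genes x 5 TFs x 300 cells; converged after 300 iterations

# how well do inferred activities track the simulated truth?
sapply(1:5, function(k) abs(cor(truth$Z_true[k, ], fit$Z_mean[k, ])))
#>   TF1   TF2   TF3   TF4   TF5
#> 0.986 0.987 0.994 0.989 0.992

# preferred targets of TF1, ranked by posterior weight
head(rank_targets(fit, "TF1", 5, "positive"))
#>       gene   weight
#> 1 gene0085 2.488075
#> 2 gene0051 1.715880
#> 3 gene0014 1.572528
#> 4 gene0162 1.433417
#> 5 gene0021 1.366665

# which TF marks cell type 1?
head(marker_tfs(fit, truth$labels, "type1", seed = 1), 3)
#>    tf importance
#> 1 TF1 0.65183338
#> 2 TF2 0.09984800
#> 3 TF3 0.08673258
```

The correlations say the five latent activity programs are recovered almost
exactly; the ranking puts genuine (simulated) TF1 targets at the top; and
the planted type-specific program TF1 dominates the random-forest
importance for its cell type.

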