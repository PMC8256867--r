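---
title: "Inferring transcription factor activities with sctfa: model, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring transcription factor activities with sctfa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sctfa)
```

## The model

`sctfa` treats the log-normalized expression profile of each cell as a
linear mixture of transcription-factor regulatory programs:

$$ Y = W Z + \Phi $$

with $Y$ genes × cells, $W$ genes × TFs (loadings), $Z$ TFs × cells
(activities), and $\Phi$ residual noise. The model is Bayesian, and its
distinguishing feature is that ChIP-seq evidence enters as the *prior
structure* of $W$:

* $W_{nk} \sim N(0,\, 1/\delta_k)$ when gene $n$ is a prior target of TF
  $k$ (its promoter window overlaps a ChIP-seq peak of $k$), and
  $W_{nk} \sim N(0,\, 0.001)$ otherwise. Second parameters are read as
  variances, so the off-target standard deviation is about 0.03: loadings
  without binding evidence are pinned near zero.
* $\delta_k \sim \mathrm{Gamma}(10^{-3}, 10^{-3})$ (shape/rate). This is an
  automatic-relevance-determination (ARD) hyperprior: each factor learns
  its own loading precision, so prior target genes that the data do not
  support are shrunk away, which is what turns a generic ChIP-seq target
  list into a dataset-specific one.
* $Z_{km} \sim \mathrm{Beta}(0.5, 0.5)$. Activities live in $(0,1)$; the
  horseshoe-shaped Beta prefers clearly-on or clearly-off states but does
  not force them.
* $\phi_{nm} \sim N(0, \varepsilon_n)$ with
  $\varepsilon_n \sim \mathrm{Gamma}(1,1)$, interpreted as a prior on the
  per-gene noise *standard deviation*.

Assumptions worth stating plainly: the expression of a gene is a *linear*
function of TF activities on the log-normalized scale; programs combine
additively; noise is Gaussian (not count-based — the model is meant to run
after log-normalization, not on raw counts); and a TF without surviving
ChIP-seq targets cannot be assigned an activity at all.

### Ambiguities resolved by configuration

Two notational readings of the priors are defensible and both are
implemented. `prior_scale_reading = "variance"` (default) takes
$1/\delta_k$ and $0.001$ as variances, the ARD convention; `"sd"` takes
them as standard deviations, which is what a literal Stan transliteration
would do. Similarly the residual scale is per-gene by default
(`noise_model = "per_gene"`, matching "for gene n") with a shared scalar
available. Defaults were chosen once, on the ARD-convention argument, and
the switch is exposed rather than silently decided.

## Inference

The posterior is approximated by mean-field automatic-differentiation
variational inference (ADVI), implemented natively in the package:

1. All parameters are mapped to unconstrained space — identity for $W$,
   logit for $Z$, log for $\delta$ and $\varepsilon$ — with Jacobian terms
   included in the objective.
2. The variational family is a fully factorized Gaussian
   $q(u) = \prod_i N(u_i \mid \mu_i, \sigma_i^2)$.
3. The ELBO is maximized by stochastic gradient ascent with reparameterized
   gradients. Gradients of the log joint are analytic (the model is simple
   enough that autodiff would add nothing), estimated from
   `grad_mc_samples = 1` Monte Carlo draw per step, and fed to Adam
   (base step `learning_rate = 0.05`, decayed by $(1 + 10^{-3} t)^{-1/2}$).
   Variational standard deviations are initialized at 0.1 and means at 0
   (so $Z$ starts at 0.5, $\delta$ and $\varepsilon$ at 1).
4. Every `elbo_eval_every = 100` steps the ELBO is estimated from
   `elbo_mc_samples = 100` draws. The optimizer stops when the mean
   relative ELBO change across the trailing `elbo_window = 2` evaluations
   falls below `rel_tol = 0.01`, or at `max_iterations = 20000`.
5. Reported `W_mean`, `Z_mean`, `delta_mean`, `noise_mean` are means of
   `n_posterior_draws = 300` draws from the fitted variational posterior,
   not the variational means themselves.

All randomness flows from `model_config(seed = ...)` through R's RNG, so a
fit is bitwise reproducible: identical seed and configuration give
identical outputs, and `write_fit()` serializes at 17 significant digits so
a round trip through disk is exact.

The factor decomposition has no rotation ambiguity here because each
factor's prior support differs (mask columns are distinct); the remaining
scale trade-off between $W$ and $Z$ is bounded by $Z \in (0,1)$ and the
priors, which in practice pins columns well enough that activities are
compared to ground truth directly, without alignment.

## Preprocessing

`log_normalize()` computes
$\ln(1 + c_{gc} \cdot s / \mathrm{total}_c)$ with scale $s = 10{,}000$;
the natural logarithm matches the standard LogNormalize procedure.
`select_variable_genes()` keeps genes with mean log expression strictly
above 0.1 *and* variance-to-mean ratio strictly above 1, using the
population (divide-by-$M$) variance — the simpler fixed choice, documented
here because sample variance would move genes near the boundary. No
bin-wise dispersion z-scoring is applied: the two numeric cutoffs alone
define selection. `select_tfs()` then retains TFs that are themselves
variably expressed (or explicitly user-included), have ChIP-seq data, and
keep at least 10 prior targets after intersecting with the variable genes;
the intersection becomes the TF's effective target set.

## Prior construction

Promoter windows default to 2 kb upstream and 200 bp downstream of the
TSS and are strand-aware (upstream means 5′ of the gene); strand awareness
can be switched off, and `promoter_window_presets()` exposes the window
sweep from narrow ([−500, +50]) to distal ([−10 kb, +10 kb]). Genes with
several TSS records contribute the union of their windows. A single base of
overlap between a peak and a promoter (half-open semantics, so abutting
intervals do not touch) makes a gene a prior target; duplicated peaks are
harmless because the rule is existential. All internal coordinates are
0-based half-open; BED is read natively and 1-based TSS tables are shifted
on input. With accessibility data, `filter_targets_by_accessibility()`
drops targets whose promoters overlap no open region.

## Downstream analysis

**Target ranking** sorts a TF's posterior loading column, descending for
preferred targets and ascending for repression-like negative weights, with
lexicographic gene-id tie-breaks.

**Marker TFs** are ranked by impurity importance of a random forest
classifying one cell type against the rest from the activity matrix.
Cells are canonically ordered by id before training so the result is
independent of input order at a fixed seed; importances are normalized to
sum to one.

**Clustering** builds diffusion distances on cells — Gaussian kernel with
bandwidth equal to the median pairwise Euclidean distance, density
normalization with $\alpha = 1$, row-normalization to a Markov matrix,
eigendecomposition, distances at diffusion time 1 from the top 20
non-trivial components — then keeps the
$\lfloor 0.2 \cdot M(M-1)/2 \rfloor$ smallest distances as an unweighted
graph (ties at the cutoff broken by node-pair order) and runs Louvain
modularity optimization. The diffusion construction parameters are not
canonical — any fixed, documented variant separates well-separated
populations — and are exposed in the configuration. Partition agreement is
reported as RI, ARI and NMI ($2I/(H_X + H_Y)$, natural logarithms; the
base cancels except for the two-single-cluster case, defined as 1).

**Perturbation benchmark.** For each targeted TF, every cell receives a
logFC of its inferred activity against the mean activity over control
cells, $\log_2\!\big((z + p)/(\bar z_{\mathrm{ctrl}} + p)\big)$ with
pseudocount $p = 10^{-6}$. A *per-cell* reference-to-control-mean logFC is
the only reading under which thresholding individual cells is well defined;
a group-level logFC would give one number per experiment. Cells targeted
for the TF form the positive class, controls the negative class, the score
is the negated logFC, all (score, label) pairs across TFs are pooled, and
the AUROC is the Mann–Whitney $U/(n_+ n_-)$ with half-credit ties. A
per-TF AUROC table is attached for diagnostics.

## The synthetic generator

`simulate_ground_truth()` emulates the structure the model assumes: K TFs
with disjoint 10-gene programs, positive loadings
$|N(\mu = 1, \sigma = 1/3)|$ (mixed-sign optional), activities drawn
Beta(5, 2) in cell types where a TF's program is active and Beta(2, 5)
elsewhere — bimodal but inside the model's Beta support, detectable without
being trivial — and expression $WZ$ plus Gaussian noise (sd 0.1 by
default), clipped at zero. `simulate_counts()` layers multinomial
library-size sampling on top so the normalization path can be tested
against the log-scale truth, and `simulate_perturbation()` appends copies
of existing cells with one TF's activity scaled by $1-\text{efficiency}$,
reusing the source cell's noise realization so a zero-efficiency knockdown
is an exact duplicate.

What the generator does *not* emulate: zero inflation and dropout curves,
batch effects, varying sequencing depth, gene–gene correlation beyond the
factor structure, overlapping TF programs, or any mismatch between the
ChIP-seq mask and the true loadings (in real data the mask is both noisy
and incomplete). Passing the synthetic recovery tests therefore shows the
estimator is correct *under its own assumptions*; it does not certify
performance on real tissues, where prior quality dominates.

Validation problem sizes were chosen once as desk-scale regimes that still
exercise every code path: recovery and ranking at 200 genes × 5 TFs × 300
cells with noise sd 0.1 over five seeds; the perturbation protocol at 100
genes × 3 TFs × 120 cells with 30 perturbed cells; clustering on 300 cells
in three planted activity blobs (centroid separation ≈ 0.6, within-blob sd
0.05 — the Beta-drawn activities themselves form overlapping clouds, which
is a statement about that generator setting, not about the clustering
code).

## Numerical and degenerate-input choices

* Strict inequalities at the selection cutoffs, verbatim from their
  definition ("higher than", "larger than").
* Population variance in the VMR; zero-mean genes are excluded outright.
* Cells with zero total counts are an error (listing the offending ids),
  not silently dropped.
* All-zero mask columns are rejected before fitting (an unidentifiable
  factor); genes targeted by no TF are kept with all-zero mask rows.
* Duplicate gene or cell identifiers are rejected at the boundary rather
  than resolved by guessing.
* Kernel bandwidth falling to zero (all cells identical) is replaced by 1;
  every distance is then 0 and downstream behavior is well defined.
* Edge selection and target ranking use deterministic tie-breaks (node
  order, gene id) so outputs are stable across runs.
* Fit serialization uses 17 significant digits (`%.17g`), the minimum that
  round-trips IEEE doubles exactly.

## Known limitations

The likelihood is Gaussian on log-normalized values, so the model should
not be pointed at raw counts; there is no intercept term (an optional
row-centering flag exists, off by default, since the reference formulation
has none); inference is full-batch, so very large cell numbers pay memory
proportional to $K \times M$; TF identity resolution is exact string
matching, with no alias mapping; and the mean-field approximation
underestimates posterior variance, so `W_mean`/`Z_mean` are useful point
summaries while the variational spread should not be read as a calibrated
credible interval.
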