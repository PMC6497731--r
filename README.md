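# hci

High-order correlation integration for clustering single-cell or bulk
RNA-seq samples.

## What it does, and for whom

Unsupervised clustering of cells (scRNA-seq) or patients (bulk
multi-omics) is fragile when the expression matrix is noisy and sparse.
`hci` is for analysts who want a clustering that does not hinge on any
single representation of the data: it derives sample-similarity views
from the expression matrix itself, fuses everything into one
low-dimensional sample pattern, and clusters that.

The pipeline, for a gene-by-sample matrix **X** (m × n):

1. **High-order correlation views.** **F**¹ is the n × n Pearson
   correlation matrix of the sample columns of **X**;
   **F**² = corr(**F**¹) treats **F**¹ as an n-feature × n-sample matrix
   and correlates again. Samples of one type have similar correlation
   *profiles* even when their raw profiles are noisy, so each iteration
   sharpens cluster block structure (it saturates at order 2, the
   default).
2. **Local patterns.** Each view **W** ∈ {**X**, **F**¹, **F**²} is
   centered and factorized, **W** ≈ **c1**ᵀ + **U Y**ᵢ, keeping the
   smallest dimension whose eigenvalues reach 80% (expression) or 90%
   (correlation views) of the spectrum.
3. **Global pattern.** The local patterns **Y**ᵢ are fused by adaptively
   weighted generalized Procrustes alignment: minimize
   Σᵢ wᵢ‖**Y** − **A**ᵢ**Y**ᵢ‖²_F with orthonormal maps **A**ᵢ and
   softmax weights wᵢ ∝ exp(−rᵢ/λ), so views that disagree with the
   consensus (e.g. a pure-noise omics layer) are down-weighted.
4. **Clustering.** K-means (k-means++ seeding, best of restarts) on the
   columns of **Y**. The cluster number K is estimated from the RDC
   curve, RDC = D_in/D_out (mean within- over mean between-cluster
   pairwise distance), averaged over repeated K-means runs: the chosen K
   is the smallest one at which the curve stops decreasing meaningfully.
   Agreement with known labels is scored by the adjusted Rand index.
5. **Differential features.** Genes/miRNAs are ranked by the coefficient
   of variation of their loading rows (cᵢ = δᵢ/μᵢ on loading
   magnitudes); features above a threshold (default: the 90th
   percentile) are called differential and exported for downstream
   network/enrichment tools.

The same machinery integrates several omics matrices over shared samples
(mRNA + miRNA + methylation): every view contributes its expression
matrix and its **F**¹/**F**² to the joint alignment.

## Worked example

```r
library(hci)

sim <- simulate_expression(synthetic_spec(n_samples = 90, n_features = 500,
                                          k_true = 3, seed = 7))
X   <- normalize_columns(filter_zero_features(sim$X), "log1p-zscore")
fit <- hci_fit(X, max_order = 2)
fit$global
#> GlobalPattern: 55 x 90; 3 views; 9 iterations (converged)
#>   weights: mRNA=0.415 mRNA.F1=0.479 mRNA.F2=0.105

curve <- estimate_k(fit, k_max = 8, n_repeats = 10, seed = 7)
curve
#> RDCCurve over K = 2..8: chosen K = 3
#>   mean RDC: 0.870 0.782 0.788 0.792 0.794 0.795 0.795

cl <- kmeans_on_pattern(fit, curve$chosen_k, seed = 7)
adjusted_rand_index(cl$labels, sim$labels)
#> [1] 1

tab <- select_differential(cv_weights(fit, view = "mRNA"))
attr(tab, "n_selected")
#> [1] 50
```

Reading: the three views were fused into a 55-dimensional sample pattern
with the second-order view contributing 10% of the consensus weight; the
RDC curve drops steeply to K = 3 and flattens (0.870 → 0.782, then ~flat),
so K = 3 is selected; clustering at K = 3 reproduces the planted labels
exactly (ARI 1); and 50 of 500 genes — the generator plants 10% markers —
exceed the differential-feature threshold.

The same flows are scriptable from a shell:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "hci.R", package = "hci"))')" \
    cluster --input expr.tsv --labels labels.tsv --outdir out --seed 1
```

with subcommands `cluster`, `integrate`, `features`, `simulate` writing
`pattern.tsv`, `labels.tsv`, `rdc_curve.tsv`, `weights_<view>.tsv`,
`model.rds` and a `summary.json` that echoes the full configuration.

## Scope

Visualization (t-SNE/heatmaps), marker-based cell annotation, and
external-database steps (STRING, miRDB, GO/KEGG/IPA enrichment, survival
analysis) are out of scope; the ranked feature lists are formatted as
input for such tools.
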