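# biamil

Attention-based multiple-instance learning (MIL) for slide-level
classification of H&E whole-slide images, with the full surrounding
pipeline: tiling and background filtering, structure-preserving stain
normalization, leakage-free patient-level splits, bag construction, a
bi-directional two-head self-attention aggregator with its training loop,
slide-level evaluation with bootstrap confidence intervals, and
interpretability tools (attention tile ranking, Smooth Grad-CAM,
tumor-infiltrating-lymphocyte quantification, cell-morphology clustering,
2-D projections, rank-sum group comparisons). Everything runs end to end
on seeded synthetic data with known ground truth, so the package is fully
testable without any image downloads.

## Who this is for

Computational-pathology researchers who want a transparent, dependency-light
reference implementation of attention MIL in R — for methods work, teaching,
or as the statistical/evaluation backbone of a slide-classification study
where the image backbone is supplied externally.

## The model

A slide is cut into 512×512 tiles (50 % overlap; tiles with more than 75 %
background are discarded), tiles become D-dimensional feature vectors
through a pluggable backbone, and each slide contributes bags of N = 35
instances. Per bag `X ∈ R^{N×D}`:

- embedding: `E = X Wₑᵀ + bₑ`
- two attention heads, per head: `K, Q, V = E W_{k,q,v}ᵀ`,
  scores `α = Q Kᵀ` (`α[i,j] = q_i · k_j`), `A = softmax(α) V`
- pooling: `A_c = [A_h ‖ A_l]`, instance weights
  `w = softmax(A_c W_A)`, pooled vectors `f_h = A_hᵀ w`, `f_l = A_lᵀ w`
- classification: `z = γ f_h + μ f_l` (γ, μ learnable, init 0.5), MLP
  `D → 64 → 2` with Tanh, softmax, cross-entropy loss

Training uses Adam at the published operating point (lr 0.001, batch 18,
20 epochs, lr ×0.1 every 10 epochs) with hand-derived analytic gradients,
verified against finite differences in the test suite. The instance
weights `w` are the interpretable per-tile attention; the bag probability
is provably invariant to instance order. Slide score = mean bag
probability.

## Worked example

Train on the standard planted-witness benchmark (200 training bags, 100
test bags, N = 10, D = 32; positive bags contain two instances shifted by
2 along a hidden direction) and evaluate:

```r
library(biamil)
bench <- mil_benchmark(seed = 1)
fit   <- train_biamil(bench$train$bags,
                      hyperparams = biamil_hyperparams(d_k = 8L), seed = 1)
preds <- predict_bags(fit$params, bench$test$bags)
report <- compute_metrics(aggregate_slides(preds)$label,
                          aggregate_slides(preds)$slide_prob, seed = 1)
print(report)
```

```
Slide-level metrics (n = 100, threshold = 0.50)
  auroc        0.841  [0.757, 0.913]
  accuracy     0.750  [0.660, 0.830]
  sensitivity  0.760  [0.640, 0.880]
  specificity  0.740  [0.620, 0.860]
  ppv          0.745  [0.655, 0.840]
  npv          0.755  [0.660, 0.857]
  f1           0.752  [0.660, 0.832]
```

Each row is a slide-level metric with its seeded stratified-bootstrap 95 %
interval. For context, `witness_bayes_auroc(seed = 1)` returns the
information ceiling of this generator — the AUROC of the exact
likelihood-ratio classifier, about 0.90 at these settings — so 0.84 from
20 epochs on 200 bags means the aggregator has learned most of the
available signal. `run_mil_benchmark(seed = 1)` wraps the above and also
reports how often the true witness instances receive above-average
attention in positive bags.

The methods vignette (`vignettes/biamil-methods.Rmd`) documents the model,
the preprocessing, every tunable default, and the design decisions.

## A thin CLI

`inst/cli/biamil.R` exposes tiling, patient splitting, synthetic-data
generation, and slide-level evaluation as shell commands, e.g.

```sh
Rscript inst/cli/biamil.R tile --width 2048 --height 2048 --out tiles.csv
Rscript inst/cli/biamil.R evaluate --preds preds.csv
```
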