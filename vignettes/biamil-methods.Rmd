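---
title: "Attention-based multiple-instance learning for slide-level
  classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attention-based multiple-instance learning for slide-level classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biamil)
```

## The problem

A whole-slide image (WSI) of an H&E-stained tumor section is a gigapixel
object, but its clinically interesting label — here, whether the patient
carries a *BRCA1/2* pathogenic variant (PV) versus wild-type (WT) — attaches
to the slide, not to any individual region. Multiple-instance learning (MIL)
is the natural formulation: the slide is cut into tiles, tiles are grouped
into *bags* of feature vectors, and a classifier maps each bag to a label
while learning, without tile-level supervision, *which* instances carry the
signal. Most tiles are uninformative; a few "witness" tiles (e.g. regions
rich in tumor cells or lymphocytic infiltration) drive the label.

`biamil` implements the full desk-scale pipeline around this idea:
preprocessing (tiling, background filtering, stain normalization),
leakage-free cohort handling, the bi-directional attention aggregator
itself, slide-level evaluation, and interpretability tools. Because real
cohorts of this kind are private, every stage is exercised on seeded
synthetic generators with known ground truth; what that does and does not
establish is discussed at the end.

## Preprocessing

**Tiling.** Slides are covered by 512×512-pixel windows with 50 % overlap
(stride 256). A window is emitted only if it fits entirely inside the
image; there is no padding, so the count per axis is
`floor((dim − tile)/stride) + 1`. Coordinates are 0-based with a top-left
origin, enumerated row-major.

**Background filtering.** A pixel is background if it is near-white
(`min(R,G,B) ≥ 220`) or essentially unsaturated (HSV saturation ≤ 0.05).
Tiles with *more than* 75 % background are discarded; exactly 75 % keeps.
The threshold is the standard one for H&E tissue detection; the rule is
deliberately cheap and testable on constructed tiles.

**Stain normalization.** Color variation between scanners and staining
batches is removed in optical-density (OD) space:
`OD = −log((I+1)/256)`. Tissue pixels (max channel OD ≥ 0.15) are
factorized as `OD ≈ S C` with a 2-column non-negative dictionary `S`
(unit-norm stain vectors; hematoxylin is the column with the larger
blue-channel OD) and sparse non-negative concentrations `C`, fitted by
seeded multiplicative updates with an L1 penalty (default weight 0.1, 500
iterations, at most 5000 randomly subsampled pixels). A tile is normalized
by decomposing it under its source basis with per-pixel non-negative least
squares, rescaling each stain channel by the ratio of 99th-percentile
concentrations, and recombining under the target basis. Tiles whose stain
estimation fails (fewer than 1 % tissue pixels) are passed through
unnormalized rather than dropped, since excess background is the only
stated drop criterion. The normalization target is a free choice; in
practice any representative tissue-rich tile serves.

**Augmentation.** Random flips, 90° rotations, crop-and-resize, and
brightness/contrast/saturation/hue jitter, all drawn from a seeded RNG so a
given `(tile, seed, config)` triple is bit-reproducible. The identity
configuration returns the input unchanged.

## Cohort handling

Labels live at the patient level, so all splitting is at patient
granularity: a stratified 80/20 train/test split assigns
`round(0.8 · class size)` patients of each class to training, and k-fold
cross-validation (default k = 5) deals shuffled patients of each class
round-robin, balancing folds to within one patient. Because patients —
never slides — are assigned, no patient's slides can straddle partitions;
the test suite verifies this across 1000 seeds.

Bags are formed per slide: tile features are shuffled with a seeded RNG and
cut into disjoint chunks of exactly `N = 35` (the published operating
point); the remainder is dropped by default, or one padded bag can be
formed by resampling. Keeping bags within one slide is the conservative
choice given that slide-level scores are averages over that slide's bags.

## The aggregator

Each bag is an `N × D` matrix `X` (rows = instances; `D = 1000` for a
conventional backbone). The model is:

1. **Embedding** — a row-wise affine map `E = X Wₑᵀ + bₑ`, preserving `D`.
2. **Two attention heads** (`h` and `l`, nominally high- and low-risk; no
   head-specific supervision is imposed). Per head:
   `K = E W_kᵀ`, `Q = E W_qᵀ`, `V = E W_vᵀ`, pairwise scores
   `α[i,j] = q_i · k_j`, and `A = softmax(α) V`, where the softmax runs
   over the key axis so each instance's mixing weights form a simplex.
   `d_k` defaults to 256; `d_v = D` so `A` is `N × D`.
3. **Pooling** — the heads are concatenated feature-wise,
   `A_c = [A_h ‖ A_l]`, every instance gets a score `s = A_c W_A`, the
   scores become simplex weights `w = softmax(s)` over instances, and each
   head is pooled with those shared weights: `f_h = A_hᵀ w`, `f_l = A_lᵀ w`.
4. **Head combination and classification** — `z = γ f_h + μ f_l` with
   learnable scalars `γ, μ` initialized at 0.5, then an MLP
   `D → 64 → 2` with Tanh and a softmax; the loss is the bag-level
   cross-entropy.

Two dimensional ambiguities in the published description were resolved as
design choices: the softmax axis in `A = V·softmax(α)` is taken over keys
(each instance's mixing weights a simplex), and the pooling weight vector
`W_A ∈ R^{2d_v}` scores *instances* with `σ` read as a softmax over
instances — the only reading under which the concatenated attention matrix,
the stated 1000-dimensional pooled vectors, and the `γ/μ` "mask" selection
of per-head blocks are simultaneously type-correct. The "mask" is block
selection, not stochastic masking.

The pooled weights `w` are exactly the interpretable per-tile attention
used downstream. Because attention is permutation-equivariant and pooling
contracts it with a symmetric weighting, the bag probability is invariant
to instance order; the suite checks this to 1e−6 and checks every formula
against explicit-loop oracles to 1e−9.

**Training.** Mini-batch Adam at the published operating point: learning
rate 0.001, batch 18, 20 epochs, learning rate ×0.1 every ten epochs.
Gradients are analytic (hand-derived backpropagation through the attention
algebra, verified against finite differences); initialization is the
standard uniform fan-in rule `U(±1/√fan_in)`. The score matrix `α = KᵀQ`
carries no `1/√d_k` temperature — the published formulation has none — so
the conservative init scale is what keeps the score softmax out of
saturation at the start of training; with a larger (e.g. `√(6/fan_in)`)
scale the attention saturates at random and the model memorizes instead of
learning. Training, including bag shuffling, is a pure function of the
seed.

## Evaluation

A slide's score is the arithmetic mean of its bags' positive-class
probabilities. Metrics are AUROC (rank-based, ties counted ½ — equal to
the normalized Mann–Whitney U), plus accuracy, sensitivity, specificity,
PPV, NPV and F1 at a 0.5 threshold (the threshold is a package default; no
published value exists). 95 % confidence intervals use a seeded,
class-stratified percentile bootstrap (2000 replicates) uniformly for all
metrics; resampling is done from class-sorted score vectors so results are
invariant to slide ordering. Ratios with empty denominators are reported
as `NaN` and flagged rather than silently imputed.

## Interpretability

* **Attention ranking** — per-tile weights are the mean of a tile's
  instance weights across the bags containing it; the top
  `ceil(0.2 · n)` tiles per slide are returned, ties broken by tile index.
* **Smooth Grad-CAM** — for a backbone exposing convolutional activations,
  the class-activation map is the ReLU-rectified sum of activation maps
  weighted by spatially averaged gradients, averaged over Gaussian-noised
  copies of the input (default 25 samples, σ = 0.1 of the intensity
  range), bilinearly upsampled and min–max normalized. With one noiseless
  sample it reduces to plain Grad-CAM. A small deterministic convnet
  (conv → ReLU → global average pool → linear) ships for testing;
  production backbones plug in through the same contract.
* **TILs quantification** — `TILs% = TILs/(TILs + tumor cells) × 100`;
  stroma is excluded by the definition.
* **Cell-morphology clustering** — features are z-scored (unscaled
  k-means would be dominated by the area features), constant columns are
  dropped with a warning, and `stats::kmeans` runs with 10 seeded restarts
  at k = 6. Cluster–feature association is the point-biserial (Pearson on
  one-hot indicator) correlation.
* **Group comparison** — two-sided Wilcoxon rank-sum: exact permutation
  distribution when both groups have ≤ 8 untied observations, otherwise
  the normal approximation with tie and continuity corrections.
* **2-D projection** — exact (dense) t-SNE and a UMAP-style fuzzy-graph
  layout, both implemented in-package as compact, seeded, full-batch
  algorithms intended for the hundreds-to-thousands of points this
  pipeline visualizes. They are not replacements for the reference
  implementations at scale.

## Synthetic data: what it emulates and what it does not

* **Slides** — colored elliptical blobs (hematoxylin-purple "tumor",
  eosin-pink "stroma") on a white canvas with an exact tumor mask. This
  exercises tiling geometry, the background rule, and tumor-tile
  classification contracts — not histologic texture.
* **Bags** — background instances `N(0, σ²I)`; in positive bags
  `round(witness_rate · N)` instances are additionally shifted by `shift`
  along one seeded unit direction shared between train and test. This is
  deliberately the *weakest* structure sufficient to test whether
  attention finds witnesses; real tile features are far richer.
* **Cell tables** — log-normal cell and nucleus areas with the
  nucleus-to-cell ratio drawn in (0, 1) (so the containment invariant
  holds by construction), tumor/TIL/stroma classes at 60/20/20 %, and
  additive log-scale shifts for the PV group.

The standard benchmark uses 200 training and 100 test bags, `N = 10`,
`D = 32`, witness rate 0.2, shift 2, unit noise — sized for minutes-scale
single-CPU training while keeping the task non-trivial. For the benchmark
model `d_k` follows the same 1:4 ratio to `D` as the full-size defaults
(256:1000), i.e. `d_k = 8`.

```{r benchmark, eval = FALSE}
res <- run_mil_benchmark(seed = 1)
res$auroc             # held-out bag-level AUROC
res$witness_recovery  # fraction of positive bags whose witnesses got
                      # above-average attention
```

An important calibration: because only the projection of each instance on
the signal direction is informative, the Bayes-optimal bag classifier has
a closed-form likelihood-ratio score, and its AUROC — computable with
`witness_bayes_auroc()` — is the ceiling for *any* learner at these
generator settings. At the default settings that ceiling is close to 0.9,
so observed benchmark AUROCs in the 0.7–0.85 range reflect the intrinsic
hardness of the task plus finite training data, not necessarily an
implementation defect. The null benchmark (`shift = 0`) makes positive and
negative bags exchangeable, and a sound pipeline must score near 0.5 on
it; this guards against label leakage through the generator or the
training loop.

Passing on these generators establishes the algebra, the optimization, the
splitting discipline and the statistical machinery. It does not establish
performance on real H&E images: no photorealistic texture, no scanner
variation beyond the simulated stain bases, no spatial correlation among
tiles, and no pretrained backbone are modeled.

## Numerical choices and degenerate inputs

* Softmaxes are computed with max-subtraction; cross-entropy clamps
  probabilities at 1e−12.
* Stain NMF: OD floor 0.15, seeded init, 500 multiplicative updates;
  per-pixel decomposition solves the 2-variable non-negative least-squares
  problem in closed form (clamp-and-refit).
* k-means ties are resolved by best inertia over 10 restarts; constant
  features are dropped (clustering) or reported as zero correlation with a
  flag (association).
* Wilcoxon exactness cutoff is both groups ≤ 8 without ties, where
  enumeration is cheap and the approximation is weakest.
* Empty bags, single-class training sets, all-white tiles, and
  zero-denominator metrics raise typed errors (`invalid-argument`,
  `invalid-training-set`, `stain-estimation-failure`, `undefined-ratio`)
  rather than propagating `NaN`.

## Known limitations

* The pretrained feature backbone and the tumor-segmentation network are
  plug-in contracts, not deliverables; the shipped extractors and the
  purple-fraction classifier are deterministic test doubles.
* Only the sparse-NMF structure-preserving normalizer is provided; GAN
  color transfer is out of scope.
* The two heads carry no head-specific supervision; their "high-/low-risk"
  semantics emerge (or not) from training.
* The in-package t-SNE/UMAP layouts are quadratic in the number of points.
* Benchmark AUROC is bounded by the generator's Bayes ceiling (see above);
  results on real slides depend on data and backbone quality and cannot be
  inferred from the synthetic benchmark.
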