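# Interpretability: attention-ranked tiles, class-activation heatmaps, TILs
# quantification, cell-morphology clustering, and group statistics.

#' Rank a slide's tiles by attention weight
#'
#' Aggregates per-instance attention weights to per-tile weights (mean over
#' the bags a tile occurs in), then returns the `ceiling(fraction * n_tiles)`
#' highest-weight tiles. Ties are broken by tile index (lower index first).
#'
#' @param traces List of `attention_trace` objects (one per bag, from
#'   [biamil_forward()] or [predict_bags()]).
#' @param tile_idx List parallel to `traces`: for each bag, the tile indices
#'   of its instances (e.g. the `tile_idx` field of each `bag`).
#' @param fraction Fraction of tiles to keep. Default 0.2 (the top 20%).
#' @return `data.frame` with `tile` (index) and `weight`, one row per
#'   selected tile, ordered by decreasing weight.
#' @export
rank_tiles_by_attention <- function(traces, tile_idx, fraction = 0.2) {
  if (!length(traces)) stop("invalid-argument: no attention traces",
                            call. = FALSE)
  stopifnot(length(traces) == length(tile_idx))
  w <- unlist(lapply(traces, `[[`, "instance_weights"))
  idx <- unlist(tile_idx)
  stopifnot(length(w) == length(idx))
  agg <- tapply(w, idx, mean)
  tiles <- as.integer(names(agg))
  n_top <- ceiling(fraction * length(tiles))
  ord <- order(-as.numeric(agg), tiles)
  sel <- ord[seq_len(n_top)]
  data.frame(tile = tiles[sel], weight = as.numeric(agg)[sel],
             row.names = NULL)
}

# ---- toy convolutional backbone + Smooth Grad-CAM ---------------------------

#' A small convolutional backbone for class-activation mapping
#'
#' One valid-convolution layer (`k x k x 3 x F` filters + bias, ReLU),
#' global average pooling, and a linear classifier -- the minimal
#' architecture exposing the named convolutional activations and their
#' gradients that Grad-CAM requires. Filters and weights are seeded random
#' unless supplied.
#'
#' @param k Filter side length. Default 3.
#' @param n_filters Number of filters. Default 4.
#' @param n_classes Output classes. Default 2.
#' @param filters,class_weights Optional explicit parameters
#'   (`k x k x 3 x F` array; `n_classes x F` matrix).
#' @param seed Seed for random parameters.
#' @return A list of class `toy_convnet`.
#' @export
toy_convnet <- function(k = 3L, n_filters = 4L, n_classes = 2L,
                        filters = NULL, class_weights = NULL, seed = 1L) {
  with_seed_(seed, {
    if (is.null(filters))
      filters <- array(stats::rnorm(k * k * 3 * n_filters, sd = 0.1),
                       c(k, k, 3, n_filters))
    if (is.null(class_weights))
      class_weights <- matrix(stats::rnorm(n_classes * n_filters, sd = 0.5),
                              n_classes, n_filters)
  })
  structure(list(filters = filters, class_weights = class_weights,
                 k = dim(filters)[1], n_filters = dim(filters)[4],
                 n_classes = nrow(class_weights)),
            class = "toy_convnet")
}

# Valid convolution of an H x W x 3 image with the backbone filters;
# returns post-ReLU activation maps (H-k+1) x (W-k+1) x F.
convnet_activations <- function(net, img) {
  stopifnot_image(img)
  k <- net$k
  oh <- dim(img)[1] - k + 1L; ow <- dim(img)[2] - k + 1L
  if (oh < 1L || ow < 1L) stop("image smaller than filter", call. = FALSE)
  act <- array(0, c(oh, ow, net$n_filters))
  for (f in seq_len(net$n_filters)) {
    acc <- matrix(0, oh, ow)
    for (dy in seq_len(k)) for (dx in seq_len(k)) for (ch in 1:3) {
      acc <- acc + net$filters[dy, dx, ch, f] *
        img[dy:(dy + oh - 1L), dx:(dx + ow - 1L), ch]
    }
    act[, , f] <- pmax(acc, 0)
  }
  act
}

# Class scores from activations: GAP then linear.
convnet_scores <- function(net, act) {
  gap <- apply(act, 3L, mean)
  as.numeric(net$class_weights %*% gap)
}

#' Smooth Grad-CAM heatmap for a tile
#'
#' Grad-CAM weighs each convolutional activation map by the spatially
#' averaged gradient of the target-class score with respect to that map, and
#' rectifies the weighted sum. The smoothed variant averages the map over
#' `n_samples` Gaussian-noise perturbations of the input. The result is
#' bilinearly upsampled to the tile size and min-max normalized to `[0, 1]`.
#' With `n_samples = 1` and `noise_sigma = 0` it reduces to plain Grad-CAM.
#'
#' @param net A [toy_convnet()] (or any list with the same fields).
#' @param tile_image H x W x 3 RGB array, 0--255 scale.
#' @param target_class Class index (1-based) whose evidence is mapped.
#' @param n_samples Noise samples. Default 25.
#' @param noise_sigma Noise standard deviation on the 0--255 scale relative
#'   to 255 (i.e. 0.1 means sd 25.5). Default 0.1.
#' @param seed Seed for the noise draws.
#' @return H x W matrix in `[0, 1]`.
#' @export
smooth_grad_cam <- function(net, tile_image, target_class = 2L,
                            n_samples = 25L, noise_sigma = 0.1, seed = 1L) {
  stopifnot_image(tile_image)
  h <- dim(tile_image)[1]; w <- dim(tile_image)[2]
  cam_one <- function(img) {
    act <- convnet_activations(net, img)
    npix <- prod(dim(act)[1:2])
    # d score / d act[f] is class_weights[c, f] / npix at active units;
    # Grad-CAM averages the gradient over space, then weighs the maps.
    gw <- vapply(seq_len(net$n_filters), function(f) {
      mean((act[, , f] > 0) * net$class_weights[target_class, f] / npix)
    }, numeric(1))
    cam <- matrix(0, dim(act)[1], dim(act)[2])
    for (f in seq_len(net$n_filters)) cam <- cam + gw[f] * act[, , f]
    pmax(cam, 0)
  }
  cam <- with_seed_(seed, {
    acc <- NULL
    for (i in seq_len(n_samples)) {
      img <- tile_image
      if (noise_sigma > 0)
        img <- img + array(stats::rnorm(length(img), sd = noise_sigma * 255),
                           dim(img))
      ci <- cam_one(img)
      acc <- if (is.null(acc)) ci else acc + ci
    }
    acc / n_samples
  })
  up <- resize_bilinear(array(rep(cam, 3), c(dim(cam), 3)), h, w)[, , 1]
  rng <- range(up)
  if (rng[2] > rng[1]) (up - rng[1]) / (rng[2] - rng[1]) else up * 0
}

# ---- TILs -------------------------------------------------------------------

#' Tumor-infiltrating-lymphocyte percentage
#'
#' `TILs% = TILs / (TILs + tumor cells) * 100`; stromal cells are excluded
#' by the definition.
#'
#' @param n_tils,n_tumor Non-negative cell counts.
#' @return Percentage in `[0, 100]`.
#' @export
tils_percent <- function(n_tils, n_tumor) {
  if (n_tils < 0 || n_tumor < 0) stop("counts must be non-negative",
                                      call. = FALSE)
  if (n_tils + n_tumor < 1) stop("undefined-ratio: no TILs or tumor cells",
                                 call. = FALSE)
  100 * n_tils / (n_tils + n_tumor)
}

#' TILs percentage from a cell table
#'
#' @param cell_table `data.frame` with a `cell_class` column using levels
#'   `tumor`, `TIL`, `stroma`.
#' @return Percentage in `[0, 100]`.
#' @export
tils_percent_from_table <- function(cell_table) {
  tils_percent(sum(cell_table$cell_class == "TIL"),
               sum(cell_table$cell_class == "tumor"))
}

# ---- cell-morphology clustering --------------------------------------------

#' Cluster cells on standardized morphology features
#'
#' Z-scores each feature column, drops degenerate (constant) columns with a
#' warning, and runs seeded k-means (k-means++-free base `stats::kmeans`
#' with 10 random restarts, best inertia kept). The cluster-feature
#' correlation matrix holds the Pearson correlation of each one-hot cluster
#' indicator with each standardized feature (point-biserial correlation).
#'
#' @param cell_table `data.frame`; non-feature columns (`cell_id`,
#'   `slide_id`, `cell_class`, `group`, `tile`) are ignored automatically.
#' @param k Number of clusters. Default 6.
#' @param seed Integer seed.
#' @param standardize Z-score features before clustering. Default TRUE.
#' @return A `cluster_summary` list: `k`, `labels` (0-based cluster index
#'   per cell), `centroids`, `correlation` (k x F), `features_used`.
#' @export
cluster_cells <- function(cell_table, k = 6L, seed = 1L, standardize = TRUE) {
  meta <- c("cell_id", "slide_id", "cell_class", "group", "tile", "tile_ref")
  feat_cols <- setdiff(names(cell_table)[vapply(cell_table, is.numeric,
                                                TRUE)], meta)
  x <- as.matrix(cell_table[, feat_cols, drop = FALSE])
  if (nrow(x) < k) stop("fewer cells than clusters", call. = FALSE)
  if (any(!is.finite(x))) stop("non-finite feature values", call. = FALSE)
  const <- apply(x, 2L, function(col) stats::sd(col) == 0)
  if (any(const)) {
    warning("dropping constant feature column(s): ",
            paste(feat_cols[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
    feat_cols <- feat_cols[!const]
  }
  if (standardize) x <- scale(x)
  km <- with_seed_(seed,
                   stats::kmeans(x, centers = k, nstart = 10L,
                                 iter.max = 100L))
  labels <- km$cluster - 1L
  correlation <- cluster_feature_correlation(labels, x, k = k)
  structure(list(k = k, labels = labels, centroids = km$centers,
                 correlation = correlation, features_used = feat_cols),
            class = "cluster_summary")
}

#' Cluster-feature correlation matrix
#'
#' Point-biserial (Pearson-on-indicator) correlation of each cluster's
#' one-hot membership vector with each feature column. Constant features get
#' correlation 0 and are flagged via the `"constant_features"` attribute.
#'
#' @param labels 0-based integer cluster labels.
#' @param features Numeric matrix, rows aligned with `labels`.
#' @param k Number of clusters (default `max(labels) + 1`).
#' @return `k x F` matrix with entries in `[-1, 1]`.
#' @export
cluster_feature_correlation <- function(labels, features, k = NULL) {
  features <- as.matrix(features)
  if (is.null(k)) k <- max(labels) + 1L
  const <- apply(features, 2L, function(col) stats::sd(col) == 0)
  out <- matrix(0, k, ncol(features),
                dimnames = list(paste0("cluster", seq_len(k) - 1L),
                                colnames(features)))
  if (any(!const)) {
    for (cl in seq_len(k) - 1L) {
      ind <- as.numeric(labels == cl)
      if (stats::sd(ind) == 0) next
      out[cl + 1L, !const] <- apply(features[, !const, drop = FALSE], 2L,
                                    function(col) stats::cor(ind, col))
    }
  }
  attr(out, "constant_features") <- colnames(features)[const]
  out
}

# ---- group comparison -------------------------------------------------------

#' Two-sided Wilcoxon rank-sum comparison of two groups
#'
#' Reports both group medians and the two-sided rank-sum p-value: exact (by
#' the null permutation distribution of the rank sum) when both groups have
#' at most 8 observations and there are no ties, otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param values_a,values_b Non-empty numeric vectors.
#' @param exact_max Largest group size for which the exact distribution is
#'   used. Default 8.
#' @return List with `median_a`, `median_b`, `p_value`, `method`.
#' @export
compare_groups_wilcoxon <- function(values_a, values_b, exact_max = 8L) {
  if (!length(values_a) || !length(values_b))
    stop("invalid-argument: a group is empty", call. = FALSE)
  ties <- anyDuplicated(c(values_a, values_b)) > 0L
  use_exact <- !ties && length(values_a) <= exact_max &&
    length(values_b) <= exact_max
  wt <- suppressWarnings(
    stats::wilcox.test(values_a, values_b, exact = use_exact,
                       correct = TRUE, alternative = "two.sided"))
  list(median_a = stats::median(values_a),
       median_b = stats::median(values_b),
       p_value = wt$p.value,
       method = if (use_exact) "exact" else "normal-approximation")
}
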