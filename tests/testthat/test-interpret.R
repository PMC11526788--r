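fake_trace <- function(w) structure(list(instance_weights = w),
                                    class = "attention_trace")

test_that("top-fraction attention ranking selects ceil(fraction * n) tiles", {
  tr <- list(fake_trace(c(0.5, 0.3, 0.1, 0.07, 0.03)))
  idx <- list(1:5)
  top <- rank_tiles_by_attention(tr, idx, fraction = 0.2)
  expect_equal(nrow(top), 1L)
  expect_equal(top$tile, 1L)

  all_t <- rank_tiles_by_attention(tr, idx, fraction = 1)
  expect_equal(sort(all_t$tile), 1:5)

  # equal weights: the tie rule picks the lowest indices
  eq <- rank_tiles_by_attention(list(fake_trace(rep(0.1, 10))), list(1:10),
                                fraction = 0.2)
  expect_equal(eq$tile, c(1L, 2L))
  expect_error(rank_tiles_by_attention(list(), list()), "invalid-argument")
})

test_that("attention ranking averages a tile's weight across bags", {
  # tile 3 occurs in two bags with weights 0.6 and 0.2 -> mean 0.4
  tr <- list(fake_trace(c(0.6, 0.4)), fake_trace(c(0.2, 0.8)))
  idx <- list(c(3L, 1L), c(3L, 2L))
  top <- rank_tiles_by_attention(tr, idx, fraction = 1)
  expect_equal(top$weight[top$tile == 3L], 0.4)
  expect_equal(top$tile[1], 2L)  # 0.8 is the single highest mean
})

test_that("smooth grad-cam localizes a bright square and stays in [0,1]", {
  img <- array(0, c(32, 32, 3))
  img[10:20, 14:24, ] <- 255
  net <- toy_convnet(filters = array(1 / 27, c(3, 3, 3, 2)),
                     class_weights = matrix(1, 2, 2))
  hm <- smooth_grad_cam(net, img, target_class = 1, n_samples = 1,
                        noise_sigma = 0)
  expect_equal(dim(hm), c(32L, 32L))
  expect_gte(min(hm), 0)
  expect_lte(max(hm), 1)
  am <- which(hm == max(hm), arr.ind = TRUE)[1, ]
  expect_true(am[1] >= 10 && am[1] <= 20)
  expect_true(am[2] >= 14 && am[2] <= 24)
})

test_that("smoothing with one noiseless sample equals plain grad-cam", {
  img <- withr::with_seed(8, array(runif(20 * 20 * 3, 0, 255), c(20, 20, 3)))
  net <- toy_convnet(seed = 4)
  h1 <- smooth_grad_cam(net, img, target_class = 2, n_samples = 1,
                        noise_sigma = 0, seed = 1)
  h2 <- smooth_grad_cam(net, img, target_class = 2, n_samples = 1,
                        noise_sigma = 0, seed = 99)
  expect_equal(h1, h2)  # no noise: seed-independent, pure grad-cam
  hs <- smooth_grad_cam(net, img, target_class = 2, n_samples = 5,
                        noise_sigma = 0.1, seed = 3)
  expect_identical(hs, smooth_grad_cam(net, img, target_class = 2,
                                       n_samples = 5, noise_sigma = 0.1,
                                       seed = 3))
})

test_that("TILs percentage follows its defining formula", {
  expect_equal(tils_percent(0, 100), 0)
  expect_equal(tils_percent(50, 50), 50)
  expect_equal(tils_percent(31, 89), 100 * 31 / 120)
  expect_error(tils_percent(0, 0), "undefined-ratio")
  # monotone in the TIL count at fixed tumor count
  vals <- vapply(1:20, tils_percent, numeric(1), n_tumor = 10)
  expect_true(all(diff(vals) > 0))
  expect_true(all(vals >= 0 & vals <= 100))
  # stroma is excluded by construction
  tab <- data.frame(cell_class = c("TIL", "tumor", "stroma", "stroma", "TIL"))
  expect_equal(tils_percent_from_table(tab), 100 * 2 / 3)
})

test_that("k-means recovers separated blobs and flags indicator features", {
  skip_if_not_installed("mclust")
  withr::with_seed(42, {
    centers <- matrix(rnorm(6 * 4, sd = 8), 6, 4)
    truth <- rep(1:6, each = 60)
    x <- centers[truth, ] + matrix(rnorm(360 * 4, sd = 0.5), 360, 4)
  })
  tab <- as.data.frame(x)
  names(tab) <- paste0("f", 1:4)
  cs <- cluster_cells(tab, k = 6, seed = 3)
  ari <- mclust::adjustedRandIndex(cs$labels, truth)
  expect_gte(ari, 0.95)
  expect_true(all(cs$correlation >= -1 & cs$correlation <= 1))

  # a feature equal to a cluster's indicator correlates 1 with that cluster
  ind <- as.numeric(cs$labels == 2)
  cor_mat <- cluster_feature_correlation(cs$labels, cbind(ind = ind))
  expect_equal(unname(cor_mat["cluster2", "ind"]), 1)
  expect_true(all(cor_mat[-3, "ind"] < 0))
})

test_that("degenerate feature columns are dropped or zero-flagged", {
  tab <- data.frame(a = rnorm(50), b = rep(1, 50))
  expect_warning(cs <- cluster_cells(tab, k = 2, seed = 1), "constant")
  expect_equal(cs$features_used, "a")
  cm <- cluster_feature_correlation(rep(0:1, 25), cbind(const = rep(2, 50)))
  expect_true(all(cm == 0))
  expect_equal(attr(cm, "constant_features"), "const")
  # k = 1: everything in cluster 0
  expect_true(all(cluster_cells(data.frame(a = rnorm(20)), k = 1,
                                seed = 1)$labels == 0L))
})

test_that("a label-independent feature has near-zero correlation", {
  withr::with_seed(11, {
    labels <- sample(0:2, 1000, replace = TRUE)
    feat <- cbind(noise = rnorm(1000))
  })
  cm <- cluster_feature_correlation(labels, feat, k = 3)
  expect_true(all(abs(cm) < 0.1))
})

test_that("2-D projections are seeded and preserve blob separation", {
  withr::with_seed(9, {
    x <- rbind(matrix(rnorm(40 * 6), 40, 6),
               matrix(rnorm(40 * 6, mean = 10), 40, 6))
  })
  for (m in c("tsne", "umap")) {
    y1 <- project_2d(x, method = m, seed = 4)
    y2 <- project_2d(x, method = m, seed = 4)
    expect_identical(y1, y2)
    expect_equal(dim(y1), c(80L, 2L))
    expect_true(all(is.finite(y1)))
    between <- sqrt(sum((colMeans(y1[1:40, ]) - colMeans(y1[41:80, ]))^2))
    within <- max(sqrt(rowSums(sweep(y1[1:40, ], 2,
                                     colMeans(y1[1:40, ]))^2)),
                  sqrt(rowSums(sweep(y1[41:80, ], 2,
                                     colMeans(y1[41:80, ]))^2)))
    expect_gt(between, within)
  }
  expect_error(project_2d(matrix(0, 3, 2)), "invalid-argument")
})

test_that("rank-sum comparison is exact for small untied groups", {
  r <- compare_groups_wilcoxon(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$method, "exact")
  expect_equal(r$median_a, 2)

  # identical tied groups: symmetric, p = 1 under the corrected approximation
  rt <- compare_groups_wilcoxon(c(1, 2, 3), c(1, 2, 3))
  expect_equal(rt$p_value, 1)
  expect_equal(rt$method, "normal-approximation")
  expect_error(compare_groups_wilcoxon(numeric(), 1:3), "invalid-argument")
})

test_that("rank-sum p-values equal exhaustive enumeration for all sizes <= 6", {
  withr::with_seed(29, {
    for (m in 2:6) for (n in 2:6) {
      vals <- sample(seq(0.01, 1, by = 0.01), m + n)  # untied by construction
      a <- vals[seq_len(m)]; b <- vals[-seq_len(m)]
      expect_equal(compare_groups_wilcoxon(a, b)$p_value,
                   oracle_wilcoxon_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("a powered shift is detected with the expected direction", {
  withr::with_seed(17, {
    a <- rnorm(200, mean = 1)
    b <- rnorm(200)
  })
  r <- compare_groups_wilcoxon(a, b)
  expect_lt(r$p_value, 1e-6)
  expect_gt(r$median_a, r$median_b)
})
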