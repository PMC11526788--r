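# 2-D embeddings for visualization: exact (dense) t-SNE and a UMAP-style
# fuzzy-graph layout. Both are compact in-package implementations intended
# for the moderate cell/tile counts this pipeline visualizes (hundreds to a
# few thousand points); both are pure functions of (data, seed).

#' Project feature vectors to two dimensions
#'
#' @param features Numeric `n x d` matrix (`n >= 5`).
#' @param method `"umap"` (fuzzy-graph layout) or `"tsne"` (exact t-SNE).
#' @param seed Integer seed; the same seed yields identical coordinates.
#' @param ... Passed to the underlying embedding (`perplexity`, `n_iter` for
#'   t-SNE; `n_neighbors`, `n_iter` for UMAP).
#' @return `n x 2` numeric matrix of finite coordinates.
#' @export
project_2d <- function(features, method = c("umap", "tsne"), seed = 1L, ...) {
  method <- match.arg(method)
  features <- as.matrix(features)
  if (nrow(features) < 5L)
    stop("invalid-argument: need at least 5 points", call. = FALSE)
  out <- switch(method,
                tsne = tsne_embed(features, seed = seed, ...),
                umap = umap_embed(features, seed = seed, ...))
  stopifnot(all(is.finite(out)))
  out
}

pairwise_sqdist <- function(x) {
  s <- rowSums(x^2)
  d <- outer(s, s, "+") - 2 * tcrossprod(x)
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# Binary-search the Gaussian bandwidth of each point to hit the target
# perplexity; returns the row-conditional affinity matrix.
tsne_affinities <- function(d2, perplexity) {
  n <- nrow(d2)
  p <- matrix(0, n, n)
  log_u <- log(perplexity)
  for (i in seq_len(n)) {
    di <- d2[i, -i]
    lo <- -Inf; hi <- Inf; beta <- 1
    for (it in 1:50) {
      w <- exp(-di * beta)
      sw <- sum(w)
      if (sw == 0) { h <- 0 } else {
        h <- log(sw) + beta * sum(di * w) / sw
      }
      if (abs(h - log_u) < 1e-5) break
      if (h > log_u) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2
                                           else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2
                                 else beta / 2 }
    }
    p[i, -i] <- w / max(sum(w), 1e-12)
  }
  p
}

tsne_embed <- function(x, seed = 1L, perplexity = 30, n_iter = 500L,
                       learning_rate = NULL) {
  n <- nrow(x)
  perplexity <- min(perplexity, (n - 1) / 3)
  d2 <- pairwise_sqdist(x)
  p <- tsne_affinities(d2, perplexity)
  p <- (p + t(p)) / (2 * n)
  p <- pmax(p, 1e-12)
  if (is.null(learning_rate)) learning_rate <- max(n / 12, 50)
  with_seed_(seed, {
    y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
    gain <- matrix(1, n, 2); inc <- matrix(0, n, 2)
    exaggeration <- 12
    for (iter in seq_len(n_iter)) {
      pe <- if (iter <= 100L) p * exaggeration else p
      dy2 <- pairwise_sqdist(y)
      num <- 1 / (1 + dy2); diag(num) <- 0
      q <- pmax(num / sum(num), 1e-12)
      l <- (pe - q) * num
      grad <- 4 * (diag(rowSums(l)) - l) %*% y
      momentum <- if (iter <= 250L) 0.5 else 0.8
      gain <- ifelse(sign(grad) != sign(inc), gain + 0.2, gain * 0.8)
      gain[gain < 0.01] <- 0.01
      inc <- momentum * inc - learning_rate * gain * grad
      y <- y + inc
      y <- sweep(y, 2L, colMeans(y))
    }
    y
  })
}

# ---- UMAP-style layout ------------------------------------------------------

# Fuzzy membership graph: per-point adaptive kernel on the k nearest
# neighbours (smoothed so the effective neighbour count matches
# log2(n_neighbors)), symmetrized by probabilistic union.
umap_graph <- function(d2, n_neighbors) {
  n <- nrow(d2)
  w <- matrix(0, n, n)
  target <- log2(n_neighbors)
  for (i in seq_len(n)) {
    di <- sqrt(d2[i, -i])
    nn <- order(di)[seq_len(min(n_neighbors, n - 1L))]
    dnn <- di[nn]
    rho <- min(dnn)
    lo <- 0; hi <- Inf; sigma <- 1
    for (it in 1:50) {
      s <- sum(exp(-pmax(dnn - rho, 0) / sigma))
      if (abs(s - target) < 1e-5) break
      if (s > target) { hi <- sigma; sigma <- (sigma + lo) / 2 }
      else { lo <- sigma; sigma <- if (is.finite(hi)) (sigma + hi) / 2
                                   else sigma * 2 }
    }
    idx <- seq_len(n)[-i][nn]
    w[i, idx] <- exp(-pmax(dnn - rho, 0) / sigma)
  }
  w + t(w) - w * t(w)
}

umap_embed <- function(x, seed = 1L, n_neighbors = 15L, n_iter = 200L,
                       a = 1.577, b = 0.8951, learning_rate = 1) {
  n <- nrow(x)
  n_neighbors <- min(n_neighbors, n - 1L)
  w <- umap_graph(pairwise_sqdist(x), n_neighbors)
  # deterministic PCA init (signs fixed), small seeded jitter to break exact
  # coincidences
  pc <- stats::prcomp(x, rank. = 2L)$x[, 1:2, drop = FALSE]
  if (ncol(pc) < 2L) pc <- cbind(pc, 0)
  for (j in 1:2) if (pc[which.max(abs(pc[, j])), j] < 0) pc[, j] <- -pc[, j]
  spread <- max(apply(pc, 2L, stats::sd), 1e-8)
  y <- pc / spread * 10
  y <- y + with_seed_(seed, matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2))
  eps <- 1e-3
  for (iter in seq_len(n_iter)) {
    alpha <- learning_rate * (1 - (iter - 1) / n_iter)
    dy2 <- pairwise_sqdist(y)
    phi <- 1 / (1 + a * dy2^b)
    att <- -2 * a * b * dy2^pmax(b - 1, 0) * phi * w        # attractive
    rep_ <- 2 * b / ((eps + dy2) * (1 + a * dy2^b)) * (1 - w) # repulsive
    coef <- att + rep_
    diag(coef) <- 0
    grad <- (diag(rowSums(coef)) - coef) %*% y * -2
    gnorm <- pmin(pmax(grad, -4), 4)
    y <- y - alpha * gnorm / n
    y <- sweep(y, 2L, colMeans(y))
  }
  y
}
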