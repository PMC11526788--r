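test_that("embedding is a row-wise affine map", {
  X <- matrix(rnorm(12), 3, 4)
  expect_equal(embed_instances(X, diag(4), numeric(4)), X)
  b <- c(1, -2, 0.5, 3)
  E0 <- embed_instances(X, matrix(0, 4, 4), b)
  expect_true(all(apply(E0, 1, function(r) all(r == b))))
  # affine identity: embed(a x) - a embed(x) = (1 - a) b
  W <- matrix(rnorm(16), 4, 4)
  a <- 0.3
  delta <- embed_instances(a * X, W, b) - a * embed_instances(X, W, b)
  expect_equal(delta, matrix((1 - a) * b, 3, 4, byrow = TRUE),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("single-instance attention returns that instance's value vector", {
  p <- random_params(D = 5, d_k = 3, seed = 2)
  x <- matrix(rnorm(5), 1, 5)
  E <- embed_instances(x, p$We, p$be)
  h <- head_self_attention(E, p$Wk_h, p$Wq_h, p$Wv_h)
  expect_equal(h$P, matrix(1, 1, 1))
  expect_equal(as.numeric(h$A), as.numeric(E %*% t(p$Wv_h)))
})

test_that("vectorized attention matches the explicit-loop oracle", {
  withr::with_seed(7, {
    for (rep in 1:20) {
      n <- sample(2:6, 1); D <- sample(3:8, 1); d_k <- sample(2:8, 1)
      p <- random_params(D = D, d_k = d_k, d_v = D, seed = rep)
      E <- matrix(rnorm(n * D), n, D)
      fast <- head_self_attention(E, p$Wk_h, p$Wq_h, p$Wv_h)
      slow <- oracle_head_attention(E, p$Wk_h, p$Wq_h, p$Wv_h)
      expect_lt(max(abs(fast$alpha - slow$alpha)), 1e-9)
      expect_lt(max(abs(fast$A - slow$A)), 1e-9)
    }
  })
})

test_that("attention is equivariant under instance permutation", {
  p <- random_params(D = 6, d_k = 4, seed = 3)
  E <- matrix(rnorm(5 * 6), 5, 6)
  perm <- c(3, 5, 1, 2, 4)
  A <- head_self_attention(E, p$Wk_h, p$Wq_h, p$Wv_h)$A
  Ap <- head_self_attention(E[perm, ], p$Wk_h, p$Wq_h, p$Wv_h)$A
  expect_equal(Ap, A[perm, ], tolerance = 1e-10)
})

test_that("pooling produces simplex weights and head-wise weighted sums", {
  A_h <- matrix(rnorm(8), 2, 4); A_l <- matrix(rnorm(8), 2, 4)
  # single instance: weight 1, f equals the row
  p1 <- attention_pool(A_h[1, , drop = FALSE], A_l[1, , drop = FALSE],
                       rnorm(8))
  expect_equal(p1$instance_weights, 1)
  expect_equal(p1$f_h, A_h[1, ])
  # zero scorer: uniform weights, column means
  p0 <- attention_pool(A_h, A_l, numeric(8))
  expect_equal(p0$instance_weights, c(0.5, 0.5))
  expect_equal(p0$f_h, colMeans(A_h))
  # duplicated instances share the weight
  Ad <- rbind(A_h[1, ], A_h[1, ], A_h[2, ])
  pd <- attention_pool(Ad, rbind(A_l[1, ], A_l[1, ], A_l[2, ]), rnorm(8))
  expect_equal(pd$instance_weights[1], pd$instance_weights[2])
})

test_that("pooling matches the loop oracle", {
  withr::with_seed(13, {
    for (rep in 1:20) {
      n <- sample(1:6, 1); d_v <- sample(2:8, 1)
      A_h <- matrix(rnorm(n * d_v), n, d_v)
      A_l <- matrix(rnorm(n * d_v), n, d_v)
      W_A <- rnorm(2 * d_v)
      fast <- attention_pool(A_h, A_l, W_A)
      slow <- oracle_pool(A_h, A_l, W_A)
      expect_lt(max(abs(fast$instance_weights - slow$instance_weights)), 1e-9)
      expect_lt(max(abs(fast$f_h - slow$f_h)), 1e-9)
      expect_lt(max(abs(fast$f_l - slow$f_l)), 1e-9)
    }
  })
})

test_that("the classifier head combines and normalizes correctly", {
  f_h <- rnorm(6); f_l <- rnorm(6)
  z0 <- combine_and_classify(f_h, f_l, 0.5, 0.5, matrix(0, 4, 6), numeric(4),
                             matrix(0, 2, 4), numeric(2))
  expect_equal(z0$bag_prob, c(0.5, 0.5))
  # gamma == mu collapses to gamma * (f_h + f_l)
  W1 <- matrix(rnorm(24), 4, 6); b1 <- rnorm(4)
  W2 <- matrix(rnorm(8), 2, 4); b2 <- rnorm(2)
  c1 <- combine_and_classify(f_h, f_l, 0.7, 0.7, W1, b1, W2, b2)
  expect_equal(c1$z, 0.7 * (f_h + f_l))
  expect_equal(sum(c1$bag_prob), 1, tolerance = 1e-12)
  expect_true(all(c1$bag_prob > 0 & c1$bag_prob < 1))
})

test_that("the loss takes its closed-form values and composes over batches", {
  expect_equal(biamil_loss(c(1, 0), c(1, 0)), 0)
  expect_equal(biamil_loss(c(0.5, 0.5), c(0, 1)), log(2))
  withr::with_seed(5, {
    probs <- lapply(1:10, function(i) { p <- runif(2); p / sum(p) })
    ys <- lapply(1:10, function(i) sample(list(c(1, 0), c(0, 1)), 1)[[1]])
    batch_mean <- mean(mapply(biamil_loss, probs, ys))
    loop_mean <- 0
    for (i in 1:10) loop_mean <- loop_mean + biamil_loss(probs[[i]], ys[[i]])
    expect_lt(abs(batch_mean - loop_mean / 10), 1e-9)
  })
})

test_that("bag probability is invariant under instance permutation", {
  withr::with_seed(21, {
    for (rep in 1:10) {
      n <- sample(2:8, 1); D <- 6
      p <- random_params(D = D, d_k = 3, seed = rep)
      X <- matrix(rnorm(n * D), n, D)
      perm <- sample(n)
      fw <- biamil_forward(p, X)
      fwp <- biamil_forward(p, X[perm, , drop = FALSE])
      expect_lt(max(abs(fw$bag_prob - fwp$bag_prob)), 1e-6)
      expect_lt(max(abs(fwp$instance_weights - fw$instance_weights[perm])),
                1e-6)
    }
  })
})

test_that("instance weights and bag probabilities are simplices", {
  withr::with_seed(31, {
    for (rep in 1:50) {
      n <- sample(1:7, 1); D <- sample(3:8, 1)
      p <- random_params(D = D, d_k = 4, seed = rep + 100)
      fw <- biamil_forward(p, matrix(rnorm(n * D), n, D))
      expect_lt(abs(sum(fw$instance_weights) - 1), 1e-9)
      expect_true(all(fw$instance_weights >= 0))
      expect_lt(abs(sum(fw$bag_prob) - 1), 1e-9)
    }
  })
})

test_that("analytic gradients for gamma and mu match finite differences", {
  p <- random_params(D = 6, d_k = 3, d_hidden = 4, seed = 17)
  X <- matrix(rnorm(4 * 6), 4, 6)
  y <- c(0, 1)
  g <- biamil:::biamil_backward(p, biamil_forward(p, X), y)
  eps <- 1e-6
  for (nm in c("gamma", "mu")) {
    p_hi <- p; p_hi[[nm]] <- p_hi[[nm]] + eps
    p_lo <- p; p_lo[[nm]] <- p_lo[[nm]] - eps
    fd <- (biamil_loss(biamil_forward(p_hi, X)$bag_prob, y) -
           biamil_loss(biamil_forward(p_lo, X)$bag_prob, y)) / (2 * eps)
    expect_lt(abs(g[[nm]] - fd) / max(abs(fd), 1e-8), 1e-4)
  }
})

test_that("training defaults mirror the published operating point", {
  hp <- biamil_hyperparams()
  expect_equal(hp$N, 35L)
  expect_equal(hp$lr, 0.001)
  expect_equal(hp$batch_size, 18L)
  expect_equal(hp$epochs, 20L)
  expect_equal(hp$lr_decay, 0.1)
  expect_equal(hp$decay_every, 10L)
  p <- biamil_params(D = 4, d_k = 2, d_hidden = 3, seed = 1)
  expect_equal(p$gamma, 0.5)
  expect_equal(p$mu, 0.5)
})

test_that("training is deterministic and decreases the loss", {
  bench <- mil_benchmark(seed = 5, n_train = 40, n_test = 10)
  hp <- biamil_hyperparams(epochs = 4L, d_k = 8L)
  f1 <- train_biamil(bench$train$bags, hyperparams = hp, seed = 5)
  f2 <- train_biamil(bench$train$bags, hyperparams = hp, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_lt(utils::tail(f1$history$train_loss, 1), f1$history$train_loss[1])
  # validation loss is tracked when a validation set is supplied
  f3 <- train_biamil(bench$train$bags, val_bags = bench$test$bags,
                     hyperparams = biamil_hyperparams(epochs = 2L, d_k = 8L),
                     seed = 5)
  expect_true(all(is.finite(f3$history$val_loss)))
  expect_error(train_biamil(bench$train$bags[1:20], hyperparams = hp),
               "invalid-training-set")
})
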