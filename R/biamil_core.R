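# The bi-directional attention MIL aggregator.
#
# Architecture, per bag of N instances with D-dimensional features X:
#   E  = X We' + be                      feature embedding (D -> D affine)
#   per head (two heads, "high-risk" h and "low-risk" l):
#     K = E Wk', Q = E Wq', V = E Wv'    rows are instances
#     alpha[i, j] = q_i . k_j            pairwise attention scores
#     P = softmax(alpha) over the key axis (each row a simplex)
#     A = P V                            attention-mixed value vectors
#   A_c = [A_h || A_l]                   feature-axis concatenation
#   s = A_c W_A,  w = softmax(s)         instance scores -> simplex weights
#   f_h = A_h' w, f_l = A_l' w           pooled per-head bag vectors
#   z = gamma f_h + mu f_l               learnable head combination
#   p = softmax(W2 tanh(W1 z + b1) + b2) bag probability (2 classes)
# loss = cross-entropy against the one-hot bag label.
#
# All tensors are plain base-R matrices; gradients are analytic (verified by
# finite differences in the test suite) and optimization is Adam.

#' Initialize the parameters of the attention MIL model
#'
#' All weight matrices are drawn from a seeded uniform fan-in distribution
#' `U(-1/sqrt(fan_in), 1/sqrt(fan_in))` (the conventional linear-layer
#' default). The attention scores `alpha = K' Q` carry no `1/sqrt(d_k)`
#' temperature, so a conservative weight scale is what keeps the score
#' softmax out of saturation at the start of training. Biases start at zero
#' and the head-combination scalars `gamma` and `mu` start at 0.5.
#'
#' @param D Instance feature dimensionality (default 1000).
#' @param d_k Key/query dimensionality per head (default 256).
#' @param d_v Value dimensionality per head; defaults to `D` so each head's
#'   attention matrix is `N x D`.
#' @param d_hidden Hidden width of the classifier MLP (default 64).
#' @param seed Integer seed for the initialization draws.
#' @return An object of class `biamil_params`: a named list of matrices,
#'   vectors, and the scalars `gamma`, `mu`.
#' @export
biamil_params <- function(D = 1000L, d_k = 256L, d_v = D, d_hidden = 64L,
                          seed = 1L) {
  ku <- function(nout, nin) {
    lim <- 1 / sqrt(nin)
    matrix(stats::runif(nout * nin, -lim, lim), nout, nin)
  }
  p <- with_seed_(seed, list(
    We = ku(D, D), be = numeric(D),
    Wk_h = ku(d_k, D), Wq_h = ku(d_k, D), Wv_h = ku(d_v, D),
    Wk_l = ku(d_k, D), Wq_l = ku(d_k, D), Wv_l = ku(d_v, D),
    W_A = as.numeric(ku(2L * d_v, 1L)),
    gamma = 0.5, mu = 0.5,
    W1 = ku(d_hidden, d_v), b1 = numeric(d_hidden),
    W2 = ku(2L, d_hidden), b2 = numeric(2L)))
  structure(p, class = "biamil_params",
            dims = list(D = D, d_k = d_k, d_v = d_v, d_hidden = d_hidden),
            seed = as.integer(seed))
}

#' @export
print.biamil_params <- function(x, ...) {
  d <- attr(x, "dims")
  cat(sprintf(paste0("<biamil_params: D=%d, d_k=%d, d_v=%d, mlp %d-%d-2, ",
                     "gamma=%.3f, mu=%.3f>\n"),
              d$D, d$d_k, d$d_v, d$d_v, d$d_hidden, x$gamma, x$mu))
  invisible(x)
}

#' Row-wise affine embedding of instance features
#'
#' @param features `N x D` matrix (rows are instances).
#' @param W `D x D` weight matrix.
#' @param b Length-`D` bias vector.
#' @return `N x D` matrix `features %*% t(W) + b`.
#' @export
embed_instances <- function(features, W, b) {
  features <- as.matrix(features)
  if (ncol(features) != ncol(W))
    stop("feature dimension does not match embedding weights", call. = FALSE)
  sweep(features %*% t(W), 2L, b, "+")
}

#' Single-head self-attention over a bag
#'
#' Computes keys, queries and values by linear maps of the embedded
#' instances, pairwise scores `alpha[i, j] = q_i . k_j`, a softmax over the
#' key axis (so each instance's mixing weights form a simplex), and the
#' attention-mixed values `A = P V`.
#'
#' @param E `N x D` embedded instances.
#' @param Wk,Wq `d_k x D` key/query weights.
#' @param Wv `d_v x D` value weights.
#' @return List with `K`, `Q`, `V`, `alpha` (`N x N`), `P` (row-stochastic),
#'   and `A` (`N x d_v`).
#' @export
head_self_attention <- function(E, Wk, Wq, Wv) {
  E <- as.matrix(E)
  K <- E %*% t(Wk); Q <- E %*% t(Wq); V <- E %*% t(Wv)
  alpha <- Q %*% t(K)
  if (any(!is.finite(alpha)))
    stop("numeric-failure: non-finite attention scores", call. = FALSE)
  P <- softmax_rows(alpha)
  list(K = K, Q = Q, V = V, alpha = alpha, P = P, A = P %*% V)
}

#' Attention pooling over the two heads
#'
#' Concatenates the two heads' attention matrices along the feature axis,
#' scores every instance with the weight vector `W_A`, converts the scores to
#' simplex weights with a softmax over instances, and pools each head's
#' matrix with those shared weights.
#'
#' @param A_h,A_l `N x d_v` attention matrices of the two heads.
#' @param W_A Length-`2 d_v` instance-scoring vector.
#' @return List with `instance_weights` (length `N`, sums to 1), `f_h`,
#'   `f_l` (length-`d_v` pooled bag vectors), and `scores`.
#' @export
attention_pool <- function(A_h, A_l, W_A) {
  A_h <- as.matrix(A_h); A_l <- as.matrix(A_l)
  if (!all(dim(A_h) == dim(A_l)))
    stop("head attention matrices must share a shape", call. = FALSE)
  s <- as.numeric(cbind(A_h, A_l) %*% W_A)
  w <- softmax_vec(s)
  list(instance_weights = w,
       f_h = as.numeric(crossprod(A_h, w)),
       f_l = as.numeric(crossprod(A_l, w)),
       scores = s)
}

#' Combine head vectors and classify the bag
#'
#' Forms `z = gamma * f_h + mu * f_l` and passes it through the classifier
#' MLP (affine to `d_hidden`, `tanh`, affine to 2) followed by a softmax.
#'
#' @param f_h,f_l Pooled per-head bag vectors.
#' @param gamma,mu Head-combination scalars.
#' @param W1,b1,W2,b2 MLP parameters.
#' @return List with `bag_prob` (2-simplex: `(p_WT, p_PV)`), `z`, `h1`
#'   (post-tanh hidden), `logits`.
#' @export
combine_and_classify <- function(f_h, f_l, gamma, mu, W1, b1, W2, b2) {
  z <- gamma * f_h + mu * f_l
  h1 <- tanh(as.numeric(W1 %*% z) + b1)
  logits <- as.numeric(W2 %*% h1) + b2
  list(bag_prob = softmax_vec(logits), z = z, h1 = h1, logits = logits)
}

#' Cross-entropy bag loss
#'
#' `-sum(y * log(p))` with probabilities clamped at `1e-12`.
#'
#' @param bag_prob Length-2 probability vector.
#' @param y One-hot length-2 label vector (`(1,0)` = WT, `(0,1)` = PV).
#' @return Non-negative scalar.
#' @export
biamil_loss <- function(bag_prob, y) {
  -sum(y * log(pmax(bag_prob, 1e-12)))
}

#' Full forward pass for one bag
#'
#' Runs embedding, both attention heads, pooling, and classification,
#' returning every intermediate needed for interpretation or
#' backpropagation.
#'
#' @param params A [biamil_params()] object.
#' @param X `N x D` bag feature matrix.
#' @return List of class `attention_trace` with elements `A_h`, `A_l`,
#'   `instance_weights`, `f_h`, `f_l`, `bag_prob`, plus internal
#'   intermediates.
#' @export
biamil_forward <- function(params, X) {
  X <- as.matrix(X)
  E <- embed_instances(X, params$We, params$be)
  hh <- head_self_attention(E, params$Wk_h, params$Wq_h, params$Wv_h)
  hl <- head_self_attention(E, params$Wk_l, params$Wq_l, params$Wv_l)
  pool <- attention_pool(hh$A, hl$A, params$W_A)
  cls <- combine_and_classify(pool$f_h, pool$f_l, params$gamma, params$mu,
                              params$W1, params$b1, params$W2, params$b2)
  structure(list(X = X, E = E, head_h = hh, head_l = hl,
                 A_h = hh$A, A_l = hl$A,
                 instance_weights = pool$instance_weights,
                 scores = pool$scores,
                 f_h = pool$f_h, f_l = pool$f_l,
                 z = cls$z, h1 = cls$h1, logits = cls$logits,
                 bag_prob = cls$bag_prob),
            class = "attention_trace")
}

# Backward pass for one bag: gradient of biamil_loss(biamil_forward(...), y)
# with respect to every parameter. Returns a list with the same names/shapes
# as the parameter list.
biamil_backward <- function(params, fw, y) {
  N <- nrow(fw$X)
  dlogits <- fw$bag_prob - y                       # softmax + CE
  dW2 <- outer(dlogits, fw$h1)
  db2 <- dlogits
  dh1 <- as.numeric(t(params$W2) %*% dlogits)
  da1 <- dh1 * (1 - fw$h1^2)
  dW1 <- outer(da1, fw$z)
  db1 <- da1
  dz <- as.numeric(t(params$W1) %*% da1)
  dgamma <- sum(dz * fw$f_h)
  dmu <- sum(dz * fw$f_l)
  df_h <- params$gamma * dz
  df_l <- params$mu * dz
  w <- fw$instance_weights
  # pooling: f = A' w for each head
  dA_h_pool <- outer(w, df_h)
  dA_l_pool <- outer(w, df_l)
  dw <- as.numeric(fw$A_h %*% df_h) + as.numeric(fw$A_l %*% df_l)
  ds <- w * (dw - sum(dw * w))                     # softmax over instances
  dW_A <- as.numeric(crossprod(cbind(fw$A_h, fw$A_l), ds))
  dAc <- outer(ds, params$W_A)
  d_v <- ncol(fw$A_h)
  dA_h <- dA_h_pool + dAc[, seq_len(d_v), drop = FALSE]
  dA_l <- dA_l_pool + dAc[, d_v + seq_len(d_v), drop = FALSE]
  back_head <- function(hd, dA, Wk, Wq, Wv) {
    dP <- dA %*% t(hd$V)
    dV <- t(hd$P) %*% dA
    dalpha <- hd$P * (dP - rowSums(dP * hd$P))     # row-wise softmax jacobian
    dQ <- dalpha %*% hd$K
    dK <- t(dalpha) %*% hd$Q
    list(dWk = t(dK) %*% fw$E, dWq = t(dQ) %*% fw$E, dWv = t(dV) %*% fw$E,
         dE = dK %*% Wk + dQ %*% Wq + dV %*% Wv)
  }
  bh <- back_head(fw$head_h, dA_h, params$Wk_h, params$Wq_h, params$Wv_h)
  bl <- back_head(fw$head_l, dA_l, params$Wk_l, params$Wq_l, params$Wv_l)
  dE <- bh$dE + bl$dE
  list(We = t(dE) %*% fw$X, be = colSums(dE),
       Wk_h = bh$dWk, Wq_h = bh$dWq, Wv_h = bh$dWv,
       Wk_l = bl$dWk, Wq_l = bl$dWq, Wv_l = bl$dWv,
       W_A = dW_A, gamma = dgamma, mu = dmu,
       W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
}

label_onehot <- function(label) {
  if (is.factor(label)) label <- as.character(label)
  if (identical(label, "PV")) c(0, 1)
  else if (identical(label, "WT")) c(1, 0)
  else stop("bag label must be 'PV' or 'WT'", call. = FALSE)
}

#' Default training hyperparameters
#'
#' The published operating point of the model: bags of 35 instances, Adam
#' with learning rate 0.001, batch size 18, 20 epochs, and the learning rate
#' multiplied by 0.1 every ten epochs.
#'
#' @param N Bag size.
#' @param lr Initial Adam learning rate.
#' @param batch_size Bags per optimizer step.
#' @param epochs Training epochs.
#' @param lr_decay Multiplicative decay factor.
#' @param decay_every Epoch period of the decay.
#' @param d_k,d_hidden Model dimensions handed to [biamil_params()].
#' @return A named list.
#' @export
biamil_hyperparams <- function(N = 35L, lr = 0.001, batch_size = 18L,
                               epochs = 20L, lr_decay = 0.1,
                               decay_every = 10L, d_k = 256L,
                               d_hidden = 64L) {
  list(N = N, lr = lr, batch_size = batch_size, epochs = epochs,
       lr_decay = lr_decay, decay_every = decay_every, d_k = d_k,
       d_hidden = d_hidden)
}

#' Train the attention MIL classifier
#'
#' Mini-batch Adam on the bag-level cross-entropy with the configured
#' learning-rate schedule. Initialization, bag shuffling, and therefore the
#' whole loss history are pure functions of `seed`.
#'
#' @param train_bags List of `bag` objects (see [make_bags()]); both classes
#'   must be present.
#' @param val_bags Optional held-out bags; per-epoch validation loss is
#'   recorded when supplied.
#' @param hyperparams A [biamil_hyperparams()] list.
#' @param seed Integer seed.
#' @return List with `params` (trained [biamil_params()]) and `history`
#'   (`data.frame` of per-epoch mean train and validation loss).
#' @export
train_biamil <- function(train_bags, val_bags = NULL,
                         hyperparams = biamil_hyperparams(), seed = 1L) {
  if (!length(train_bags)) stop("invalid-training-set: empty", call. = FALSE)
  labs <- vapply(train_bags, function(b) as.character(b$label), "")
  if (length(unique(labs)) < 2L)
    stop("invalid-training-set: need at least one bag per class",
         call. = FALSE)
  D <- ncol(train_bags[[1]]$features)
  hp <- hyperparams
  params <- biamil_params(D = D, d_k = hp$d_k, d_v = D,
                          d_hidden = hp$d_hidden, seed = seed)
  ys <- lapply(labs, label_onehot)
  yv <- if (length(val_bags))
    lapply(val_bags, function(b) label_onehot(b$label))
  # Adam state
  m <- lapply(params[param_names()], function(x) x * 0)
  v <- m
  step <- 0L
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  history <- data.frame(epoch = integer(), train_loss = numeric(),
                        val_loss = numeric())
  with_seed_(seed + 1L, {
    for (epoch in seq_len(hp$epochs)) {
      lr_e <- hp$lr * hp$lr_decay^(floor((epoch - 1L) / hp$decay_every))
      ord <- sample.int(length(train_bags))
      batches <- split(ord, ceiling(seq_along(ord) / hp$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        gsum <- NULL
        bloss <- 0
        for (i in batch) {
          fw <- biamil_forward(params, train_bags[[i]]$features)
          bloss <- bloss + biamil_loss(fw$bag_prob, ys[[i]])
          g <- biamil_backward(params, fw, ys[[i]])
          gsum <- if (is.null(gsum)) g
                  else mapply(`+`, gsum, g, SIMPLIFY = FALSE)
        }
        nb <- length(batch)
        step <- step + 1L
        for (nm in param_names()) {
          grad <- gsum[[nm]] / nb
          m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * grad
          v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * grad^2
          mhat <- m[[nm]] / (1 - beta1^step)
          vhat <- v[[nm]] / (1 - beta2^step)
          params[[nm]] <- params[[nm]] - lr_e * mhat / (sqrt(vhat) + eps)
        }
        epoch_loss <- epoch_loss + bloss
      }
      val_loss <- NA_real_
      if (length(val_bags)) {
        val_loss <- mean(vapply(seq_along(val_bags), function(i) {
          fw <- biamil_forward(params, val_bags[[i]]$features)
          biamil_loss(fw$bag_prob, yv[[i]])
        }, numeric(1)))
      }
      history <- rbind(history,
                       data.frame(epoch = epoch,
                                  train_loss = epoch_loss / length(train_bags),
                                  val_loss = val_loss))
    }
  })
  list(params = params, history = history)
}

param_names <- function() {
  c("We", "be", "Wk_h", "Wq_h", "Wv_h", "Wk_l", "Wq_l", "Wv_l",
    "W_A", "gamma", "mu", "W1", "b1", "W2", "b2")
}

#' Predict bag-level probabilities
#'
#' @param params Trained [biamil_params()].
#' @param bags List of `bag` objects.
#' @param keep_traces Keep the full [biamil_forward()] trace per bag
#'   (needed for attention-based interpretation).
#' @return A `data.frame` with `bag_id`, `slide_id`, `patient_id`, `label`,
#'   `p_pv` (probability of the PV class); when `keep_traces` the traces are
#'   attached as attribute `"traces"`.
#' @export
predict_bags <- function(params, bags, keep_traces = FALSE) {
  traces <- lapply(bags, function(b) biamil_forward(params, b$features))
  out <- data.frame(
    bag_id = vapply(bags, `[[`, "", "bag_id"),
    slide_id = vapply(bags, `[[`, "", "slide_id"),
    patient_id = vapply(bags, `[[`, "", "patient_id"),
    label = vapply(bags, function(b) as.character(b$label), ""),
    p_pv = vapply(traces, function(tr) tr$bag_prob[2], numeric(1)),
    stringsAsFactors = FALSE)
  if (keep_traces) attr(out, "traces") <- traces
  out
}
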