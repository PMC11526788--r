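# Independent oracle implementations used to cross-check the vectorized
# package code. These deliberately use explicit loops / enumeration and no
# package internals.

# Element-by-element attention: alpha[i, j] = sum_c q_i[c] * k_j[c],
# row softmax by explicit exp/sum, A[i, ] = sum_j P[i, j] * v_j.
oracle_head_attention <- function(E, Wk, Wq, Wv) {
  n <- nrow(E); d_k <- nrow(Wk); d_v <- nrow(Wv)
  K <- matrix(0, n, d_k); Q <- matrix(0, n, d_k); V <- matrix(0, n, d_v)
  for (i in seq_len(n)) {
    for (c in seq_len(d_k)) {
      K[i, c] <- sum(Wk[c, ] * E[i, ])
      Q[i, c] <- sum(Wq[c, ] * E[i, ])
    }
    for (c in seq_len(d_v)) V[i, c] <- sum(Wv[c, ] * E[i, ])
  }
  alpha <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n))
    alpha[i, j] <- sum(Q[i, ] * K[j, ])
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    e <- exp(alpha[i, ] - max(alpha[i, ]))
    P[i, ] <- e / sum(e)
  }
  A <- matrix(0, n, d_v)
  for (i in seq_len(n)) for (j in seq_len(n))
    A[i, ] <- A[i, ] + P[i, j] * V[j, ]
  list(alpha = alpha, P = P, A = A)
}

# Loop version of the instance pooling.
oracle_pool <- function(A_h, A_l, W_A) {
  n <- nrow(A_h); d_v <- ncol(A_h)
  s <- numeric(n)
  for (i in seq_len(n))
    s[i] <- sum(c(A_h[i, ], A_l[i, ]) * W_A)
  e <- exp(s - max(s)); w <- e / sum(e)
  f_h <- numeric(d_v); f_l <- numeric(d_v)
  for (i in seq_len(n)) {
    f_h <- f_h + w[i] * A_h[i, ]
    f_l <- f_l + w[i] * A_l[i, ]
  }
  list(instance_weights = w, f_h = f_h, f_l = f_l)
}

# Exhaustive-enumeration two-sided rank-sum p-value (no ties assumed):
# distribution of the Mann-Whitney U over all assignments of the pooled
# values to group A.
oracle_wilcoxon_p <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_stat <- function(ix) {
    ga <- pooled[ix]; gb <- pooled[-ix]
    sum(outer(ga, gb, ">"))
  }
  u_obs <- sum(outer(a, b, ">"))
  us <- utils::combn(m + n, m, u_stat)
  p_lo <- mean(us <= u_obs)
  p_hi <- mean(us >= u_obs)
  min(1, 2 * min(p_lo, p_hi))
}

# Mann-Whitney U via midranks, independent of the package's AUROC.
oracle_auroc_u <- function(y, p) {
  pos <- p[y == 1]; neg <- p[y == 0]
  u <- 0
  for (a in pos) u <- u + sum(a > neg) + 0.5 * sum(a == neg)
  u / (length(pos) * length(neg))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Small random parameter set for forward-pass property tests.
random_params <- function(D, d_k, d_v = D, d_hidden = 4L, seed = 1L) {
  biamil_params(D = D, d_k = d_k, d_v = d_v, d_hidden = d_hidden,
                seed = seed)
}

# A tiny two-class manifest with n_pv + n_wt patients, one or two slides
# each.
toy_manifest <- function(n_pv = 5L, n_wt = 5L, slides_per_patient = 1L) {
  pat <- c(sprintf("pv%02d", seq_len(n_pv)), sprintf("wt%02d", seq_len(n_wt)))
  lab <- c(rep("PV", n_pv), rep("WT", n_wt))
  do.call(rbind, lapply(seq_along(pat), function(i) {
    data.frame(patient_id = pat[i],
               slide_id = sprintf("%s_s%d", pat[i],
                                  seq_len(slides_per_patient)),
               label = lab[i], stringsAsFactors = FALSE)
  }))
}
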