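#' The standard planted-witness MIL benchmark
#'
#' Convenience wrapper around [make_synthetic_bags()] producing the
#' package's standard CPU-scale benchmark: 200 training bags and 100 test
#' bags (balanced classes) of `N = 10` instances in `D = 32` dimensions,
#' witness rate 0.2, shift 2, unit noise. Train and test sets use disjoint
#' seeded streams derived from `seed`.
#'
#' @param seed Integer seed.
#' @param shift Witness shift (set 0 for the null benchmark).
#' @param n_train,n_test Total bag counts (split evenly between classes).
#' @param N,D,witness_rate,noise_sd Passed through.
#' @return List with `train`, `test` (each a [make_synthetic_bags()]
#'   result).
#' @export
mil_benchmark <- function(seed = 1L, shift = 2.0, n_train = 200L,
                          n_test = 100L, N = 10L, D = 32L,
                          witness_rate = 0.2, noise_sd = 1.0) {
  # one signal direction shared by the train and test generators
  u <- with_seed_(seed, {
    u0 <- stats::rnorm(D)
    u0 / sqrt(sum(u0^2))
  })
  list(
    train = make_synthetic_bags(n_bags_pos = n_train %/% 2L,
                                n_bags_neg = n_train - n_train %/% 2L,
                                N = N, D = D, witness_rate = witness_rate,
                                shift = shift, noise_sd = noise_sd,
                                seed = seed, direction = u),
    test = make_synthetic_bags(n_bags_pos = n_test %/% 2L,
                               n_bags_neg = n_test - n_test %/% 2L,
                               N = N, D = D, witness_rate = witness_rate,
                               shift = shift, noise_sd = noise_sd,
                               seed = seed + 10000L, direction = u))
}

#' Run the planted-witness benchmark end to end
#'
#' Trains the attention MIL model on the benchmark's training bags with the
#' default published optimizer settings and returns test-set bag-level
#' AUROC together with the witness-attention recovery rate: the fraction of
#' positive test bags in which the mean attention weight over true witness
#' instances exceeds the mean over background instances.
#'
#' @param seed Integer seed.
#' @param shift Witness shift.
#' @param d_k Key/query width used for the benchmark model; the default
#'   scales with the feature dimension at the same 1:4 ratio as the
#'   full-size model's defaults (`d_k` 256 for `D` 1000).
#' @param ... Passed to [mil_benchmark()].
#' @return List with `auroc`, `witness_recovery`, `fit` (the
#'   [train_biamil()] result), `preds` (test-bag predictions), `bench`.
#' @export
run_mil_benchmark <- function(seed = 1L, shift = 2.0, d_k = NULL, ...) {
  bench <- mil_benchmark(seed = seed, shift = shift, ...)
  if (is.null(d_k))
    d_k <- max(2L, round(ncol(bench$train$bags[[1]]$features) / 4))
  hp <- biamil_hyperparams(d_k = d_k)
  fit <- train_biamil(bench$train$bags, hyperparams = hp, seed = seed)
  preds <- predict_bags(fit$params, bench$test$bags, keep_traces = TRUE)
  traces <- attr(preds, "traces")
  auc <- auroc(preds$label == "PV", preds$p_pv)
  pos <- which(preds$label == "PV")
  recov <- vapply(pos, function(i) {
    wmask <- bench$test$witness[[i]]
    wts <- traces[[i]]$instance_weights
    mean(wts[wmask]) > mean(wts[!wmask])
  }, logical(1))
  list(auroc = auc, witness_recovery = mean(recov), fit = fit,
       preds = preds, bench = bench)
}

#' Bayes-optimal AUROC of the planted-witness bag model
#'
#' For the generator of [make_synthetic_bags()] the likelihood ratio of a
#' bag depends only on the instance projections onto the signal direction:
#' under the positive class exactly `round(witness_rate * N)` of the `N`
#' projections are shifted by `shift`. The optimal bag score is the
#' log-likelihood ratio marginalized over which instances are witnesses;
#' its AUROC -- estimated here by Monte-Carlo simulation -- is the ceiling no
#' trained bag classifier can exceed, and calibrates what benchmark results
#' can be expected.
#'
#' @param N Instances per bag.
#' @param witness_rate,shift,noise_sd Generator parameters.
#' @param n_sim Simulated bags per class.
#' @param seed Integer seed.
#' @return Estimated Bayes AUROC in `[0, 1]`.
#' @export
witness_bayes_auroc <- function(N = 10L, witness_rate = 0.2, shift = 2.0,
                                noise_sd = 1.0, n_sim = 20000L, seed = 1L) {
  k <- max(1L, round(witness_rate * N))
  s <- shift / noise_sd
  subsets <- utils::combn(N, k)
  llr <- function(t) {
    lr_i <- s * t - s^2 / 2
    m <- colSums(matrix(lr_i[subsets], nrow = k))
    mx <- max(m)
    mx + log(mean(exp(m - mx)))
  }
  with_seed_(seed, {
    pos <- vapply(seq_len(n_sim), function(i) {
      t <- stats::rnorm(N)
      t[seq_len(k)] <- t[seq_len(k)] + s
      llr(t)
    }, numeric(1))
    neg <- vapply(seq_len(n_sim), function(i) llr(stats::rnorm(N)),
                  numeric(1))
  })
  auroc(rep(1:0, each = n_sim), c(pos, neg))
}
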