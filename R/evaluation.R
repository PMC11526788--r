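# Bag -> slide aggregation and the slide-level metric suite.

#' Aggregate bag probabilities to a slide probability
#'
#' The slide-level score is the arithmetic mean of its bags' positive-class
#' probabilities.
#'
#' @param bag_probs Non-empty numeric vector of bag probabilities in `[0,1]`.
#' @return A single number in `[0, 1]`.
#' @export
slide_probability <- function(bag_probs) {
  if (!length(bag_probs)) stop("invalid-argument: no bag probabilities",
                               call. = FALSE)
  if (any(bag_probs < 0 | bag_probs > 1))
    stop("bag probabilities must lie in [0, 1]", call. = FALSE)
  mean(bag_probs)
}

#' Collapse bag predictions to slide predictions
#'
#' @param bag_preds Output of [predict_bags()].
#' @return One row per slide: `slide_id`, `label`, `slide_prob`, `n_bags`.
#' @export
aggregate_slides <- function(bag_preds) {
  sp <- split(bag_preds, bag_preds$slide_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    data.frame(slide_id = d$slide_id[1], label = d$label[1],
               slide_prob = slide_probability(d$p_pv), n_bags = nrow(d),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Area under the ROC curve
#'
#' Rank-based AUROC with ties counted one half: the probability that a
#' random positive scores above a random negative, plus half the probability
#' of a tie (equivalently the normalized Mann-Whitney U statistic, or the
#' trapezoidal area under the empirical ROC curve).
#'
#' @param y_true 0/1 (or logical) labels; 1 is the positive class.
#' @param y_prob Numeric scores.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(y_true, y_prob) {
  y_true <- as.integer(y_true)
  n_pos <- sum(y_true == 1L); n_neg <- sum(y_true == 0L)
  if (n_pos == 0L || n_neg == 0L)
    stop("auroc-undefined: both classes must be present", call. = FALSE)
  r <- rank(y_prob, ties.method = "average")
  (sum(r[y_true == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

confusion_metrics <- function(y_true, y_prob, threshold) {
  pred <- as.integer(y_prob >= threshold)
  tp <- sum(pred == 1L & y_true == 1L)
  fp <- sum(pred == 1L & y_true == 0L)
  tn <- sum(pred == 0L & y_true == 0L)
  fn <- sum(pred == 0L & y_true == 1L)
  safe <- function(num, den) if (den == 0) NaN else num / den
  sens <- safe(tp, tp + fn)
  ppv <- safe(tp, tp + fp)
  c(accuracy = safe(tp + tn, tp + fp + tn + fn),
    sensitivity = sens,
    specificity = safe(tn, tn + fp),
    ppv = ppv,
    npv = safe(tn, tn + fn),
    f1 = if (is.nan(sens) || is.nan(ppv) || (sens + ppv) == 0) NaN
         else 2 * sens * ppv / (sens + ppv))
}

#' Slide-level classification metrics with bootstrap confidence intervals
#'
#' Computes AUROC (rank method, ties one half), and accuracy, sensitivity,
#' specificity, PPV, NPV and F1 at the given probability threshold. 95%
#' confidence intervals come from a seeded class-stratified percentile
#' bootstrap over slides. Ratios with a zero denominator are reported as
#' `NaN` and flagged.
#'
#' @param y_true 0/1 (or logical, or factor `WT`/`PV`) slide labels.
#' @param y_prob Slide probabilities.
#' @param threshold Decision threshold on the probability. Default 0.5.
#' @param n_boot Bootstrap replicates. Default 2000.
#' @param conf Confidence level. Default 0.95.
#' @param seed Integer seed for the bootstrap.
#' @return A `metrics_report` list: `metrics` (named vector), `ci`
#'   (matrix with rows `low`/`high`), `threshold`, `n_slides`, `seed`,
#'   `undefined` (names of metrics with zero denominators).
#' @export
compute_metrics <- function(y_true, y_prob, threshold = 0.5, n_boot = 2000L,
                            conf = 0.95, seed = 1L) {
  if (is.factor(y_true) || is.character(y_true))
    y_true <- as.integer(as.character(y_true) == "PV")
  y_true <- as.integer(y_true)
  stopifnot(length(y_true) == length(y_prob))
  point <- c(auroc = auroc(y_true, y_prob),
             confusion_metrics(y_true, y_prob, threshold))
  # resample from class-sorted score vectors so the CIs are invariant to
  # slide ordering as well as reproducible under the seed
  p_pos <- sort(y_prob[y_true == 1L]); p_neg <- sort(y_prob[y_true == 0L])
  boots <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(i) {
      bp <- sample(p_pos, length(p_pos), replace = TRUE)
      bn <- sample(p_neg, length(p_neg), replace = TRUE)
      yb <- c(rep(1L, length(bp)), rep(0L, length(bn)))
      pb <- c(bp, bn)
      c(auroc = auroc(yb, pb), confusion_metrics(yb, pb, threshold))
    }, numeric(7))
  })
  a <- (1 - conf) / 2
  ci <- apply(boots, 1L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
              names = FALSE)
  rownames(ci) <- c("low", "high")
  structure(list(metrics = point, ci = ci, threshold = threshold,
                 n_slides = length(y_true), seed = as.integer(seed),
                 undefined = names(point)[is.nan(point)]),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("Slide-level metrics (n = %d, threshold = %.2f)\n",
              x$n_slides, x$threshold))
  for (nm in names(x$metrics))
    cat(sprintf("  %-12s %.3f  [%.3f, %.3f]\n", nm, x$metrics[nm],
                x$ci["low", nm], x$ci["high", nm]))
  if (length(x$undefined))
    cat("  undefined (zero denominator):",
        paste(x$undefined, collapse = ", "), "\n")
  invisible(x)
}
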