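# Pluggable tile-level feature extraction and tumor/non-tumor tile calls.
#
# The pipeline treats the backbone (in production a pretrained convolutional
# network with a 1000-dimensional output) as a plug-in: any function mapping
# an RGB tile to a fixed-length numeric vector qualifies. The package ships
# two small deterministic extractors so every downstream stage is testable
# without network weights.

#' Extract a feature matrix from a list of tiles
#'
#' Applies `extractor` to each tile image and stacks the results row-wise.
#' The extractor must return a numeric vector of the same length for every
#' tile; a mismatch is a contract violation.
#'
#' @param tiles List of H x W x 3 RGB arrays (0--255 scale).
#' @param extractor Function: tile image -> numeric D-vector.
#' @param extractor_id Identifier stored alongside the matrix.
#' @return A numeric `N x D` matrix with attributes `extractor_id`.
#' @export
extract_features <- function(tiles, extractor, extractor_id = "custom") {
  if (!length(tiles)) stop("no tiles supplied", call. = FALSE)
  rows <- lapply(tiles, function(t) {
    v <- as.numeric(extractor(t))
    if (!all(is.finite(v)))
      stop("contract-violation: extractor returned non-finite values",
           call. = FALSE)
    v
  })
  d <- unique(lengths(rows))
  if (length(d) != 1L)
    stop("contract-violation: extractor output dimension varies across tiles",
         call. = FALSE)
  out <- do.call(rbind, rows)
  attr(out, "extractor_id") <- extractor_id
  out
}

#' Deterministic test extractors
#'
#' `zero_extractor(d)` returns a constant-zero D-vector for any tile;
#' `histogram_extractor(d)` returns per-channel intensity histograms plus
#' channel means/variances, zero-padded or truncated to exactly `d` values.
#' Both are pure functions of the pixel bytes, so repeated calls on the same
#' tile are bit-identical.
#'
#' @param d Output dimensionality (default 1000, the conventional backbone
#'   output width).
#' @return A function suitable for [extract_features()].
#' @export
zero_extractor <- function(d = 1000L) {
  force(d)
  function(tile) numeric(d)
}

#' @rdname zero_extractor
#' @export
histogram_extractor <- function(d = 1000L) {
  force(d)
  n_bins <- max(1L, (d - 6L) %/% 3L)
  breaks <- seq(0, 255, length.out = n_bins + 1L)
  function(tile) {
    stopifnot_image(tile)
    v <- unlist(lapply(1:3, function(ch) {
      x <- pmin(pmax(as.vector(tile[, , ch]), 0), 255)
      tabulate(findInterval(x, breaks, rightmost.closed = TRUE),
               nbins = n_bins) / length(x)
    }))
    v <- c(v, vapply(1:3, function(ch) mean(tile[, , ch]) / 255, 0),
           vapply(1:3, function(ch) stats::var(as.vector(tile[, , ch])) / 255^2,
                  0))
    length(v) <- d
    v[is.na(v)] <- 0
    v
  }
}

#' Classify tiles as tumor or non-tumor
#'
#' Applies a probabilistic tile classifier and thresholds the tumor
#' probability; the call is `tumor` when `p_tumor >= threshold`. Downstream
#' bag construction consumes only tumor-called tiles.
#'
#' @param tiles List of RGB tile arrays.
#' @param classifier Function: tile image -> probability of tumor in `[0,1]`.
#' @param threshold Decision threshold. Default 0.5 (ties call tumor).
#' @return A `data.frame` with columns `tile` (index), `p_tumor`, `call`.
#' @export
classify_tumor_tiles <- function(tiles, classifier, threshold = 0.5) {
  p <- vapply(tiles, function(t) as.numeric(classifier(t)), numeric(1))
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("contract-violation: classifier probability outside [0, 1]",
         call. = FALSE)
  data.frame(tile = seq_along(tiles), p_tumor = p,
             call = ifelse(p >= threshold, "tumor", "non-tumor"),
             stringsAsFactors = FALSE)
}

#' Rule-based tumor-tile classifier stand-in
#'
#' Scores a tile by the fraction of "purple" pixels -- pixels where blue and
#' red both exceed green by a margin, the signature of hematoxylin-dense
#' (nuclear, tumor-cell-rich) regions -- and maps that fraction `f` to the
#' probability `f / (f + purple_frac)`, which crosses 0.5 exactly at
#' `purple_frac`, so the default call is tumor iff more than 30% of the
#' pixels are purple. Intended as a deterministic test double for a trained
#' segmentation network on synthetic slides with known blob colors.
#'
#' @param purple_frac Purple-pixel fraction at which the tumor probability
#'   crosses 0.5. Default 0.3.
#' @param margin Minimum excess of R and B over G (0--255 scale) for a pixel
#'   to count as purple. Default 20.
#' @return A classifier function for [classify_tumor_tiles()].
#' @export
purple_fraction_classifier <- function(purple_frac = 0.3, margin = 20) {
  function(tile) {
    stopifnot_image(tile)
    purple <- (tile[, , 1] > tile[, , 2] + margin) &
      (tile[, , 3] > tile[, , 2] + margin)
    f <- mean(purple)
    f / (f + purple_frac)
  }
}
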