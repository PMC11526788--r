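# Internal helpers shared across modules.

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All user-facing randomness goes through this.
with_seed_ <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

stopifnot_image <- function(img, arg = "tile_image") {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop(sprintf("`%s` must be an H x W x 3 RGB array", arg), call. = FALSE)
  if (dim(img)[1] < 1L || dim(img)[2] < 1L)
    stop(sprintf("`%s` must be non-empty", arg), call. = FALSE)
  invisible(TRUE)
}

# Numerically stable softmax along a vector.
softmax_vec <- function(x) {
  m <- max(x)
  e <- exp(x - m)
  e / sum(e)
}

# Row-wise stable softmax of a matrix.
softmax_rows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}
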