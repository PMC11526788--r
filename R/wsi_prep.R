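#' Enumerate a tile grid over a slide
#'
#' Enumerates square tile windows over a `width` x `height` image in row-major
#' order. A window is emitted only if it lies fully inside the image: there is
#' no padding and no clamping at the right/bottom edges, matching the common
#' whole-slide tiling convention of fixed-size overlapping patches. With the
#' defaults (512-pixel tiles, 50% overlap) the stride is 256 pixels and the
#' number of tiles per axis is `floor((dim - tile) / stride) + 1` whenever the
#' axis is at least one tile long.
#'
#' @param width,height Slide dimensions in pixels (positive integers).
#' @param tile Tile side length in pixels. Default 512.
#' @param overlap_frac Fractional overlap between neighbouring tiles in
#'   `[0, 1)`. Default 0.5 (half-tile stride).
#' @param slide_id Identifier copied into every row of the result.
#' @return A `data.frame` (one row per tile) with columns `slide_id`, `col`,
#'   `row` (0-based grid indices), `x0`, `y0` (0-based top-left pixel),
#'   `width`, `height`, and placeholder columns `background_fraction` (`NA`)
#'   and `kept` (`NA`) to be filled by [score_tile_background()] /
#'   [filter_tiles()].
#' @examples
#' nrow(tile_grid(1024, 1024))          # 9 tiles
#' tile_grid(700, 512)$x0               # only x0 = 0 fits
#' @export
tile_grid <- function(width, height, tile = 512L, overlap_frac = 0.5,
                      slide_id = "slide") {
  if (length(width) != 1L || length(height) != 1L ||
      !is.finite(width) || !is.finite(height) || width < 1 || height < 1)
    stop("`width` and `height` must be positive", call. = FALSE)
  if (overlap_frac < 0 || overlap_frac >= 1)
    stop("`overlap_frac` must lie in [0, 1)", call. = FALSE)
  stride <- round(tile * (1 - overlap_frac))
  if (stride < 1) stop("stride rounds to zero; decrease `overlap_frac`",
                       call. = FALSE)
  n_x <- if (width >= tile) floor((width - tile) / stride) + 1L else 0L
  n_y <- if (height >= tile) floor((height - tile) / stride) + 1L else 0L
  if (n_x == 0L || n_y == 0L) {
    return(data.frame(slide_id = character(), col = integer(), row = integer(),
                      x0 = integer(), y0 = integer(), width = integer(),
                      height = integer(), background_fraction = numeric(),
                      kept = logical(), stringsAsFactors = FALSE))
  }
  # row-major: all columns of row 0 first
  grid <- expand.grid(col = seq_len(n_x) - 1L, row = seq_len(n_y) - 1L)
  grid <- grid[order(grid$row, grid$col), , drop = FALSE]
  data.frame(slide_id = slide_id,
             col = grid$col, row = grid$row,
             x0 = grid$col * stride, y0 = grid$row * stride,
             width = as.integer(tile), height = as.integer(tile),
             background_fraction = NA_real_, kept = NA,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Fraction of background pixels in a tile
#'
#' A pixel is called background when it is either near-white
#' (`min(R, G, B) >= 220` on the 0--255 scale) or essentially unsaturated
#' (HSV saturation `<= 0.05`), the standard brightness/saturation rule for
#' H&E tissue detection. Tiles with more than 75% background are discarded
#' downstream (see [filter_tiles()]).
#'
#' @param tile_image Numeric H x W x 3 RGB array on the 0--255 scale.
#' @param white_level Brightness threshold for the near-white rule.
#' @param sat_threshold Saturation threshold for the grey/unsaturated rule.
#' @return A single number in `[0, 1]`.
#' @export
background_fraction <- function(tile_image, white_level = 220,
                                sat_threshold = 0.05) {
  stopifnot_image(tile_image)
  r <- tile_image[, , 1]; g <- tile_image[, , 2]; b <- tile_image[, , 3]
  mn <- pmin(r, g, b)
  mx <- pmax(r, g, b)
  sat <- ifelse(mx > 0, 1 - mn / mx, 0)
  mean(mn >= white_level | sat <= sat_threshold)
}

#' Score tiles for background content
#'
#' Fills the `background_fraction` and `kept` columns of a tile manifest by
#' cropping each tile out of the slide image and applying
#' [background_fraction()]. A tile is kept iff its background fraction is at
#' most `bg_threshold` (strictly more background than the threshold discards).
#'
#' @param tiles Tile manifest from [tile_grid()].
#' @param slide_image Numeric H x W x 3 array, 0--255 scale.
#' @param bg_threshold Maximum tolerated background fraction. Default 0.75.
#' @return The manifest with `background_fraction` and `kept` populated.
#' @export
score_tile_background <- function(tiles, slide_image, bg_threshold = 0.75) {
  stopifnot_image(slide_image, "slide_image")
  h <- dim(slide_image)[1]; w <- dim(slide_image)[2]
  frac <- vapply(seq_len(nrow(tiles)), function(i) {
    t <- tiles[i, ]
    if (t$x0 + t$width > w || t$y0 + t$height > h)
      stop("tile overruns slide bounds", call. = FALSE)
    sub <- slide_image[(t$y0 + 1):(t$y0 + t$height),
                       (t$x0 + 1):(t$x0 + t$width), , drop = FALSE]
    background_fraction(sub)
  }, numeric(1))
  tiles$background_fraction <- frac
  tiles$kept <- frac <= bg_threshold
  tiles
}

#' Discard high-background tiles
#'
#' Keeps tiles whose background fraction does not exceed the threshold;
#' equality keeps (the discard rule is strictly "more than" the threshold).
#'
#' @param tiles Tile manifest with `background_fraction` populated.
#' @param bg_threshold Maximum tolerated background fraction. Default 0.75.
#' @return The kept subset of the manifest, with `kept = TRUE`.
#' @export
filter_tiles <- function(tiles, bg_threshold = 0.75) {
  if (any(is.na(tiles$background_fraction)))
    stop("`background_fraction` must be populated before filtering",
         call. = FALSE)
  tiles$kept <- tiles$background_fraction <= bg_threshold
  tiles[tiles$kept, , drop = FALSE]
}

# ---- stain normalization (SPCN, Vahadane-style sparse NMF) ------------------

#' Convert RGB intensities to optical density
#'
#' `OD = -log((I + 1) / 256)` for intensities `I` on the 0--255 scale; white
#' maps to (approximately) zero absorbance.
#' @param img Numeric array or vector of intensities, 0--255.
#' @return Same shape, optical-density units.
#' @export
rgb_to_od <- function(img) -log((img + 1) / 256)

#' Convert optical density back to RGB
#' @param od Optical-density values.
#' @return Intensities clipped to the 0--255 range.
#' @export
od_to_rgb <- function(od) pmin(pmax(256 * exp(-od) - 1, 0), 255)

#' Estimate a two-stain basis from a tile (structure-preserving normalization)
#'
#' Fits a 2-column non-negative sparse dictionary to the tile's
#' optical-density pixels: `OD ~ S %*% C` with unit-norm non-negative stain
#' vectors `S` (3 x 2) and non-negative sparse concentrations `C`, by seeded
#' multiplicative updates with an L1 penalty on `C`. Columns are ordered so
#' that column 1 is hematoxylin (larger blue-channel optical density than
#' eosin). The per-stain concentration scale is the 99th percentile of the
#' fitted concentrations, used by [normalize_color()] to equalize stain
#' intensity between images.
#'
#' @param tile_image Numeric H x W x 3 RGB array, 0--255 scale.
#' @param sparsity L1 weight on the concentration matrix. Default 0.1.
#' @param od_floor Pixels whose maximum channel OD falls below this floor are
#'   treated as background and excluded from the fit. Default 0.15.
#' @param max_pixels Random subsample cap on the pixels used for fitting.
#' @param n_iter Multiplicative-update iterations.
#' @param seed Seed for the pixel subsample and dictionary initialization.
#' @return An object of class `stain_basis`: list with `stain_vectors`
#'   (3 x 2, unit-norm columns, hematoxylin first) and `concentration_scale`
#'   (length-2 positive vector).
#' @export
estimate_stain_basis <- function(tile_image, sparsity = 0.1, od_floor = 0.15,
                                 max_pixels = 5000L, n_iter = 500L, seed = 1L) {
  stopifnot_image(tile_image)
  od <- rgb_to_od(tile_image)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  tissue <- apply(odm, 2L, max) >= od_floor
  if (mean(tissue) < 0.01)
    stop("stain-estimation-failure: fewer than 1% tissue pixels above the ",
         "optical-density floor", call. = FALSE)
  y <- odm[, tissue, drop = FALSE]
  with_seed_(seed, {
    if (ncol(y) > max_pixels)
      y <- y[, sample.int(ncol(y), max_pixels), drop = FALSE]
    s <- matrix(stats::runif(6, 0.1, 1), 3, 2)
    s <- sweep(s, 2L, sqrt(colSums(s^2)), "/")
    cc <- matrix(stats::runif(2 * ncol(y), 0, 1), 2, ncol(y))
    eps <- 1e-12
    for (it in seq_len(n_iter)) {
      cc <- cc * (crossprod(s, y)) / (crossprod(s) %*% cc + sparsity + eps)
      s <- s * (y %*% t(cc)) / (s %*% tcrossprod(cc) + eps)
      nrm <- sqrt(colSums(s^2))
      nrm[nrm < eps] <- eps
      s <- sweep(s, 2L, nrm, "/")
      cc <- cc * nrm
    }
  })
  # hematoxylin = column with larger blue-channel OD
  if (s[3, 1] < s[3, 2]) {
    s <- s[, 2:1, drop = FALSE]
    cc <- cc[2:1, , drop = FALSE]
  }
  scale99 <- apply(cc, 1L, stats::quantile, probs = 0.99, names = FALSE)
  scale99[scale99 <= 0] <- 1e-6
  structure(list(stain_vectors = s, concentration_scale = scale99),
            class = "stain_basis")
}

# Non-negative least squares of a 3 x M OD matrix onto a 3 x 2 stain basis.
# The 2-variable case is solved in closed form: unconstrained LS, then each
# negative coordinate clamped to zero with the other refit.
project_concentrations <- function(odm, s) {
  g <- crossprod(s)              # 2 x 2 Gram
  b <- crossprod(s, odm)         # 2 x M
  det <- g[1, 1] * g[2, 2] - g[1, 2]^2
  c1 <- (g[2, 2] * b[1, ] - g[1, 2] * b[2, ]) / det
  c2 <- (g[1, 1] * b[2, ] - g[1, 2] * b[1, ]) / det
  neg1 <- c1 < 0; neg2 <- c2 < 0
  c1[neg1] <- 0
  c2[neg1] <- pmax(b[2, neg1] / g[2, 2], 0)
  c2[neg2 & !neg1] <- 0
  c1[neg2 & !neg1] <- pmax(b[1, neg2 & !neg1] / g[1, 1], 0)
  rbind(c1, c2)
}

#' Normalize a tile's color to a target stain basis
#'
#' Decomposes the tile into per-pixel stain concentrations under its `source`
#' basis, rescales each stain channel by the ratio of target to source
#' concentration scales, and recombines with the target stain vectors,
#' preserving tissue structure while matching the target's color statistics.
#'
#' @param tile_image Numeric H x W x 3 RGB array, 0--255 scale.
#' @param source [estimate_stain_basis()] result for this tile (or its slide).
#' @param target Reference basis all tiles are normalized towards.
#' @return RGB array of the same shape, 0--255 scale.
#' @export
normalize_color <- function(tile_image, source, target) {
  stopifnot_image(tile_image)
  stopifnot(inherits(source, "stain_basis"), inherits(target, "stain_basis"))
  d <- dim(tile_image)
  od <- rgb_to_od(tile_image)
  odm <- rbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  conc <- project_concentrations(odm, source$stain_vectors)
  conc <- conc * (target$concentration_scale / source$concentration_scale)
  od_new <- target$stain_vectors %*% conc
  out <- array(0, d)
  for (ch in 1:3) out[, , ch] <- matrix(od_to_rgb(od_new[ch, ]), d[1], d[2])
  out
}

# ---- augmentation -----------------------------------------------------------

#' Default augmentation configuration
#'
#' Flip/rotation probabilities and jitter ranges used by [augment_tile()].
#' With all probabilities zero and unit/zero jitter ranges the augmentation
#' is the identity.
#'
#' @param p_flip_h,p_flip_v Probabilities of horizontal/vertical flips.
#' @param p_rotate Probability of a rotation by a random multiple of 90
#'   degrees (size-preserving).
#' @param crop_scale Two-vector: range of the area fraction of a random crop,
#'   which is resized back to the tile size. `c(1, 1)` disables cropping.
#' @param brightness,contrast,saturation Two-vectors: multiplicative jitter
#'   ranges; `c(1, 1)` disables.
#' @param hue Two-vector: additive hue-shift range (fraction of the hue
#'   circle); `c(0, 0)` disables.
#' @return A list of class `augment_config`.
#' @export
augment_config <- function(p_flip_h = 0.5, p_flip_v = 0.5, p_rotate = 0.5,
                           crop_scale = c(0.8, 1),
                           brightness = c(0.9, 1.1), contrast = c(0.9, 1.1),
                           saturation = c(0.9, 1.1), hue = c(-0.05, 0.05)) {
  structure(list(p_flip_h = p_flip_h, p_flip_v = p_flip_v,
                 p_rotate = p_rotate, crop_scale = crop_scale,
                 brightness = brightness, contrast = contrast,
                 saturation = saturation, hue = hue),
            class = "augment_config")
}

# vectorized HSV -> RGB on the 0..1 scale (h in [0,1))
hsv_to_rgb_mat <- function(h, s, v) {
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - f * s); t <- v * (1 - (1 - f) * s)
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

rgb_to_hsv_mat <- function(r, g, b) {
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  nz <- d > 0
  hr <- nz & mx == r; hg <- nz & !hr & mx == g; hb <- nz & !hr & !hg
  h[hr] <- ((g[hr] - b[hr]) / d[hr]) / 6
  h[hg] <- (2 + (b[hg] - r[hg]) / d[hg]) / 6
  h[hb] <- (4 + (r[hb] - g[hb]) / d[hb]) / 6
  h <- h %% 1
  s <- ifelse(mx > 0, d / mx, 0)
  list(h = h, s = s, v = mx)
}

#' Seeded tile augmentation
#'
#' Applies random flips, 90-degree rotations, random crop-and-resize, and
#' brightness/contrast/saturation/hue jitter, all drawn from a seeded RNG so
#' that the same `(tile, seed, config)` triple always yields a bit-identical
#' output. The output is re-standardized to the input size.
#'
#' @param tile_image Numeric H x W x 3 RGB array, 0--255 scale.
#' @param seed Integer seed driving all random draws.
#' @param config An [augment_config()].
#' @return Augmented RGB array, same shape and scale as the input.
#' @export
augment_tile <- function(tile_image, seed, config = augment_config()) {
  stopifnot_image(tile_image)
  h0 <- dim(tile_image)[1]; w0 <- dim(tile_image)[2]
  img <- tile_image
  with_seed_(seed, {
    if (stats::runif(1) < config$p_flip_h)
      img <- img[, w0:1, , drop = FALSE]
    if (stats::runif(1) < config$p_flip_v)
      img <- img[h0:1, , , drop = FALSE]
    if (stats::runif(1) < config$p_rotate) {
      k <- sample(1:3, 1L)
      for (i in seq_len(k)) img <- aperm(img, c(2, 1, 3))[dim(img)[2]:1, , ,
                                                          drop = FALSE]
    }
    scale <- stats::runif(1, config$crop_scale[1], config$crop_scale[2])
    if (scale < 1) {
      ch <- max(1L, round(dim(img)[1] * sqrt(scale)))
      cw <- max(1L, round(dim(img)[2] * sqrt(scale)))
      y0 <- sample.int(dim(img)[1] - ch + 1L, 1L)
      x0 <- sample.int(dim(img)[2] - cw + 1L, 1L)
      img <- img[y0:(y0 + ch - 1L), x0:(x0 + cw - 1L), , drop = FALSE]
    }
    if (dim(img)[1] != h0 || dim(img)[2] != w0)
      img <- resize_bilinear(img, h0, w0)
    br <- stats::runif(1, config$brightness[1], config$brightness[2])
    ct <- stats::runif(1, config$contrast[1], config$contrast[2])
    if (br != 1) img <- img * br
    if (ct != 1) img <- (img - mean(img)) * ct + mean(img)
    st <- stats::runif(1, config$saturation[1], config$saturation[2])
    hu <- stats::runif(1, config$hue[1], config$hue[2])
    if (st != 1 || hu != 0) {
      hsv <- rgb_to_hsv_mat(img[, , 1] / 255, img[, , 2] / 255,
                            img[, , 3] / 255)
      rgb <- hsv_to_rgb_mat(hsv$h + hu, pmin(pmax(hsv$s * st, 0), 1),
                            pmin(pmax(hsv$v, 0), 1))
      img[, , 1] <- rgb$r * 255; img[, , 2] <- rgb$g * 255
      img[, , 3] <- rgb$b * 255
    }
  })
  pmin(pmax(img, 0), 255)
}

# Bilinear resize of an H x W x 3 array via EBImage.
resize_bilinear <- function(img, out_h, out_w) {
  eb <- EBImage::Image(aperm(img / 255, c(2, 1, 3)), colormode = "Color")
  out <- EBImage::resize(eb, w = out_w, h = out_h)
  aperm(EBImage::imageData(out), c(2, 1, 3)) * 255
}
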