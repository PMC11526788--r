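test_that("tile grid enumerates exactly the fully contained windows", {
  g1 <- tile_grid(512, 512)
  expect_equal(nrow(g1), 1L)
  expect_equal(c(g1$x0, g1$y0), c(0L, 0L))

  g9 <- tile_grid(1024, 1024)
  expect_equal(nrow(g9), 9L)
  expect_setequal(unique(g9$x0), c(0L, 256L, 512L))
  expect_setequal(unique(g9$y0), c(0L, 256L, 512L))
  # row-major: first three tiles share row 0
  expect_equal(g9$row[1:3], c(0L, 0L, 0L))
  expect_equal(g9$col[1:3], c(0L, 1L, 2L))

  # x0 = 256 would overrun a 700-px axis (256 + 512 > 700)
  g <- tile_grid(700, 512)
  expect_equal(nrow(g), 1L)

  expect_equal(nrow(tile_grid(511, 2048)), 0L)
  expect_error(tile_grid(0, 100), "positive")
})

test_that("tile counts follow the closed form on random slide sizes", {
  withr::with_seed(101, {
    for (i in 1:50) {
      w <- sample(1:3000, 1); h <- sample(1:3000, 1)
      g <- tile_grid(w, h, tile = 512, overlap_frac = 0.5)
      nx <- if (w >= 512) floor((w - 512) / 256) + 1 else 0
      ny <- if (h >= 512) floor((h - 512) / 256) + 1 else 0
      expect_equal(nrow(g), nx * ny)
      if (nrow(g)) {
        expect_true(all(g$x0 + g$width <= w))
        expect_true(all(g$y0 + g$height <= h))
      }
    }
  })
})

test_that("background fraction implements the brightness/saturation rule", {
  white <- array(255, c(8, 8, 3))
  expect_equal(background_fraction(white), 1)
  purple <- array(0, c(8, 8, 3))
  purple[, , 1] <- 120; purple[, , 2] <- 60; purple[, , 3] <- 140
  expect_equal(background_fraction(purple), 0)
  half <- purple
  half[1:4, , ] <- 255
  expect_equal(background_fraction(half), 0.5)
  # mid-grey is unsaturated background even though it is not near-white
  grey <- array(128, c(4, 4, 3))
  expect_equal(background_fraction(grey), 1)
  expect_error(background_fraction(matrix(0, 3, 3)), "RGB")
})

test_that("the 75% rule keeps at the boundary and discards strictly above", {
  tiles <- tile_grid(2048, 512)
  tiles <- tiles[1:4, ]
  tiles$background_fraction <- c(0.0, 0.5, 0.76, 1.0)
  kept <- filter_tiles(tiles)
  expect_equal(nrow(kept), 2L)
  expect_true(all(kept$background_fraction <= 0.75))

  tiles$background_fraction <- c(0.75, 0.76, 0.80, 0.7499)
  kept <- filter_tiles(tiles)
  expect_equal(sort(kept$background_fraction), c(0.7499, 0.75))
})

test_that("stain basis recovery matches the generating vectors", {
  si <- make_synthetic_stain_image(seed = 3)
  sb <- estimate_stain_basis(si$image, seed = 1)
  expect_s3_class(sb, "stain_basis")
  expect_equal(colSums(sb$stain_vectors^2), c(1, 1), tolerance = 1e-8)
  expect_true(all(sb$stain_vectors >= 0))
  expect_true(all(sb$concentration_scale > 0))
  expect_gt(cosine_sim(sb$stain_vectors[, 1], si$stain_vectors[, 1]), 0.99)
  expect_gt(cosine_sim(sb$stain_vectors[, 2], si$stain_vectors[, 2]), 0.99)
})

test_that("stain estimation fails cleanly without tissue pixels", {
  white <- array(255, c(16, 16, 3))
  expect_error(estimate_stain_basis(white), "stain-estimation-failure")
})

test_that("a single pure stain yields a dominant parallel column", {
  s <- c(0.65, 0.70, 0.29); s <- s / sqrt(sum(s^2))
  conc <- withr::with_seed(5, stats::runif(400, 0.5, 1.5))
  od <- outer(s, conc)
  img <- array(0, c(20, 20, 3))
  for (ch in 1:3) img[, , ch] <- matrix(od_to_rgb(od[ch, ]), 20, 20)
  sb <- estimate_stain_basis(img, seed = 2)
  dom <- which.max(sb$concentration_scale)
  expect_gt(cosine_sim(sb$stain_vectors[, dom], s), 0.99)
})

test_that("normalization to the source basis is the identity up to quantization", {
  si <- make_synthetic_stain_image(seed = 3)
  sb <- estimate_stain_basis(si$image, seed = 1)
  out <- normalize_color(si$image, sb, sb)
  expect_equal(dim(out), dim(si$image))
  expect_lt(mean(abs(out - si$image)), 2)
  # white stays white: OD ~ 0 implies zero concentrations
  white <- array(255, c(8, 8, 3))
  wout <- normalize_color(white, sb, sb)
  expect_lt(mean(abs(wout - 255)), 2)
})

test_that("same concentrations under different bases collapse after normalization", {
  si1 <- make_synthetic_stain_image(seed = 3)
  s2 <- cbind(c(0.5, 0.75, 0.45), c(0.2, 0.9, 0.2))
  s2 <- sweep(s2, 2, sqrt(colSums(s2^2)), "/")
  si2 <- make_synthetic_stain_image(stain_vectors = s2, seed = 3)
  b1 <- estimate_stain_basis(si1$image, seed = 1)
  b2 <- estimate_stain_basis(si2$image, seed = 1)
  n1 <- normalize_color(si1$image, b1, b1)
  n2 <- normalize_color(si2$image, b2, b1)
  expect_lt(mean(abs(n1 - n2)), 2)
})

test_that("normalization is idempotent to within quantization", {
  si <- make_synthetic_stain_image(seed = 7)
  src <- estimate_stain_basis(si$image, seed = 1)
  tgt <- estimate_stain_basis(make_synthetic_stain_image(seed = 8)$image,
                              seed = 1)
  once <- normalize_color(si$image, src, tgt)
  src2 <- estimate_stain_basis(once, seed = 1)
  twice <- normalize_color(once, src2, tgt)
  expect_lt(mean(abs(twice - once)), 2)
})

test_that("augmentation is seeded, identity-able, and involutive for flips", {
  img <- withr::with_seed(4, array(runif(24 * 24 * 3, 0, 255), c(24, 24, 3)))
  ident <- augment_config(p_flip_h = 0, p_flip_v = 0, p_rotate = 0,
                          crop_scale = c(1, 1), brightness = c(1, 1),
                          contrast = c(1, 1), saturation = c(1, 1),
                          hue = c(0, 0))
  expect_equal(augment_tile(img, seed = 9, config = ident), img)

  cfg <- augment_config()
  a1 <- augment_tile(img, seed = 5, config = cfg)
  a2 <- augment_tile(img, seed = 5, config = cfg)
  expect_identical(a1, a2)
  expect_equal(dim(a1), dim(img))

  fliponly <- augment_config(p_flip_h = 1, p_flip_v = 0, p_rotate = 0,
                             crop_scale = c(1, 1), brightness = c(1, 1),
                             contrast = c(1, 1), saturation = c(1, 1),
                             hue = c(0, 0))
  f1 <- augment_tile(img, seed = 1, config = fliponly)
  expect_equal(f1, img[, 24:1, , drop = FALSE])
  expect_equal(augment_tile(f1, seed = 2, config = fliponly), img)
})
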