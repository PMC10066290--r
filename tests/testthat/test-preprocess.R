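ecfg <- enhance_config()

test_that("brightness transform: identity at ratio 1, black fixed, hand value", {
  img <- fixture_image()
  expect_equal(brightness_transform(img, 1), img, tolerance = 1e-12)
  zero <- array(0, dim = c(4, 4, 3))
  expect_identical(brightness_transform(zero, 7), zero)
  # single-pixel hand evaluation of the BTF at k = 2
  half <- array(0.5, dim = c(2, 2, 3))
  ka <- 2^ecfg$a
  expected <- exp(ecfg$b * (1 - ka)) * 0.5^ka
  expect_equal(brightness_transform(half, 2)[1, 1, 1], expected, tolerance = 1e-12)
  expect_error(brightness_transform(img, 0), class = "fangmark_btf")
  expect_error(brightness_transform(img, -2), class = "fangmark_btf")
})

test_that("brightness transform is monotone non-decreasing in intensity", {
  set.seed(1)
  for (k in c(1.3, 2, 5)) {
    v <- sort(runif(50))
    img <- array(rep(v, 3), dim = c(5, 10, 3))
    out <- brightness_transform(img, k)
    expect_true(all(diff(as.vector(out[, , 1])) >= -1e-12))  # v was sorted
    expect_true(all(out >= 0 & out <= 1))
  }
})

test_that("weight map is the illumination estimate to the mu power", {
  white <- array(1, dim = c(3, 3, 3))
  expect_equal(estimate_weight_map(white, 0.5), matrix(1, 3, 3))
  black <- array(0, dim = c(3, 3, 3))
  expect_equal(estimate_weight_map(black, 0.5), matrix(0, 3, 3))
  px <- array(c(0.25, 0.16, 0.04), dim = c(1, 1, 3))
  expect_equal(estimate_weight_map(px, 0.5)[1, 1], 0.5)  # max 0.25, sqrt
})

test_that("exposure-ratio search follows the entropy rule on the grid", {
  # no under-exposed pixels -> smallest ratio (degenerate convention)
  bright <- array(0.9, dim = c(8, 8, 3))
  expect_identical(find_exposure_ratio(bright, ecfg), ecfg$grid[1])
  # single-candidate grid is forced
  one <- enhance_config(grid = 4)
  expect_identical(find_exposure_ratio(fixture_image() * 0.2, one), 4)
  expect_error(enhance_config(grid = numeric()), class = "fangmark_config")
  # half-black / half-gray fixture: brute-force the 3 candidates independently
  img <- array(0, dim = c(10, 10, 3))
  img[6:10, , ] <- 0.18
  grid <- c(1.5, 3, 6)
  w <- estimate_weight_map(img, ecfg$mu)
  under <- w < 0.5
  ent <- vapply(grid, function(k) {
    v <- fangmark:::to_gray(brightness_transform(img, k, ecfg))[under]
    h <- tabulate(pmin(64, floor(v * 64) + 1), nbins = 64)
    p <- h[h > 0] / sum(h)
    -sum(p * log2(p))
  }, numeric(1))
  expect_identical(find_exposure_ratio(img, enhance_config(grid = grid)),
                   grid[which.max(ent)])
})

test_that("fusion is the per-pixel weighted sum of the exposure set", {
  img <- fixture_image()
  ones <- matrix(1, nrow(img), ncol(img))
  expect_equal(fuse_exposures(exposure_set(list(img), list(ones), 1)), img)
  halves <- ones / 2
  expect_equal(fuse_exposures(exposure_set(list(img, img), list(halves, halves), c(1, 2))),
               img, tolerance = 1e-12)
  # hand arithmetic at one pixel: 0.25 * 0.2 + 0.75 * 0.6 = 0.5
  p1 <- array(0.2, dim = c(1, 1, 3)); p2 <- array(0.6, dim = c(1, 1, 3))
  es <- exposure_set(list(p1, p2), list(matrix(0.25), matrix(0.75)), c(1, 2))
  expect_equal(fuse_exposures(es)[1, 1, 1], 0.5)
  # contract violations
  expect_error(exposure_set(list(p1, fixture_image()), list(matrix(0.5), matrix(0.5)), c(1, 2)),
               class = "fangmark_fusion")
  expect_error(exposure_set(list(p1, p2), list(matrix(0.3), matrix(0.3)), c(1, 2)),
               class = "fangmark_fusion")
})

test_that("fusion is linear in the images for fixed weights", {
  set.seed(2)
  w <- matrix(runif(36), 6, 6); w2 <- 1 - w
  mk <- function() array(runif(6 * 6 * 3, 0, 0.5), dim = c(6, 6, 3))
  p <- mk(); q <- mk(); r <- mk(); s <- mk()
  a <- 0.3; b <- 0.7
  lhs <- fuse_exposures(exposure_set(list(a * p + b * q, a * r + b * s),
                                     list(w, w2), c(1, 2)))
  rhs <- a * fuse_exposures(exposure_set(list(p, r), list(w, w2), c(1, 2))) +
         b * fuse_exposures(exposure_set(list(q, s), list(w, w2), c(1, 2)))
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("enhance lifts dark images, passes through bright ones, saturates", {
  # well-exposed: fusion weight of the synthetic exposure ~ 0
  bright <- clamp_fixture <- fixture_image() * 0 + 0.95
  expect_lt(max(abs(enhance(bright, ecfg) - bright)), 0.02)
  # darkened synthetic fixture: mean intensity strictly increases
  dark <- generate_bite_image("cobra", generator_config(size = 64), 11)$pixels * 0.3
  out <- enhance(dark, ecfg)
  expect_gt(mean(out), mean(dark))
  # under-exposed regions do not get darker
  w <- estimate_weight_map(dark, ecfg$mu)
  under <- w < 0.5
  expect_gte(mean(fangmark:::to_gray(out)[under]),
             mean(fangmark:::to_gray(dark)[under]))
  # black is a fixed point
  zero <- array(0, dim = c(6, 6, 3))
  expect_identical(enhance(zero, ecfg), zero)
  # idempotent in the limit
  twice <- enhance(out, ecfg)
  expect_lt(mean(abs(twice - out)), 0.05)
})

test_that("resize reaches the canonical side and replicates grayscale", {
  img <- array(runif(640 * 480 * 3), dim = c(640, 480, 3))
  out <- resize_to_canonical(img, 1000)
  expect_identical(dim(out), c(1000L, 1000L, 3L))
  sq <- fixture_image(32, 32)
  expect_identical(resize_to_canonical(sq, 32), sq)
  gray <- matrix(runif(100), 10, 10)
  rep3 <- resize_to_canonical(gray, 10)
  expect_identical(rep3[, , 1], rep3[, , 2])
  expect_identical(rep3[, , 2], rep3[, , 3])
  expect_error(resize_to_canonical(fixture_image(), 4), class = "fangmark_resize")
})

test_that("augmentation emits original + one variant per enabled kind", {
  img <- fixture_image()
  out <- augment(img, augment_config(seed = 1))
  expect_length(out, 3)
  expect_identical(out[[1]], img)
  # zoom forced to 1 -> zoom variant equals the original
  out1 <- augment(img, augment_config(zoom = c(1, 1), seed = 1))
  expect_equal(out1[[3]], img, tolerance = 1e-12)
  # rotation has order 4
  r <- img
  for (i in 1:4) r <- fangmark:::rotate90(r)
  expect_equal(r, img, tolerance = 1e-12)
  # mirror variant adds one more
  expect_length(augment(img, augment_config(mirror = TRUE, seed = 1)), 4)
  # determinism under seed
  expect_identical(augment(img, augment_config(seed = 9)),
                   augment(img, augment_config(seed = 9)))
})

test_that("augmenting a dataset of 10 yields 30 labelled images", {
  ds <- fixture_dataset(5, seed = 4)   # 10 images
  out <- augment_dataset(ds, augment_config(seed = 0))
  expect_length(out, 30)
  expect_identical(vapply(out[1:3], function(d) d$label, character(1)),
                   rep(ds[[1]]$label, 3))
})

test_that("preprocess ops preserve the [0, 1] range", {
  img <- generate_bite_image("other", generator_config(size = 64), 2)$pixels
  for (out in c(list(brightness_transform(img, 3), enhance(img),
                     resize_to_canonical(img, 48)), augment(img))) {
    expect_gte(min(out), 0)
    expect_lte(max(out), 1)
  }
})
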