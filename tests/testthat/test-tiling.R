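# exhaustive-scan Otsu oracle: try every histogram cut point directly
otsu_oracle <- function(g, levels = 256L) {
  v <- as.vector(g)
  bin <- pmin(floor(v * levels), levels - 1L)
  best <- -1; best_k <- NA
  for (k in seq_len(levels - 1L)) {
    lo <- bin < k
    w0 <- mean(lo)
    if (w0 == 0 || w0 == 1) next
    mids <- (bin + 0.5) / levels
    bcv <- w0 * (1 - w0) * (mean(mids[lo]) - mean(mids[!lo]))^2
    if (bcv > best) { best <- bcv; best_k <- k }
  }
  best_k / levels
}

test_that("Otsu splits a two-level image exactly at the dark half", {
  g <- matrix(0.9, 40, 40)
  g[, 1:20] <- 0.1
  m <- tissue_mask(g)
  expect_true(m$threshold > 0.1 && m$threshold < 0.9)
  expect_identical(m$mask, g < m$threshold)
  expect_true(all(m$mask[, 1:20]) && !any(m$mask[, 21:40]))
})

test_that("a constant thumbnail raises a degenerate-histogram error", {
  expect_error(tissue_mask(matrix(1, 16, 16)), "degenerate histogram")
})

test_that("Otsu threshold agrees with a brute-force scan and EBImage", {
  skip_if_not_installed("EBImage")
  set.seed(42)
  for (i in 1:8) {
    g <- matrix(sample(0:255, 900, replace = TRUE) / 255, 30, 30)
    # bimodal mixture resembling tissue/glass
    if (i %% 2 == 0) g <- matrix(c(rbeta(450, 2, 6), rbeta(450, 8, 2)), 30, 30)
    ours <- tissue_mask(g)$threshold
    expect_equal(ours, otsu_oracle(g), tolerance = 1 / 256)
    eb <- EBImage::otsu(EBImage::Image(t(g)), range = c(0, 1), levels = 256)
    expect_lt(abs(ours - eb), 2.5 / 256)  # binning conventions differ by a bin
  }
})

test_that("tile enumeration produces the expected grids", {
  m <- tissue_mask(fake_slide(448, 448, margin = 1))
  expect_equal(nrow(enumerate_rois(m, size = 224, stride = 112, min_tissue = 0)), 9L)
  expect_equal(nrow(enumerate_rois(m, size = 224, stride = 224, min_tissue = 0)), 4L)
  # slide smaller than the tile: empty, not an error
  small <- tissue_mask(fake_slide(100, 100, margin = 10))
  expect_equal(nrow(enumerate_rois(small, size = 224)), 0L)
  expect_error(enumerate_rois(m, size = 224, stride = 0), "stride")
  expect_error(enumerate_rois(m, size = 224, stride = 300), "stride")
})

test_that("tiles stay inside slide bounds with bounded overlap", {
  set.seed(3)
  for (i in 1:5) {
    h <- sample(300:500, 1); w <- sample(300:500, 1)
    size <- sample(c(96, 128, 224), 1); stride <- sample(c(size %/% 2, size), 1)
    m <- tissue_mask(fake_slide(h, w, margin = 5))
    co <- enumerate_rois(m, size = size, stride = stride, min_tissue = 0)
    expect_true(all(co$x >= 0 & co$x + size <= w))
    expect_true(all(co$y >= 0 & co$y + size <= h))
    xs <- sort(unique(co$x))
    if (length(xs) > 1L) expect_true(all(diff(xs) >= stride))
  }
})

test_that("min_tissue = 1 keeps only tiles fully inside tissue", {
  g <- matrix(0.95, 256, 256)
  g[, 1:128] <- 0.3  # left half tissue
  m <- tissue_mask(g)
  co <- enumerate_rois(m, size = 64, stride = 32, min_tissue = 1)
  expect_true(nrow(co) > 0L)
  expect_true(all(co$x + 64 <= 128))
})

test_that("sample_rois is deterministic, distinct when possible, exhaustive when topped up", {
  coords <- expand.grid(x = seq(0, 960, 32), y = seq(0, 960, 32))
  coords$slide_id <- "s"; coords$size <- 64L
  a <- sample_rois(coords, 500, seed = 5)
  b <- sample_rois(coords, 500, seed = 5)
  expect_identical(a, b)
  expect_equal(nrow(a), 500L)
  expect_equal(anyDuplicated(a[, c("x", "y")]), 0L)

  ten <- coords[1:10, ]
  full <- sample_rois(ten, 10, seed = 1)
  expect_setequal(paste(full$x, full$y), paste(ten$x, ten$y))

  three <- coords[1:3, ]
  six <- sample_rois(three, 6, seed = 2)
  expect_equal(nrow(six), 6L)
  expect_setequal(paste(six$x, six$y), paste(three$x, three$y))  # pigeonhole
  expect_error(sample_rois(coords[0, ], 5), "no tissue")
})

test_that("augmentation is shape/range preserving and pure given a seed", {
  patch <- rand_patch(7, 32)
  for (s in c(1, 2, 3, 10)) {
    out <- augment_patch(patch, seed = s)
    expect_identical(dim(out), dim(patch))
    expect_true(min(out) >= 0 && max(out) <= 1)
    expect_identical(out, augment_patch(patch, seed = s))
  }
})

test_that("some augmentation seed draws the identity transform", {
  patch <- rand_patch(8, 16)
  hit <- FALSE
  for (s in 1:300) {
    if (identical(augment_patch(patch, seed = s), patch)) { hit <- TRUE; break }
  }
  expect_true(hit)  # all six gates silent has probability 1/64 per seed
})

test_that("180-degree rotation is an involution", {
  patch <- rand_patch(9, 20)
  expect_identical(histrisk:::rotate_image(histrisk:::rotate_image(patch, 180), 180), patch)
  expect_identical(histrisk:::rotate_image(patch, 0), patch)
})

test_that("random erasing changes a 2-20 percent fraction of pixels", {
  patch <- rand_patch(11, 64)
  set.seed(99)
  for (af in c(0.02, 0.1, 0.2)) {
    out <- histrisk:::erase_rect(patch, af, aspect = 1.3, cx = 0.4, cy = 0.6)
    frac <- mean(out[, , 1] != patch[, , 1])
    expect_gte(frac, 0.015)
    expect_lte(frac, 0.21)
  }
})

test_that("ImageNet normalization matches the fixed constants and is affine", {
  mean_img <- array(rep(c(0.485, 0.456, 0.406), each = 16), dim = c(4, 4, 3))
  expect_equal(max(abs(normalize_imagenet(mean_img))), 0)
  white <- array(1, dim = c(4, 4, 3))
  out <- normalize_imagenet(white)
  expect_equal(out[1, 1, ], (1 - c(0.485, 0.456, 0.406)) / c(0.229, 0.224, 0.225))
  # affinity: normalize(a x + b) is a linear map of normalize(x) per channel
  x <- rand_patch(13, 8)
  a <- 0.5; b <- 0.2
  lhs <- normalize_imagenet(a * x + b)
  rhs <- normalize_imagenet(x)
  for (c in 1:3) {
    resid <- lhs[, , c] - a * rhs[, , c]
    expect_lt(diff(range(resid)), 1e-12)  # constant per channel
  }
  expect_error(normalize_imagenet(x + 10), "0, 1")
})
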