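tiny_test_model <- function(seed = 7, sd = 0.3, ...) {
  init_weights(risk_model(backbone = "custom", input_size = 8L,
                          channels = c(2L, 3L, 4L), fc_dim = 5L, ...),
               seed = seed, sd = sd)
}

test_that("attention gates are sigmoids of the spatial / channel means", {
  F0 <- array(0, dim = c(4, 6, 5))
  expect_equal(channel_attention(F0), rep(0.5, 5))
  expect_equal(as.vector(spatial_attention(F0)), rep(0.5, 24))

  Fc <- array(1.7, dim = c(3, 3, 4))
  expect_equal(channel_attention(Fc), rep(plogis(1.7), 4))
  expect_equal(spatial_attention(Fc)[2, 2], plogis(1.7))

  set.seed(5)
  Fr <- array(rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  # brute-force means by explicit loops
  cm <- sapply(1:6, function(d) mean(Fr[, , d]))
  sm <- matrix(0, 4, 5)
  for (y in 1:4) for (x in 1:5) sm[y, x] <- mean(Fr[y, x, ])
  expect_equal(channel_attention(Fr), plogis(cm))
  expect_equal(spatial_attention(Fr), plogis(sm))
})

test_that("raising one pixel's channel mean raises only that spatial gate", {
  set.seed(8)
  Fr <- array(rnorm(3 * 3 * 4), dim = c(3, 3, 4))
  g0 <- spatial_attention(Fr)
  Fr2 <- Fr
  Fr2[2, 3, ] <- Fr2[2, 3, ] + 1
  g1 <- spatial_attention(Fr2)
  expect_gt(g1[2, 3], g0[2, 3])
  g1[2, 3] <- g0[2, 3]
  expect_equal(g1, g0)
})

test_that("attention fusion sums the two gated branches", {
  F0 <- array(0, dim = c(4, 4, 3))
  expect_equal(attention_fuse(F0), F0)

  Fc <- array(-0.8, dim = c(5, 2, 6))
  expect_equal(attention_fuse(Fc), 2 * plogis(-0.8) * Fc)

  set.seed(6)
  for (d in list(c(2L, 7L, 3L), c(8L, 8L, 1L), c(1L, 5L, 9L))) {
    Fr <- array(rnorm(prod(d)), dim = d)
    out <- attention_fuse(Fr)
    expect_identical(dim(out), d)
    expect_true(all(abs(out) <= 2 * abs(Fr) + 1e-12))  # gates < 1
  }
})

test_that("weight initialisation is Gaussian sd 0.01 with zero biases", {
  m <- risk_model(seed = 1)
  ws <- unlist(m$params[grep("_W$", names(m$params))])
  expect_lt(abs(sd(ws) - 0.01), 5e-4)
  expect_lt(abs(mean(ws)), 5e-4)
  expect_true(all(unlist(m$params[grep("_b$", names(m$params))]) == 0))
  expect_identical(init_weights(m, 3)$params, init_weights(m, 3)$params)
  expect_false(identical(init_weights(m, 3)$params, init_weights(m, 4)$params))
})

test_that("the model maps a tile to one deterministic finite scalar", {
  m <- risk_model(seed = 2)
  patch <- normalize_imagenet(rand_patch(3, 64))
  r1 <- predict_risk(m, patch)
  r2 <- predict_risk(m, patch)
  expect_length(r1, 1L)
  expect_true(is.finite(r1))
  expect_identical(r1, r2)
  expect_error(predict_risk(m, normalize_imagenet(rand_patch(3, 32))), "input size")
  bad <- patch; bad[1, 1, 1] <- NaN
  expect_error(predict_risk(m, bad), "non-finite")
})

test_that("the attention switch changes the output but not the parameter count", {
  on <- risk_model(attention_enabled = TRUE, seed = 5)
  off <- risk_model(attention_enabled = FALSE, seed = 5)
  expect_identical(n_parameters(on), n_parameters(off))
  expect_identical(on$params, off$params)
  patch <- normalize_imagenet(rand_patch(4, 64))
  expect_false(isTRUE(all.equal(predict_risk(on, patch), predict_risk(off, patch))))
  expect_true(is.finite(predict_risk(off, patch)))
  # learnable attention adds parameters and still runs
  lm <- risk_model(attention_learnable = TRUE, seed = 5)
  expect_gt(n_parameters(lm), n_parameters(on))
  expect_true(is.finite(predict_risk(lm, patch)))
})

test_that("named large backbones are rejected with guidance", {
  expect_error(risk_model(backbone = "resnet18"), "not bundled")
  expect_error(risk_model(backbone = "nope"), "unknown backbone")
  expect_error(risk_model(backbone = "custom", input_size = 65L), "divisible")
})

test_that("autodiff matches central finite differences on every parameter", {
  for (learnable in c(FALSE, TRUE)) {
    m <- tiny_test_model(attention_learnable = learnable)
    set.seed(11)
    x <- array(rnorm(8 * 8 * 3), dim = c(8, 8, 3))
    X <- histrisk:::stack_patches(list(x))
    fw <- histrisk:::risk_forward(m, X, want_cache = TRUE)
    bw <- histrisk:::risk_backward(m, fw$cache, 1, input_grad = TRUE)
    h <- 1e-6
    for (nm in names(bw$grads)) {
      p0 <- m$params[[nm]]
      fd <- p0 * 0
      for (j in seq_along(p0)) {
        mp <- m; mp$params[[nm]][j] <- p0[j] + h
        mm <- m; mm$params[[nm]][j] <- p0[j] - h
        fd[j] <- (histrisk:::risk_forward(mp, X)$risk -
                  histrisk:::risk_forward(mm, X)$risk) / (2 * h)
      }
      expect_lt(max(abs(bw$grads[[nm]] - fd) / pmax(abs(fd), 1e-4)), 1e-4)
    }
  }
})

test_that("input gradients of the tiny backbone match finite differences", {
  m <- init_weights(risk_model(seed = 0), seed = 5, sd = 0.1)
  set.seed(12)
  x <- normalize_imagenet(rand_patch(21, 64))
  X <- histrisk:::stack_patches(list(x))
  fw <- histrisk:::risk_forward(m, X, want_cache = TRUE)
  bw <- histrisk:::risk_backward(m, fw$cache, 1, input_grad = TRUE)
  set.seed(13)
  pix <- cbind(sample(64, 8), sample(64, 8), sample(3, 8, replace = TRUE))
  h <- 1e-5
  for (i in seq_len(nrow(pix))) {
    xp <- x; xm <- x
    xp[pix[i, 1], pix[i, 2], pix[i, 3]] <- x[pix[i, 1], pix[i, 2], pix[i, 3]] + h
    xm[pix[i, 1], pix[i, 2], pix[i, 3]] <- x[pix[i, 1], pix[i, 2], pix[i, 3]] - h
    fd <- (histrisk:::risk_forward(m, histrisk:::stack_patches(list(xp)))$risk -
           histrisk:::risk_forward(m, histrisk:::stack_patches(list(xm)))$risk) / (2 * h)
    an <- bw$dX[pix[i, 1], pix[i, 2], pix[i, 3], 1]
    expect_lt(abs(an - fd) / max(abs(fd), 1e-6), 1e-4)
  }
})

test_that("batched and single-tile forward passes agree", {
  m <- risk_model(seed = 9)
  tiles <- lapply(1:5, function(s) normalize_imagenet(rand_patch(s, 64)))
  batch <- predict_risk_batch(m, tiles, chunk = 3L)
  single <- vapply(tiles, function(t) predict_risk(m, t), 0)
  expect_equal(batch, single, tolerance = 1e-12)
})
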