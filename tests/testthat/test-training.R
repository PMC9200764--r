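test_that("the Cox loss reproduces hand-computed fixtures", {
  # singleton risk set: r - log exp(r) = 0
  expect_equal(cox_nll(2.3, 5, 1), 0)
  # no events: empty sum
  expect_equal(cox_nll(c(1, 2, 3), c(1, 2, 3), c(0, 0, 0)), 0)
  # two subjects, hand arithmetic
  expect_equal(cox_nll(c(1, 0), c(1, 2), c(1, 1)),
               -((1 - log(exp(1) + 1)) + (0 - log(1))), tolerance = 1e-12)
  expect_equal(cox_nll(c(1, 0), c(1, 2), c(1, 1)), 0.3132617, tolerance = 1e-6)
  expect_error(cox_nll(numeric(0), numeric(0), numeric(0)), "empty")
  expect_error(cox_nll(c(1, 2), 1, c(1, 0)), "equal length")
})

test_that("the Cox loss value matches the survival package at a fixed coefficient", {
  set.seed(14)
  for (ties in c("breslow", "efron")) {
    t <- c(1, 1, 2, 3, 3, 4, 6, 6, 6, 9)
    e <- c(1, 1, 1, 0, 1, 1, 1, 1, 0, 1)
    r <- rnorm(10)
    fit <- survival::coxph(survival::Surv(t, e) ~ r, init = 1,
                           control = survival::coxph.control(iter.max = 0), ties = ties)
    expect_equal(cox_nll(r, t, e, ties = ties), -fit$loglik[2], tolerance = 1e-9)
  }
})

test_that("the Cox loss gradient matches central finite differences", {
  set.seed(15)
  for (rep in 1:5) {
    n <- sample(4:12, 1)
    t <- sample(1:6, n, replace = TRUE)       # include ties
    e <- rbinom(n, 1, 0.7)
    if (!any(e == 1)) e[1] <- 1
    r <- rnorm(n)
    for (ties in c("breslow", "efron")) {
      g <- cox_nll_grad(r, t, e, ties = ties)
      h <- 1e-6
      fd <- vapply(seq_len(n), function(i) {
        rp <- r; rm <- r
        rp[i] <- r[i] + h; rm[i] <- r[i] - h
        (cox_nll(rp, t, e, ties) - cox_nll(rm, t, e, ties)) / (2 * h)
      }, 0)
      expect_lt(max(abs(g - fd) / pmax(abs(fd), 1e-3)), 1e-5)
    }
  }
})

test_that("the partial likelihood is invariant to shifting all risks", {
  set.seed(16)
  for (rep in 1:5) {
    n <- 10
    r <- rnorm(n); t <- rexp(n); e <- rbinom(n, 1, 0.6)
    if (!any(e == 1)) e[1] <- 1
    for (cst in c(-5, 0.3, 40)) {
      expect_equal(cox_nll(r + cst, t, e), cox_nll(r, t, e), tolerance = 1e-9)
    }
  }
})

test_that("mini-batches draw at most one tile per patient and always hold an event", {
  idx <- data.frame(patient_id = rep(sprintf("P%d", 1:8), each = 5),
                    item = rep(1:5, 8), stringsAsFactors = FALSE)
  events <- stats::setNames(c(1, 0, 1, 1, 0, 1, 0, 1), sprintf("P%d", 1:8))
  batches <- make_minibatches(idx, 8, events, seed = 4)
  expect_true(all(vapply(batches, function(b) anyDuplicated(b$patient_id) == 0L, TRUE)))
  expect_true(all(vapply(batches, function(b) length(b$patient_id) == 8L, TRUE)))
  expect_true(all(vapply(batches, function(b) any(events[b$patient_id] == 1), TRUE)))
  expect_identical(batches, make_minibatches(idx, 8, events, seed = 4))
  expect_false(identical(batches, make_minibatches(idx, 8, events, seed = 5)))
  expect_error(make_minibatches(idx, 9, events), "exceeds")
  # every tile is used exactly once per epoch when all batches are full
  used <- do.call(rbind, batches)
  expect_equal(nrow(used), nrow(idx))
  expect_equal(anyDuplicated(used[, c("patient_id", "item")]), 0L)
})

test_that("batches smaller than batch_size survive only with 2+ patients and an event", {
  idx <- data.frame(patient_id = sprintf("P%d", 1:5), item = 1L,
                    stringsAsFactors = FALSE)
  events <- stats::setNames(c(1, 1, 1, 0, 0), sprintf("P%d", 1:5))
  batches <- make_minibatches(idx, 3, events, seed = 2)
  expect_true(all(vapply(batches, function(b) nrow(b) >= 2L, TRUE)))
  expect_true(all(vapply(batches, function(b) any(events[b$patient_id] == 1), TRUE)))
})

test_that("the Cox loss decreases on a separable toy problem", {
  # every tile is a constant image whose intensity linearly encodes the
  # patient's true log-hazard covariate z
  set.seed(55)
  n <- 12
  z <- as.vector(scale(rnorm(n)))
  p <- data.frame(patient_id = sprintf("P%02d", 1:n),
                  time_months = rexp(n, 0.02 * exp(1.5 * z)),
                  event = rep(1L, n), stringsAsFactors = FALSE)
  p$slide_ids <- as.list(rep("in-memory", n))
  co <- cohort(p)
  pools <- stats::setNames(lapply(1:n, function(i) {
    lapply(1:6, function(j) array(0.5 + 0.15 * z[i], c(8, 8, 3)))
  }), p$patient_id)
  model <- risk_model(backbone = "custom", input_size = 8L,
                      channels = c(2L, 3L, 4L), fc_dim = 5L, seed = 2)
  fit <- train_risk_model(model, pools, co, p$patient_id[1:10], p$patient_id[11:12],
                          train_config(epochs = 10, batch_size = 5, lr0 = 1e-3,
                                       augment = FALSE, seed = 3))
  expect_lt(fit$history$loss[10], fit$history$loss[1] - 0.3)
  expect_true(all(is.finite(fit$history$loss)))
})

test_that("training on synthetic slides is deterministic with the stated schedule", {
  synth <- generate_cohort(synth_params(n_patients = 16, slide_size = 128,
                                        beta_true = 2, censor_rate = 0.2, seed = 51))
  pools <- cohort_tile_pools(synth$slides, n_per_slide = 8, size = 32, seed = 52)
  ids <- synth$cohort$patients$patient_id
  cfg <- train_config(epochs = 3, batch_size = 6, seed = 54)
  factory <- function() risk_model(backbone = "custom", input_size = 32L,
                                   channels = c(6L, 12L, 24L), fc_dim = 8L, seed = 53)
  fit <- train_risk_model(factory(), pools, synth$cohort,
                          train_ids = ids[1:13], val_ids = ids[14:16], cfg)
  expect_equal(nrow(fit$history), 3L)
  expect_true(all(is.finite(fit$history$loss)))
  # learning-rate schedule: lr0 * decay^(epoch - 1)
  expect_equal(fit$history$lr, 1e-4 * 0.97^(0:2))
  fit2 <- train_risk_model(factory(), pools, synth$cohort, ids[1:13], ids[14:16], cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$final_model$params, fit2$final_model$params)
})
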