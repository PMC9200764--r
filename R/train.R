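#' Training configuration
#'
#' Defaults follow the training protocol the package implements: adaptive
#' per-parameter gradient accumulation (AdaGrad) combined with heavy-ball
#' momentum 0.95, initial learning rate `1e-4` decayed by `0.97` per epoch,
#' on-the-fly augmentation of every tile, weights initialised as Gaussians
#' with standard deviation 0.01.
#'
#' @param epochs training epochs.
#' @param batch_size patients (= tiles) per mini-batch.
#' @param lr0 initial learning rate.
#' @param lr_decay multiplicative per-epoch decay in `(0, 1]`.
#' @param momentum heavy-ball momentum coefficient.
#' @param optimizer `"adagrad_momentum"` (default), `"adagrad"` or
#'   `"sgd_momentum"`.
#' @param augment apply [augment_patch()] to every training tile each epoch.
#' @param ties tie handling of the Cox loss.
#' @param seed integer master seed for batching/augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 10L, batch_size = 8L, lr0 = 1e-4,
                         lr_decay = 0.97, momentum = 0.95,
                         optimizer = c("adagrad_momentum", "adagrad", "sgd_momentum"),
                         augment = TRUE, ties = "breslow", seed = 1L) {
  stopifnot(lr0 > 0, lr_decay > 0, lr_decay <= 1, momentum >= 0, momentum < 1)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr0 = lr0, lr_decay = lr_decay, momentum = momentum,
                 optimizer = match.arg(optimizer), augment = augment,
                 ties = ties, seed = as.integer(seed)),
            class = "train_config")
}

#' Unique-patient mini-batches over a tile index
#'
#' Shuffles the tile pool each call and emits batches that contain at most
#' one tile per patient, so the in-batch risk set of the Cox loss is a valid
#' sample of the cohort. Batches without any observed event are skipped (the
#' partial likelihood is an empty sum there); a final short batch is kept
#' only if it still has at least two patients and one event.
#'
#' @param index data.frame with columns `patient_id` and `item` (an
#'   identifier of the tile within the patient's pool).
#' @param batch_size number of patients per batch; must not exceed the
#'   number of distinct patients.
#' @param events named 0/1 vector of event indicators by patient id.
#' @param seed integer; the batch sequence is deterministic given the seed.
#' @return list of data.frames (`patient_id`, `item`), one per batch.
#' @export
make_minibatches <- function(index, batch_size, events, seed = 1L) {
  stopifnot(is.data.frame(index), all(c("patient_id", "item") %in% names(index)))
  pts <- unique(index$patient_id)
  if (batch_size > length(pts)) {
    stop_validation("batch_size (%d) exceeds the number of distinct patients (%d)",
                    batch_size, length(pts))
  }
  if (!all(pts %in% names(events))) stop_validation("events must be named by patient id")
  with_local_seed(seed, {
    pools <- lapply(split(seq_len(nrow(index)), index$patient_id),
                    function(x) x[sample.int(length(x))])
    rounds <- max(lengths(pools))
    batches <- list()
    for (r in seq_len(rounds)) {
      avail <- names(pools)[lengths(pools) >= r]
      avail <- sample(avail)
      i <- 1L
      while (i <= length(avail)) {
        j <- min(i + batch_size - 1L, length(avail))
        ids <- avail[i:j]
        i <- j + 1L
        if (length(ids) < batch_size && (length(ids) < 2L || !any(events[ids] == 1))) next
        if (!any(events[ids] == 1)) next
        rows <- vapply(ids, function(id) pools[[id]][r], 0L)
        batches[[length(batches) + 1L]] <-
          data.frame(patient_id = ids, item = index$item[rows],
                     row.names = NULL, stringsAsFactors = FALSE)
      }
    }
    batches
  })
}

# one optimizer step over all parameters; state carries accumulators
optim_step <- function(params, grads, state, lr, cfg) {
  eps <- 1e-10
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state$G[[nm]])) {
      state$G[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    step <- switch(cfg$optimizer,
      adagrad_momentum = {
        state$G[[nm]] <- state$G[[nm]] + g^2
        lr * g / (sqrt(state$G[[nm]]) + eps)
      },
      adagrad = {
        state$G[[nm]] <- state$G[[nm]] + g^2
        lr * g / (sqrt(state$G[[nm]]) + eps)
      },
      sgd_momentum = lr * g
    )
    mom <- if (cfg$optimizer == "adagrad") 0 else cfg$momentum
    state$v[[nm]] <- mom * state$v[[nm]] + step
    params[[nm]] <- params[[nm]] - state$v[[nm]]
  }
  list(params = params, state = state)
}

# median tile risk per patient (normalization applied here)
patient_median_risks <- function(model, patches, ids) {
  vapply(ids, function(id) {
    tiles <- lapply(patches[[id]], normalize_imagenet)
    stats::median(predict_risk_batch(model, tiles))
  }, 0)
}

#' Train a risk model on weakly labeled tiles
#'
#' Optimizes the Cox negative log partial likelihood over unique-patient
#' mini-batches with the configured adaptive-gradient schedule
#' (`lr_t = lr0 * lr_decay^epoch`). Tiles enter as raw `[0, 1]` images; each
#' epoch they are (optionally) augmented and then ImageNet-normalized. The
#' per-epoch history records the mean train loss and the validation c-index
#' of patient-median risks; the checkpoint with the best validation c-index
#' is returned.
#'
#' @param model a [risk_model].
#' @param patches named list: patient id -> list of raw tiles (pooled across
#'   all the patient's slides).
#' @param x a [cohort] providing times/events for the patients.
#' @param train_ids,val_ids patient id vectors.
#' @param config a [train_config].
#' @return list with `model` (best-validation checkpoint), `final_model`,
#'   and `history` (data.frame epoch/loss/val_cindex/lr).
#' @export
train_risk_model <- function(model, patches, x, train_ids, val_ids,
                             config = train_config()) {
  stopifnot(inherits(x, "cohort"), inherits(config, "train_config"))
  p <- x$patients
  times <- stats::setNames(p$time_months, p$patient_id)
  events <- stats::setNames(p$event, p$patient_id)
  missing_tiles <- setdiff(train_ids, names(patches))
  if (length(missing_tiles)) {
    stop_validation("no tiles for patient(s): %s", paste(missing_tiles, collapse = ", "))
  }
  index <- do.call(rbind, lapply(train_ids, function(id) {
    data.frame(patient_id = id, item = seq_along(patches[[id]]),
               stringsAsFactors = FALSE)
  }))

  state <- list(G = list(), v = list())
  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_cindex = numeric(), lr = numeric())
  best <- list(cindex = -Inf, params = model$params)

  for (epoch in seq_len(config$epochs)) {
    lr <- config$lr0 * config$lr_decay^(epoch - 1)
    batches <- make_minibatches(index, config$batch_size, events,
                                seed = config$seed * 1000L + epoch)
    ep_losses <- numeric(length(batches))
    for (bi in seq_along(batches)) {
      b <- batches[[bi]]
      tiles <- lapply(seq_len(nrow(b)), function(i) {
        tile <- patches[[b$patient_id[i]]][[b$item[i]]]
        if (config$augment) {
          tile <- augment_patch(tile, seed = config$seed + 7919L * epoch + 131L * bi + i)
        }
        normalize_imagenet(tile)
      })
      fw <- risk_forward(model, stack_patches(tiles), want_cache = TRUE)
      pl <- cox_pl(fw$risk, times[b$patient_id], events[b$patient_id], ties = config$ties)
      if (!is.finite(pl$loss)) {
        stop_validation("non-finite training loss at epoch %d batch %d", epoch, bi)
      }
      ep_losses[bi] <- pl$loss
      bw <- risk_backward(model, fw$cache, pl$grad)
      upd <- optim_step(model$params, bw$grads, state, lr, config)
      model$params <- upd$params
      state <- upd$state
    }
    val_ci <- NA_real_
    if (length(val_ids) >= 2L) {
      vr <- patient_median_risks(model, patches, val_ids)
      val_ci <- tryCatch(concordance_index(vr, times[val_ids], events[val_ids]),
                         error = function(e) NA_real_)
    }
    history <- rbind(history, data.frame(epoch = epoch, loss = mean(ep_losses),
                                         val_cindex = val_ci, lr = lr))
    if (!is.na(val_ci) && val_ci > best$cindex) {
      best <- list(cindex = val_ci, params = model$params)
    }
  }
  best_model <- model
  if (is.finite(best$cindex)) best_model$params <- best$params
  list(model = best_model, final_model = model, history = history)
}

#' Patient-level cross-validated risk scores
#'
#' Runs the full weakly supervised protocol: a patient-level k-fold plan,
#' one model trained per fold, and each patient scored (median tile risk)
#' by the model that never saw it, so every patient receives exactly one
#' out-of-fold risk.
#'
#' @param x a [cohort].
#' @param patches named list: patient id -> list of raw tiles.
#' @param k folds.
#' @param config a [train_config].
#' @param model_factory zero-argument function creating a fresh untrained
#'   [risk_model] for each fold.
#' @param seed seed of the split plan and per-fold weight init.
#' @return list with `risks` (data.frame patient_id/risk/fold), `histories`,
#'   `models` (the per-fold best checkpoints) and `plan` (the split plan).
#' @export
crossval_risks <- function(x, patches, k = 5L, config = train_config(),
                           model_factory = function() risk_model(),
                           seed = 1L) {
  plan <- make_split_plan(x, k = k, seed = seed)
  out <- list()
  histories <- list()
  models <- list()
  for (f in seq_len(k)) {
    fold <- plan$folds[[f]]
    model <- init_weights(model_factory(), seed = seed * 100L + f)
    cfg <- config
    cfg$seed <- config$seed * 100L + f
    fit <- train_risk_model(model, patches, x, fold$train, fold$val, cfg)
    risks <- patient_median_risks(fit$model, patches, fold$test)
    out[[f]] <- data.frame(patient_id = fold$test, risk = unname(risks),
                           fold = f, stringsAsFactors = FALSE)
    histories[[f]] <- fit$history
    models[[f]] <- fit$model
  }
  list(risks = do.call(rbind, out), histories = histories, models = models,
       plan = plan)
}

#' Cross-validated concordance of out-of-fold risks
#'
#' Cox-style risk scores are only defined up to a monotone transform, so
#' risks emitted by different fold models live on incommensurable scales and
#' must not be ranked against each other. The held-out concordance is
#' therefore computed within each fold and averaged; folds without a
#' comparable pair are dropped.
#'
#' @param risks data.frame with `patient_id`, `risk`, `fold` (as returned in
#'   `crossval_risks()$risks`).
#' @param x the [cohort] the risks were computed on.
#' @return list with `per_fold` (named numeric, `NA` where undefined) and
#'   `mean` (average over defined folds).
#' @export
crossval_cindex <- function(risks, x) {
  stopifnot(inherits(x, "cohort"), all(c("patient_id", "risk", "fold") %in% names(risks)))
  p <- x$patients
  m <- match(risks$patient_id, p$patient_id)
  if (anyNA(m)) stop_validation("risks contain unknown patient ids")
  per_fold <- vapply(sort(unique(risks$fold)), function(f) {
    i <- risks$fold == f
    tryCatch(concordance_index(risks$risk[i], p$time_months[m][i], p$event[m][i]),
             error = function(e) NA_real_)
  }, 0)
  names(per_fold) <- sort(unique(risks$fold))
  list(per_fold = per_fold, mean = mean(per_fold, na.rm = TRUE))
}
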