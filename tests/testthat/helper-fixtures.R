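# Shared fixtures, memoised so expensive objects are built once per run.
.fixtures <- new.env(parent = emptyenv())

fx <- function(key, builder) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- builder()
  .fixtures[[key]]
}

# deterministic fake slide: dark tissue block in a white field
fake_slide <- function(h = 128, w = 128, tissue_val = 0.6, margin = 16) {
  img <- array(0.95, dim = c(h, w, 3L))
  img[(margin + 1):(h - margin), (margin + 1):(w - margin), ] <- tissue_val
  # a pinch of deterministic texture so the histogram is not two spikes
  img[, , 1L] <- img[, , 1L] + 0.01 * sin(seq_len(h) / 3)
  clamp_fake(img)
}

clamp_fake <- function(x) pmin(pmax(x, 0), 1)

rand_patch <- function(seed = 1, size = 16) {
  set.seed(seed)
  array(runif(size * size * 3), dim = c(size, size, 3L))
}

# study-condition synthetic cohort used by the heavy end-to-end checks
fx_signal_synth <- function() fx("signal_synth", function() {
  generate_cohort(synth_params(n_patients = 40, beta_true = 1.5,
                               censor_rate = 0.3, seed = 11))
})

fx_signal_pools <- function() fx("signal_pools", function() {
  cohort_tile_pools(fx_signal_synth()$slides, n_per_slide = 30, size = 64, seed = 12)
})

fx_signal_cv <- function() fx("signal_cv", function() {
  crossval_risks(fx_signal_synth()$cohort, fx_signal_pools(), k = 5,
                 config = train_config(epochs = 10, batch_size = 8, seed = 13),
                 model_factory = function() risk_model(input_size = 64L),
                 seed = 14)
})

fx_control_cv <- function() fx("control_cv", function() {
  synth <- generate_cohort(synth_params(n_patients = 40, beta_true = 0,
                                        censor_rate = 0.3, seed = 31))
  pools <- cohort_tile_pools(synth$slides, n_per_slide = 30, size = 64, seed = 32)
  list(synth = synth,
       cv = crossval_risks(synth$cohort, pools, k = 5,
                           config = train_config(epochs = 10, batch_size = 8, seed = 33),
                           model_factory = function() risk_model(input_size = 64L),
                           seed = 34))
})

# independent brute-force c-index oracle: explicit double loop over pairs
cindex_bruteforce <- function(risks, times, events) {
  n <- length(risks)
  num <- 0; den <- 0
  for (m in seq_len(n)) {
    for (j in seq_len(n)) {
      if (m == j) next
      if (times[m] < times[j] && events[m] == 1) {
        den <- den + 1
        if (risks[m] > risks[j]) num <- num + 1
        else if (risks[m] == risks[j]) num <- num + 0.5
      }
    }
  }
  if (den == 0) stop("no comparable pairs")
  num / den
}
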