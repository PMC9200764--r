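SOTA_BACKBONES <- c("resnet18", "vgg11bn", "densenet121", "alexnet")

#' Construct a convolutional risk model
#'
#' A compact convolutional network mapping a normalized RGB tile to one
#' scalar risk (higher value = higher hazard): stacked 3x3 convolution /
#' ReLU / 2x2 max-pool blocks, attention gating of the final convolutional
#' feature map (after the last block, before global pooling), global average
#' pooling, one hidden fully connected layer and a single linear output.
#'
#' The default `"tiny"` backbone (three blocks, 64 px input) is sized for
#' CPU training. Large ImageNet-style backbones are not bundled; requesting
#' one raises an informative error. A custom backbone is specified through
#' `channels`/`fc_dim`/`input_size`.
#'
#' @param backbone `"tiny"` or `"custom"`.
#' @param attention_enabled gate the final feature map with channel and
#'   spatial attention (the default gating has no learnable parameters, so
#'   switching attention off leaves the parameter count unchanged).
#' @param attention_learnable replace the fixed attention projections with
#'   learnable 1x1 projections (adds parameters; off by default).
#' @param input_size tile side in pixels; must be divisible by
#'   `2^length(channels)`.
#' @param channels output channels of the convolutional blocks.
#' @param fc_dim width of the hidden fully connected layer.
#' @param seed seed for the initial weights (see [init_weights()]).
#' @return object of class `risk_model`.
#' @export
risk_model <- function(backbone = "tiny", attention_enabled = TRUE,
                       attention_learnable = FALSE, input_size = 64L,
                       channels = c(8L, 16L, 32L), fc_dim = 16L, seed = 0L) {
  if (backbone %in% SOTA_BACKBONES) {
    stop_validation(paste0(
      "backbone '%s' is not bundled with this package; use backbone = 'tiny' ",
      "or a custom channel specification"), backbone)
  }
  if (!backbone %in% c("tiny", "custom")) {
    stop_validation("unknown backbone '%s'", backbone)
  }
  if (backbone == "tiny") {
    channels <- c(8L, 16L, 32L)
    fc_dim <- 16L
  }
  nblk <- length(channels)
  if (input_size %% (2^nblk) != 0) {
    stop_validation("input_size must be divisible by %d", 2^nblk)
  }
  cin <- c(3L, channels[-nblk])
  params <- list()
  for (k in seq_len(nblk)) {
    params[[sprintf("conv%d_W", k)]] <- matrix(0, 9L * cin[k], channels[k])
    params[[sprintf("conv%d_b", k)]] <- numeric(channels[k])
  }
  D <- channels[nblk]
  params$fc1_W <- matrix(0, D, fc_dim)
  params$fc1_b <- numeric(fc_dim)
  params$fc2_W <- matrix(0, fc_dim, 1L)
  params$fc2_b <- 0
  if (attention_learnable) {
    params$attn_Wc <- diag(D)
    params$attn_Ws <- matrix(1 / D, D, 1L)
  }
  model <- structure(list(
    config = list(backbone = backbone, attention_enabled = attention_enabled,
                  attention_learnable = attention_learnable,
                  input_size = as.integer(input_size), channels = channels,
                  fc_dim = fc_dim),
    params = params,
    env = new.env(parent = emptyenv())
  ), class = "risk_model")
  init_weights(model, seed)
}

#' @export
print.risk_model <- function(x, ...) {
  cat(sprintf("<risk_model backbone='%s'> input %dpx, channels %s, attention %s%s, %d parameters\n",
              x$config$backbone, x$config$input_size,
              paste(x$config$channels, collapse = "-"),
              if (x$config$attention_enabled) "on" else "off",
              if (x$config$attention_learnable) " (learnable)" else "",
              n_parameters(x)))
  invisible(x)
}

#' Number of learnable parameters
#' @param model a [risk_model].
#' @return integer count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' Initialize model weights
#'
#' Draws every learnable weight from a Gaussian with mean 0 and standard
#' deviation `sd` (default 0.01) and sets all biases to zero; deterministic
#' given `seed`.
#'
#' @param model a [risk_model].
#' @param seed integer seed.
#' @param sd weight standard deviation.
#' @return the re-initialized model.
#' @export
init_weights <- function(model, seed = 0L, sd = 0.01) {
  with_local_seed(seed, {
    for (nm in names(model$params)) {
      p <- model$params[[nm]]
      if (grepl("_b$", nm)) {
        model$params[[nm]] <- p * 0
      } else {
        model$params[[nm]][] <- stats::rnorm(length(p), 0, sd)
      }
    }
  })
  model
}

# Full forward pass over a batch array (H, W, 3, B). Returns risks and,
# when `want_cache`, everything backward needs.
risk_forward <- function(model, X, want_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  env <- model$env
  B <- dim(X)[4L]
  nblk <- length(cfg$channels)
  caches <- vector("list", nblk)
  H <- dim(X)[1L]; W <- dim(X)[2L]
  cur <- X
  for (k in seq_len(nblk)) {
    cf <- conv_forward(cur, p[[sprintf("conv%d_W", k)]], p[[sprintf("conv%d_b", k)]], env)
    rf <- relu_forward(cf$Y, want_mask = want_cache)
    pf <- maxpool_forward(rf$Z, H, W, B, env, want_cache = want_cache)
    if (want_cache) caches[[k]] <- list(conv = cf$cache, mask = rf$mask, pool = pf$cache)
    H <- H %/% 2L; W <- W %/% 2L
    if (k < nblk) {
      cur <- mat_to_arr(pf$P, H, W, cfg$channels[k], B)
    } else {
      cur <- pf$P  # stay in matrix form for attention / pooling head
    }
  }
  HW <- H * W
  D <- cfg$channels[nblk]
  if (cfg$attention_enabled) {
    at <- attn_forward(cur, HW, B, Wc = p$attn_Wc, Ws = p$attn_Ws)
    feat <- at$out
  } else {
    at <- NULL
    feat <- cur
  }
  group <- rep(seq_len(B), each = HW)
  gap <- rowsum(feat, group) / HW                      # B x D
  h_pre <- gap %*% p$fc1_W + rep(p$fc1_b, each = B)
  h <- pmax(h_pre, 0)
  r <- drop(h %*% p$fc2_W) + p$fc2_b
  if (!all(is.finite(r))) stop_validation("non-finite activations in forward pass")
  if (!want_cache) return(list(risk = r))
  list(risk = r,
       cache = list(caches = caches, attn = at, gap = gap, h_pre = h_pre, h = h,
                    group = group, HW = HW, D = D, B = B, Hl = H, Wl = W))
}

# Backward pass; `drisk` is dLoss/drisk (length B). Returns gradients named
# like the parameters, plus dX (w.r.t. the input batch) when requested.
risk_backward <- function(model, cache, drisk, input_grad = FALSE) {
  cfg <- model$config
  p <- model$params
  grads <- list()
  B <- cache$B; HW <- cache$HW
  dr <- matrix(drisk, B, 1L)
  grads$fc2_W <- crossprod(cache$h, dr)
  grads$fc2_b <- sum(dr)
  dh <- tcrossprod(dr, p$fc2_W) * (cache$h_pre > 0)
  grads$fc1_W <- crossprod(cache$gap, dh)
  grads$fc1_b <- colSums(dh)
  dgap <- tcrossprod(dh, p$fc1_W)
  dfeat <- dgap[cache$group, , drop = FALSE] / HW
  if (cfg$attention_enabled) {
    ab <- attn_backward(dfeat, cache$attn$cache, Wc = p$attn_Wc, Ws = p$attn_Ws)
    dcur <- ab$dF
    if (cfg$attention_learnable) {
      grads$attn_Wc <- ab$dWc
      grads$attn_Ws <- ab$dWs
    }
  } else {
    dcur <- dfeat
  }
  nblk <- length(cfg$channels)
  dP <- dcur
  for (k in rev(seq_len(nblk))) {
    lc <- cache$caches[[k]]
    dZ <- maxpool_backward(dP, lc$pool)
    dY <- dZ * lc$mask
    need_dx <- k > 1L || input_grad
    cb <- conv_backward(dY, lc$conv, p[[sprintf("conv%d_W", k)]], model$env,
                        need_dx = need_dx)
    grads[[sprintf("conv%d_W", k)]] <- cb$dW
    grads[[sprintf("conv%d_b", k)]] <- cb$db
    dP <- cb$dXm
  }
  dX <- NULL
  if (input_grad && !is.null(dP)) {
    s <- cfg$input_size
    dX <- mat_to_arr(dP, s, s, 3L, cache$B)
  }
  list(grads = grads, dX = dX)
}

# stack a list of H x W x 3 patches into a batch array
stack_patches <- function(patches) {
  d <- dim(patches[[1L]])
  X <- array(0, dim = c(d[1L], d[2L], 3L, length(patches)))
  for (i in seq_along(patches)) X[, , , i] <- patches[[i]]
  X
}

#' Predict the risk of one normalized tile
#'
#' @param model a [risk_model].
#' @param patch normalized `input_size x input_size x 3` array (see
#'   [normalize_imagenet()]).
#' @return finite scalar risk; higher value = higher hazard.
#' @export
predict_risk <- function(model, patch) {
  stopifnot(length(dim(patch)) == 3L)
  if (dim(patch)[1L] != model$config$input_size) {
    stop_validation("patch size %d does not match configured input size %d",
                    dim(patch)[1L], model$config$input_size)
  }
  risk_forward(model, stack_patches(list(patch)))$risk
}

#' Predict risks for many tiles
#'
#' @param model a [risk_model].
#' @param patches list of normalized tiles.
#' @param chunk internal batch size.
#' @return numeric vector of risks.
#' @export
predict_risk_batch <- function(model, patches, chunk = 32L) {
  out <- numeric(length(patches))
  i <- 1L
  while (i <= length(patches)) {
    j <- min(i + chunk - 1L, length(patches))
    out[i:j] <- risk_forward(model, stack_patches(patches[i:j]))$risk
    i <- j + 1L
  }
  out
}
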