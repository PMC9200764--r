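# Low-level neural-network layers, written against BLAS matrix products.
#
# Batches of feature maps travel in two interchangeable layouts:
#   array  (H, W, C, B)            -- spatial layout for convolutions
#   matrix (B*H*W) x C             -- rows grouped per sample (b-major),
#                                     within a sample column-major pixel
#                                     order p = y + (x-1)*H
# Convolutions are 3x3, stride 1, zero-padded ("same"); pooling is 2x2 max.

sigmoid <- function(x) 1 / (1 + exp(-x))

arr_to_mat <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1L, 2L, 4L, 3L)), d[1L] * d[2L] * d[4L], d[3L])
}

mat_to_arr <- function(M, H, W, C, B) {
  aperm(array(M, dim = c(H, W, B, C)), c(1L, 2L, 4L, 3L))
}

# single-sample im2col index matrix (H*W) x (9*C) into the zero-padded
# (H+2, W+2, C) array; column order: channel-major, then kernel dx, dy
conv_idx <- function(H, W, C) {
  Hp <- H + 2L; Wp <- W + 2L
  py <- rep(seq_len(H), times = W)
  px <- rep(seq_len(W), each = H)
  cols <- vector("list", 9L * C)
  i <- 0L
  for (c in seq_len(C)) {
    for (kx in -1:1) {
      for (ky in -1:1) {
        i <- i + 1L
        cols[[i]] <- (py + 1L + ky) + (px + kx) * Hp + (c - 1L) * Hp * Wp
      }
    }
  }
  do.call(cbind, cols)
}

pool_idx <- function(H, W) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  py <- rep(seq_len(H2), times = W2)
  px <- rep(seq_len(W2), each = H2)
  q <- function(dy, dx) (2L * py - 1L + dy) + (2L * px - 2L + dx) * H
  cbind(q(0L, 0L), q(1L, 0L), q(0L, 1L), q(1L, 1L))
}

# fetch (and memoise) batch-expanded index structures
get_idx <- function(env, key, builder) {
  if (is.null(env[[key]])) env[[key]] <- builder()
  env[[key]]
}

batch_rows <- function(idx, block, B, offset_unit) {
  idx[rep(seq_len(block), B), , drop = FALSE] +
    rep((seq_len(B) - 1L) * offset_unit, each = block)
}

conv_forward <- function(X, W, b, env) {
  d <- dim(X)
  H <- d[1L]; Wd <- d[2L]; C <- d[3L]; B <- d[4L]
  Hp <- H + 2L; Wp <- Wd + 2L
  idx <- get_idx(env, sprintf("conv_%d_%d_%d", H, Wd, C), function() conv_idx(H, Wd, C))
  bigidx <- get_idx(env, sprintf("convB_%d_%d_%d_%d", H, Wd, C, B),
                    function() batch_rows(idx, H * Wd, B, Hp * Wp * C))
  bigvec <- get_idx(env, sprintf("convV_%d_%d_%d_%d", H, Wd, C, B),
                    function() as.vector(bigidx))
  Xp <- array(0, dim = c(Hp, Wp, C, B))
  Xp[2:(H + 1L), 2:(Wd + 1L), , ] <- X
  M <- Xp[bigvec]
  dim(M) <- dim(bigidx)
  Y <- M %*% W
  Y <- Y + rep(b, each = nrow(Y))
  list(Y = Y, cache = list(M = M, H = H, W = Wd, C = C, B = B))
}

# Wt[(co, kx', ky'), ci] = W[(ci, -kx', -ky'), co]: kernel flip + channel
# transpose turning the input gradient into a plain convolution of dY
flip_perm <- function(Cin, Cout) {
  perm <- integer(9L * Cout * Cin)
  for (ci in seq_len(Cin)) {
    for (co in seq_len(Cout)) {
      for (kx in -1:1) {
        for (ky in -1:1) {
          rowt <- (co - 1L) * 9L + (kx + 1L) * 3L + (ky + 1L) + 1L
          rows <- (ci - 1L) * 9L + (-kx + 1L) * 3L + (-ky + 1L) + 1L
          perm[rowt + (ci - 1L) * 9L * Cout] <- rows + (co - 1L) * 9L * Cin
        }
      }
    }
  }
  perm
}

conv_backward <- function(dY, cache, W, env, need_dx = TRUE) {
  dW <- crossprod(cache$M, dY)
  db <- colSums(dY)
  dXm <- NULL
  if (need_dx) {
    H <- cache$H; Wd <- cache$W; Cin <- cache$C; B <- cache$B
    Cout <- ncol(dY)
    Hp <- H + 2L; Wp <- Wd + 2L
    idx <- get_idx(env, sprintf("conv_%d_%d_%d", H, Wd, Cout),
                   function() conv_idx(H, Wd, Cout))
    bigvec <- get_idx(env, sprintf("convV_%d_%d_%d_%d", H, Wd, Cout, B), function() {
      as.vector(batch_rows(idx, H * Wd, B, Hp * Wp * Cout))
    })
    dYp <- array(0, dim = c(Hp, Wp, Cout, B))
    dYp[2:(H + 1L), 2:(Wd + 1L), , ] <- mat_to_arr(dY, H, Wd, Cout, B)
    Md <- dYp[bigvec]
    dim(Md) <- c(H * Wd * B, 9L * Cout)
    perm <- get_idx(env, sprintf("flip_%d_%d", Cin, Cout),
                    function() flip_perm(Cin, Cout))
    Wt <- W[perm]
    dim(Wt) <- c(9L * Cout, Cin)
    dXm <- Md %*% Wt                      # matrix form (B*H*W) x Cin
  }
  list(dW = dW, db = db, dXm = dXm)
}

relu_forward <- function(Y, want_mask = TRUE) {
  mask <- Y > 0
  list(Z = Y * mask, mask = if (want_mask) mask else NULL)
}

maxpool_forward <- function(Z, H, W, B, env, want_cache = TRUE) {
  H2 <- H %/% 2L; W2 <- W %/% 2L
  idx <- get_idx(env, sprintf("pool_%d_%d", H, W), function() pool_idx(H, W))
  bigq <- get_idx(env, sprintf("poolB_%d_%d_%d", H, W, B),
                  function() batch_rows(idx, H2 * W2, B, H * W))
  n <- nrow(bigq)
  C <- ncol(Z)
  A <- Z[bigq[, 1L], , drop = FALSE]
  if (!want_cache) {
    for (k in 2:4) A <- pmax(A, Z[bigq[, k], , drop = FALSE])
    return(list(P = A, cache = NULL))
  }
  # one (n*C) x 4 comparison: max.col picks the winning quadrant per element
  Q <- cbind(as.vector(A),
             as.vector(Z[bigq[, 2L], , drop = FALSE]),
             as.vector(Z[bigq[, 3L], , drop = FALSE]),
             as.vector(Z[bigq[, 4L], , drop = FALSE]))
  mc <- max.col(Q, ties.method = "first")
  nC <- n * C
  P <- Q[seq_len(nC) + (mc - 1L) * nC]
  dim(P) <- c(n, C)
  rowv <- get_idx(env, sprintf("poolR_%d_%d", n, C),
                  function() rep.int(seq_len(n), C))
  src <- bigq[rowv + (mc - 1L) * n]
  dim(src) <- c(n, C)
  list(P = P, cache = list(src = src, n_in = nrow(Z), H2 = H2, W2 = W2))
}

maxpool_backward <- function(dP, cache) {
  n_in <- cache$n_in
  C <- ncol(dP)
  dZ <- matrix(0, n_in, C)
  lin <- as.vector(cache$src) + rep((seq_len(C) - 1L) * n_in, each = nrow(dP))
  dZ[lin] <- as.vector(dP)
  dZ
}

# --- attention gating --------------------------------------------------------

attn_forward <- function(F_mat, HW, B, Wc = NULL, Ws = NULL) {
  group <- rep(seq_len(B), each = HW)
  P <- if (is.null(Wc)) F_mat else F_mat %*% Wc
  cm <- rowsum(P, group) / HW            # B x D per-channel spatial means
  gc <- sigmoid(cm)
  sm <- if (is.null(Ws)) rowMeans(F_mat) else drop(F_mat %*% Ws)
  gs <- sigmoid(sm)                      # length B*HW per-pixel gates
  gc_exp <- gc[group, , drop = FALSE]
  out <- F_mat * (gc_exp + gs)
  list(out = out,
       cache = list(F = F_mat, gc = gc, gs = gs, gc_exp = gc_exp,
                    group = group, HW = HW, B = B))
}

attn_backward <- function(G, cache, Wc = NULL, Ws = NULL) {
  D <- ncol(G)
  dF <- G * (cache$gc_exp + cache$gs)
  GF <- G * cache$F
  # channel branch
  A <- rowsum(GF, cache$group)                       # B x D
  dcm <- A * cache$gc * (1 - cache$gc)
  dP <- (dcm / cache$HW)[cache$group, , drop = FALSE]
  dWc <- NULL
  if (is.null(Wc)) {
    dF <- dF + dP
  } else {
    dWc <- crossprod(cache$F, dP)
    dF <- dF + tcrossprod(dP, Wc)
  }
  # spatial branch
  tv <- rowSums(GF)
  dsm <- tv * cache$gs * (1 - cache$gs)
  dWs <- NULL
  if (is.null(Ws)) {
    dF <- dF + dsm / D
  } else {
    dWs <- crossprod(cache$F, matrix(dsm))
    dF <- dF + matrix(dsm) %*% t(Ws)
  }
  list(dF = dF, dWc = dWc, dWs = dWs)
}

#' Channel attention gates of a feature map
#'
#' Computes one gate per channel as the sigmoid of the channel's global
#' spatial mean. The default gating carries no learnable parameters, so a
#' model with and without attention has the same parameter count.
#'
#' @param F_arr `H x W x D` numeric feature map.
#' @return numeric vector of `D` gates, each strictly in `(0, 1)`.
#' @export
channel_attention <- function(F_arr) {
  stopifnot(length(dim(F_arr)) == 3L, all(is.finite(F_arr)))
  d <- dim(F_arr)
  sigmoid(colMeans(matrix(F_arr, d[1L] * d[2L], d[3L])))
}

#' Spatial attention gates of a feature map
#'
#' One gate per pixel: the sigmoid of the pixel's mean across channels.
#'
#' @param F_arr `H x W x D` numeric feature map.
#' @return `H x W` matrix of gates in `(0, 1)`.
#' @export
spatial_attention <- function(F_arr) {
  stopifnot(length(dim(F_arr)) == 3L, all(is.finite(F_arr)))
  d <- dim(F_arr)
  matrix(sigmoid(rowMeans(matrix(F_arr, d[1L] * d[2L], d[3L]))), d[1L], d[2L])
}

#' Attention-refined feature map
#'
#' Fuses channel and spatial gates with the input by element-wise
#' (Hadamard) products and sums the two branches:
#' `C_att(F) (x) F + S_att(F) (x) F`, gates broadcast over the missing axis.
#' Summation (rather than a product of branches) keeps gradient paths short.
#'
#' @param F_arr `H x W x D` numeric feature map.
#' @return refined feature map, same shape as the input.
#' @export
attention_fuse <- function(F_arr) {
  stopifnot(length(dim(F_arr)) == 3L, all(is.finite(F_arr)))
  d <- dim(F_arr)
  M <- matrix(F_arr, d[1L] * d[2L], d[3L])
  out <- attn_forward(M, HW = d[1L] * d[2L], B = 1L)$out
  array(out, dim = d)
}
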