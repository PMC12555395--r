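#' Self-attention block parameters
#'
#' The query and key projections share one parameter matrix `W_qk` whose
#' output width is the channel count divided by 4 — a deliberate
#' down-scaling that lightens the score computation and stabilizes the
#' attention distribution. `W_v` keeps full width, and `lbr` is the
#' linear + batchnorm + ReLU unit of the residual enhancement.
#'
#' @param C Channel count; must be divisible by 4.
#' @param qk_scale Down-scaling factor of the shared Q/K projection
#'   (fixed at 4).
#' @return List with `W_qk` (`C x C/4`), `W_v` (`C x C`), `lbr`.
#' @export
attention_params <- function(C, qk_scale = 4L) {
  if (C %% qk_scale != 0)
    stop("channel count must be divisible by ", qk_scale)
  list(W_qk = he_init(C, C %/% qk_scale),
       W_v = he_init(C, C),
       lbr = lbr_init(C, C))
}

#' Self-attention forward pass
#'
#' Computes `Q = K = F_in W_qk`, the attention score `S = Q K^T` (no
#' additional scaling factor — the 4x channel reduction of `W_qk` is the
#' stabilizer), row-wise softmax weights `A`, and the attended features
#' `F_sa = A (F_in W_v)`. Because Q and K share parameters the score matrix
#' is symmetric; the weight matrix is row-stochastic (each query row sums
#' to 1).
#'
#' @param F_in Numeric `N x C` input features, `C` divisible by 4.
#' @param params An [attention_params()].
#' @return List: `F_sa` (`N x C`) and `state` with `Q`, `K`, `V`,
#'   `score` (`N x N`), `weight` (row-stochastic `N x N`).
#' @export
self_attention_forward <- function(F_in, params) {
  F_in <- as.matrix(F_in)
  if (ncol(F_in) %% 4 != 0)
    stop("channel count must be divisible by 4")
  Q <- F_in %*% params$W_qk
  S <- tcrossprod(Q)                  # Q K^T with K = Q
  A <- row_softmax(S)
  V <- F_in %*% params$W_v
  F_sa <- A %*% V
  list(F_sa = F_sa,
       state = list(Q = Q, K = Q, V = V, score = S, weight = A))
}

# Backward of self_attention_forward. With shared W_qk, S = Q Q^T, so
# dQ = (dS + dS^T) Q.
self_attention_bwd <- function(dF_sa, F_in, state, params) {
  dA <- tcrossprod(dF_sa, state$V)    # dF_sa V^T
  dV <- crossprod(state$weight, dF_sa)
  dS <- row_softmax_bwd(dA, state$weight)
  dQ <- (dS + t(dS)) %*% state$Q
  dW_qk <- crossprod(F_in, dQ)
  dW_v <- crossprod(F_in, dV)
  dF <- dQ %*% t(params$W_qk) + dV %*% t(params$W_v)
  list(dF = dF, grad = list(W_qk = dW_qk, W_v = dW_v))
}

#' Laplacian-style residual enhancement
#'
#' Computes `LBR(F_in - F_sa) + F_in`. Because the attention weight matrix
#' `A` is row-stochastic, `F_in - A F_in = (I - A) F_in` acts like a
#' combinatorial graph Laplacian `D - E` applied to the features (row sums
#' of `I - A` are zero, so constants are annihilated); the enhancement
#' sharpens feature differences between points before the residual add.
#'
#' @param F_in,F_sa Numeric `N x C` matrices (input and attended features).
#' @param params An [attention_params()] (its `lbr` element is used).
#' @param mode Kept for API symmetry with the network forward; the
#'   normalization uses per-cloud statistics in both modes, so the result
#'   is identical and deterministic either way.
#' @return `N x C` enhanced features.
#' @export
laplacian_enhance <- function(F_in, F_sa, params, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (!identical(dim(F_in), dim(F_sa)))
    stop("F_in and F_sa must have identical shapes")
  lbr_fwd(F_in - F_sa, params$lbr)$out + F_in
}

attention_block_fwd <- function(F_in, params) {
  sa <- self_attention_forward(F_in, params)
  D <- F_in - sa$F_sa
  lb <- lbr_fwd(D, params$lbr)
  list(out = lb$out + F_in,
       cache = list(F_in = F_in, sa = sa, lbr = lb))
}

attention_block_bwd <- function(dY, cache, params) {
  lb <- lbr_bwd(dY, cache$lbr, params$lbr)
  dD <- lb$dX
  sab <- self_attention_bwd(-dD, cache$F_in, cache$sa$state, params)
  dF <- dY + dD + sab$dF
  list(dF = dF,
       grad = list(W_qk = sab$grad$W_qk, W_v = sab$grad$W_v,
                   lbr = lb$grad))
}

#' Multi-head attention parameters
#'
#' Standard multi-head generalization used by the ablation harness as a
#' drop-in replacement for the shared-projection attention: per-head Q/K
#' projections of width `d_qk` and V projections of width `C / n_heads`,
#' head outputs concatenated and mixed by an output projection `W_o`.
#'
#' @param C Channel count, divisible by `n_heads`.
#' @param n_heads Number of heads.
#' @param d_qk Per-head Q/K width (default `C / n_heads`).
#' @return List with `heads` (each `W_q`, `W_k`, `W_v`) and `W_o`.
#' @export
multihead_params <- function(C, n_heads, d_qk = NULL) {
  if (C %% n_heads != 0)
    stop("channel count must be divisible by n_heads")
  d_v <- C %/% n_heads
  if (is.null(d_qk)) d_qk <- d_v
  heads <- lapply(seq_len(n_heads), function(h)
    list(W_q = he_init(C, d_qk), W_k = he_init(C, d_qk),
         W_v = he_init(C, d_v)))
  names(heads) <- paste0("head", seq_len(n_heads))
  list(heads = heads, W_o = diag(C))
}

#' Multi-head attention forward pass
#'
#' @param F_in Numeric `N x C` input features.
#' @param params A [multihead_params()].
#' @param with_cache Also return the cache for the backward pass.
#' @return `N x C` matrix, or `list(out, cache)` when `with_cache`.
#' @export
multihead_attention_forward <- function(F_in, params, with_cache = FALSE) {
  F_in <- as.matrix(F_in)
  hs <- lapply(params$heads, function(hp) {
    Q <- F_in %*% hp$W_q
    K <- F_in %*% hp$W_k
    A <- row_softmax(tcrossprod(Q, K))
    V <- F_in %*% hp$W_v
    list(Q = Q, K = K, V = V, A = A, out = A %*% V)
  })
  cat_out <- do.call(cbind, lapply(hs, `[[`, "out"))
  out <- cat_out %*% params$W_o
  if (!with_cache) return(out)
  list(out = out, cache = list(F_in = F_in, heads = hs, cat_out = cat_out))
}

multihead_attention_bwd <- function(dY, cache, params) {
  F_in <- cache$F_in
  dCat <- dY %*% t(params$W_o)
  dW_o <- crossprod(cache$cat_out, dY)
  dF <- matrix(0, nrow(F_in), ncol(F_in))
  gheads <- vector("list", length(params$heads))
  off <- 0L
  for (h in seq_along(params$heads)) {
    hp <- params$heads[[h]]
    hc <- cache$heads[[h]]
    d_v <- ncol(hp$W_v)
    dOut <- dCat[, off + seq_len(d_v), drop = FALSE]
    off <- off + d_v
    dA <- tcrossprod(dOut, hc$V)
    dV <- crossprod(hc$A, dOut)
    dS <- row_softmax_bwd(dA, hc$A)
    dQ <- dS %*% hc$K
    dK <- crossprod(dS, hc$Q)
    gheads[[h]] <- list(W_q = crossprod(F_in, dQ),
                        W_k = crossprod(F_in, dK),
                        W_v = crossprod(F_in, dV))
    dF <- dF + dQ %*% t(hp$W_q) + dK %*% t(hp$W_k) + dV %*% t(hp$W_v)
  }
  names(gheads) <- names(params$heads)
  list(dF = dF, grad = list(heads = gheads, W_o = dW_o))
}
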