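# Minimal dense-layer toolkit with explicit forward caches and hand-derived
# backward passes. All layers operate on N x C matrices (one row per point);
# parameters are plain nested lists of numeric leaves so a whole model can be
# walked generically by the optimizer.

BN_EPS <- 1e-5

he_init <- function(n_in, n_out) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / n_in)), n_in, n_out)
}

linear_init <- function(n_in, n_out, zero = FALSE) {
  list(W = if (zero) matrix(0, n_in, n_out) else he_init(n_in, n_out),
       b = numeric(n_out))
}

linear_fwd <- function(X, p) {
  list(out = X %*% p$W + rep(p$b, each = nrow(X)), X = X)
}

linear_bwd <- function(dY, cache, p) {
  list(dX = dY %*% t(p$W),
       grad = list(W = crossprod(cache$X, dY), b = colSums(dY)))
}

relu_fwd <- function(X) list(out = pmax(X, 0), mask = X > 0)
relu_bwd <- function(dY, cache) dY * cache$mask

# Per-cloud ("instance") batch normalization: per-channel statistics over
# the N points of the cloud at hand, in training and at eval alike. This
# keeps the normalization the network trains with identical to the one it
# is evaluated with, and an eval forward is a deterministic function of a
# single cloud (no state carried between clouds).
bn_init <- function(C) {
  list(gamma = rep(1, C), beta = numeric(C))
}

bn_fwd <- function(X, p) {
  n <- nrow(X)
  mu <- colMeans(X)
  xc <- X - rep(mu, each = n)
  v <- colMeans(xc^2)
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(istd, each = n)
  out <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  list(out = out, xhat = xhat, istd = istd)
}

bn_bwd <- function(dY, cache, p) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(p$gamma, each = n)
  # standard backward through the per-cloud mean and variance
  dX <- (dxhat - rep(colMeans(dxhat), each = n) -
           cache$xhat * rep(colMeans(dxhat * cache$xhat), each = n)) *
    rep(cache$istd, each = n)
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

# Layer normalization: per-row statistics across channels. Used where a
# single pooled vector must be normalized (batch statistics are undefined
# for one row).
ln_init <- function(C) list(gamma = rep(1, C), beta = numeric(C))

ln_fwd <- function(X, p) {
  mu <- rowMeans(X)
  xc <- X - mu
  v <- rowMeans(xc^2)
  istd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * istd
  n <- nrow(X)
  out <- xhat * rep(p$gamma, each = n) + rep(p$beta, each = n)
  list(out = out, xhat = xhat, istd = istd)
}

ln_bwd <- function(dY, cache, p) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(p$gamma, each = n)
  dX <- (dxhat - rowMeans(dxhat) -
           cache$xhat * rowMeans(dxhat * cache$xhat)) * cache$istd
  list(dX = dX, grad = list(gamma = dgamma, beta = dbeta))
}

# LBR = linear + batchnorm + ReLU, the attention block's residual unit.
lbr_init <- function(n_in, n_out) {
  list(lin = linear_init(n_in, n_out), bn = bn_init(n_out))
}

lbr_fwd <- function(X, p) {
  l <- linear_fwd(X, p$lin)
  b <- bn_fwd(l$out, p$bn)
  r <- relu_fwd(b$out)
  list(out = r$out, lin = l, bn = b, relu = r)
}

lbr_bwd <- function(dY, cache, p) {
  d <- relu_bwd(dY, cache$relu)
  b <- bn_bwd(d, cache$bn, p$bn)
  l <- linear_bwd(b$dX, cache$lin, p$lin)
  list(dX = l$dX, grad = list(lin = l$grad, bn = b$grad))
}

# Inverted dropout: active only in training; consumes the session RNG.
dropout_fwd <- function(X, rate, train) {
  if (!train || rate <= 0) return(list(out = X, mask = NULL))
  mask <- matrix(stats::runif(length(X)) >= rate, nrow(X)) / (1 - rate)
  list(out = X * mask, mask = mask)
}

dropout_bwd <- function(dY, cache) {
  if (is.null(cache$mask)) dY else dY * cache$mask
}

# Numerically safe row-wise softmax.
row_softmax <- function(S) {
  mx <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  e <- exp(S - mx)
  e / rowSums(e)
}

# d/dS of row_softmax given upstream dA.
row_softmax_bwd <- function(dA, A) {
  A * (dA - rowSums(dA * A))
}

# --- generic nested-list parameter utilities --------------------------------

# Sum two structurally identical gradient trees leaf-wise.
grad_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.list(a)) mapply(grad_add, a, b, SIMPLIFY = FALSE) else a + b
}

grad_scale <- function(g, s) {
  if (is.list(g)) lapply(g, grad_scale, s = s) else g * s
}

# Overall L2 norm of a gradient (sub)tree.
grad_norm <- function(g) sqrt(sum(param_flatten(g)^2))

# Flatten all numeric leaves into one vector.
param_flatten <- function(p) {
  if (is.list(p)) unlist(lapply(p, param_flatten), use.names = FALSE)
  else if (is.numeric(p)) as.numeric(p) else numeric(0)
}

# Overwrite the numeric leaves from a flat vector (same traversal order).
param_set_flat <- function(params, values) {
  param_unflatten(params, values)$node
}

# Refill the numeric leaves of a nested structure from a flat vector
# (inverse of param_flatten).
param_unflatten <- function(template, values, pos = 1L) {
  if (is.list(template)) {
    out <- template
    for (i in seq_along(template)) {
      r <- param_unflatten(template[[i]], values, pos)
      out[[i]] <- r$node
      pos <- r$pos
    }
    list(node = out, pos = pos)
  } else if (is.numeric(template)) {
    n <- length(template)
    node <- template
    node[] <- values[pos:(pos + n - 1L)]
    list(node = node, pos = pos + n)
  } else list(node = template, pos = pos)
}

# One SGD step with momentum and weight decay (torch convention:
# v <- mu*v + (g + wd*p); p <- p - lr*v). The gradient tree's named leaves
# drive the recursion, so batch-norm running state is never updated here.
sgd_step <- function(params, grads, vel, lr, momentum, weight_decay) {
  step <- function(p, g, v) {
    if (is.list(g)) {
      if (is.null(v)) v <- vector("list", length(g))
      for (i in seq_along(g)) {
        nm <- names(g)[i]
        r <- step(p[[nm]], g[[i]], v[[i]])
        p[[nm]] <- r$p
        v[[i]] <- r$v
      }
      names(v) <- names(g)
      list(p = p, v = v)
    } else {
      gg <- g + weight_decay * p
      v <- if (is.null(v)) gg else momentum * v + gg
      list(p = p - lr * v, v = v)
    }
  }
  step(params, grads, vel)
}
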