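#' Model configuration
#'
#' Architecture hyperparameters of the segmentation network: stacked GCASM
#' units (graph aggregation + self-attention + Laplacian-style enhancement),
#' an optional learned 3x3 alignment (Trans-net), a fuse MLP producing one
#' global feature vector per cloud, and a per-point segmentation head.
#'
#' @param n_classes Number of organ classes `P` (>= 2).
#' @param n_gcasm_layers Number of stacked GCASM units (default 3).
#' @param channels Integer vector of per-layer output widths (default
#'   `c(64, 64, 64)`); all divisible by 4.
#' @param k Local graph size including the center point (default 30).
#' @param global_dim Width of the pooled global feature (default 1024).
#' @param head_dims Widths of the two hidden head layers (default
#'   `c(512, 256)`).
#' @param dropout_rate Head dropout rate (default 0.5).
#' @param attn_variant `"gcasm"` (shared-projection attention with
#'   Laplacian enhancement, the default), `"general"` (unshared
#'   single-head), `"multihead4"` or `"multihead8"`.
#' @param graph_metric Neighborhood metric, see [neighborhood_score()].
#' @param weight_sq_euclid Distance weight for `graph_metric = "weighted"`.
#' @param graph_space `"features"` (dynamic graph: each layer's kNN is
#'   computed on its own input features) or `"coords"` (static graph on the
#'   aligned coordinates).
#' @param use_transnet Include the learned 3x3 alignment (default `TRUE`).
#' @return A `model_config` list.
#' @export
model_config <- function(n_classes,
                         n_gcasm_layers = 3L,
                         channels = rep(64L, n_gcasm_layers),
                         k = 30L,
                         global_dim = 1024L,
                         head_dims = c(512L, 256L),
                         dropout_rate = 0.5,
                         attn_variant = c("gcasm", "general",
                                          "multihead4", "multihead8"),
                         graph_metric = c("sq_euclidean", "cosine",
                                          "pearson", "weighted"),
                         weight_sq_euclid = 0.7,
                         graph_space = c("features", "coords"),
                         use_transnet = TRUE) {
  attn_variant <- match.arg(attn_variant)
  graph_metric <- match.arg(graph_metric)
  graph_space <- match.arg(graph_space)
  n_gcasm_layers <- as.integer(n_gcasm_layers)
  channels <- as.integer(channels)
  if (n_gcasm_layers < 1L) stop("need at least one GCASM layer")
  if (length(channels) != n_gcasm_layers)
    stop("channels must list one width per GCASM layer")
  if (any(channels %% 4L != 0L))
    stop("all channel widths must be divisible by 4")
  if (n_classes < 2L) stop("need at least 2 classes")
  if (k < 1L) stop("k must be >= 1")
  structure(list(n_classes = as.integer(n_classes),
                 n_gcasm_layers = n_gcasm_layers, channels = channels,
                 k = as.integer(k), global_dim = as.integer(global_dim),
                 head_dims = as.integer(head_dims),
                 dropout_rate = dropout_rate, attn_variant = attn_variant,
                 graph_metric = graph_metric,
                 weight_sq_euclid = weight_sq_euclid,
                 graph_space = graph_space, use_transnet = use_transnet),
            class = "model_config")
}

#' Reduced configuration for desk-scale experiments
#'
#' A deliberately small network — one GCASM layer of width 32, `k = 10`,
#' a 256-wide global feature and a (128, 64) head — sized so that training
#' on a few dozen 512-point synthetic plants takes minutes on one CPU while
#' exercising every architectural component of the full model.
#'
#' @param n_classes Number of classes (default 2: stem vs leaf).
#' @param ... Overrides passed to [model_config()].
#' @return A `model_config`.
#' @export
reduced_model_config <- function(n_classes = 2L, ...) {
  args <- utils::modifyList(
    list(n_classes = n_classes, n_gcasm_layers = 1L, channels = 32L,
         k = 10L, global_dim = 256L, head_dims = c(128L, 64L)),
    list(...))
  do.call(model_config, args)
}

variant_heads <- function(variant) {
  switch(variant, general = 1L, multihead4 = 4L, multihead8 = 8L, 0L)
}

gcasm_layer_init <- function(c_in, c_out, config) {
  attn <- if (config$attn_variant == "gcasm") attention_params(c_out)
          else multihead_params(c_out, variant_heads(config$attn_variant),
                                d_qk = max(1L, c_out %/% 4L))
  list(graph = graph_block_params(c_in, c_out), attn = attn)
}

#' Initialize model parameters
#'
#' He-initialized weights throughout, except the final Trans-net layer which
#' starts at exactly zero so the predicted transform begins as the 3x3
#' identity (standard spatial-transformer practice: a random 3x3 at step 0
#' would destroy the input geometry).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for the weight draw.
#' @return Nested parameter list (`transnet`, `gcasm_layers`, `fuse`,
#'   `head`).
#' @export
gcassn_init <- function(config, seed = 1L) {
  with_seed(seed, {
    ch <- config$channels
    layers <- vector("list", config$n_gcasm_layers)
    c_in <- 3L
    for (l in seq_len(config$n_gcasm_layers)) {
      layers[[l]] <- gcasm_layer_init(c_in, ch[l], config)
      c_in <- ch[l]
    }
    names(layers) <- paste0("layer", seq_len(config$n_gcasm_layers))
    transnet <- if (config$use_transnet) list(
      gcasm = gcasm_layer_init(3L, ch[1L], config),
      mlp = lbr_init(ch[1L], config$global_dim),
      fc1 = linear_init(config$global_dim, 512L),
      ln1 = ln_init(512L),
      fc2 = linear_init(512L, 256L),
      ln2 = ln_init(256L),
      fc3 = linear_init(256L, 9L, zero = TRUE))
    head_in <- 3L + sum(ch) + config$global_dim
    list(transnet = transnet,
         gcasm_layers = layers,
         fuse = lbr_init(sum(ch), config$global_dim),
         head = list(h1 = lbr_init(head_in, config$head_dims[1L]),
                     h2 = lbr_init(config$head_dims[1L],
                                   config$head_dims[2L]),
                     h3 = linear_init(config$head_dims[2L],
                                      config$n_classes)))
  })
}

# --- GCASM unit -------------------------------------------------------------

gcasm_fwd <- function(F, coords, layer_params, config, train) {
  space <- if (config$graph_space == "features") F else coords
  sc <- neighborhood_score(space, config$graph_metric,
                           config$weight_sq_euclid)
  idx <- knn_graph(sc, config$k)
  ga <- graph_aggregate(F, idx, layer_params$graph, with_cache = TRUE)
  if (config$attn_variant == "gcasm") {
    at <- attention_block_fwd(ga$out, layer_params$attn)
    out <- at$out
    atc <- at$cache
  } else {
    mh <- multihead_attention_forward(ga$out, layer_params$attn,
                                      with_cache = TRUE)
    out <- ga$out + mh$out
    atc <- mh$cache
  }
  list(out = out, cache = list(ga = ga$cache, attn = atc, idx = idx))
}

gcasm_bwd <- function(dY, cache, layer_params, config, train) {
  if (config$attn_variant == "gcasm") {
    ab <- attention_block_bwd(dY, cache$attn, layer_params$attn)
    dF1 <- ab$dF
    gattn <- ab$grad
  } else {
    mb <- multihead_attention_bwd(dY, cache$attn, layer_params$attn)
    dF1 <- dY + mb$dF
    gattn <- mb$grad
  }
  gb <- graph_aggregate_bwd(dF1, cache$ga, layer_params$graph)
  list(dF = gb$dF, grad = list(graph = gb$grad, attn = gattn))
}

#' One GCASM unit forward pass (eval mode)
#'
#' Composes, in order: kNN local-graph aggregation on the unit's own input
#' features, self-attention, and the Laplacian-style residual enhancement.
#'
#' @param F Numeric `N x C_in` input features.
#' @param layer_params One element of the `gcasm_layers` list from
#'   [gcassn_init()].
#' @param config A [model_config()].
#' @return `N x C_out` updated features.
#' @export
gcasm_forward <- function(F, layer_params, config) {
  gcasm_fwd(as.matrix(F), as.matrix(F), layer_params, config,
            train = FALSE)$out
}

# --- Trans-net --------------------------------------------------------------

# Column-wise max pool over points with argmax kept for the backward pass.
pool_rows_fwd <- function(X) {
  arg <- max.col(t(X), ties.method = "first")
  list(out = matrix(X[cbind(arg, seq_len(ncol(X)))], 1L), arg = arg)
}

pool_rows_bwd <- function(dvec, arg, n) {
  dX <- matrix(0, n, length(arg))
  dX[cbind(arg, seq_along(arg))] <- dvec
  dX
}

transnet_fwd <- function(X, params, config, train) {
  g <- gcasm_fwd(X, X, params$gcasm, config, train)
  m <- lbr_fwd(g$out, params$mlp)
  pool <- pool_rows_fwd(m$out)
  f1 <- linear_fwd(pool$out, params$fc1)
  l1 <- ln_fwd(f1$out, params$ln1)
  r1 <- relu_fwd(l1$out)
  f2 <- linear_fwd(r1$out, params$fc2)
  l2 <- ln_fwd(f2$out, params$ln2)
  r2 <- relu_fwd(l2$out)
  f3 <- linear_fwd(r2$out, params$fc3)
  # tanh-bounded offset from the identity: the transform stays a moderate
  # pose correction and its gradient saturates instead of running away
  # under the high reference learning rate; zero init still yields exactly
  # the identity transform
  A <- tanh(as.vector(f3$out))
  M <- matrix(A, 3L, 3L) + diag(3)
  list(M = M,
       cache = list(g = g, m = m, pool = pool, n = nrow(X), A = A,
                    f1 = f1, l1 = l1, r1 = r1, f2 = f2, l2 = l2,
                    r2 = r2, f3 = f3))
}

transnet_bwd <- function(dM, cache, params, config, train) {
  # activity penalty on the pre-tanh offset keeps the transform a mild
  # pose correction; applied pre-squashing so the pull persists even if
  # the tanh saturates early in training
  d9 <- matrix(as.vector(dM) * (1 - cache$A^2) +
                 2 * TRANSNET_TETHER_LAMBDA * as.vector(cache$f3$out), 1L)
  b3 <- linear_bwd(d9, cache$f3, params$fc3)
  n2 <- ln_bwd(relu_bwd(b3$dX, cache$r2), cache$l2, params$ln2)
  b2 <- linear_bwd(n2$dX, cache$f2, params$fc2)
  n1 <- ln_bwd(relu_bwd(b2$dX, cache$r1), cache$l1, params$ln1)
  b1 <- linear_bwd(n1$dX, cache$f1, params$fc1)
  dPool <- pool_rows_bwd(as.vector(b1$dX), cache$pool$arg, cache$n)
  mb <- lbr_bwd(dPool, cache$m, params$mlp)
  gb <- gcasm_bwd(mb$dX, cache$g$cache, params$gcasm, config, train)
  list(grad = list(gcasm = gb$grad, mlp = mb$grad,
                   fc1 = b1$grad, ln1 = n1$grad,
                   fc2 = b2$grad, ln2 = n2$grad, fc3 = b3$grad))
}

#' Predict the 3x3 alignment transform for a cloud (eval mode)
#'
#' The alignment sub-network pools GCASM features through an MLP to one
#' global vector, maps it down 512 -> 256 -> 9, and reshapes the 9-vector —
#' added to the flattened identity — into a 3x3 matrix. At initialization
#' the transform is exactly the identity.
#'
#' @param coords Numeric `N x 3` coordinates (`N >= k`).
#' @param params The `transnet` element of [gcassn_init()] output.
#' @param config A [model_config()].
#' @return A 3x3 transform matrix.
#' @export
transnet_forward <- function(coords, params, config) {
  coords <- as.matrix(coords)
  if (nrow(coords) < config$k)
    stop("cloud must contain at least k points")
  transnet_fwd(coords, params, config, train = FALSE)$M
}

#' Apply a 3x3 transform to a cloud
#'
#' Row-vector convention: each output row is `x^T M`.
#'
#' @param coords Numeric `N x 3` matrix.
#' @param M 3x3 transform matrix.
#' @return Transformed `N x 3` matrix.
#' @export
apply_transform <- function(coords, M) {
  coords <- as.matrix(coords)
  if (!all(dim(M) == c(3L, 3L))) stop("M must be 3x3")
  if (ncol(coords) != 3L) stop("coords must be N x 3")
  coords %*% M
}

# --- full network -----------------------------------------------------------

gcassn_fwd_full <- function(X, params, config, train) {
  if (nrow(X) < config$k) stop("cloud must contain at least k points")
  if (config$use_transnet) {
    tn <- transnet_fwd(X, params$transnet, config, train)
    Xp <- X %*% tn$M
  } else {
    tn <- NULL
    Xp <- X
  }
  L <- config$n_gcasm_layers
  feats <- vector("list", L)
  caches <- vector("list", L)
  Fcur <- Xp
  for (l in seq_len(L)) {
    r <- gcasm_fwd(Fcur, Xp, params$gcasm_layers[[l]], config, train)
    feats[[l]] <- r$out
    caches[[l]] <- r$cache
    Fcur <- r$out
  }
  cat_feats <- do.call(cbind, feats)
  fu <- lbr_fwd(cat_feats, params$fuse)
  pool <- pool_rows_fwd(fu$out)
  n <- nrow(X)
  H <- cbind(Xp, cat_feats,
             matrix(pool$out, n, config$global_dim, byrow = TRUE))
  h1 <- lbr_fwd(H, params$head$h1)
  d1 <- dropout_fwd(h1$out, config$dropout_rate, train)
  h2 <- lbr_fwd(d1$out, params$head$h2)
  d2 <- dropout_fwd(h2$out, config$dropout_rate, train)
  h3 <- linear_fwd(d2$out, params$head$h3)
  list(logits = h3$out,
       cache = list(X = X, tn = tn, Xp = Xp, caches = caches,
                    fu = fu, pool = pool, n = n,
                    h1 = h1, d1 = d1, h2 = h2, d2 = d2, h3 = h3))
}

gcassn_bwd_full <- function(dLogits, cache, params, config, train) {
  ch <- config$channels
  L <- config$n_gcasm_layers
  n <- cache$n
  b3 <- linear_bwd(dLogits, cache$h3, params$head$h3)
  b2 <- lbr_bwd(dropout_bwd(b3$dX, cache$d2), cache$h2, params$head$h2)
  b1 <- lbr_bwd(dropout_bwd(b2$dX, cache$d1), cache$h1, params$head$h1)
  dH <- b1$dX
  dXp <- dH[, 1:3, drop = FALSE]
  off <- 3L
  dFeats <- vector("list", L)
  for (l in seq_len(L)) {
    dFeats[[l]] <- dH[, off + seq_len(ch[l]), drop = FALSE]
    off <- off + ch[l]
  }
  dg <- colSums(dH[, off + seq_len(config$global_dim), drop = FALSE])
  dFu <- pool_rows_bwd(dg, cache$pool$arg, n)
  fub <- lbr_bwd(dFu, cache$fu, params$fuse)
  off <- 0L
  for (l in seq_len(L)) {
    dFeats[[l]] <- dFeats[[l]] + fub$dX[, off + seq_len(ch[l]), drop = FALSE]
    off <- off + ch[l]
  }
  glayers <- vector("list", L)
  dCur <- matrix(0, n, ch[L])
  for (l in rev(seq_len(L))) {
    dCur <- dCur + dFeats[[l]]
    gb <- gcasm_bwd(dCur, cache$caches[[l]], params$gcasm_layers[[l]],
                    config, train)
    glayers[[l]] <- gb$grad
    dCur <- gb$dF
  }
  names(glayers) <- paste0("layer", seq_len(L))
  dXp <- dXp + dCur
  grads <- list(gcasm_layers = glayers, fuse = fub$grad,
                head = list(h1 = b1$grad, h2 = b2$grad, h3 = b3$grad))
  if (config$use_transnet) {
    dM <- crossprod(cache$X, dXp)
    tb <- transnet_bwd(dM, cache$tn$cache, params$transnet, config, train)
    grads <- c(list(transnet = tb$grad), grads)
  }
  grads
}

TRANSNET_TETHER_LAMBDA <- 0.05

#' Full network forward pass
#'
#' Pipeline: (1) the alignment sub-network re-poses the cloud; (2) the
#' stacked GCASM units produce multi-level features; (3) their concatenation
#' passes through a shared MLP to the global width and is max-pooled into
#' one global feature vector; (4) per point, the aligned coordinates, all
#' GCASM features and the broadcast global feature feed the segmentation
#' head, producing `N x P` logits.
#'
#' @param cloud A [labeled_cloud()] or plain `N x 3` matrix (`N >= k`).
#' @param params Parameters from [gcassn_init()].
#' @param config A [model_config()].
#' @param mode `"eval"` (deterministic: running batchnorm statistics, no
#'   dropout) or `"train"`.
#' @return A `segmentation_result`: list with `logits` (`N x P`) and
#'   `predicted` (length-`N` argmax labels in `0..P-1`, lowest class index
#'   on ties).
#' @export
gcassn_forward <- function(cloud, params, config, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  X <- if (inherits(cloud, "labeled_cloud")) cloud$coords else as.matrix(cloud)
  r <- gcassn_fwd_full(X, params, config, train = (mode == "train"))
  structure(list(logits = r$logits,
                 predicted = max.col(r$logits, ties.method = "first") - 1L),
            class = "segmentation_result")
}

#' Count learnable parameters
#'
#' Exact count of learnable scalars for a configuration, decomposable per
#' sub-module.
#'
#' @param config A [model_config()].
#' @return Integer total with a named `breakdown` attribute.
#' @export
count_parameters <- function(config) {
  p <- gcassn_init(config, seed = 0L)
  parts <- vapply(p[!vapply(p, is.null, TRUE)],
                  function(x) length(param_flatten(x)), numeric(1))
  structure(as.integer(sum(parts)), breakdown = parts)
}

# --- checkpointing ----------------------------------------------------------

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Save / load a model checkpoint
#'
#' A plain-text JSON archive holding the configuration, its hash, and every
#' parameter leaf flattened to one numeric vector. The loader refuses an archive whose stored configuration
#' hash does not match the configuration it re-builds.
#'
#' @param params,config Model parameters and configuration.
#' @param path Destination / source file.
#' @return `save_model`: `path` invisibly. `load_model`: list with
#'   `params` and `config`.
#' @export
save_model <- function(params, config, path) {
  obj <- list(config = unclass(config),
              config_hash = config_hash(config),
              values = param_flatten(params))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cfg <- obj$config
  config <- model_config(n_classes = cfg$n_classes,
                         n_gcasm_layers = cfg$n_gcasm_layers,
                         channels = cfg$channels, k = cfg$k,
                         global_dim = cfg$global_dim,
                         head_dims = cfg$head_dims,
                         dropout_rate = cfg$dropout_rate,
                         attn_variant = cfg$attn_variant,
                         graph_metric = cfg$graph_metric,
                         weight_sq_euclid = cfg$weight_sq_euclid,
                         graph_space = cfg$graph_space,
                         use_transnet = cfg$use_transnet)
  if (!identical(config_hash(config), obj$config_hash))
    stop("checkpoint config hash mismatch; refusing to load")
  template <- gcassn_init(config, seed = 0L)
  flat <- param_flatten(template)
  if (length(flat) != length(obj$values))
    stop("checkpoint parameter count does not match the configuration")
  params <- param_unflatten(template, obj$values)$node
  list(params = params, config = config)
}
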