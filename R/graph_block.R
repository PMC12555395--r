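#' Pairwise neighborhood scores between point features
#'
#' Scores every pair of points for local-graph construction, in a
#' "smaller = closer" orientation for all metrics. `sq_euclidean` is the
#' squared Euclidean distance (computed with the
#' \eqn{\|x\|^2 + \|y\|^2 - 2 x\cdot y} identity, clamped at zero);
#' `cosine` and `pearson` are converted to dissimilarities
#' \eqn{1 - \mathrm{sim}}; `weighted` linearly combines the per-cloud
#' max-normalized squared distance with the cosine dissimilarity:
#' \eqn{w \, d^2/\max d^2 + (1-w)(1-\cos)}.
#'
#' A zero-norm row under `cosine` (or zero-variance row under `pearson`) has
#' no direction: it scores dissimilarity 1 to every other point and 0 to
#' itself, never `NaN`.
#'
#' @param F Numeric `N x C` feature matrix (`N >= 2`).
#' @param metric One of `"sq_euclidean"`, `"cosine"`, `"pearson"`,
#'   `"weighted"`.
#' @param weight_sq_euclid Weight `w` in `[0, 1]` on the distance term
#'   (only for `metric = "weighted"`; default 0.7).
#' @return An object of class `neighborhood_score`: list with the `N x N`
#'   `matrix`, `metric`, and `weight_sq_euclid`.
#' @examples
#' F <- rbind(c(1, 2, 2), c(0, 0, 0))
#' neighborhood_score(F)$matrix[1, 2]   # 1 + 4 + 4 = 9
#' @export
neighborhood_score <- function(F,
                               metric = c("sq_euclidean", "cosine",
                                          "pearson", "weighted"),
                               weight_sq_euclid = 0.7) {
  metric <- match.arg(metric)
  F <- as.matrix(F)
  if (nrow(F) < 2L) stop("need at least 2 points")
  if (metric == "weighted" &&
      (weight_sq_euclid < 0 || weight_sq_euclid > 1))
    stop("weight_sq_euclid must be in [0, 1]")
  m <- switch(metric,
    sq_euclidean = sq_dist(F),
    cosine = 1 - cosine_sim(F),
    pearson = 1 - pearson_sim(F),
    weighted = {
      d2 <- sq_dist(F)
      mx <- max(d2)
      if (mx > 0) d2 <- d2 / mx
      weight_sq_euclid * d2 + (1 - weight_sq_euclid) * (1 - cosine_sim(F))
    })
  structure(list(matrix = m, metric = metric,
                 weight_sq_euclid = weight_sq_euclid),
            class = "neighborhood_score")
}

sq_dist <- function(F) {
  sq <- rowSums(F^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(F)
  d2[d2 < 0] <- 0
  diag(d2) <- 0
  d2
}

cosine_sim <- function(F) {
  nrm <- sqrt(rowSums(F^2))
  degen <- nrm == 0
  nrm[degen] <- 1
  S <- tcrossprod(F / nrm)
  S[S > 1] <- 1
  S[S < -1] <- -1
  if (any(degen)) {
    S[degen, ] <- 0
    S[, degen] <- 0
  }
  diag(S) <- 1
  S
}

pearson_sim <- function(F) {
  Fc <- F - rowMeans(F)
  cosine_sim(Fc)
}

#' k-nearest-neighbor local graph from a score matrix
#'
#' Row `i` lists the `k` member indices of point `i`'s local graph: the
#' center itself first, then its `k - 1` closest points by ascending score.
#' Ties are broken by ascending point index, making the result fully
#' deterministic.
#'
#' @param score A [neighborhood_score()] or a plain `N x N` score matrix.
#' @param k Local graph size including the center (`1 <= k <= N`).
#' @return Integer `N x k` matrix of neighbor indices; column 1 is
#'   `1..N`.
#' @export
knn_graph <- function(score, k) {
  m <- if (inherits(score, "neighborhood_score")) score$matrix else score
  n <- nrow(m)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be >= 1")
  if (k > n) stop("k cannot exceed the number of points")
  .knn_select(m, k)
}

#' Edge features of a local graph
#'
#' The edge from center `i` to neighbor `j` is the feature difference
#' `F[j, ] - F[i, ]`; self edges are zero. Differences are translation
#' invariant, which is what makes them encode local geometry.
#'
#' @param F Numeric `N x C` feature matrix.
#' @param neighbor_idx Integer `N x K` neighbor matrix from [knn_graph()].
#' @return Numeric `N x K x C` array of edge features.
#' @export
edge_features <- function(F, neighbor_idx) {
  F <- as.matrix(F)
  n <- nrow(F)
  if (any(neighbor_idx < 1L) || any(neighbor_idx > n))
    stop("neighbor index out of range")
  K <- ncol(neighbor_idx)
  # gather neighbors as an (N*K) x C matrix, subtract the repeated centers
  nb <- F[as.vector(neighbor_idx), , drop = FALSE]
  ctr <- F[rep(seq_len(n), times = K), , drop = FALSE]
  array(nb - ctr, dim = c(n, K, ncol(F)))
}

#' Graph Creation Block parameters
#'
#' One shared per-edge linear map ("1x1 convolution") taking the spliced
#' center-plus-edge feature of width `2C` to `C_out`, followed — as is
#' conventional for edge convolutions — by per-channel batch normalization
#' over all edges before the activation (without it the reference training
#' recipe, SGD at learning rate 0.1, is unstable). Set
#' `batchnorm = FALSE` for the bare conv + ReLU + max chain.
#'
#' @param c_in Input feature width `C`.
#' @param c_out Output width.
#' @param batchnorm Include the edge batch normalization (default `TRUE`).
#' @return List with `conv = list(W (2C x C_out), b)` and optionally `bn`.
#' @export
graph_block_params <- function(c_in, c_out, batchnorm = TRUE) {
  c(list(conv = linear_init(2L * c_in, c_out)),
    if (batchnorm) list(bn = bn_init(c_out)))
}

#' Graph aggregation: conv + ReLU + max over the local graph
#'
#' For every center `i`, the `K` spliced rows
#' \eqn{(F_i \,\|\, e_{ij}) \in R^{2C}} pass through the shared linear map
#' and ReLU; element-wise max pooling over the `K` rows yields one `C_out`
#' vector per point:
#' \deqn{F_{graph} = \max(\mathrm{relu}(\mathrm{conv}(F_{concate})))}
#'
#' @param F Numeric `N x C` feature matrix.
#' @param neighbor_idx Integer `N x K` matrix from [knn_graph()].
#' @param params A [graph_block_params()] with input width `2C`.
#' @param with_cache Return the cache needed by [graph_aggregate_bwd()].
#' @return `N x C_out` matrix, or `list(out, cache)` when `with_cache`.
#' @export
graph_aggregate <- function(F, neighbor_idx, params, with_cache = FALSE) {
  F <- as.matrix(F)
  n <- nrow(F)
  C <- ncol(F)
  K <- ncol(neighbor_idx)
  if (nrow(params$conv$W) != 2L * C)
    stop(sprintf("conv expects input width %d, features have width 2*%d",
                 nrow(params$conv$W), C))
  nb_flat <- as.vector(neighbor_idx)           # column-major: j varies slow
  ctr_rep <- rep(seq_len(n), times = K)
  M <- cbind(F[ctr_rep, , drop = FALSE],
             F[nb_flat, , drop = FALSE] - F[ctr_rep, , drop = FALSE])
  lin <- linear_fwd(M, params$conv)
  bnc <- if (!is.null(params$bn)) bn_fwd(lin$out, params$bn)
  act <- relu_fwd(if (is.null(bnc)) lin$out else bnc$out)
  H <- array(act$out, dim = c(n, K, ncol(act$out)))
  out <- apply_max_k(H)
  if (!with_cache) return(out$max)
  list(out = out$max,
       cache = list(lin = lin, bn = bnc, act = act, argmax = out$argmax,
                    nb_flat = nb_flat, ctr_rep = ctr_rep,
                    n = n, K = K, C = C))
}

# Max over the K dimension of an N x K x C array, with argmax kept for
# gradient routing.
apply_max_k <- function(H) {
  n <- dim(H)[1]; K <- dim(H)[2]; C <- dim(H)[3]
  mx <- H[, 1, , drop = TRUE]
  if (is.null(dim(mx))) mx <- matrix(mx, n, C)
  arg <- matrix(1L, n, C)
  if (K > 1) for (j in 2:K) {
    hj <- H[, j, , drop = TRUE]
    if (is.null(dim(hj))) hj <- matrix(hj, n, C)
    upd <- hj > mx
    mx[upd] <- hj[upd]
    arg[upd] <- j
  }
  list(max = mx, argmax = arg)
}

# Backward pass of graph_aggregate: routes dOut through the argmax winners,
# the ReLU mask, the edge batchnorm and the shared conv, then scatters into
# dF through both the center copy and the edge difference. kNN indices are
# treated as constants.
graph_aggregate_bwd <- function(dOut, cache, params) {
  n <- cache$n; K <- cache$K; C <- cache$C
  c_out <- ncol(dOut)
  dH <- matrix(0, n * K, c_out)
  # winner row index in the flat (N*K) layout for each (i, channel)
  flat <- rep(seq_len(n), c_out) + (as.vector(cache$argmax) - 1L) * n
  col <- rep(seq_len(c_out), each = n)
  dH[cbind(flat, col)] <- as.vector(dOut)
  dH <- relu_bwd(dH, cache$act)
  gbn <- NULL
  if (!is.null(cache$bn)) {
    bb <- bn_bwd(dH, cache$bn, params$bn)
    dH <- bb$dX
    gbn <- bb$grad
  }
  lb <- linear_bwd(dH, cache$lin, params$conv)
  dM <- lb$dX
  dCtr <- dM[, seq_len(C), drop = FALSE]
  dEdge <- dM[, C + seq_len(C), drop = FALSE]
  dF <- matrix(0, n, C)
  # center receives the center-half gradient minus the edge-half gradient
  dF <- accumulate_rows(dF, cache$ctr_rep, dCtr - dEdge)
  dF <- accumulate_rows(dF, cache$nb_flat, dEdge)
  list(dF = dF, grad = c(list(conv = lb$grad),
                         if (!is.null(gbn)) list(bn = gbn)))
}

# dF[idx[r], ] += rows[r, ] with repeated indices summed.
accumulate_rows <- function(dF, idx, rows) {
  agg <- rowsum(rows, group = idx, reorder = FALSE)
  keys <- as.integer(rownames(agg))
  dF[keys, ] <- dF[keys, , drop = FALSE] + agg
  dF
}
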