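test_that("squared Euclidean scores match the definitional sum of squares", {
  F <- rbind(c(1, 2, 2), c(0, 0, 0))
  sc <- neighborhood_score(F, "sq_euclidean")
  expect_equal(sc$matrix[1, 2], 9)
  expect_equal(sc$matrix[2, 1], 9)
  expect_equal(diag(sc$matrix), c(0, 0))
  # matrix identity |x|^2 + |y|^2 - 2xy equals the elementwise definition
  set.seed(3)
  X <- matrix(rnorm(50 * 6), 50, 6)
  direct <- as.matrix(dist(X))^2
  expect_lt(max(abs(neighborhood_score(X)$matrix - direct)), 1e-6)
  expect_true(isSymmetric(neighborhood_score(X)$matrix))
})

test_that("cosine / pearson / weighted metrics are dissimilarities with safe degenerate rows", {
  F <- rbind(c(1, 0), c(2, 0), c(0, 3), c(0, 0))
  cs <- neighborhood_score(F, "cosine")$matrix
  expect_equal(cs[1, 2], 0)                    # parallel vectors
  expect_equal(cs[1, 3], 1)                    # orthogonal
  expect_equal(diag(cs), rep(0, 4))            # self-score 0 for all rows
  expect_equal(cs[4, 1], 1)                    # zero-norm row: dissim 1
  expect_false(anyNA(cs))
  pe <- neighborhood_score(rbind(c(1, 2, 3), c(2, 4, 6), c(5, 5, 5)),
                           "pearson")$matrix
  expect_equal(pe[1, 2], 0, tolerance = 1e-12) # perfectly correlated
  expect_equal(pe[3, 1], 1)                    # constant row fallback
  set.seed(4)
  X <- matrix(rnorm(30), 10, 3)
  w <- neighborhood_score(X, "weighted", weight_sq_euclid = 0.7)$matrix
  d2 <- neighborhood_score(X, "sq_euclidean")$matrix
  co <- neighborhood_score(X, "cosine")$matrix
  expect_equal(w, 0.7 * d2 / max(d2) + 0.3 * co, tolerance = 1e-12)
  expect_error(neighborhood_score(X, "weighted", weight_sq_euclid = 1.5),
               "weight")
})

test_that("knn_graph selects the k-1 closest with center first and index tie-break", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(4, 0, 0))
  sc <- neighborhood_score(pts)
  idx <- knn_graph(sc, 2)
  expect_identical(idx[3, ], c(3L, 2L))        # d2=1 beats d2=4
  expect_identical(knn_graph(sc, 1)[, 1], 1:4)
  tie <- neighborhood_score(rbind(c(0, 0, 0), c(1, 0, 0), c(-1, 0, 0)))
  expect_identical(knn_graph(tie, 2)[1, ], c(1L, 2L))  # lowest-index tie
  expect_error(knn_graph(sc, 5), "exceed")
  expect_error(knn_graph(sc, 0), "k must")
})

test_that("knn_graph matches the brute-force full-sort oracle on random clouds", {
  set.seed(11)
  for (rep in 1:20) {
    C <- sample(c(3, 64), 1)
    X <- matrix(rnorm(60 * C), 60, C)
    m <- neighborhood_score(X)$matrix
    for (k in c(1, 5, 30))
      expect_identical(knn_graph(m, k), knn_oracle(m, k))
  }
})

test_that("neighbor sets are nested as k grows", {
  set.seed(12)
  m <- neighborhood_score(matrix(rnorm(120), 40, 3))$matrix
  k_small <- knn_graph(m, 5)
  k_big <- knn_graph(m, 12)
  for (i in 1:40)
    expect_true(all(k_small[i, ] %in% k_big[i, ]))
})

test_that("edge features are neighbor-minus-center and translation invariant", {
  F <- rbind(c(1, 1, 1), c(2, 3, 1))
  idx <- rbind(c(1L, 2L), c(2L, 1L))
  e <- edge_features(F, idx)
  expect_equal(e[1, 1, ], c(0, 0, 0))          # self edge
  expect_equal(e[1, 2, ], c(1, 2, 0))
  shifted <- edge_features(F + rep(c(5, -2, 7), each = 2), idx)
  expect_equal(shifted, e, tolerance = 1e-12)
  expect_error(edge_features(F, rbind(c(1L, 3L), c(2L, 1L))), "out of range")
})

test_that("graph_aggregate equals the per-point conv+relu+max definition", {
  pts <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(4, 0, 0))
  idx <- knn_graph(neighborhood_score(pts), 2)
  C <- 3
  # projector returning the edge half unchanged (no batchnorm)
  p_edge <- graph_block_params(C, C, batchnorm = FALSE)
  p_edge$conv$W <- rbind(matrix(0, C, C), diag(C))
  p_edge$conv$b <- numeric(C)
  out <- graph_aggregate(pts, idx, p_edge)
  expect_equal(out[3, ], c(0, 0, 0))           # max(relu{0, (-1,0,0)})
  expect_equal(out[1, ], c(1, 0, 0))           # neighbor at +1 on x
  # projector returning the center half -> relu(F) for every point
  p_ctr <- graph_block_params(C, C, batchnorm = FALSE)
  p_ctr$conv$W <- rbind(diag(C), matrix(0, C, C))
  p_ctr$conv$b <- numeric(C)
  expect_equal(graph_aggregate(pts, idx, p_ctr), pmax(pts, 0),
               tolerance = 1e-12)
  # generic parameters against a literal per-point loop
  set.seed(5)
  F <- matrix(rnorm(10 * 4), 10, 4)
  idxF <- knn_graph(neighborhood_score(F), 3)
  pr <- graph_block_params(4, 6, batchnorm = FALSE)
  got <- graph_aggregate(F, idxF, pr)
  for (i in c(1, 4, 10)) {
    rows <- t(vapply(seq_len(3), function(j)
      c(F[i, ], F[idxF[i, j], ] - F[i, ]), numeric(8)))
    ref <- apply(pmax(rows %*% pr$conv$W +
                        rep(pr$conv$b, each = 3), 0), 2, max)
    expect_equal(got[i, ], ref, tolerance = 1e-10)
  }
})

test_that("graph_aggregate is invariant to neighbor order and equivariant to point order", {
  set.seed(6)
  F <- matrix(rnorm(15 * 4), 15, 4)
  idx <- knn_graph(neighborhood_score(F), 4)
  pr <- graph_block_params(4, 8)
  base <- graph_aggregate(F, idx, pr)
  shuf <- cbind(idx[, 1], idx[, c(3, 4, 2)])   # permute true neighbors
  expect_equal(graph_aggregate(F, shuf, pr), base, tolerance = 1e-10)
  perm <- sample(15)
  Fp <- F[perm, , drop = FALSE]
  permuted <- graph_aggregate(Fp, knn_graph(neighborhood_score(Fp), 4), pr)
  expect_equal(permuted, base[perm, , drop = FALSE], tolerance = 1e-5)
})
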