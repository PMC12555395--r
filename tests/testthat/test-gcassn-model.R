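test_that("model_config validates its invariants", {
  expect_error(model_config(n_classes = 1), "2 classes")
  expect_error(model_config(n_classes = 3, channels = c(10, 10),
                            n_gcasm_layers = 2), "divisible by 4")
  expect_error(model_config(n_classes = 3, n_gcasm_layers = 0), "one GCASM")
  cfg <- model_config(n_classes = 3)
  expect_equal(cfg$channels, rep(64L, 3))
  expect_equal(cfg$k, 30L)
})

test_that("gcasm_forward honors the shape contract and permutation equivariance", {
  set.seed(31)
  cfg <- tiny_config()
  p <- gcassn_init(cfg, seed = 1)
  F <- matrix(rnorm(20 * 3), 20, 3)
  out <- gcasm_forward(F, p$gcasm_layers$layer1, cfg)
  expect_equal(dim(out), c(20L, 8L))
  perm <- sample(20)
  out_p <- gcasm_forward(F[perm, ], p$gcasm_layers$layer1, cfg)
  expect_equal(out_p, out[perm, ], tolerance = 1e-5)
})

test_that("transnet starts at the identity and is permutation invariant", {
  cfg <- tiny_config()
  p <- gcassn_init(cfg, seed = 2)
  X <- tiny_cloud(25, seed = 3)$coords
  M <- transnet_forward(X, p$transnet, cfg)
  expect_identical(M, diag(3))                  # bit-exact at zero init
  expect_identical(apply_transform(X, M), X)
  # after perturbing the final layer the matrix is still 3x3 and
  # invariant to point order (max-pool invariance)
  p$transnet$fc3$W[] <- rnorm(length(p$transnet$fc3$W), sd = 0.1)
  M2 <- transnet_forward(X, p$transnet, cfg)
  expect_equal(dim(M2), c(3L, 3L))
  set.seed(4)
  perm <- sample(25)
  expect_equal(transnet_forward(X[perm, ], p$transnet, cfg), M2,
               tolerance = 1e-5)
  expect_error(transnet_forward(X[1:2, ], p$transnet, cfg), "k points")
})

test_that("apply_transform follows the row-vector convention and composes", {
  Rz <- rbind(c(0, 1, 0), c(-1, 0, 0), c(0, 0, 1))  # 90 deg about z
  expect_equal(apply_transform(matrix(c(1, 0, 0), 1), Rz),
               matrix(c(0, 1, 0), 1))
  set.seed(32)
  X <- matrix(rnorm(30), 10, 3)
  A <- matrix(rnorm(9), 3, 3)
  B <- matrix(rnorm(9), 3, 3)
  expect_equal(apply_transform(apply_transform(X, A), B),
               apply_transform(X, A %*% B), tolerance = 1e-6)
  expect_error(apply_transform(X, diag(2)), "3x3")
})

test_that("gcassn_forward returns N x P logits with argmax predictions", {
  cfg <- tiny_config()
  p <- gcassn_init(cfg, seed = 5)
  cl <- tiny_cloud(30, seed = 6)
  r <- gcassn_forward(cl, p, cfg)
  expect_s3_class(r, "segmentation_result")
  expect_equal(dim(r$logits), c(30L, 2L))
  expect_identical(r$predicted,
                   max.col(r$logits, ties.method = "first") - 1L)
  # the no-alignment ablation path still runs end to end
  cfg2 <- tiny_config(use_transnet = FALSE)
  r2 <- gcassn_forward(cl, gcassn_init(cfg2, seed = 5), cfg2)
  expect_equal(dim(r2$logits), c(30L, 2L))
})

test_that("eval-mode forward is bit-deterministic and permutation equivariant", {
  cfg <- tiny_config(n_gcasm_layers = 2, channels = c(8, 8))
  p <- gcassn_init(cfg, seed = 7)
  cl <- tiny_cloud(26, seed = 8)
  r1 <- gcassn_forward(cl, p, cfg)
  r2 <- gcassn_forward(cl, p, cfg)
  expect_identical(r1$logits, r2$logits)
  set.seed(9)
  perm <- sample(26)
  rp <- gcassn_forward(cl$coords[perm, ], p, cfg)
  expect_lt(max(abs(rp$logits - r1$logits[perm, ])), 1e-4)
})

test_that("count_parameters matches hand bookkeeping on a tiny config", {
  cfg <- tiny_config()
  # hand enumeration, C_in = 3, C = 8, qk = 2, G = 16, head (12, 8), P = 2
  lin <- function(i, o) i * o + o
  bn <- function(c) 2 * c
  gcasm <- (lin(6, 8) + bn(8)) +                       # graph conv + bn
    (8 * 2 + 8 * 8) + (lin(8, 8) + bn(8))              # W_qk, W_v, lbr
  transnet <- gcasm + (lin(8, 16) + bn(16)) +          # internal gcasm + mlp
    lin(16, 512) + bn(512) + lin(512, 256) + bn(256) + # fc1/ln1, fc2/ln2
    lin(256, 9)
  fuse <- lin(8, 16) + bn(16)
  head <- (lin(3 + 8 + 16, 12) + bn(12)) + (lin(12, 8) + bn(8)) + lin(8, 2)
  expect_equal(as.integer(count_parameters(cfg)),
               transnet + gcasm + fuse + head)
  # monotonicity in depth; full-size model lands in the 1-2 M range
  expect_lt(count_parameters(model_config(n_classes = 3, n_gcasm_layers = 2,
                                          channels = c(64, 64))),
            count_parameters(model_config(n_classes = 3)))
  full <- count_parameters(model_config(n_classes = 3))
  expect_gt(full, 1e6)
  expect_lt(full, 2.5e6)
  expect_equal(length(gcassn:::param_flatten(
    gcassn:::linear_init(4, 2))) , 10)  # 4*2 weights + 2 biases
})

test_that("checkpoints round trip and refuse mismatched configurations", {
  cfg <- tiny_config()
  p <- gcassn_init(cfg, seed = 10)
  f <- withr::local_tempfile(fileext = ".json")
  save_model(p, cfg, f)
  ck <- load_model(f)
  cl <- tiny_cloud(20, seed = 11)
  expect_equal(gcassn_forward(cl, ck$params, ck$config)$logits,
               gcassn_forward(cl, p, cfg)$logits, tolerance = 1e-12)
  # tamper with the stored hash
  txt <- readLines(f)
  txt <- sub("\"config_hash\":\"[a-f0-9]+\"", "\"config_hash\":\"deadbeef\"",
             txt)
  writeLines(txt, f)
  expect_error(load_model(f), "hash mismatch")
})

test_that("every parameter group receives gradient after one training step", {
  cfg <- tiny_config(n_gcasm_layers = 2, channels = c(8, 8),
                     dropout_rate = 0.5)
  p <- gcassn_init(cfg, seed = 12)
  cl <- tiny_cloud(24, seed = 13)
  g <- gcassn:::with_seed(14, {
    fw <- gcassn:::gcassn_fwd_full(cl$coords, p, cfg, train = TRUE)
    ce <- cross_entropy(fw$logits, cl$labels)
    gcassn:::gcassn_bwd_full(ce$dlogits, fw$cache, p, cfg, train = TRUE)
  })
  norms <- vapply(g, gcassn:::grad_norm, numeric(1))
  expect_named(norms, c("transnet", "gcasm_layers", "fuse", "head"))
  expect_true(all(norms > 0))
  for (l in g$gcasm_layers) expect_gt(gcassn:::grad_norm(l), 0)
})
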