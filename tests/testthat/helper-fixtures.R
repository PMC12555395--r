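# Shared fixtures: tiny deterministic clouds and configurations.

tiny_cloud <- function(n = 20, seed = 42, P = 2) {
  gcassn:::with_seed(seed, labeled_cloud(matrix(stats::rnorm(3 * n), n, 3),
                                         sample(0:(P - 1), n, replace = TRUE)))
}

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_classes = 2, n_gcasm_layers = 1L, channels = 8L, k = 4L,
         global_dim = 16L, head_dims = c(12L, 8L), dropout_rate = 0),
    list(...))
  do.call(model_config, args)
}

# Brute-force kNN oracle: full sort of each row by (score, index), center
# first. Independent of the package's partial-selection implementation.
knn_oracle <- function(score_matrix, k) {
  n <- nrow(score_matrix)
  out <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    s <- score_matrix[i, ]
    s[i] <- Inf
    ord <- order(s, seq_len(n))
    out[i, ] <- c(i, ord)[seq_len(k)]
  }
  out
}

# Direct per-point tally oracle for segmentation metrics.
metrics_oracle <- function(truth, pred, P) {
  iou <- numeric(P)
  defined <- logical(P)
  correct <- 0
  for (c in 0:(P - 1)) {
    tp <- sum(truth == c & pred == c)
    fp <- sum(truth != c & pred == c)
    fn <- sum(truth == c & pred != c)
    correct <- correct + tp
    if (tp + fp + fn > 0) {
      iou[c + 1] <- tp / (tp + fp + fn)
      defined[c + 1] <- TRUE
    } else iou[c + 1] <- NA_real_
  }
  list(iou = iou, miou = mean(iou[defined]),
       acc = correct / length(truth))
}
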