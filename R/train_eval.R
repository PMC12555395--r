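#' Training configuration
#'
#' The reference recipe: SGD with momentum 0.9 and weight decay 1e-4,
#' batch size 8, initial learning rate 0.1 halved every 20 epochs, 200
#' epochs, with the reported model taken from the epoch of best test mIoU.
#'
#' @param epochs Number of epochs.
#' @param batch_size Clouds per SGD step.
#' @param lr0 Initial learning rate.
#' @param decay_factor Multiplicative decay (in `(0, 1)`).
#' @param decay_every Epochs between decays.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay coefficient.
#' @param seed Integer seed governing init, shuffling and dropout.
#' @return A `train_config` list.
#' @export
train_config <- function(epochs = 200L, batch_size = 8L, lr0 = 0.1,
                         decay_factor = 0.5, decay_every = 20L,
                         momentum = 0.9, weight_decay = 1e-4, seed = 1L) {
  stopifnot(epochs >= 1, batch_size >= 1, lr0 > 0,
            decay_factor > 0, decay_factor < 1, decay_every >= 1,
            momentum >= 0, weight_decay >= 0)
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr0 = lr0,
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 momentum = momentum, weight_decay = weight_decay,
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Step-decay learning-rate schedule
#'
#' `lr0 * decay_factor^floor(epoch / decay_every)` for a 0-based epoch
#' index: 0.1 at epoch 0, 0.05 at epoch 20, 0.0125 at epoch 45 under the
#' defaults.
#'
#' @param epoch 0-based epoch index (>= 0).
#' @param cfg A [train_config()].
#' @return The learning rate.
#' @export
lr_schedule <- function(epoch, cfg = train_config()) {
  if (any(epoch < 0)) stop("epoch must be non-negative")
  cfg$lr0 * cfg$decay_factor^(floor(epoch / cfg$decay_every))
}

#' Confusion matrix of a point-wise prediction
#'
#' @param true_labels,predicted_labels Integer vectors of equal length with
#'   values in `0..P-1`.
#' @param P Number of classes.
#' @return `P x P` integer matrix; entry `(t, p)` counts points of true
#'   class `t - 1` predicted as `p - 1`.
#' @export
confusion_matrix <- function(true_labels, predicted_labels, P) {
  if (length(true_labels) != length(predicted_labels))
    stop("label vectors must have equal length")
  if (any(true_labels < 0L | true_labels >= P) ||
      any(predicted_labels < 0L | predicted_labels >= P))
    stop("labels out of range 0..P-1")
  cm <- matrix(0L, P, P)
  tab <- table(factor(true_labels, levels = 0:(P - 1)),
               factor(predicted_labels, levels = 0:(P - 1)))
  cm[] <- as.integer(tab)
  cm
}

#' Segmentation metrics from a confusion matrix
#'
#' Per-class intersection over union
#' \eqn{IoU_i = TP_i / (TP_i + FP_i + FN_i)}, their unweighted mean (mIoU),
#' overall point accuracy (trace / total), and per-class accuracy
#' \eqn{(TP_i + TN_i) / total}. Classes absent from both truth and
#' prediction have an undefined IoU; by default they are excluded from the
#' mean (`absent_class = "exclude"`) rather than scored.
#'
#' @param confusion Square non-negative count matrix (rows = truth).
#' @param absent_class `"exclude"` (default) or `"score_one"` for classes
#'   with zero union.
#' @return A `seg_metrics` list: `confusion`, `iou_per_class`, `miou`,
#'   `acc_overall`, `acc_per_class`, `acc_mean_class`, `n_points`.
#' @export
segmentation_metrics <- function(confusion,
                                 absent_class = c("exclude", "score_one")) {
  absent_class <- match.arg(absent_class)
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("confusion must be a square non-negative matrix")
  total <- sum(confusion)
  if (total == 0) stop("empty confusion matrix")
  tp <- diag(confusion)
  fp <- colSums(confusion) - tp
  fn <- rowSums(confusion) - tp
  tn <- total - tp - fp - fn
  union <- tp + fp + fn
  iou <- ifelse(union > 0, tp / union, NA_real_)
  defined <- if (absent_class == "exclude") !is.na(iou) else rep(TRUE, length(iou))
  if (absent_class == "score_one") iou[is.na(iou)] <- 1
  structure(list(confusion = confusion,
                 iou_per_class = iou,
                 miou = mean(iou[defined]),
                 acc_overall = sum(tp) / total,
                 acc_per_class = (tp + tn) / total,
                 acc_mean_class = mean((tp + tn) / total),
                 n_points = total),
            class = "seg_metrics")
}

#' @export
print.seg_metrics <- function(x, ...) {
  cat(sprintf("<seg_metrics> %d points | acc %.4f | mIoU %.4f\n",
              x$n_points, x$acc_overall, x$miou))
  cat("  per-class IoU:", paste(sprintf("%.4f", x$iou_per_class),
                                collapse = " "), "\n")
  invisible(x)
}

#' Instance and category-mean IoU (ShapeNet convention)
#'
#' `miou` averages the per-instance part mIoU over all instances; `mciou`
#' first averages within each shape category and then over categories.
#'
#' @param category Character/factor vector, one entry per instance.
#' @param instance_miou Numeric vector of per-instance part mIoUs.
#' @return List with `miou` and `mciou`.
#' @export
shapenet_mciou <- function(category, instance_miou) {
  if (length(category) == 0L) stop("need at least one instance")
  if (length(category) != length(instance_miou))
    stop("category and instance_miou must have equal length")
  list(miou = mean(instance_miou),
       mciou = mean(tapply(instance_miou, category, mean)))
}

#' Randomly drop points from a cloud
#'
#' Uniform removal without replacement; labels travel with the survivors.
#'
#' @param cloud A [labeled_cloud()].
#' @param n_drop Number of points to remove (`0 <= n_drop < N`).
#' @param seed Integer seed.
#' @return The thinned [labeled_cloud()].
#' @export
drop_points <- function(cloud, n_drop, seed = 1L) {
  n <- n_points(cloud)
  n_drop <- as.integer(n_drop)
  if (n_drop < 0L || n_drop >= n)
    stop("n_drop must be in [0, N)")
  if (n_drop == 0L) return(cloud)
  keep <- with_seed(seed, sort(sample.int(n, n - n_drop)))
  labeled_cloud(cloud$coords[keep, , drop = FALSE],
                if (!is.null(cloud$labels)) cloud$labels[keep],
                cloud$source_id)
}

#' Add Gaussian coordinate noise to a cloud
#'
#' Independent zero-mean Gaussian perturbation with standard deviation
#' `sigma` on every coordinate. `sigma` is expressed in normalized
#' coordinate units (apply after [normalize_cloud()]); labels unchanged.
#'
#' @param cloud A [labeled_cloud()].
#' @param sigma Noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return The perturbed [labeled_cloud()].
#' @export
gaussian_perturb <- function(cloud, sigma, seed = 1L) {
  if (sigma < 0) stop("sigma must be non-negative")
  if (sigma == 0) return(cloud)
  co <- cloud$coords +
    with_seed(seed, matrix(stats::rnorm(length(cloud$coords), sd = sigma),
                           nrow(cloud$coords)))
  labeled_cloud(co, cloud$labels, cloud$source_id)
}

#' Softmax cross-entropy loss over per-point logits
#'
#' @param logits `N x P` matrix.
#' @param labels Integer vector in `0..P-1`.
#' @return List: `loss` (mean negative log-likelihood) and `dlogits`
#'   (`(softmax - onehot) / N`).
#' @export
cross_entropy <- function(logits, labels) {
  n <- nrow(logits)
  p <- row_softmax(logits)
  ix <- cbind(seq_len(n), labels + 1L)
  loss <- -mean(log(pmax(p[ix], 1e-12)))
  d <- p
  d[ix] <- d[ix] - 1
  list(loss = loss, dlogits = d / n)
}

#' Train the segmentation network
#'
#' Per-point cross-entropy, SGD with momentum / weight decay / step decay
#' as configured, batch-norm statistics over the points of each cloud,
#' test-set evaluation every epoch, and best-epoch selection by test mIoU.
#' Fully reproducible for a fixed `train_cfg$seed`.
#'
#' @param model_cfg A [model_config()].
#' @param train_set,test_set Non-empty lists of labeled clouds. Without
#'   `resample_n`, all clouds must share one point count.
#' @param train_cfg A [train_config()].
#' @param resample_n Optional working size: each epoch every training
#'   cloud is re-subsampled to `resample_n` points (the random-sampling
#'   preprocessing applied per epoch, which doubles as augmentation
#'   against memorizing individual point sets). Test clouds are sampled
#'   once. `NULL` uses the clouds as given.
#' @param verbose Print one line per epoch.
#' @return List: `params` (best-epoch parameters), `final_params`,
#'   `history` (data.frame epoch / loss / lr / test_miou / test_acc),
#'   `best_epoch` (1-based row of the best test mIoU).
#' @export
fit <- function(model_cfg, train_set, test_set,
                train_cfg = train_config(), resample_n = NULL,
                verbose = FALSE) {
  if (length(train_set) == 0L || length(test_set) == 0L)
    stop("train and test sets must be non-empty")
  if (!is.null(resample_n)) {
    test_set <- lapply(seq_along(test_set), function(i)
      random_sample(test_set[[i]], resample_n,
                    seed = train_cfg$seed + 5000L + i))
  }
  ns <- vapply(c(train_set, test_set), n_points, numeric(1))
  if (is.null(resample_n) && length(unique(ns)) != 1L)
    stop("all clouds must be sampled to a common size")
  if (any(vapply(c(train_set, test_set),
                 function(cl) is.null(cl$labels), TRUE)))
    stop("all clouds must be labeled")
  params <- gcassn_init(model_cfg, seed = train_cfg$seed)
  vel <- NULL
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric(),
                        test_miou = numeric(), test_acc = numeric())
  best <- list(miou = -Inf, params = params, epoch = 0L)
  with_seed(train_cfg$seed + 1L, {
    n_tr <- length(train_set)
    for (epoch in seq_len(train_cfg$epochs)) {
      lr <- lr_schedule(epoch - 1L, train_cfg)
      ord <- sample.int(n_tr)
      epoch_set <- if (is.null(resample_n)) train_set
        else lapply(seq_along(train_set), function(i)
          random_sample(train_set[[i]], resample_n,
                        seed = train_cfg$seed + 1000L * epoch + i))
      losses <- numeric(0)
      for (start in seq(1L, n_tr, by = train_cfg$batch_size)) {
        batch <- ord[start:min(start + train_cfg$batch_size - 1L, n_tr)]
        grads <- NULL
        bl <- 0
        for (ci in batch) {
          cl <- epoch_set[[ci]]
          fw <- gcassn_fwd_full(cl$coords, params, model_cfg,
                                train = TRUE)
          ce <- cross_entropy(fw$logits, cl$labels)
          bl <- bl + ce$loss
          g <- gcassn_bwd_full(ce$dlogits, fw$cache, params, model_cfg,
                               train = TRUE)
          grads <- grad_add(grads, g)
        }
        grads <- grad_scale(grads, 1 / length(batch))
        st <- sgd_step(params, grads, vel, lr,
                       train_cfg$momentum, train_cfg$weight_decay)
        params <- st$p
        vel <- st$v
        losses <- c(losses, bl / length(batch))
      }
      m <- evaluate(params, model_cfg, test_set)
      history[epoch, ] <- list(epoch, mean(losses), lr, m$miou,
                               m$acc_overall)
      if (m$miou > best$miou)
        best <- list(miou = m$miou, params = params, epoch = epoch)
      if (verbose)
        cat(sprintf("epoch %3d  loss %.4f  lr %.5f  test acc %.4f  mIoU %.4f\n",
                    epoch, mean(losses), lr, m$acc_overall, m$miou))
    }
  })
  list(params = best$params, final_params = params, history = history,
       best_epoch = best$epoch)
}

#' Evaluate a model (or oracle predictor) on a test set
#'
#' Runs an eval-mode forward pass per cloud, optionally after a robustness
#' perturbation, and pools one confusion matrix over all points of the set.
#' `params` may also be a function `cloud -> integer labels` (e.g. a
#' perfect oracle), which is used directly as the predictor.
#'
#' @param params Model parameters from [gcassn_init()]/[fit()], or a
#'   predictor function.
#' @param model_cfg A [model_config()] (ignored for predictor functions).
#' @param test_set Non-empty list of labeled clouds.
#' @param perturbation Optional: `list(type = "drop", n_drop =, seed =)` or
#'   `list(type = "noise", sigma =, seed =)` applied to each cloud before
#'   prediction.
#' @return A `seg_metrics` object (see [segmentation_metrics()]).
#' @export
evaluate <- function(params, model_cfg, test_set, perturbation = NULL) {
  if (length(test_set) == 0L) stop("test set is empty")
  P <- if (is.function(params))
    max(vapply(test_set, function(cl) max(cl$labels), numeric(1))) + 1L
  else model_cfg$n_classes
  cm <- matrix(0L, P, P)
  for (i in seq_along(test_set)) {
    cl <- test_set[[i]]
    if (!is.null(perturbation)) {
      pseed <- (perturbation$seed %||% 1L) + i
      cl <- switch(perturbation$type,
        drop = drop_points(cl, perturbation$n_drop, seed = pseed),
        noise = gaussian_perturb(cl, perturbation$sigma, seed = pseed),
        stop("unknown perturbation type"))
    }
    pred <- if (is.function(params)) params(cl)
            else gcassn_forward(cl, params, model_cfg, mode = "eval")$predicted
    cm <- cm + confusion_matrix(cl$labels, pred, P)
  }
  segmentation_metrics(cm)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robustness sweep over point-drop fractions
#'
#' Mirrors the density-robustness protocol: evaluate the same model after
#' removing a growing fraction of each test cloud's points.
#'
#' @param params,model_cfg,test_set As in [evaluate()].
#' @param drop_fractions Fractions of points to remove (default
#'   `c(0, 0.25, 0.5, 0.75)`).
#' @param seed Perturbation seed.
#' @return data.frame with `drop_fraction`, `n_drop`, `acc`, `miou`.
#' @export
drop_sweep <- function(params, model_cfg, test_set,
                       drop_fractions = c(0, 0.25, 0.5, 0.75), seed = 1L) {
  n <- n_points(test_set[[1L]])
  rows <- lapply(drop_fractions, function(f) {
    nd <- as.integer(round(f * n))
    m <- evaluate(params, model_cfg, test_set,
                  perturbation = if (nd > 0)
                    list(type = "drop", n_drop = nd, seed = seed))
    data.frame(drop_fraction = f, n_drop = nd,
               acc = m$acc_overall, miou = m$miou)
  })
  do.call(rbind, rows)
}

#' Robustness sweep over Gaussian noise levels
#'
#' @param params,model_cfg,test_set As in [evaluate()].
#' @param sigmas Noise standard deviations (default
#'   `c(0, 0.01, 0.02, 0.04, 0.08)`, in normalized units).
#' @param seed Perturbation seed.
#' @return data.frame with `sigma`, `acc`, `miou`.
#' @export
noise_sweep <- function(params, model_cfg, test_set,
                        sigmas = c(0, 0.01, 0.02, 0.04, 0.08), seed = 1L) {
  rows <- lapply(sigmas, function(s) {
    m <- evaluate(params, model_cfg, test_set,
                  perturbation = if (s > 0)
                    list(type = "noise", sigma = s, seed = seed))
    data.frame(sigma = s, acc = m$acc_overall, miou = m$miou)
  })
  do.call(rbind, rows)
}
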