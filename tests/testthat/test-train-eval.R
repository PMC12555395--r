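test_that("lr_schedule follows the closed-form step decay", {
  cfg <- train_config()
  expect_equal(lr_schedule(0, cfg), 0.1)
  expect_equal(lr_schedule(19, cfg), 0.1)
  expect_equal(lr_schedule(20, cfg), 0.05)
  expect_equal(lr_schedule(45, cfg), 0.1 * 0.5^2)  # two completed decays
  eps <- lr_schedule(0:199, cfg)
  expect_true(all(diff(eps) <= 0))                   # non-increasing
  expect_equal(length(unique(eps[1:20])), 1L)        # piecewise constant
  expect_equal(length(unique(eps[21:40])), 1L)
  expect_error(lr_schedule(-1, cfg), "non-negative")
})

test_that("confusion_matrix tallies true-by-predicted counts", {
  expect_equal(confusion_matrix(c(0, 1, 2, 1), c(0, 1, 2, 1), 3),
               diag(c(1L, 2L, 1L)))
  expect_equal(confusion_matrix(c(0, 0, 1, 1), c(0, 1, 1, 1), 2),
               rbind(c(1L, 1L), c(0L, 2L)))
  set.seed(41)
  tr <- sample(0:3, 500, replace = TRUE)
  pr <- sample(0:3, 500, replace = TRUE)
  expect_equal(sum(confusion_matrix(tr, pr, 4)), 500)
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "out of range")
  expect_error(confusion_matrix(0:1, 0:2, 3), "equal length")
})

test_that("segmentation_metrics implements IoU / mIoU / accuracies", {
  # one class with TP=3, FP=1, FN=1 -> IoU 0.6
  cm <- rbind(c(3, 1), c(1, 5))
  m <- segmentation_metrics(cm)
  expect_equal(m$iou_per_class[1], 3 / (3 + 1 + 1))
  perfect <- segmentation_metrics(diag(c(4, 6, 2)))
  expect_equal(perfect$iou_per_class, rep(1, 3))
  expect_equal(perfect$miou, 1)
  expect_equal(perfect$acc_overall, 1)
  # unweighted mean over per-class IoUs {1, 1, 0.5, 0.5} -> 0.75
  cm2 <- rbind(c(2, 0, 0, 0), c(0, 2, 0, 0),
               c(0, 0, 1, 1), c(0, 0, 0, 1))
  m2 <- segmentation_metrics(cm2)
  expect_equal(unname(m2$iou_per_class), c(1, 1, 0.5, 0.5))
  expect_equal(m2$miou, 0.75)
  # a class absent from truth AND prediction is excluded from the mean
  cm3 <- rbind(c(3, 1, 0), c(1, 2, 0), c(0, 0, 0))
  m3 <- segmentation_metrics(cm3)
  expect_equal(unname(m3$iou_per_class), c(0.6, 0.5, NA))
  expect_equal(m3$miou, 0.55)
  m3b <- segmentation_metrics(cm3, absent_class = "score_one")
  expect_equal(m3b$miou, (0.6 + 0.5 + 1) / 3)
  expect_error(segmentation_metrics(matrix(0, 2, 2)), "empty")
})

test_that("segmentation_metrics agrees exactly with the counting oracle", {
  set.seed(42)
  for (rep in 1:100) {
    P <- sample(2:4, 1)
    n <- sample(20:200, 1)
    tr <- sample(0:(P - 1), n, replace = TRUE)
    pr <- sample(0:(P - 1), n, replace = TRUE)
    m <- segmentation_metrics(confusion_matrix(tr, pr, P))
    o <- metrics_oracle(tr, pr, P)
    expect_equal(unname(m$iou_per_class), o$iou)
    expect_equal(m$miou, o$miou)
    expect_equal(m$acc_overall, o$acc)
  }
})

test_that("shapenet_mciou averages instances then categories", {
  r <- shapenet_mciou(c("A", "A", "B"), c(0.8, 0.6, 1.0))
  expect_equal(r$miou, 0.8)
  expect_equal(r$mciou, (0.7 + 1.0) / 2)
  one <- shapenet_mciou(rep("A", 3), c(0.5, 0.7, 0.9))
  expect_equal(one$miou, one$mciou)
  allv <- shapenet_mciou(c("A", "B", "C"), rep(0.4, 3))
  expect_equal(allv$miou, 0.4)
  expect_equal(allv$mciou, 0.4)
  expect_error(shapenet_mciou(character(0), numeric(0)), "at least one")
})

test_that("drop_points removes without replacement, seed-deterministically", {
  cl <- tiny_cloud(2048, seed = 43)
  expect_identical(drop_points(cl, 0), cl)
  d <- drop_points(cl, 512, seed = 1)
  expect_equal(n_points(d), 1536)
  key <- paste(cl$coords[, 1], cl$coords[, 2], cl$coords[, 3])
  expect_true(all(paste(d$coords[, 1], d$coords[, 2], d$coords[, 3]) %in% key))
  expect_identical(drop_points(cl, 100, seed = 2),
                   drop_points(cl, 100, seed = 2))
  expect_error(drop_points(cl, 2048), "n_drop")
})

test_that("gaussian_perturb adds noise of the stated scale, labels untouched", {
  cl <- tiny_cloud(34000, seed = 44)         # ~1e5 coordinates
  expect_identical(gaussian_perturb(cl, 0), cl)
  g <- gaussian_perturb(cl, 0.02, seed = 3)
  emp <- sd(g$coords - cl$coords)
  expect_lt(abs(emp - 0.02) / 0.02, 0.05)
  expect_identical(g$labels, cl$labels)
  expect_identical(gaussian_perturb(cl, 0.01, seed = 4)$coords,
                   gaussian_perturb(cl, 0.01, seed = 4)$coords)
  expect_error(gaussian_perturb(cl, -1), "non-negative")
})

test_that("cross_entropy has the closed-form uniform limit and a valid gradient", {
  for (P in 2:4) {
    ce <- cross_entropy(matrix(0, 7, P), sample(0:(P - 1), 7, replace = TRUE))
    expect_equal(ce$loss, log(P), tolerance = 1e-6)
  }
  set.seed(45)
  logits <- matrix(rnorm(12), 4, 3)
  y <- c(0L, 2L, 1L, 0L)
  ce <- cross_entropy(logits, y)
  expect_gt(ce$loss, 0)
  expect_equal(rowSums(ce$dlogits), rep(0, 4), tolerance = 1e-12)
  num <- (cross_entropy(logits + c(1e-6, rep(0, 11)), y)$loss - ce$loss) / 1e-6
  expect_equal(num, ce$dlogits[1, 1], tolerance = 1e-4)
})

test_that("evaluate pools confusion across clouds and accepts oracle predictors", {
  clouds <- lapply(1:3, function(i) tiny_cloud(40, seed = 50 + i, P = 3))
  oracle <- function(cl) cl$labels
  m <- evaluate(oracle, NULL, clouds)
  expect_equal(m$miou, 1)
  expect_equal(m$acc_overall, 1)
  expect_equal(m$n_points, 120)
  cfg <- tiny_config(n_classes = 3)
  p <- gcassn_init(cfg, seed = 1)
  m1 <- evaluate(p, cfg, clouds)
  m2 <- evaluate(p, cfg, clouds)
  expect_identical(m1$confusion, m2$confusion)   # eval determinism
  sweep <- drop_sweep(p, cfg, clouds, drop_fractions = c(0, 0.25, 0.5))
  expect_equal(nrow(sweep), 3)
  expect_equal(sweep$n_drop, c(0L, 10L, 20L))
})

test_that("tiny fit runs reproducibly and records history / best epoch", {
  clouds <- lapply(1:6, function(i) {
    cl <- tiny_cloud(24, seed = 60 + i, P = 2)
    labeled_cloud(cl$coords, as.integer(cl$coords[, 3] > 0))
  })
  cfg <- tiny_config(dropout_rate = 0.5)
  tc <- train_config(epochs = 3, batch_size = 2, seed = 9)
  r1 <- fit(cfg, clouds[1:4], clouds[5:6], tc)
  r2 <- fit(cfg, clouds[1:4], clouds[5:6], tc)
  expect_equal(r1$history$loss, r2$history$loss)   # seed determinism
  expect_equal(nrow(r1$history), 3)
  expect_true(all(is.finite(r1$history$loss)) && all(r1$history$loss > 0))
  expect_equal(r1$best_epoch,
               which.max(r1$history$test_miou))
  expect_error(fit(cfg, list(), clouds[5:6], tc), "non-empty")
})

test_that("label-shuffled training cannot beat chance by a wide margin", {
  set.seed(70)
  clouds <- lapply(1:8, function(i) {
    cl <- tiny_cloud(64, seed = 70 + i, P = 2)
    labeled_cloud(cl$coords, sample(cl$labels))   # destroy structure
  })
  cfg <- tiny_config(dropout_rate = 0.5)
  r <- fit(cfg, clouds[1:6], clouds[7:8],
           train_config(epochs = 3, batch_size = 3, seed = 1))
  chance <- max(table(unlist(lapply(clouds[7:8], `[[`, "labels")))) / 128
  expect_lte(max(r$history$test_acc), chance + 0.1)
})
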