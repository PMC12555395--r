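test_that("reading xyz_label_text remaps raw label codes and preserves order", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment line", "0 0 0 0", "1 0 0 1", "0 1 0 3"), f)
  cl <- read_labeled_cloud(f, label_map())
  expect_equal(n_points(cl), 3)
  expect_identical(cl$labels, c(0L, 1L, 2L))
  expect_equal(cl$coords, rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0)))
})

test_that("malformed and degenerate files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(character(0), f)
  expect_error(read_labeled_cloud(f), "no point records")
  writeLines(c("0 0 0 0", "1 oops 0 1"), f)
  expect_error(read_labeled_cloud(f), "line 2")
  writeLines(c("0 0 0 5"), f)
  expect_error(read_labeled_cloud(f), "unknown label")
  expect_error(read_labeled_cloud(tempfile()), "not found")
})

test_that("write/read round trips both dialects", {
  cl <- tiny_cloud(30, seed = 7, P = 3)
  for (dialect in c("xyz_label_text", "ascii_ply")) {
    f <- withr::local_tempfile(fileext = ".txt")
    write_labeled_cloud(cl, f, dialect = dialect)
    back <- read_labeled_cloud(f, dialect = dialect)
    expect_equal(back$coords, cl$coords, tolerance = 1e-6)
    expect_identical(back$labels, cl$labels)
  }
})

test_that("unlabeled clouds round trip without a label column", {
  cl <- labeled_cloud(matrix(rnorm(15), 5, 3))
  f <- withr::local_tempfile(fileext = ".txt")
  write_labeled_cloud(cl, f)
  expect_null(read_labeled_cloud(f)$labels)
})

test_that("random_sample subsamples, pads deficits, and is seed-stable", {
  big <- tiny_cloud(4096, seed = 1)
  s <- random_sample(big, 2048, seed = 3)
  expect_equal(n_points(s), 2048)
  # n_points == N gives a permutation (equal row multisets)
  perm <- random_sample(big, 4096, seed = 3)
  key <- function(cl) sort(paste(cl$coords[, 1], cl$coords[, 2],
                                 cl$coords[, 3], cl$labels))
  expect_identical(key(perm), key(big))
  # deficit: all original points kept, rest drawn with replacement
  small <- tiny_cloud(10, seed = 2)
  pad <- random_sample(small, 25, seed = 4)
  expect_equal(n_points(pad), 25)
  expect_true(all(paste(small$coords[, 1]) %in% paste(pad$coords[, 1])))
  expect_identical(random_sample(big, 100, seed = 9),
                   random_sample(big, 100, seed = 9))
  expect_error(random_sample(big, 0), "n_points")
})

test_that("random_sample preserves label proportions in expectation", {
  cl <- labeled_cloud(matrix(rnorm(600), 200, 3),
                      rep(c(0L, 1L), each = 100))
  fr <- vapply(1:200, function(s)
    mean(random_sample(cl, 50, seed = s)$labels == 0L), numeric(1))
  expect_lt(abs(mean(fr) - 0.5), 0.05)
})

test_that("normalize_cloud centers, scales to the unit sphere, idempotent", {
  cl <- labeled_cloud(rbind(c(0, 0, 0), c(2, 0, 0)))
  nm <- normalize_cloud(cl)
  expect_equal(nm$coords, rbind(c(-1, 0, 0), c(1, 0, 0)))
  expect_equal(normalize_cloud(nm)$coords, nm$coords, tolerance = 1e-6)
  one <- normalize_cloud(labeled_cloud(matrix(5, 1, 3)))
  expect_equal(as.vector(one$coords), c(0, 0, 0))
  big <- tiny_cloud(50)
  nb <- normalize_cloud(big)
  expect_equal(colMeans(nb$coords), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(max(sqrt(rowSums(nb$coords^2))), 1, tolerance = 1e-12)
  expect_identical(normalize_cloud(big, mode = "none"), big)
})

test_that("split_dataset partitions with round(train_fraction * n)", {
  clouds <- lapply(1:35, function(i) tiny_cloud(5, seed = i))
  sp <- split_dataset(clouds, 0.8, seed = 1)
  expect_length(sp$train, 28)
  expect_length(sp$test, 7)
  expect_identical(sort(c(sp$train_idx, sp$test_idx)), 1:35)
  expect_identical(split_dataset(clouds, 0.8, seed = 2)$train_idx,
                   split_dataset(clouds, 0.8, seed = 2)$train_idx)
  for (n in c(2, 3, 17, 100)) {
    cls <- lapply(seq_len(n), function(i) tiny_cloud(4, seed = i))
    spn <- split_dataset(cls, 0.8, seed = 5)
    expect_equal(length(spn$train) + length(spn$test), n)
    expect_length(intersect(spn$train_idx, spn$test_idx), 0)
  }
  expect_error(split_dataset(clouds[1], 0.8), "at least 2")
  expect_error(split_dataset(clouds, 1.2), "train_fraction")
})
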