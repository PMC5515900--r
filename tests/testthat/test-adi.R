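test_that("class balancing subsamples to the minority size", {
  labels <- rep(c("a", "b"), c(12, 8))
  set.seed(20)
  idx <- balance_classes(labels)
  expect_identical(length(idx), 16L)
  expect_identical(as.integer(table(labels[idx])), c(8L, 8L))
  expect_identical(anyDuplicated(idx), 0L)

  even <- rep(c("a", "b"), each = 10)
  set.seed(21)
  expect_identical(sort(balance_classes(even)), 1:20)

  set.seed(22); d1 <- balance_classes(labels)
  set.seed(22); d2 <- balance_classes(labels)
  expect_identical(d1, d2)
  expect_error(balance_classes(rep("a", 5)), "two classes")
})

test_that("add-feature-in curve matches an independent re-implementation", {
  # Oracle: plain-loop GNB over every fold and nested subset, sharing only
  # the documented RNG contract (repetition r draws balance + folds under
  # substream_seed(seed, r)).
  set.seed(23)
  X <- cbind(c(0, 0.4, 1, 1.4) + rnorm(4, sd = 0.01),
             c(0, 1, 1, 0))
  y <- c("a", "a", "b", "b")
  got <- optimize_feature_count(X, y, ranking = 1:2, reps = 1, folds = 2,
                                seed = 7)

  fold_of <- crossday:::with_seed(crossday:::substream_seed(7, 1), {
    keep <- balance_classes(y)
    f <- integer(4)
    f[keep] <- crossday:::stratified_folds(y[keep], 2)
    f
  })
  acc <- matrix(NA, 2, 2)                  # folds x candidate counts
  for (f in 1:2) {
    tr <- which(fold_of != f); te <- which(fold_of == f)
    for (d in 1:2) {
      cols <- seq_len(d)
      mu_a <- colMeans(X[intersect(tr, which(y == "a")), cols, drop = FALSE])
      mu_b <- colMeans(X[intersect(tr, which(y == "b")), cols, drop = FALSE])
      # Single-trial classes: variances floor to equality => nearest mean.
      pred <- sapply(te, function(i) {
        da <- sum((X[i, cols] - mu_a)^2)
        db <- sum((X[i, cols] - mu_b)^2)
        if (da <= db) "a" else "b"
      })
      acc[f, d] <- mean(pred == y[te])
    }
  }
  expect_equal(got$curve, colMeans(acc))
  expect_identical(got$d_star, which.max(colMeans(acc)))
})

test_that("a perfectly separating top feature selects d* = 1", {
  set.seed(24)
  X <- cbind(rep(c(0, 10), each = 10) + rnorm(20, sd = 0.1),
             matrix(rnorm(20 * 9), 20, 9))
  y <- rep(c("a", "b"), each = 10)
  ranking <- feature_ranking(fscore(X, y))
  expect_identical(ranking[1], 1L)
  opt <- optimize_feature_count(X, y, ranking, reps = 5, folds = 5, seed = 1)
  expect_identical(opt$d_star, 1L)
  expect_gte(opt$curve[1], 0.99)
})

test_that("pure-noise features give a flat chance-level curve", {
  curves <- sapply(1:5, function(s) {
    X <- crossday:::with_seed(s, matrix(rnorm(24 * 10), 24, 10))
    y <- rep(c("a", "b"), 12)
    optimize_feature_count(X, y, 1:10, reps = 10, folds = 4, seed = s)$curve
  })
  expect_equal(mean(curves), 0.5, tolerance = 0.1)
  # Tie-break contract: d* is the first index attaining the curve maximum.
  opt <- optimize_feature_count(
    crossday:::with_seed(99, matrix(rnorm(24 * 10), 24, 10)),
    rep(c("a", "b"), 12), 1:10, reps = 5, folds = 4, seed = 3)
  expect_identical(opt$d_star, which(opt$curve == max(opt$curve))[1])
})

test_that("a five-day dataset yields the four printed conditions", {
  ds <- tiny_dataset(seed = 30, n_days = 5, trials_per_day = 5)
  rep <- run_adi(ds, "original", reps = 2, folds = 5, seed = 1)
  expect_identical(nrow(rep$results), 4L)
  expect_identical(rep$results$training_days,
                   c("1", "1,2", "1,2,3", "1,2,3,4"))
  expect_identical(rep$results$test_day, c(2, 3, 4, 5))
  expect_true(all(rep$results$accuracy >= 0 & rep$results$accuracy <= 1))
  expect_true(all(rep$results$d_star >= 1 & rep$results$d_star <= 110))
})

test_that("no day shift and a large effect classify almost perfectly", {
  accs <- sapply(1:5, function(s) {
    ds <- tiny_dataset(seed = s, n_days = 2, trials_per_day = 8,
                       day_drift = 0, effect_size = 3, noise_sd = 0.3)
    run_adi(ds, "original", reps = 3, folds = 4, seed = s)$results$accuracy
  })
  expect_gte(mean(accs), 0.95)
})

test_that("test-day data never leak into selection or optimisation", {
  ds <- tiny_dataset(seed = 41, n_days = 3, trials_per_day = 6)
  r1 <- run_adi(ds, "original", reps = 3, folds = 3, seed = 5)
  ds2 <- ds
  ds2$days[[3]]$trials <- lapply(ds2$days[[3]]$trials, function(X)
    crossday:::with_seed(1, matrix(rnorm(length(X)), nrow(X))))
  r2 <- run_adi(ds2, "original", reps = 3, folds = 3, seed = 5)
  # Condition 1 (train day 1, test day 2) untouched; condition 2 trains on
  # days 1-2 and only its test day changed.
  expect_identical(r1$results$d_star, r2$results$d_star)
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$results$accuracy[1], r2$results$accuracy[1])
})

test_that("reports are reproducible under a fixed seed", {
  ds <- tiny_dataset(seed = 42)
  r1 <- run_adi(ds, "original", reps = 3, folds = 3, seed = 9)
  r2 <- run_adi(ds, "original", reps = 3, folds = 3, seed = 9)
  expect_identical(r1, r2)
})

test_that("days lacking a class are rejected", {
  ds <- tiny_dataset(seed = 43)
  ds$days[[2]]$labels[] <- "happiness"
  expect_error(run_adi(ds, "original", reps = 2, folds = 2, seed = 1),
               "lacks")
})
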