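test_that("well-separated clusters separate along axis 1", {
  set.seed(50)
  n <- 30
  X <- rbind(matrix(rnorm(n * 20), n), matrix(rnorm(n * 20, mean = 3), n))
  y <- rep(c("a", "b"), each = n)
  pr <- discriminant_project(X, y)
  gap <- abs(diff(pr$centroids[, 1]))
  spread <- sd(pr$coords[y == "a", 1])
  expect_gt(gap, 10 * spread)
  expect_equal(sqrt(colSums(pr$axes^2)), c(axis1 = 1, axis2 = 1))
  expect_lt(abs(sum(pr$axes[, 1] * pr$axes[, 2])), 1e-8)
  expect_equal(pr$boundary$point, colMeans(pr$centroids))
  expect_equal(pr$boundary$normal, pr$centroids[1, ] - pr$centroids[2, ])
})

test_that("identical clusters have a vanishing centroid gap", {
  set.seed(51)
  base <- matrix(rnorm(30 * 10), 30)
  X <- rbind(base, base)                   # the two classes coincide exactly
  y <- rep(c("a", "b"), each = 30)
  pr <- discriminant_project(X, y)
  expect_equal(unname(abs(diff(pr$centroids[, 1]))), 0)
  expect_equal(unname(abs(diff(pr$centroids[, 2]))), 0)
})

test_that("permuting labels destroys the axis-1 separation", {
  set.seed(52)
  n <- 25
  X <- rbind(matrix(rnorm(n * 15), n), matrix(rnorm(n * 15, mean = 1.5), n))
  y <- rep(c("a", "b"), each = n)
  obs <- abs(diff(discriminant_project(X, y)$centroids[, 1]))
  perm <- replicate(200, {
    abs(diff(discriminant_project(X, sample(y))$centroids[, 1]))
  })
  expect_gt(obs, quantile(perm, 0.95))
})

test_that("importance maps normalise jointly and distances are Euclidean", {
  maps <- importance_maps(list(a = c(0, 5, 10), b = c(2, 4, 6)))
  expect_equal(maps$a, c(0, 0.5, 1))
  expect_equal(maps$b, c(0.2, 0.4, 0.6))
  expect_true(all(unlist(maps) >= 0 & unlist(maps) <= 1))

  expect_identical(map_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  a <- c(1, rep(0, 109)); b <- c(0, 1, rep(0, 108))
  expect_equal(map_distance(a, b), sqrt(2))
  set.seed(53)
  u <- runif(110); v <- runif(110)
  expect_identical(map_distance(u, v), map_distance(v, u))
  expect_error(map_distance(1:3, 1:4), "equal length")
})

test_that("sparse-manner importance concentrates on the true support", {
  # Property analogue of the map comparison, at the pipeline's default
  # lambda rule: the decomposition routes the discriminative structure into
  # the sparse component, so its F-score map carries more support-row mass
  # than the low-rank component's and sits farther from a no-effect
  # control.
  hits <- logical(10)
  for (s in seq_len(10)) {
    ds <- generate_feature_dataset(synthetic_config(
      n_days = 3, trials_per_day = 4, seed = 600 + s))
    ds0 <- generate_feature_dataset(synthetic_config(
      n_days = 3, trials_per_day = 4, effect_size = 0, seed = 600 + s))
    pooled <- function(dataset, part = NULL) {
      vecs <- do.call(rbind, lapply(dataset$days, function(day)
        t(sapply(day$trials, function(X) {
          if (is.null(part)) return(trial_average(X))
          trial_average(rpca(X)[[part]])
        }))))
      labels <- unlist(lapply(dataset$days, `[[`, "labels"))
      fscore(vecs, labels)$F
    }
    fS <- pooled(ds, "S")
    fL <- pooled(ds, "L")
    f0 <- pooled(ds0)
    nm <- importance_maps(list(S = fS, L = fL, ctrl = f0))
    mass <- function(v) sum(v[ds$support]) / max(sum(v), 1e-12)
    hits[s] <- mass(nm$S) > mass(nm$L) &&
      map_distance(nm$S, nm$ctrl) > map_distance(nm$L, nm$ctrl)
  }
  expect_gte(mean(hits), 0.9)
})

test_that("signed-rank p matches exhaustive sign enumeration at n = 8", {
  set.seed(54)
  d <- round(rnorm(8, 0.4, 1), 3)
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  got <- wilcoxon_signed_rank(d)
  # Oracle: all 2^8 sign assignments of the ranked magnitudes.
  r <- rank(abs(d))
  V_obs <- sum(r[d > 0])
  signs <- expand.grid(rep(list(c(0, 1)), 8))
  V_all <- as.matrix(signs) %*% r
  p_exact <- min(1, 2 * min(mean(V_all <= V_obs), mean(V_all >= V_obs)))
  expect_identical(got$statistic, V_obs)
  expect_equal(got$p.value, p_exact)
  # Independent cross-check against the stock implementation.
  wt <- suppressWarnings(stats::wilcox.test(d, exact = TRUE))
  expect_equal(got$p.value, wt$p.value)
})

test_that("uniform positive differences reach the exact minimum p", {
  d <- seq(0.1, 1.2, length.out = 12)
  got <- wilcoxon_signed_rank(d)
  expect_equal(got$statistic, sum(1:12))
  expect_equal(got$p.value, 2 * stats::psignrank(0, 12))
})

test_that("symmetric pairs centre the statistic at its null mean", {
  x <- c(0.3, -0.3, 1.1, -1.1, 2.2, -2.2, 0.7, -0.7)
  got <- wilcoxon_signed_rank(x)
  expect_equal(got$statistic, 8 * 9 / 4)
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "tied")
})
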