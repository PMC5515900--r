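test_that("generator is deterministic and self-consistent", {
  cfg <- synthetic_config(n_days = 3, trials_per_day = 4, seed = 99)
  d1 <- generate_feature_dataset(cfg)
  d2 <- generate_feature_dataset(cfg)
  expect_identical(d1, d2)

  for (d in seq_along(d1$days)) {
    day <- d1$days[[d]]
    for (t in seq_along(day$trials)) {
      tr <- day$truth[[t]]
      expect_identical(day$trials[[t]],
                       tr$background + tr$sparse + tr$noise)
      off <- setdiff(seq_len(110), d1$support)
      expect_true(all(tr$sparse[off, ] == 0))
    }
  }
})

test_that("degenerate config collapses day structure", {
  cfg <- synthetic_config(n_days = 3, trials_per_day = 2, day_drift = 0,
                          noise_sd = 0, effect_size = 0, seed = 5)
  ds <- generate_feature_dataset(cfg)
  # With no drift every day shares the same basis, so same-index trials
  # across days differ only through their V draws: the column spaces agree.
  b1 <- ds$days[[1]]$truth[[1]]$background
  b3 <- ds$days[[3]]$truth[[1]]$background
  sv <- svd(cbind(b1, b3), nu = 0, nv = 0)$d
  expect_equal(sum(sv > 1e-8 * sv[1]), cfg$background_rank)
  expect_true(all(vapply(ds$days, function(day)
    all(vapply(day$truth, function(tr) all(tr$sparse == 0), TRUE)), TRUE)))
})

test_that("class separation on support rows matches the configured effect", {
  # Oracle: direct averaging of trial means over many trials.
  cfg <- synthetic_config(n_days = 1, trials_per_day = 60, day_drift = 0,
                          effect_size = 2, noise_sd = 0.1, seed = 31)
  ds <- generate_feature_dataset(cfg)
  vecs <- t(sapply(ds$days[[1]]$trials, rowMeans))
  lab <- ds$days[[1]]$labels
  gap <- colMeans(vecs[lab == "happiness", ]) -
    colMeans(vecs[lab == "sadness", ])
  expect_equal(mean(abs(gap[ds$support])), 2, tolerance = 0.05)
  expect_lt(mean(abs(gap[-ds$support])), 0.05)

  # Scaling: doubling the effect doubles the empirical gap.
  cfg2 <- synthetic_config(n_days = 1, trials_per_day = 60, day_drift = 0,
                           effect_size = 4, noise_sd = 0.1, seed = 31)
  ds2 <- generate_feature_dataset(cfg2)
  vecs2 <- t(sapply(ds2$days[[1]]$trials, rowMeans))
  gap2 <- colMeans(vecs2[lab == "happiness", ]) -
    colMeans(vecs2[lab == "sadness", ])
  expect_equal(mean(abs(gap2[ds2$support])) / mean(abs(gap[ds$support])),
               2, tolerance = 0.05)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(trials_per_day = 0), "positive integer")
  expect_error(synthetic_config(sparse_support = 200), "sparse_support")
  expect_error(synthetic_config(background_rank = 80),
               "background_rank")
  expect_error(synthetic_config(day_drift = -1), "non-negative")
})

test_that("raw trials carry the configured oscillations", {
  # Single-tone config: all power lands in alpha.
  tr <- generate_raw_trial("neutral", duration = 4, seed = 3,
                           band_amps = c(delta = 0, theta = 0, alpha = 1,
                                         beta = 0, gamma = 0),
                           noise_sd = 0)
  bp <- stft_bandpower(tr)
  frac <- bp$values["alpha", 1, ] / colSums(bp$values[, 1, ])
  expect_true(all(frac > 0.9))

  # Zero-amplitude config is silent.
  tr0 <- generate_raw_trial("neutral", duration = 2, seed = 3,
                            band_amps = c(delta = 0, theta = 0, alpha = 0,
                                          beta = 0, gamma = 0),
                            noise_sd = 0)
  expect_true(all(tr0$samples == 0))

  expect_error(generate_raw_trial("joy"), "unknown label")
  expect_error(generate_raw_trial("happiness", duration = 1), "duration")
})

test_that("class modulation doubles amplitude, quadrupling alpha power", {
  # Oracle: power of a sinusoid scales with amplitude^2; the periodogram of
  # the known tone must show a factor ~4 between the classes.
  # class_gain = sqrt(2): happiness amplitude is 2x sadness on modulated
  # channels, so the alpha power ratio must be ~4.
  ratios <- vapply(1:50, function(s) {
    amps <- c(delta = 0, theta = 0, alpha = 1, beta = 0, gamma = 0)
    h <- generate_raw_trial("happiness", duration = 3, seed = s,
                            band_amps = amps, class_gain = sqrt(2),
                            noise_sd = 0)
    sdn <- generate_raw_trial("sadness", duration = 3, seed = s,
                              band_amps = amps, class_gain = sqrt(2),
                              noise_sd = 0)
    ph <- mean(stft_bandpower(h)$values["alpha", "AF3", ])
    ps <- mean(stft_bandpower(sdn)$values["alpha", "AF3", ])
    ph / ps
  }, 0)
  expect_equal(mean(ratios), 4, tolerance = 0.05 * 4)
})
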