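make_tone_trial <- function(freqs, amps, duration = 5, fs = 128) {
  tt <- (seq_len(duration * fs) - 1) / fs
  x <- rowSums(sapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * tt)))
  raw_trial(matrix(rep(x, each = 12), 12), fs)
}

# Single-bin amplitude estimate of a known tone (the oracle for filter
# attenuation): project onto the complex exponential at f.
tone_amplitude <- function(x, f, fs) {
  n <- length(x)
  tt <- (seq_len(n) - 1) / fs
  2 * abs(sum(x * exp(-2i * pi * f * tt))) / n
}

test_that("high-pass filter nulls DC and preserves the passband", {
  fs <- 128
  dc <- raw_trial(matrix(5, 12, 5 * fs), fs)
  out <- highpass_filter(dc)
  trim <- fs:(4 * fs)
  expect_lt(max(abs(out$samples[1, trim])), 1e-3 * 5)

  tone <- make_tone_trial(10, 1)
  ft <- highpass_filter(tone)
  trim <- (fs + 1):(4 * fs)
  a <- tone_amplitude(ft$samples[1, trim], 10, fs)
  expect_equal(a, 1, tolerance = 0.05)
  expect_identical(ncol(ft$samples), ncol(tone$samples))
})

test_that("drift is removed from a drift + alpha mixture", {
  fs <- 128
  mix <- make_tone_trial(c(0.2, 10), c(1, 1), duration = 10)
  out <- highpass_filter(mix)
  trim <- (fs + 1):(9 * fs)
  slow <- tone_amplitude(out$samples[1, trim], 0.2, fs)
  fast <- tone_amplitude(out$samples[1, trim], 10, fs)
  expect_lt(slow^2, 0.01)               # < 1% of its input power
  expect_equal(fast, 1, tolerance = 0.05)
})

test_that("trial too short for the filter is rejected", {
  expect_error(highpass_filter(raw_trial(matrix(0, 12, 64), 128)),
               "shorter")
})

test_that("window bookkeeping follows the 1-s / 50% scheme", {
  tr <- raw_trial(matrix(rnorm(12 * 37 * 128), 12), 128)
  bp <- stft_bandpower(tr)
  expect_identical(dim(bp$values)[3], 73L)
  expect_true(all(bp$values >= 0))
  expect_error(stft_bandpower(raw_trial(matrix(0, 12, 100), 128)),
               "shorter")
})

test_that("single tone concentrates and silence vanishes", {
  bp <- stft_bandpower(make_tone_trial(10, 1))
  other <- setdiff(names(cd_bands), "alpha")
  for (j in seq_len(dim(bp$values)[3]))
    expect_true(bp$values["alpha", 1, j] >
                  10 * max(bp$values[other, 1, j]))
  bz <- stft_bandpower(raw_trial(matrix(0, 12, 5 * 128), 128))
  expect_true(all(bz$values == 0))
})

test_that("white-noise band powers track band bin counts", {
  # Flat-spectrum oracle: for unit-variance white noise the mean per-bin
  # power is constant, so band means agree across bands.
  set.seed(8)
  tr <- raw_trial(matrix(rnorm(12 * 101 * 128), 12), 128)  # 201 windows
  bp <- stft_bandpower(tr)
  band_means <- apply(bp$values, 1, mean)
  expect_true(all(abs(band_means / mean(band_means) - 1) < 0.1))
})

test_that("total spectral power matches time-domain variance (Parseval)", {
  set.seed(9)
  fs <- 128
  x <- rnorm(fs)
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(fs - 1)) / (fs - 1))
  spec <- abs(fft(x * w))^2
  total <- sum(spec) / fs                  # Parseval: sum |X_k|^2 = N sum x^2
  expect_equal(total, sum((x * w)^2), tolerance = 0.02 * total)
})

test_that("min-max normalisation maps rows to [0, 1]", {
  expect_equal(minmax_normalize(matrix(c(2, 4, 6), 1)),
               matrix(c(0, 0.5, 1), 1))
  expect_equal(minmax_normalize(matrix(7, 1, 4)), matrix(0, 1, 4))
  m <- matrix(c(0, 0.25, 1, 5, 5, 5), 2, byrow = TRUE)
  out <- minmax_normalize(m)
  expect_identical(minmax_normalize(out), out)  # idempotent on [0,1] rows
  set.seed(10)
  r <- matrix(rnorm(50), 5)
  nr <- minmax_normalize(r)
  expect_true(all(nr >= 0 & nr <= 1))
})
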