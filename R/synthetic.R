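#' Configuration for the synthetic multi-day generator
#'
#' Describes a multi-day, feature-level EEG emotion dataset with the
#' statistical structure the decomposition pipeline assumes: every trial
#' matrix is the sum of a day-varying low-rank background, a day-stable
#' row-sparse class component, and i.i.d. Gaussian noise.
#'
#' The background of day `d` lives in an `background_rank`-dimensional
#' subspace spanned by `U_d`. Days drift progressively: the basis and the
#' in-subspace mean offset both follow a random walk (`U_d`
#' re-orthonormalised from `U_{d-1}` plus a `day_drift`-scaled Gaussian
#' step; `a_d = a_{d-1}` plus a `day_drift`-scaled Gaussian step), so an
#' unseen later day always sits outside the span of the training days — the
#' mechanism by which cross-day classifiers trained on raw features fail.
#' The offset lives *inside* the background subspace (`U_d a_d`), keeping
#' every trial's background, including its day-specific mean level, exactly
#' rank `background_rank`. The class component occupies `sparse_support`
#' fixed feature rows, constant within a trial, with the two emotion classes
#' separated by `effect_size` on every support row (random sign per row,
#' identical across days).
#'
#' @param n_days Number of recording days (default 5).
#' @param trials_per_day Trials per class per day (default 12, i.e. 24
#'   labelled trials a day as in a paired happy/sad music protocol).
#' @param n_features Feature dimension (default 110, the MESH dimension).
#' @param background_rank Rank `r` of the per-day background (default 4).
#' @param day_drift Non-negative magnitude of the per-day background
#'   perturbation: rotation of the subspace and the in-subspace mean offset
#'   both scale with it. 0 means every day is statistically identical.
#' @param sparse_support Number `k` of class-discriminative feature rows.
#' @param effect_size Mean separation between the classes on each support row.
#' @param noise_sd Standard deviation of the i.i.d. feature-level noise.
#' @param windows_per_trial Columns per trial matrix (default 73, the window
#'   count of a 37-s trial at a 1-s window and 0.5-s hop).
#' @param background_scale Scale of the background loadings (default 1).
#' @param seed Master seed; all randomness flows from it through documented
#'   substreams (basis, per-day, per-trial).
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(n_days = 5, trials_per_day = 12,
                             n_features = 110, background_rank = 4,
                             day_drift = 12, sparse_support = 10,
                             effect_size = 1.5, noise_sd = 0.5,
                             windows_per_trial = 73,
                             background_scale = 1, seed = 1) {
  cfg <- list(n_days = n_days, trials_per_day = trials_per_day,
              n_features = n_features, background_rank = background_rank,
              day_drift = day_drift, sparse_support = sparse_support,
              effect_size = effect_size, noise_sd = noise_sd,
              windows_per_trial = windows_per_trial,
              background_scale = background_scale, seed = seed)
  counts <- c("n_days", "trials_per_day", "n_features", "background_rank",
              "windows_per_trial")
  for (f in counts) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 1 || v != round(v))
      stop(sprintf("`%s` must be a positive integer", f))
  }
  if (cfg$sparse_support < 0 || cfg$sparse_support > cfg$n_features)
    stop("`sparse_support` must lie in [0, n_features]")
  if (cfg$background_rank >= min(cfg$n_features, cfg$windows_per_trial))
    stop("`background_rank` must be < min(n_features, windows_per_trial)")
  if (cfg$day_drift < 0) stop("`day_drift` must be non-negative")
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  structure(cfg, class = "synthetic_config")
}

# Orthonormal basis from a perturbed seed matrix, sign-fixed so the result is
# deterministic across LAPACK builds.
orthonormalize <- function(M) {
  Q <- qr.Q(qr(M))
  flip <- apply(Q, 2, function(col) {
    j <- which(abs(col) > 1e-12)[1]
    if (is.na(j) || col[j] >= 0) 1 else -1
  })
  sweep(Q, 2, flip, `*`)
}

#' Generate a synthetic feature-level multi-day dataset
#'
#' Draws a dataset according to a [synthetic_config()]: for each day a
#' background basis and in-subspace mean offset, for each trial a low-rank
#' background realisation plus the day-stable class component plus noise.
#' Ground truth (background, sparse component, noise, support rows) is
#' retained so that decomposition quality can be measured directly.
#'
#' The emitted object has one entry per day; each day holds `2 *
#' trials_per_day` trials with alternating `happiness` / `sadness` labels.
#' Trial matrices satisfy `X == background + sparse + noise` exactly by
#' construction.
#'
#' @param config A [synthetic_config()].
#' @return An object of class `"cd_dataset"`: a list with elements
#'   `days` (per day: `trials` — list of `n_features x windows_per_trial`
#'   matrices — `labels`, and `truth` with per-trial `background`, `sparse`,
#'   `noise`), `support` (index vector of discriminative rows),
#'   `effect_signs` (the per-row sign of the happiness minus sadness
#'   contrast), and `config`.
#' @examples
#' ds <- generate_feature_dataset(synthetic_config(n_days = 2,
#'   trials_per_day = 3, seed = 42))
#' length(ds$days)
#' dim(ds$days[[1]]$trials[[1]])
#' @export
generate_feature_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, as.list(config))
  p <- config$n_features
  r <- config$background_rank
  w <- config$windows_per_trial
  k <- config$sparse_support

  # Substream 0: common basis, support rows, effect signs.
  base <- with_seed(substream_seed(config$seed, 0), {
    U0 <- orthonormalize(matrix(stats::rnorm(p * r), p, r))
    support <- sort(sample.int(p, k))
    signs <- sample(c(-1, 1), k, replace = TRUE)
    list(U0 = U0, support = support, signs = signs)
  })

  # Class component: constant within a trial, identical across days.
  # Happiness sits at +effect/2 * sign, sadness at -effect/2 * sign, so the
  # class-mean gap on every support row is exactly `effect_size`.
  class_shift <- function(label) {
    v <- numeric(p)
    if (k > 0) {
      s <- if (label == "happiness") 0.5 else -0.5
      v[base$support] <- s * config$effect_size * base$signs
    }
    v
  }

  days <- vector("list", config$n_days)
  U_prev <- base$U0
  a_prev <- rep(0, r)
  for (d in seq_len(config$n_days)) {
    day_par <- with_seed(substream_seed(config$seed, d), {
      G <- matrix(stats::rnorm(p * r), p, r)
      # Random-walk rotation: perturb the previous day's basis by a
      # day_drift-scaled Gaussian step (column norm ~ 0.15 * day_drift
      # relative to the unit-norm columns).
      Ud <- orthonormalize(U_prev + 0.15 * config$day_drift * G / sqrt(p))
      # Random-walk mean offset inside the background subspace.
      a <- a_prev + stats::rnorm(r, sd = config$day_drift)
      list(Ud = Ud, a = a)
    })
    U_prev <- day_par$Ud
    a_prev <- day_par$a
    n_trials <- 2L * config$trials_per_day
    labels <- rep(c("happiness", "sadness"), config$trials_per_day)
    trials <- vector("list", n_trials)
    truth <- vector("list", n_trials)
    for (t in seq_len(n_trials)) {
      tr <- with_seed(substream_seed(config$seed, 1000 * d + t), {
        V <- matrix(stats::rnorm(w * r), w, r)
        noise <- matrix(stats::rnorm(p * w, sd = config$noise_sd), p, w)
        list(V = V, noise = noise)
      })
      background <- config$background_scale *
        (day_par$Ud %*% (t(tr$V) + day_par$a))
      sparse <- matrix(class_shift(labels[t]), p, w)
      trials[[t]] <- background + sparse + tr$noise
      truth[[t]] <- list(background = background, sparse = sparse,
                         noise = tr$noise)
    }
    days[[d]] <- list(trials = trials, labels = labels, truth = truth,
                      day = d)
  }

  structure(list(days = days, support = base$support,
                 effect_signs = base$signs, config = config),
            class = "cd_dataset")
}

#' @export
print.cd_dataset <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "Synthetic multi-day feature dataset\n  %d days x %d trials (%d per class), %d features x %d windows\n  background rank %d, day drift %.3g, support size %d, effect %.3g, noise sd %.3g\n",
    cfg$n_days, 2 * cfg$trials_per_day, cfg$trials_per_day, cfg$n_features,
    cfg$windows_per_trial, cfg$background_rank, cfg$day_drift,
    cfg$sparse_support, cfg$effect_size, cfg$noise_sd))
  invisible(x)
}

#' Generate a synthetic raw EEG trial
#'
#' Emits a 12-channel time-domain signal built from one band-limited sinusoid
#' per stereotypical frequency band (delta 2 Hz, theta 6 Hz, alpha 10 Hz,
#' beta 22 Hz, gamma 37 Hz; random phase per channel) plus 1/f pink noise.
#' Alpha and gamma amplitudes on `modulated_channels` are scaled by
#' `class_gain` for `happiness` and by `1 / class_gain` for `sadness`,
#' mimicking class-dependent oscillatory power; `neutral` and `baseline`
#' trials are unmodulated. The per-channel, per-band amplitudes actually used
#' are stored as the `amplitudes` attribute (ground truth).
#'
#' @param label One of `happiness`, `sadness`, `neutral`, `baseline`.
#' @param sampling_rate Sampling rate in Hz (default 128).
#' @param duration Trial length in seconds (default 37); must be >= 2.
#' @param seed Integer seed.
#' @param band_amps Named numeric vector of base amplitudes per band
#'   (microvolts); names must match `names(cd_bands)`.
#' @param modulated_channels Channels whose alpha/gamma amplitudes carry the
#'   class modulation.
#' @param class_gain Multiplicative class modulation (>= 1).
#' @param noise_sd Standard deviation of the additive 1/f noise (0 disables).
#' @param day,trial Metadata indices carried through.
#' @return A `"raw_trial"`: list with `samples` (12 x time matrix, rownames =
#'   electrode labels), `sampling_rate`, `day`, `trial`, `label`, and an
#'   `amplitudes` attribute (channels x bands).
#' @export
generate_raw_trial <- function(label, sampling_rate = 128, duration = 37,
                               seed = 1,
                               band_amps = c(delta = 1, theta = 1, alpha = 1,
                                             beta = 1, gamma = 1),
                               modulated_channels = c("AF3", "F3", "F4", "AF4"),
                               class_gain = 2, noise_sd = 0.5,
                               day = 1L, trial = 1L) {
  if (!label %in% cd_labels) stop("unknown label: ", label)
  if (duration < 2) stop("`duration` must be >= 2 seconds")
  if (!all(names(cd_bands) %in% names(band_amps)))
    stop("`band_amps` must name all five bands")
  tone_freq <- c(delta = 2, theta = 6, alpha = 10, beta = 22, gamma = 37)
  n <- round(duration * sampling_rate)
  tt <- (seq_len(n) - 1) / sampling_rate

  gain <- switch(label, happiness = class_gain,
                 sadness = 1 / class_gain, 1)
  amps <- matrix(rep(band_amps[names(cd_bands)], each = 12), nrow = 12,
                 dimnames = list(cd_channels, names(cd_bands)))
  mod <- cd_channels %in% modulated_channels
  amps[mod, c("alpha", "gamma")] <- amps[mod, c("alpha", "gamma")] * gain

  samples <- with_seed(substream_seed(seed, 0), {
    out <- matrix(0, 12, n, dimnames = list(cd_channels, NULL))
    for (ch in seq_len(12)) {
      x <- numeric(n)
      for (b in names(cd_bands)) {
        phase <- stats::runif(1, 0, 2 * pi)
        x <- x + amps[ch, b] * sin(2 * pi * tone_freq[[b]] * tt + phase)
      }
      if (noise_sd > 0) x <- x + pink_noise(n, sampling_rate, noise_sd)
      out[ch, ] <- x
    }
    out
  })

  structure(list(samples = samples, sampling_rate = sampling_rate,
                 day = day, trial = trial, label = label),
            class = "raw_trial", amplitudes = amps)
}

# 1/f ("pink") noise via spectral shaping: white Gaussian Fourier
# coefficients scaled by 1/sqrt(f), rescaled to the requested sd.
pink_noise <- function(n, sampling_rate, sd) {
  freqs <- seq(0, sampling_rate / 2, by = sampling_rate / n)
  nf <- length(freqs)
  mag <- c(0, 1 / sqrt(freqs[-1]))
  spec <- complex(real = stats::rnorm(nf), imaginary = stats::rnorm(nf)) * mag
  full <- c(spec, Conj(rev(spec[2:(n - nf + 1)])))
  x <- Re(stats::fft(full, inverse = TRUE)) / n
  s <- stats::sd(x)
  if (s == 0) return(numeric(n))
  x / s * sd
}
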