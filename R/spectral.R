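#' Construct a raw EEG trial object
#'
#' Thin validating constructor for epoched multi-channel EEG used by the
#' extraction stage. Channels must be the 12-electrode montage of
#' [cd_channels] (the 14-channel consumer headset minus T7/T8).
#'
#' @param samples Channels x time numeric matrix, rownames = electrode labels.
#' @param sampling_rate Sampling rate in Hz; must exceed twice the highest
#'   band edge (43 Hz).
#' @param day,trial Integer metadata.
#' @param label One of [cd_labels].
#' @return A `"raw_trial"` object.
#' @export
raw_trial <- function(samples, sampling_rate = 128, day = 1L, trial = 1L,
                      label = "neutral") {
  samples <- as.matrix(samples)
  if (is.null(rownames(samples))) {
    if (nrow(samples) != 12)
      stop("`samples` must have 12 rows (or electrode rownames)")
    rownames(samples) <- cd_channels
  }
  missing <- setdiff(cd_channels, rownames(samples))
  if (length(missing) > 0)
    stop("missing channel(s): ", paste(missing, collapse = ", "))
  samples <- samples[cd_channels, , drop = FALSE]
  if (sampling_rate <= 2 * 43)
    stop("`sampling_rate` must exceed 86 Hz (twice the top band edge)")
  if (!label %in% cd_labels) stop("unknown label: ", label)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 day = as.integer(day), trial = as.integer(trial),
                 label = label),
            class = "raw_trial")
}

# Linear-phase high-pass FIR: Hamming-windowed sinc low-pass, spectrally
# inverted. Taps = one sampling-rate's worth, rounded up to odd.
highpass_taps <- function(sampling_rate, cutoff) {
  ntaps <- round(sampling_rate)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  m <- ntaps - 1
  k <- 0:m
  fc <- cutoff / sampling_rate
  x <- 2 * fc * (k - m / 2)
  lp <- ifelse(x == 0, 2 * fc, 2 * fc * sin(pi * x) / (pi * x))
  w <- 0.54 - 0.46 * cos(2 * pi * k / m)
  lp <- lp * w
  lp <- lp / sum(lp)          # unit DC gain => exact DC null after inversion
  hp <- -lp
  hp[m / 2 + 1] <- hp[m / 2 + 1] + 1
  hp
}

#' High-pass filter an EEG trial
#'
#' Removes DC level and sub-cutoff drift with a linear-phase FIR filter
#' (Hamming-windowed sinc design, one sampling-rate's worth of taps rounded to
#' odd). The signal is reflection-padded, convolved, and trimmed with group
#' delay compensation so the output has the input's length and alignment. The
#' design gives an exact null at DC and < 1 dB passband ripple above twice the
#' cutoff.
#'
#' @param trial A [raw_trial()].
#' @param cutoff High-pass cutoff in Hz (default 1).
#' @return The trial with filtered `samples`.
#' @export
highpass_filter <- function(trial, cutoff = 1) {
  stopifnot(inherits(trial, "raw_trial"))
  h <- highpass_taps(trial$sampling_rate, cutoff)
  n <- ncol(trial$samples)
  if (n <= length(h))
    stop("trial shorter than the filter length (", length(h), " samples)")
  half <- (length(h) - 1) / 2
  trial$samples <- t(apply(trial$samples, 1, fir_apply, h = h, half = half))
  trial
}

# Reflection-pad, convolve, trim at the group delay.
fir_apply <- function(x, h, half) {
  n <- length(x)
  pad_l <- rev(x[2:(half + 1)])
  pad_r <- rev(x[(n - half):(n - 1)])
  xp <- c(pad_l, x, pad_r)
  y <- stats::convolve(xp, rev(h), type = "open")
  y[(2 * half + 1):(2 * half + n)]
}

#' Short-time Fourier band power
#'
#' Slices a trial into 1-s Hamming-windowed segments with 50% overlap, takes
#' the one-sided scaled periodogram of each segment (FFT length = window
#' length, Welch normalisation `fs * sum(w^2)`, interior bins doubled), and
#' averages the power over the FFT bins whose centre frequency falls inside
#' each of the five bands (edges inclusive). A 37-s trial at 128 Hz yields 73
#' windows.
#'
#' @param trial A (high-pass filtered) [raw_trial()].
#' @param window_sec Window length in seconds (default 1).
#' @param overlap Fractional overlap between consecutive windows (default
#'   0.5).
#' @return A `"band_power"` object: list with `values` (band x channel x
#'   window array), `window_times` (window start times, s), `bands`,
#'   `sampling_rate`, and the trial metadata.
#' @export
stft_bandpower <- function(trial, window_sec = 1, overlap = 0.5) {
  stopifnot(inherits(trial, "raw_trial"))
  fs <- trial$sampling_rate
  W <- round(window_sec * fs)
  hop <- round(W * (1 - overlap))
  n <- ncol(trial$samples)
  if (n < W) stop("trial shorter than one analysis window")
  n_win <- floor((n - W) / hop) + 1
  k <- 0:(W - 1)
  w <- 0.54 - 0.46 * cos(2 * pi * k / (W - 1))
  U <- fs * sum(w^2)
  nbin <- floor(W / 2) + 1
  bin_freq <- (0:(nbin - 1)) * fs / W
  scale <- rep(2, nbin)
  scale[1] <- 1
  if (W %% 2 == 0) scale[nbin] <- 1
  band_bins <- lapply(cd_bands, function(e)
    which(bin_freq >= e[1] & bin_freq <= e[2]))

  channels <- rownames(trial$samples)
  values <- array(0, dim = c(length(cd_bands), length(channels), n_win),
                  dimnames = list(names(cd_bands), channels, NULL))
  for (j in seq_len(n_win)) {
    idx <- ((j - 1) * hop + 1):((j - 1) * hop + W)
    seg <- trial$samples[, idx, drop = FALSE] *
      matrix(w, nrow(trial$samples), W, byrow = TRUE)
    spec <- stats::mvfft(t(seg))[seq_len(nbin), , drop = FALSE]
    pw <- (Mod(spec)^2) * scale / U
    for (b in seq_along(band_bins))
      values[b, , j] <- colMeans(pw[band_bins[[b]], , drop = FALSE])
  }
  structure(list(values = values,
                 window_times = (seq_len(n_win) - 1) * hop / fs,
                 bands = cd_bands, sampling_rate = fs,
                 day = trial$day, trial = trial$trial, label = trial$label),
            class = "band_power")
}

#' Min-max normalisation of feature rows
#'
#' Maps each row of a feature time-series matrix to `[0, 1]` by
#' `(x - min) / (max - min)` over the columns supplied (the normalisation
#' scope). Degenerate (constant) rows map to all zeros, keeping the output
#' bounded and deterministic.
#'
#' @param x Numeric matrix (features x samples) or vector.
#' @return Object of the same shape with every entry in `[0, 1]`.
#' @export
minmax_normalize <- function(x) {
  if (is.null(dim(x))) {
    rng <- range(x)
    if (diff(rng) == 0) return(x * 0)
    return((x - rng[1]) / diff(rng))
  }
  lo <- apply(x, 1, min)
  hi <- apply(x, 1, max)
  span <- hi - lo
  out <- (x - lo) / ifelse(span == 0, 1, span)
  out[span == 0, ] <- 0
  out
}
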